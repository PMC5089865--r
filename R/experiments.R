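#' Establishment criterion for an evolved spatial repellent
#'
#' A repellent counts as established when the population comprises at least
#' `threshold` deflected phenotypes (deflected + resistant-deflected) at
#' cycle `at_cycle`. Ties at exactly the threshold count as established.
#'
#' @param threshold Proportion in (0, 1\] (default 0.80).
#' @param at_cycle Cycle at which the proportion is read (default 300).
#' @return A list of class `"establishment_criterion"`.
#' @export
establishment_criterion <- function(threshold = 0.80, at_cycle = 300L) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  at_cycle <- as.integer(at_cycle)
  stopifnot(at_cycle >= 1L)
  structure(list(threshold = threshold, at_cycle = at_cycle),
            class = "establishment_criterion")
}

#' Classify a run against the establishment criterion
#'
#' @param ts An `"esr_timeseries"`.
#' @param criterion An [establishment_criterion()].
#' @return `TRUE` iff the deflected-phenotype proportion at the criterion's
#'   cycle meets or exceeds its threshold.
#' @export
classify_establishment <- function(ts, criterion = establishment_criterion()) {
  stopifnot(inherits(criterion, "establishment_criterion"))
  row <- match(criterion$at_cycle, ts$cycle)
  if (is.na(row)) {
    stop("time series too short: no cycle ", criterion$at_cycle)
  }
  deflected_proportion(ts)[row] >= criterion$threshold
}

#' Single insecticide swap at peak deflection ("ratchet")
#'
#' Runs the scenario once, finds the maximum deflection-allele frequency
#' achieved while using the first insecticide, then simulates replacing the
#' insecticide with a new one to which resistance is still rare: a fresh run
#' initialized at linkage equilibrium with `init_D_freq` equal to that
#' maximum and `init_R_freq = reset_R_freq`.
#'
#' @param s An `"esr_scenario"`.
#' @param reset_R_freq Resistance-allele prevalence against the replacement
#'   insecticide (default 0.005).
#' @param criterion An [establishment_criterion()] applied to the second run;
#'   defaults to the 80% threshold read at the scenario's own horizon.
#' @param clock `"from-swap"` (default): the second run gets the scenario's
#'   full cycle count, so the criterion is read `at_cycle` cycles after the
#'   swap. `"from-start"`: the second run only covers the cycles remaining
#'   after the swap, so the criterion clock runs from first introduction.
#' @return List with elements `first`, `second` (time series), `established`
#'   (classification of the second run), `max_D` and `swap_cycle`.
#' @export
ratchet_run <- function(s, reset_R_freq = 0.005,
                        criterion = NULL,
                        clock = c("from-swap", "from-start")) {
  stopifnot(inherits(s, "esr_scenario"))
  if (is.null(criterion)) {
    criterion <- establishment_criterion(0.80, s$life_history$n_cycles)
  }
  clock <- match.arg(clock)
  first <- run_scenario(s)
  i_max <- which.max(first$allele_D_freq)
  max_D <- first$allele_D_freq[i_max]
  swap_cycle <- first$cycle[i_max]
  s2 <- s
  s2$init_R_freq <- reset_R_freq
  s2$init_D_freq <- max_D
  n2 <- if (clock == "from-swap") {
    s$life_history$n_cycles
  } else {
    max(1L, s$life_history$n_cycles - as.integer(swap_cycle))
  }
  second <- run_scenario(s2, n_cycles = n2)
  established <- if (clock == "from-swap") {
    classify_establishment(second, criterion)
  } else {
    # criterion cycle counted from first introduction
    crit2 <- establishment_criterion(criterion$threshold,
                                     max(1L, criterion$at_cycle - as.integer(swap_cycle)))
    classify_establishment(second, crit2)
  }
  list(first = first, second = second, established = established,
       max_D = max_D, swap_cycle = swap_cycle)
}

# scenario template with one grid cell's survivals substituted;
# U follows F_R (no cost of resistance on the non-deflected resistant)
.grid_cell_scenario <- function(template, F_R, F_D, F_RD = F_D,
                                blend_w = NULL) {
  f0 <- template$fitness
  if (!is.null(blend_w)) F_RD <- blend_w * F_D + (1 - blend_w) * F_R
  s <- template
  s$fitness <- structure(c(F_S = f0[["F_S"]], F_R = F_R,
                           F_D = F_D, F_RD = F_RD),
                         class = "phenotype_fitness")
  s$U <- F_R
  s
}

#' Scan combinations of resistant and deflected per-cycle survival
#'
#' For each combination of resistant survival (x axis) and deflected survival
#' (y axis), runs the scenario template with those survivals (resistant-
#' deflected survival equal to the deflected survival unless `blend_w` is
#' given) and classifies establishment. Cells that fail directly are retried
#' with a single insecticide swap when `with_ratchet = TRUE`.
#'
#' @param template An `"esr_scenario"` providing every other parameter.
#' @param resistant_range,deflected_range Length-2 numeric ranges in \[0, 1\].
#' @param step Grid increment (default 0.01).
#' @param with_ratchet Retry failing cells via [ratchet_run()] (default TRUE).
#' @param blend_w Optional blend weight passed to the resistant-deflected
#'   survival: `F_RD = blend_w * F_D + (1 - blend_w) * F_R`.
#' @param criterion An [establishment_criterion()]; defaults to the 80%
#'   threshold read at the template's own horizon.
#' @param clock Ratchet clock, see [ratchet_run()].
#' @return Long-format data frame of class `"esr_grid"` with columns
#'   `resistant_survival`, `deflected_survival`, `classification`
#'   (factor: `direct`, `ratchet`, `fail`).
#' @export
grid_scan <- function(template,
                      resistant_range = c(0.30, 0.70),
                      deflected_range = c(0.20, 0.60),
                      step = 0.01,
                      with_ratchet = TRUE,
                      blend_w = NULL,
                      criterion = NULL,
                      clock = c("from-swap", "from-start")) {
  if (is.null(criterion)) {
    criterion <- establishment_criterion(0.80, template$life_history$n_cycles)
  }
  stopifnot(inherits(template, "esr_scenario"),
            all(resistant_range >= 0), all(resistant_range <= 1),
            all(deflected_range >= 0), all(deflected_range <= 1))
  clock <- match.arg(clock)
  fr <- seq(resistant_range[1], resistant_range[2], by = step)
  fd <- seq(deflected_range[1], deflected_range[2], by = step)
  cells <- expand.grid(resistant_survival = fr, deflected_survival = fd,
                       KEEP.OUT.ATTRS = FALSE)
  cls <- character(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    s <- .grid_cell_scenario(template, cells$resistant_survival[k],
                             cells$deflected_survival[k], blend_w = blend_w)
    if (classify_establishment(run_scenario(s), criterion)) {
      cls[k] <- "direct"
    } else if (with_ratchet &&
               ratchet_run(s, criterion = criterion, clock = clock)$established) {
      cls[k] <- "ratchet"
    } else {
      cls[k] <- "fail"
    }
  }
  cells$classification <- factor(cls, levels = c("direct", "ratchet", "fail"))
  class(cells) <- c("esr_grid", class(cells))
  cells
}

#' Lowest cost of resistance that rescues establishment
#'
#' For each survival combination, finds the smallest cost of resistance
#' (COR) on the resistant-deflected phenotype -- its per-cycle survival is
#' the deflected survival less the COR -- for which the run establishes,
#' without any ratchet. Resistant (non-deflected) survival is taken net of
#' any cost it bears. Cells establishing at no tested COR get `NA`.
#'
#' @inheritParams grid_scan
#' @param cor_values Ascending costs of resistance to try (default 0 to 0.2
#'   in steps of 0.05).
#' @return Data frame of class `"esr_grid"` with columns
#'   `resistant_survival`, `deflected_survival`, `min_cor`.
#' @export
min_cor_scan <- function(template,
                         cor_values = seq(0, 0.20, by = 0.05),
                         resistant_range = c(0.30, 0.70),
                         deflected_range = c(0.20, 0.60),
                         step = 0.01,
                         criterion = NULL) {
  if (is.null(criterion)) {
    criterion <- establishment_criterion(0.80, template$life_history$n_cycles)
  }
  stopifnot(inherits(template, "esr_scenario"),
            !is.unsorted(cor_values), all(cor_values >= 0),
            all(cor_values <= 1))
  fr <- seq(resistant_range[1], resistant_range[2], by = step)
  fd <- seq(deflected_range[1], deflected_range[2], by = step)
  cells <- expand.grid(resistant_survival = fr, deflected_survival = fd,
                       KEEP.OUT.ATTRS = FALSE)
  min_cor <- rep(NA_real_, nrow(cells))
  for (k in seq_len(nrow(cells))) {
    FR <- cells$resistant_survival[k]
    FD <- cells$deflected_survival[k]
    for (cor in cor_values) {
      if (cor > FD) break  # survival below zero is not a valid phenotype
      s <- .grid_cell_scenario(template, FR, FD, F_RD = FD - cor)
      if (classify_establishment(run_scenario(s), criterion)) {
        min_cor[k] <- cor
        break
      }
    }
  }
  cells$min_cor <- min_cor
  class(cells) <- c("esr_grid", class(cells))
  cells
}

#' Relative infectious bites with and without an evolved spatial repellent
#'
#' Reproduces the transmission comparison: a no-intervention baseline, an
#' unpaired insecticide, and the repellent + insecticide combination at
#' per-feed acquisition probabilities for deflected mosquitoes of 4%, 2%, 1%
#' and 0% (100%, 50%, 25% and 0% of the non-deflected value under the
#' default template). Each intervention series is expressed as infectious
#' bites per cycle relative to the baseline.
#'
#' @param template An `"esr_scenario"` (typically [baseline_scenario()]).
#' @param p_deflected Acquisition probabilities for deflected phenotypes.
#' @return Data frame with columns `cycle`, `transient`,
#'   `insecticide_only`, and one `esr_p*` column per acquisition value.
#' @export
relative_bites_experiment <- function(template,
                               p_deflected = c(0.04, 0.02, 0.01, 0)) {
  stopifnot(inherits(template, "esr_scenario"))
  base_s <- template
  base_s$intervention_mode <- "none"
  baseline <- run_scenario(base_s)

  ins_s <- template
  ins_s$intervention_mode <- "insecticide_only"
  out <- relative_infectious_bites(run_scenario(ins_s), baseline)
  names(out)[names(out) == "relative_bites"] <- "insecticide_only"

  for (p in p_deflected) {
    s <- template
    s$intervention_mode <- "esr_plus_insecticide"
    s$infection$p_acquire_deflected <- p
    rel <- relative_infectious_bites(run_scenario(s), baseline)
    out[[sprintf("esr_p%03d", round(1000 * p))]] <- rel$relative_bites
  }
  out[c("cycle", "transient", "insecticide_only",
        sprintf("esr_p%03d", round(1000 * p_deflected)))]
}
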