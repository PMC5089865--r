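#' Initialize the adult population and juvenile queue for a scenario
#'
#' Genotype frequencies start at Hardy-Weinberg and linkage equilibrium for
#' the scenario's initial allele prevalences. The standing adult population
#' is the pre-intervention equilibrium `recruits_per_cycle / (1 - U)` (the
#' sum of a geometric age structure under the no-intervention survival `U`);
#' all adults are uninfected and carry the equilibrium gamete pool as stored
#' sperm. The juvenile development queue is filled with the initial zygote
#' distribution.
#'
#' The state aggregates the cohort structure into two exact linear margins:
#' counts by (genotype x stored-sperm haplotype), which reproduction needs,
#' and counts by (genotype x infection stage), which transmission needs.
#' Survival and infection depend only on genotype and reproduction is linear
#' in the sperm pool, so the two margins evolve exactly as the full
#' cohort-resolved state would.
#'
#' @param s An `"esr_scenario"`.
#' @return A list of class `"esr_population"` with elements `N_gh` (9 x 4
#'   matrix), `N_gs` (9 x stages matrix: uninfected, incubating 1..k,
#'   infectious), `queue` (list of genotype distributions, oldest first),
#'   `cycle`, and `bites` (infectious bites emitted in the last step).
#' @export
initialize_population <- function(s) {
  stopifnot(inherits(s, "esr_scenario"))
  hle <- le_haplotypes(s$init_R_freq, s$init_D_freq)
  geno <- zygote_distribution(hle, hle)
  total <- s$life_history$recruits_per_cycle / (1 - s$U)
  n_stages <- s$infection$incubation_cycles + 2L
  N_gs <- matrix(0, 9, n_stages,
                 dimnames = list(.GENO_NAMES,
                                 c("uninfected",
                                   if (s$infection$incubation_cycles > 0)
                                     paste0("incubating_", seq_len(s$infection$incubation_cycles)),
                                   "infectious")))
  N_gs[, 1] <- total * geno
  N_gh <- total * outer(geno, unclass(hle))
  queue <- replicate(s$life_history$development_cycles, geno,
                     simplify = FALSE)
  structure(list(N_gh = N_gh, N_gs = N_gs, queue = queue,
                 cycle = 0L, bites = 0),
            class = "esr_population")
}

#' Advance the population by one feeding cycle
#'
#' Event order within a cycle: (1) per-phenotype survival; (2) survivors
#' feed -- uninfected adults acquire infection with their phenotype's
#' per-feed probability and incubating adults advance one cycle; (3)
#' infectious surviving feeders emit `count * p_infectious_bite` infectious
#' bites; (4) every surviving female contributes one unit of zygotes (her
#' gametes crossed with her stored sperm pool) to the pool entering the back
#' of the juvenile queue; (5) the front of the queue emerges as
#' `recruits_per_cycle` new adults, mated immediately within their own
#' cohort. An empty population yields a zero-emission steady state, not an
#' error.
#'
#' @param state An `"esr_population"`.
#' @param s The `"esr_scenario"` being run.
#' @return The updated `"esr_population"`; `$bites` holds this cycle's
#'   infectious bites.
#' @export
step_cycle <- function(state, s) {
  stopifnot(inherits(state, "esr_population"), inherits(s, "esr_scenario"))
  surv_g <- unname(phenotype_survival(s)[.GENO_PHENO])
  acq_g <- unname(.phenotype_acquisition(s)[.GENO_PHENO])
  inc <- s$infection$incubation_cycles
  n_stages <- inc + 2L

  # (1) survival
  N_gh <- state$N_gh * surv_g
  N_gs <- state$N_gs * surv_g

  # (2) feed: acquisition and incubation progress
  old <- N_gs
  N_gs[, 1] <- old[, 1] * (1 - acq_g)
  if (inc > 0L) {
    N_gs[, 2] <- old[, 1] * acq_g
    if (inc > 1L) {
      for (j in 3:(inc + 1L)) N_gs[, j] <- old[, j - 1L]
    }
    N_gs[, n_stages] <- old[, n_stages] + old[, inc + 1L]
  } else {
    N_gs[, 2] <- old[, 2] + old[, 1] * acq_g
  }

  # (3) infectious bites by surviving feeders
  bites <- sum(N_gs[, n_stages]) * s$infection$p_infectious_bite

  # (4) oviposition: female gametes crossed with stored sperm
  pair_mass <- .GAMETE_MAT %*% N_gh          # [female gamete, male gamete]
  zygotes <- drop(.ZYGOTE_MAP %*% as.vector(pair_mass))
  tot <- sum(zygotes)
  q_new <- if (tot > 0) zygotes / tot else zygotes * 0

  # (5) recruitment from the front of the queue, then enqueue this cycle's pool
  queue <- c(state$queue, list(q_new))
  q0 <- queue[[1]]
  queue <- queue[-1]
  if (sum(q0) > 0) {
    recruits <- s$life_history$recruits_per_cycle * q0
    sperm <- drop(.GAMETE_MAT %*% q0)
    sperm <- sperm / sum(sperm)
    N_gh <- N_gh + outer(recruits, sperm)
    N_gs[, 1] <- N_gs[, 1] + recruits
  }

  structure(list(N_gh = N_gh, N_gs = N_gs, queue = queue,
                 cycle = state$cycle + 1L, bites = bites),
            class = "esr_population")
}

# summary row of a population state (proportions, counts, bites)
.state_row <- function(state) {
  counts <- rowSums(state$N_gs)
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts * 0
  phen <- vapply(1:4, function(p) sum(freq[.GENO_PHENO == p]), numeric(1))
  c(cycle = state$cycle,
    stats::setNames(freq, paste0("freq_", gsub("/", "_", .GENO_NAMES))),
    allele_R_freq = sum(freq * .GENO_R) / 2,
    allele_D_freq = sum(freq * .GENO_D) / 2,
    stats::setNames(phen, paste0("phen_", c("susceptible", "resistant",
                                            "deflected", "resistant_deflected"))),
    adult_count = total,
    infectious_bites = state$bites)
}

#' Run a scenario for its full length
#'
#' Deterministic simulation of `n_cycles` feeding cycles. The returned time
#' series has one row for the initial state (cycle 0, zero bites) and one
#' per simulated cycle, recording genotype frequencies, allele frequencies
#' at both loci, phenotype proportions, adult population size and infectious
#' bites. Repeat runs are bit-for-bit identical.
#'
#' @param s An `"esr_scenario"`.
#' @param n_cycles Optional override of the scenario's cycle count.
#' @return A data frame of class `"esr_timeseries"`.
#' @examples
#' ts <- run_scenario(baseline_scenario(), n_cycles = 50)
#' tail(ts[, c("cycle", "allele_D_freq", "infectious_bites")])
#' @export
run_scenario <- function(s, n_cycles = NULL) {
  stopifnot(inherits(s, "esr_scenario"))
  if (is.null(n_cycles)) n_cycles <- s$life_history$n_cycles
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1L)
  state <- initialize_population(s)
  first <- .state_row(state)
  out <- matrix(NA_real_, n_cycles + 1L, length(first),
                dimnames = list(NULL, names(first)))
  out[1L, ] <- first
  for (t in seq_len(n_cycles)) {
    state <- step_cycle(state, s)
    out[t + 1L, ] <- .state_row(state)
  }
  ts <- as.data.frame(out)
  class(ts) <- c("esr_timeseries", class(ts))
  attr(ts, "scenario") <- s
  ts
}

#' Proportion of deflected phenotypes over time
#'
#' Deflected plus resistant-deflected phenotypes: both carry a deflection
#' allele and are repelled from treated properties.
#'
#' @param ts An `"esr_timeseries"`.
#' @return Numeric vector, one value per row of `ts`.
#' @export
deflected_proportion <- function(ts) {
  ts$phen_deflected + ts$phen_resistant_deflected
}

#' Infectious bites relative to a no-intervention baseline
#'
#' Elementwise ratio of per-cycle infectious bites. With the size of the
#' human population held fixed this equals the entomological inoculation
#' rate (EIR) as a proportion of the no-intervention EIR. Cycles before the
#' baseline's infectious class is populated (the initial extrinsic-incubation
#' transient) are flagged and their ratio set to `NA`; a zero baseline after
#' the transient is an error.
#'
#' @param ts,baseline `"esr_timeseries"` objects of equal length.
#' @return Data frame with columns `cycle`, `relative_bites`, `transient`.
#' @export
relative_infectious_bites <- function(ts, baseline) {
  if (nrow(ts) != nrow(baseline)) {
    stop("time series and baseline must have equal length")
  }
  b <- baseline$infectious_bites
  positive <- which(b > 0)
  if (length(positive) == 0L) stop("baseline emits no infectious bites")
  first_pos <- positive[1]
  transient <- seq_len(nrow(baseline)) < first_pos
  if (any(b[!transient] <= 0)) {
    stop("baseline infectious bites are zero after the transient")
  }
  ratio <- ifelse(transient, NA_real_, ts$infectious_bites / b)
  data.frame(cycle = ts$cycle, relative_bites = ratio, transient = transient)
}
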