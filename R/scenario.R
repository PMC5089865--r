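#' Plasmodium infection parameters
#'
#' @param p_acquire_nondeflected Probability per feed that a non-deflected
#'   mosquito acquires a Plasmodium infection (default 0.04).
#' @param p_acquire_deflected The same probability for deflected phenotypes
#'   under an active repellent. Reductions below the non-deflected value
#'   stand in for every source of reduced transmission to and from
#'   outdoor-feeding vectors (default 0.04, i.e. no reduction).
#' @param p_infectious_bite Probability per feed that an infectious mosquito
#'   gives an infectious bite on a human host (default 0.8).
#' @param incubation_cycles Extrinsic incubation period in feeding cycles: a
#'   mosquito infected at feed `t` is infectious from feed
#'   `t + incubation_cycles` inclusive (default 3).
#' @return A list of class `"infection_params"`.
#' @export
infection_params <- function(p_acquire_nondeflected = 0.04,
                             p_acquire_deflected = p_acquire_nondeflected,
                             p_infectious_bite = 0.8,
                             incubation_cycles = 3L) {
  probs <- c(p_acquire_nondeflected = p_acquire_nondeflected,
             p_acquire_deflected = p_acquire_deflected,
             p_infectious_bite = p_infectious_bite)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1][1]
    stop("'", bad, "' must be a probability in [0, 1]")
  }
  incubation_cycles <- as.integer(incubation_cycles)
  if (is.na(incubation_cycles) || incubation_cycles < 0L) {
    stop("'incubation_cycles' must be a non-negative integer")
  }
  structure(list(p_acquire_nondeflected = p_acquire_nondeflected,
                 p_acquire_deflected = p_acquire_deflected,
                 p_infectious_bite = p_infectious_bite,
                 incubation_cycles = incubation_cycles),
            class = "infection_params")
}

#' Life-history parameters of the feeding-cycle model
#'
#' @param development_cycles Time from egg laying to adult emergence, in
#'   feeding cycles (default 3).
#' @param recruits_per_cycle Number of new adult females emerging each cycle.
#'   Under juvenile density dependence this is constant; only the genotype
#'   composition of the delayed zygote pool varies. The value sets the
#'   population scale and cancels from all proportional outputs (default 100).
#' @param n_cycles Number of feeding cycles to simulate (default 300).
#' @return A list of class `"life_history_params"`.
#' @export
life_history_params <- function(development_cycles = 3L,
                                recruits_per_cycle = 100,
                                n_cycles = 300L) {
  development_cycles <- as.integer(development_cycles)
  n_cycles <- as.integer(n_cycles)
  if (is.na(development_cycles) || development_cycles < 1L) {
    stop("'development_cycles' must be an integer >= 1")
  }
  if (!is.numeric(recruits_per_cycle) || recruits_per_cycle <= 0) {
    stop("'recruits_per_cycle' must be positive")
  }
  if (is.na(n_cycles) || n_cycles < 1L) stop("'n_cycles' must be >= 1")
  structure(list(development_cycles = development_cycles,
                 recruits_per_cycle = recruits_per_cycle,
                 n_cycles = n_cycles),
            class = "life_history_params")
}

.MODES <- c("none", "insecticide_only", "esr_plus_insecticide")

#' Define an intervention scenario
#'
#' Bundles everything one run of the model needs: phenotype survivals (given
#' directly or derived from a [treatment_model()]), infection and
#' life-history parameters, initial allele prevalences, and the intervention
#' mode.
#'
#' @param fitness A `"phenotype_fitness"` vector or a `"treatment_model"`.
#' @param init_R_freq,init_D_freq Initial prevalence of the resistance and
#'   deflection alleles, in \[0, 1\].
#' @param infection An [infection_params()] object.
#' @param life_history A [life_history_params()] object.
#' @param intervention_mode `"esr_plus_insecticide"` (repellent and
#'   insecticide co-deployed), `"insecticide_only"` (deflected phenotypes
#'   lose the repellent's protection), or `"none"` (all phenotypes survive at
#'   `U`).
#' @param U Per-cycle survival with no intervention. Defaults to `F_R`, i.e.
#'   the resistant phenotype's survival with no cost of resistance.
#' @param name Optional scenario label carried into outputs.
#' @return A list of class `"esr_scenario"`.
#' @examples
#' s <- scenario(phenotype_fitness(0.20, 0.60, 0.45),
#'               init_R_freq = 0.005, init_D_freq = 0.25)
#' @export
scenario <- function(fitness,
                     init_R_freq,
                     init_D_freq,
                     infection = infection_params(),
                     life_history = life_history_params(),
                     intervention_mode = "esr_plus_insecticide",
                     U = NULL,
                     name = NULL) {
  treatment <- if (inherits(fitness, "treatment_model")) fitness else NULL
  f <- .as_fitness(fitness)
  stopifnot(inherits(infection, "infection_params"),
            inherits(life_history, "life_history_params"))
  intervention_mode <- match.arg(intervention_mode, .MODES)
  for (nm in c("init_R_freq", "init_D_freq")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("'", nm, "' must be an allele proportion in [0, 1]")
    }
  }
  if (is.null(U)) U <- if (is.null(treatment)) f[["F_R"]] else treatment$U
  if (U < 0 || U > 1) stop("'U' must be a probability in [0, 1]")
  if (U >= 1) stop("'U' must be < 1 so the pre-intervention population is finite")
  structure(list(fitness = f,
                 treatment = treatment,
                 infection = infection,
                 life_history = life_history,
                 init_R_freq = init_R_freq,
                 init_D_freq = init_D_freq,
                 intervention_mode = intervention_mode,
                 U = U,
                 name = name),
            class = "esr_scenario")
}

#' @export
print.esr_scenario <- function(x, ...) {
  cat("<esr_scenario>", if (!is.null(x$name)) paste0(" '", x$name, "'"), "\n",
      sep = "")
  cat(sprintf("  mode: %s\n", x$intervention_mode))
  cat(sprintf("  survivals: F_S=%.4g F_R=%.4g F_D=%.4g F_RD=%.4g (U=%.4g)\n",
              x$fitness[["F_S"]], x$fitness[["F_R"]], x$fitness[["F_D"]],
              x$fitness[["F_RD"]], x$U))
  cat(sprintf("  initial alleles: R=%.4g D=%.4g\n",
              x$init_R_freq, x$init_D_freq))
  cat(sprintf("  infection: acquire %.3g (non-deflected) / %.3g (deflected), bite %.3g, incubation %d cycles\n",
              x$infection$p_acquire_nondeflected,
              x$infection$p_acquire_deflected,
              x$infection$p_infectious_bite,
              x$infection$incubation_cycles))
  cat(sprintf("  life history: development %d cycles, %g recruits/cycle, %d cycles\n",
              x$life_history$development_cycles,
              x$life_history$recruits_per_cycle,
              x$life_history$n_cycles))
  invisible(x)
}

#' Per-cycle survival of each phenotype under a scenario's intervention mode
#'
#' Mode `"none"` gives every phenotype the no-intervention survival `U`.
#' Mode `"esr_plus_insecticide"` applies the scenario's four phenotype
#' survivals. Mode `"insecticide_only"` removes the repellent, so deflected
#' phenotypes lose both its protection and its cost: `F_D` becomes `F_S` and
#' `F_RD` becomes `F_R`.
#'
#' @param s An `"esr_scenario"`.
#' @param phenotype Optional phenotype label(s) to select; default all four.
#' @return Named numeric vector of survivals.
#' @export
phenotype_survival <- function(s, phenotype = NULL) {
  stopifnot(inherits(s, "esr_scenario"))
  f <- s$fitness
  surv <- switch(s$intervention_mode,
    none = c(F_S = s$U, F_R = s$U, F_D = s$U, F_RD = s$U),
    insecticide_only = c(F_S = f[["F_S"]], F_R = f[["F_R"]],
                         F_D = f[["F_S"]], F_RD = f[["F_R"]]),
    esr_plus_insecticide = f[c("F_S", "F_R", "F_D", "F_RD")]
  )
  names(surv) <- .PHENOTYPES
  if (is.null(phenotype)) surv else {
    idx <- match(phenotype, .PHENOTYPES)
    if (anyNA(idx)) stop("unknown phenotype: ", phenotype[is.na(idx)][1])
    surv[idx]
  }
}

# per-feed acquisition probability by phenotype: the deflected value only
# applies while the repellent is actually deployed (esr mode)
.phenotype_acquisition <- function(s) {
  p_non <- s$infection$p_acquire_nondeflected
  p_def <- if (s$intervention_mode == "esr_plus_insecticide") {
    s$infection$p_acquire_deflected
  } else {
    p_non
  }
  c(Susceptible = p_non, Resistant = p_non,
    Deflected = p_def, ResistantDeflected = p_def)
}
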