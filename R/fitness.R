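#' Per-cycle survival probabilities of the four phenotypes
#'
#' Container for the per-feeding-cycle survival probability of each
#' phenotype: susceptible (`F_S`), resistant (`F_R`), deflected (`F_D`) and
#' resistant-deflected (`F_RD`). An ESR programme is only relevant where the
#' fitness cost of susceptibility exceeds the cost of deflection, i.e.
#' `F_D > F_S`; a violation raises a warning, not an error.
#'
#' @param F_S,F_R,F_D,F_RD Survival probabilities in \[0, 1\].
#' @return Named numeric vector of class `"phenotype_fitness"` with elements
#'   `F_S`, `F_R`, `F_D`, `F_RD`.
#' @examples
#' phenotype_fitness(0.20, 0.60, 0.45, 0.45)
#' @export
phenotype_fitness <- function(F_S, F_R, F_D, F_RD = F_D) {
  f <- c(F_S = F_S, F_R = F_R, F_D = F_D, F_RD = F_RD)
  if (!is.numeric(f) || length(f) != 4L || anyNA(f)) {
    stop("all four survival probabilities must be supplied")
  }
  if (any(f < 0 | f > 1)) {
    bad <- names(f)[f < 0 | f > 1][1]
    stop("phenotype survival '", bad, "' outside [0, 1]: ", f[[bad]])
  }
  if (F_D <= F_S) {
    warning("F_D <= F_S: deflection costs at least as much fitness as ",
            "susceptibility; an ESR cannot establish under these values")
  }
  structure(f, class = "phenotype_fitness")
}

.as_fitness <- function(f) {
  if (inherits(f, "phenotype_fitness")) return(unclass(f))
  if (inherits(f, "treatment_model")) return(unclass(fitness_from_treatment(f)))
  if (is.numeric(f) && length(f) == 4L) {
    if (!is.null(names(f))) f <- f[c("F_S", "F_R", "F_D", "F_RD")]
    if (anyNA(f)) stop("fitness vector must have names F_S, F_R, F_D, F_RD")
    names(f) <- c("F_S", "F_R", "F_D", "F_RD")
    return(f)
  }
  stop("expected a phenotype_fitness, treatment_model or numeric(4)")
}

#' Treatment-decomposition of per-cycle survival
#'
#' The survival of each phenotype is composed from the proportion of
#' properties in four treatment categories and the survival penalties each
#' imposes: `U` is the per-cycle survival with no treatment; `I` the survival
#' reduction that insecticide causes in susceptible (non-deflected,
#' non-resistant) mosquitoes; `B` the survival reduction caused by being
#' deflected away from a protected building; `Y1..Y4` the proportions of
#' properties that are untreated, insecticide-only, repellent-only, and
#' insecticide + repellent; `COR1`/`COR2` the cost-of-resistance survival
#' reductions paid by resistant non-deflected and resistant deflected
#' phenotypes.
#'
#' @param U,I,B Probabilities in \[0, 1\].
#' @param Y Numeric vector `c(Y1, Y2, Y3, Y4)` of property-category
#'   proportions summing to 1.
#' @param COR1,COR2 Cost-of-resistance survival reductions in \[0, 1\].
#' @return A list of class `"treatment_model"`.
#' @seealso [fitness_from_treatment()]
#' @export
treatment_model <- function(U, I, B, Y = c(0, 0, 0, 1), COR1 = 0, COR2 = 0) {
  stopifnot(length(Y) == 4L, is.numeric(Y))
  for (nm in c("U", "I", "B", "COR1", "COR2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("'", nm, "' must be a probability in [0, 1]")
    }
  }
  if (any(Y < 0) || abs(sum(Y) - 1) > 1e-9) {
    stop("'Y' must be four non-negative proportions summing to 1")
  }
  structure(list(U = U, I = I, B = B, Y = as.numeric(Y),
                 COR1 = COR1, COR2 = COR2),
            class = "treatment_model")
}

#' Phenotype survivals implied by a treatment decomposition
#'
#' Averages the per-category survivals over the property mix:
#' \deqn{F_S = U - I(Y_2+Y_4),\quad F_R = U - COR_1,\quad
#'       F_D = U - I Y_2 - B(Y_3+Y_4),\quad F_{RD} = U - B(Y_3+Y_4) - COR_2.}
#' Costs of resistance are subtractive on per-cycle survival.
#'
#' @param t A `"treatment_model"`.
#' @return A `"phenotype_fitness"` vector.
#' @examples
#' # full-coverage deployment: every property gets insecticide + repellent
#' fitness_from_treatment(treatment_model(U = 0.6, I = 0.4, B = 0.15))
#' @export
fitness_from_treatment <- function(t) {
  stopifnot(inherits(t, "treatment_model"))
  Y2 <- t$Y[2]; Y34 <- t$Y[3] + t$Y[4]; Y24 <- t$Y[2] + t$Y[4]
  f <- c(F_S  = t$U - t$I * Y24,
         F_R  = t$U - t$COR1,
         F_D  = t$U - t$I * Y2 - t$B * Y34,
         F_RD = t$U - t$B * Y34 - t$COR2)
  if (any(f < 0 | f > 1)) {
    bad <- names(f)[f < 0 | f > 1][1]
    stop("treatment model implies survival '", bad, "' outside [0, 1]: ",
         format(f[[bad]]))
  }
  suppressWarnings(phenotype_fitness(f[["F_S"]], f[["F_R"]],
                                     f[["F_D"]], f[["F_RD"]]))
}

#' Blend resistant-deflected survival between the deflected and resistant values
#'
#' Models incomplete deflection: resistant-deflected phenotypes experience a
#' weighted mixture of the deflected and resistant survivals,
#' `F_RD = w * F_D + (1 - w) * F_R`. With `w = 0.75` this corresponds to
#' deflected phenotypes being deflected 75% of the time (or 75% of
#' insecticide-treated properties also carrying the repellent).
#'
#' @param f A `"phenotype_fitness"` vector.
#' @param w Blend weight on the deflected survival, in \[0, 1\].
#' @return A `"phenotype_fitness"` vector with `F_RD` replaced.
#' @export
blended_fitness <- function(f, w = 0.75) {
  f <- .as_fitness(f)
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w <= 1)
  suppressWarnings(phenotype_fitness(
    f[["F_S"]], f[["F_R"]], f[["F_D"]],
    w * f[["F_D"]] + (1 - w) * f[["F_R"]]
  ))
}

# survival per genotype (length 9) given the 4 phenotype survivals
.genotype_survival <- function(f4) f4[.GENO_PHENO]
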