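#' Mean per-cycle survival of offspring classed by inherited deflection allele
#'
#' For a zygote pool formed by random union of gametes drawn from the
#' haplotype pool `h` (the same pool for mating males and newly emerged
#' females), computes the average fitness of offspring into which deflection
#' alleles are inherited (`Fbar_D`) and into which non-deflection alleles are
#' inherited (`Fbar_d`). With haplotype frequencies written `[dr]`, `[dR]`,
#' `[Dr]`, `[DR]` (deflection-locus allele first) and marginals `[d-]`,
#' `[D-]`, `[-r]`, `[-R]`:
#' \deqn{\bar F_D = F_S + \frac{[Dr][-R] + [DR]}{[D-]}(F_{RD} - F_S)
#'                      + \frac{[Dr][-r]}{[D-]}(F_D - F_S)}
#' \deqn{\bar F_d = F_S + [dR]\Big(1 + \frac{[dr]}{[d-]}\Big)(F_R - F_S)
#'                      + \frac{[dr][Dr]}{[d-]}(F_D - F_S)
#'                      + \Big([DR] + \frac{[dR][Dr]}{[d-]}\Big)(F_{RD} - F_S)}
#'
#' @param h A `"hap_prop"` vector of gamete haplotype frequencies.
#' @param f A `"phenotype_fitness"` vector (or named numeric(4)).
#' @return Named numeric vector `c(Fbar_D = , Fbar_d = )`.
#' @seealso [brute_force_offspring_fitness()] for the enumeration oracle;
#'   [deflection_spread_predicate()] for the spread condition.
#' @export
mean_offspring_fitness_deflection <- function(h, f) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  a <- h[["rd"]]; b <- h[["rD"]]; cc <- h[["Rd"]]; e <- h[["RD"]]
  dm <- a + cc; Dm <- b + e; mr <- a + b; mR <- cc + e
  if (Dm <= 0) stop("Fbar_D undefined: deflection allele absent ([D-] = 0)")
  if (dm <= 0) stop("Fbar_d undefined: non-deflection allele absent ([d-] = 0)")
  FS <- f[["F_S"]]; FR <- f[["F_R"]]; FD <- f[["F_D"]]; FRD <- f[["F_RD"]]
  c(
    Fbar_D = FS + (b * mR + e) / Dm * (FRD - FS) + b * mr / Dm * (FD - FS),
    Fbar_d = FS + cc * (1 + a / dm) * (FR - FS) + a * b / dm * (FD - FS) +
      (e + cc * b / dm) * (FRD - FS)
  )
}

#' Mean per-cycle survival of offspring classed by inherited resistance allele
#'
#' Resistance-locus analogue of [mean_offspring_fitness_deflection()]: the
#' average fitness of offspring into which resistance (`Fbar_R`) and
#' susceptibility (`Fbar_r`) alleles are inherited, under random union of
#' gametes from `h`. Closed forms follow from conditioning a focal allele's
#' gamete on its partner gamete:
#' \deqn{\bar F_R = \frac{[Rd]([-d]F_R + [-D]F_{RD}) + [RD]F_{RD}}{[R-]}}
#' \deqn{\bar F_r = \frac{[rd]([rd]F_S + [Rd]F_R + [rD]F_D + [RD]F_{RD})
#'                 + [rD]([r-]F_D + [R-]F_{RD})}{[r-]}}
#'
#' @inheritParams mean_offspring_fitness_deflection
#' @return Named numeric vector `c(Fbar_R = , Fbar_r = )`.
#' @export
mean_offspring_fitness_resistance <- function(h, f) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  a <- h[["rd"]]; b <- h[["rD"]]; cc <- h[["Rd"]]; e <- h[["RD"]]
  rm_ <- a + b; Rm <- cc + e; md <- a + cc; mD <- b + e
  if (Rm <= 0) stop("Fbar_R undefined: resistance allele absent ([-R] = 0)")
  if (rm_ <= 0) stop("Fbar_r undefined: susceptibility allele absent ([-r] = 0)")
  FS <- f[["F_S"]]; FR <- f[["F_R"]]; FD <- f[["F_D"]]; FRD <- f[["F_RD"]]
  c(
    Fbar_R = (cc * (md * FR + mD * FRD) + e * FRD) / Rm,
    Fbar_r = (a * (a * FS + cc * FR + b * FD + e * FRD) +
                b * (rm_ * FD + Rm * FRD)) / rm_
  )
}

#' Brute-force offspring fitness by enumeration of gamete pairings
#'
#' Independent oracle for the closed-form offspring-fitness expressions:
#' enumerates all 16 ordered pairings of gametes drawn from `h`, weights each
#' zygote by its pairing probability times the number of copies of the focal
#' allele it carries, and returns the fitness-weighted mean over that weight.
#'
#' @inheritParams mean_offspring_fitness_deflection
#' @param allele One of `"D"`, `"d"`, `"R"`, `"r"`.
#' @return Mean per-cycle survival of offspring inheriting `allele`.
#' @export
brute_force_offspring_fitness <- function(h, f, allele = c("D", "d", "R", "r")) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  allele <- match.arg(allele)
  w_tot <- 0
  fw_tot <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      p <- h[[i]] * h[[j]]
      nR <- .HAP_R[i] + .HAP_R[j]
      nD <- .HAP_D[i] + .HAP_D[j]
      fit <- f[[1L + (nR > 0) + 2L * (nD > 0)]]  # F_S, F_R, F_D, F_RD
      copies <- switch(allele, D = nD, d = 2L - nD, R = nR, r = 2L - nR)
      w_tot <- w_tot + p * copies
      fw_tot <- fw_tot + p * copies * fit
    }
  }
  if (w_tot <= 0) stop("focal allele '", allele, "' absent from the pool")
  unname(fw_tot / w_tot)
}

#' Condition for the deflection allele to spread
#'
#' The proportion of deflection alleles increases over one round of random
#' mating and selection exactly when the average fitness of offspring
#' inheriting deflection alleles exceeds that of offspring inheriting
#' non-deflection alleles. The implemented inequality is
#' \deqn{\frac{[dr]^2}{[d-]}(F_D - F_S) >
#'   [dR]\Big(1+\frac{[dr]}{[d-]}\Big)(F_R - F_D) +
#'   \Big([DR]\big(1-\tfrac{1}{[D-]}\big) +
#'        [Dr]\big(\tfrac{[dR]}{[d-]} - \tfrac{[-R]}{[D-]}\big)\Big)
#'   (F_{RD} - F_D)}
#' which is algebraically equivalent to `Fbar_D > Fbar_d`. Equality resolves
#' to no spread. With the deflection allele absent or fixed the condition is
#' not applicable and `NA` is returned; callers must branch explicitly.
#'
#' @inheritParams mean_offspring_fitness_deflection
#' @return `TRUE`, `FALSE`, or `NA` when `[D-]` is 0 or 1.
#' @export
deflection_spread_predicate <- function(h, f) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  a <- h[["rd"]]; b <- h[["rD"]]; cc <- h[["Rd"]]; e <- h[["RD"]]
  dm <- a + cc; Dm <- b + e; mR <- cc + e
  if (Dm <= 0 || Dm >= 1) return(NA)
  FS <- f[["F_S"]]; FR <- f[["F_R"]]; FD <- f[["F_D"]]; FRD <- f[["F_RD"]]
  lhs <- a^2 / dm * (FD - FS)
  rhs <- cc * (1 + a / dm) * (FR - FD) +
    (e * (1 - 1 / Dm) + b * (cc / dm - mR / Dm)) * (FRD - FD)
  lhs > rhs
}

#' Condition for the resistance allele to spread
#'
#' Resistance-locus analogue of [deflection_spread_predicate()]: true exactly
#' when `Fbar_R > Fbar_r`. The implemented inequality (haplotype symbols now
#' resistance-allele first) is
#' \deqn{[rd](F_R - F_S) + [rD](F_R - F_D) +
#'   \Big([rD] + \frac{[RD][-d]}{[R-]} - \frac{[Rd][rD]}{[r-]}\Big)
#'   (F_{RD} - F_R) > \frac{[rd][rD]}{[r-]}(F_D - F_S)}
#' At deflection fixation this reduces to `F_RD > F_D`: resistance only
#' spreads if resistant-deflected phenotypes are fitter than deflected ones.
#'
#' @inheritParams mean_offspring_fitness_deflection
#' @return `TRUE`, `FALSE`, or `NA` when `[-R]` is 0 or 1.
#' @export
resistance_spread_predicate <- function(h, f) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  a <- h[["rd"]]; b <- h[["rD"]]; cc <- h[["Rd"]]; e <- h[["RD"]]
  rm_ <- a + b; Rm <- cc + e; md <- a + cc
  if (Rm <= 0 || Rm >= 1) return(NA)
  FS <- f[["F_S"]]; FR <- f[["F_R"]]; FD <- f[["F_D"]]; FRD <- f[["F_RD"]]
  lhs <- a * (FR - FS) + b * (FR - FD) +
    (b + e * md / Rm - cc * b / rm_) * (FRD - FR)
  rhs <- a * b / rm_ * (FD - FS)
  lhs > rhs
}

#' One discrete, non-overlapping generation of random mating and selection
#'
#' The simplified generation map used for analytic cross-checks: zygotes form
#' by random union of gametes from the pool `h`, survive to adulthood with
#' their phenotype's per-cycle survival, reproduce once, and die. Returns the
#' gamete pool of the surviving adults. Under equal fitnesses this map leaves
#' allele frequencies unchanged and halves linkage disequilibrium each
#' generation (unlinked loci); the sign of the change in deflection-allele
#' frequency equals [deflection_spread_predicate()] evaluated on `h`.
#'
#' @inheritParams mean_offspring_fitness_deflection
#' @return The next generation's `"hap_prop"` gamete pool.
#' @export
generation_step <- function(h, f) {
  h <- haplotype_proportions(h)
  f <- .as_fitness(f)
  z <- zygote_distribution(h, h)
  w <- z * .genotype_survival(f)
  tot <- sum(w)
  if (tot <= 0) stop("no zygotes survive: all selected fitnesses are zero")
  pool_gametes(w / tot)
}
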