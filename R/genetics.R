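#' Phenotype determined by a genotype
#'
#' Both the resistance allele R and the deflection allele D are completely
#' dominant, so any genotype carrying at least one R is resistant, at least
#' one D is deflected, and both gives the resistant-deflected phenotype.
#'
#' @param genotype Character vector of genotype names (see [genotype_names()]).
#' @return Character vector of phenotype labels (see [phenotype_names()]).
#' @examples
#' phenotype_of(c("rr/dd", "Rr/Dd", "RR/dd"))
#' @export
phenotype_of <- function(genotype) {
  idx <- match(genotype, .GENO_NAMES)
  if (anyNA(idx)) {
    stop("unknown genotype: ", paste(genotype[is.na(idx)], collapse = ", "))
  }
  .PHENOTYPES[.GENO_PHENO[idx]]
}

#' Haplotype proportions of the four gamete types
#'
#' Constructor and validator for a frequency vector over the haplotypes
#' `rd`, `rD`, `Rd`, `RD`. Frequencies must be non-negative and sum to 1
#' (tolerance 1e-9 on input; stored exactly as given).
#'
#' @param x Numeric vector of length 4. If named, names must be a permutation
#'   of [haplotype_names()]; unnamed vectors are taken in that order.
#' @return A named numeric vector of class `"hap_prop"`.
#' @seealso [le_haplotypes()] for the linkage-equilibrium constructor,
#'   [hap_marginals()] for the allele-level marginals.
#' @export
haplotype_proportions <- function(x) {
  if (length(x) != 4L || !is.numeric(x)) {
    stop("haplotype proportions must be a numeric vector of length 4")
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), .HAP_NAMES)) {
      stop("haplotype names must be ", paste(.HAP_NAMES, collapse = ", "))
    }
    x <- x[.HAP_NAMES]
  } else {
    names(x) <- .HAP_NAMES
  }
  if (any(x < 0)) stop("haplotype proportions must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) {
    stop("haplotype proportions must sum to 1 (got ",
         format(sum(x), digits = 15), ")")
  }
  structure(x, class = "hap_prop")
}

#' Haplotype frequencies at linkage equilibrium
#'
#' Builds the haplotype-frequency vector whose entries are products of the
#' allele frequencies at the two loci (zero linkage disequilibrium).
#'
#' @param R_freq Frequency of the resistance allele R, in \[0, 1\].
#' @param D_freq Frequency of the deflection allele D, in \[0, 1\].
#' @return A `"hap_prop"` vector.
#' @examples
#' le_haplotypes(0.005, 0.25)
#' @export
le_haplotypes <- function(R_freq, D_freq) {
  stopifnot(R_freq >= 0, R_freq <= 1, D_freq >= 0, D_freq <= 1)
  haplotype_proportions(c(
    rd = (1 - R_freq) * (1 - D_freq),
    rD = (1 - R_freq) * D_freq,
    Rd = R_freq * (1 - D_freq),
    RD = R_freq * D_freq
  ))
}

#' Allele-level marginals of a haplotype pool
#'
#' Returns the marginal allele frequencies implied by a haplotype-frequency
#' vector: `d`, `D` at the deflection locus and `r`, `R` at the resistance
#' locus, plus the linkage disequilibrium `ld = [RD] - [R][D]`.
#'
#' @param h A `"hap_prop"` vector (or coercible numeric of length 4).
#' @return Named list with elements `d`, `D`, `r`, `R`, `ld`.
#' @export
hap_marginals <- function(h) {
  h <- haplotype_proportions(h)
  D <- h[["rD"]] + h[["RD"]]
  R <- h[["Rd"]] + h[["RD"]]
  list(d = 1 - D, D = D, r = 1 - R, R = R, ld = h[["RD"]] - R * D)
}

#' Gamete distribution of a single genotype
#'
#' Mendelian segregation with free recombination between the two unlinked
#' loci: the unphased double heterozygote yields all four haplotypes at 1/4.
#'
#' @param genotype A single genotype name.
#' @return A `"hap_prop"` vector.
#' @examples
#' gamete_distribution("Rr/Dd")
#' @export
gamete_distribution <- function(genotype) {
  idx <- match(genotype, .GENO_NAMES)
  if (length(idx) != 1L || is.na(idx)) stop("unknown genotype: ", genotype)
  haplotype_proportions(.GAMETE_MAT[, idx])
}

.check_genotype_freqs <- function(genotype_freqs) {
  if (!is.numeric(genotype_freqs) || length(genotype_freqs) != 9L) {
    stop("genotype frequencies must be numeric of length 9")
  }
  if (!is.null(names(genotype_freqs))) {
    if (!setequal(names(genotype_freqs), .GENO_NAMES)) {
      stop("genotype names must match genotype_names()")
    }
    genotype_freqs <- genotype_freqs[.GENO_NAMES]
  } else {
    names(genotype_freqs) <- .GENO_NAMES
  }
  if (any(genotype_freqs < 0)) stop("genotype frequencies must be non-negative")
  if (abs(sum(genotype_freqs) - 1) > 1e-9) {
    stop("genotype frequencies must sum to 1")
  }
  genotype_freqs
}

#' Gamete pool of a genotype mixture
#'
#' Frequency-weighted mixture of [gamete_distribution()] over a population's
#' genotype distribution.
#'
#' @param genotype_freqs Numeric vector of length 9 summing to 1 (ordered or
#'   named as [genotype_names()]).
#' @return A `"hap_prop"` vector.
#' @export
pool_gametes <- function(genotype_freqs) {
  genotype_freqs <- .check_genotype_freqs(genotype_freqs)
  haplotype_proportions(drop(.GAMETE_MAT %*% genotype_freqs))
}

#' Zygote genotype distribution under random mating
#'
#' Crosses a female gamete pool with a male gamete pool (outer product of the
#' two haplotype distributions) and collapses ordered gamete pairs to the
#' nine unphased genotypes.
#'
#' @param female_gametes,male_gametes `"hap_prop"` vectors.
#' @return Named numeric vector of genotype frequencies summing to 1.
#' @export
zygote_distribution <- function(female_gametes, male_gametes = female_gametes) {
  f <- haplotype_proportions(female_gametes)
  m <- haplotype_proportions(male_gametes)
  drop(.ZYGOTE_MAP %*% as.vector(outer(unclass(f), unclass(m))))
}
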