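# random-input generators shared across property-style tests

rand_hap <- function() {
  x <- stats::rgamma(4, shape = 1)
  haplotype_proportions(x / sum(x))
}

rand_fitness <- function() {
  f <- stats::runif(4)
  suppressWarnings(phenotype_fitness(f[1], f[2], f[3], f[4]))
}

# fitness vectors respecting the ESR ordering F_D > F_S
rand_esr_fitness <- function() {
  FS <- stats::runif(1, 0.05, 0.5)
  FD <- stats::runif(1, FS + 0.05, 0.9)
  FR <- stats::runif(1, 0.05, 0.95)
  phenotype_fitness(FS, FR, FD, FD)
}
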