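test_that("initialization gives HWE/LE genotypes, equilibrium count and round-trip allele frequencies", {
  s <- baseline_scenario()
  pop <- initialize_population(s)
  freq <- rowSums(pop$N_gs) / sum(pop$N_gs)
  expect_equal(freq[["rr/dd"]], 0.995^2 * 0.75^2, tolerance = 1e-12)
  # pre-intervention equilibrium: recruits / (1 - U)
  expect_equal(sum(pop$N_gs), 100 / (1 - 0.6), tolerance = 1e-9)
  # allele frequencies recomputed from the state equal the inputs
  nR <- rep(0:2, times = 3); nD <- rep(0:2, each = 3)
  expect_equal(sum(freq * nR) / 2, 0.005, tolerance = 1e-12)
  expect_equal(sum(freq * nD) / 2, 0.25, tolerance = 1e-12)
  # all adults start uninfected; queue has one slot per development cycle
  expect_equal(sum(pop$N_gs[, -1]), 0)
  expect_length(pop$queue, 3)
  # degenerate initial frequencies collapse to the susceptible homozygote
  pop0 <- initialize_population(
    scenario(phenotype_fitness(0.2, 0.6, 0.45), 0, 0))
  expect_equal(unname(rowSums(pop0$N_gs) / sum(pop0$N_gs)),
               c(1, rep(0, 8)))
})

test_that("distributions stay normalized and counts non-negative through a run", {
  ts <- run_scenario(example_scenario("transient"))
  freq_cols <- grep("^freq_", names(ts))
  expect_true(all(abs(rowSums(ts[, freq_cols]) - 1) < 1e-12))
  expect_true(all(as.matrix(ts[, freq_cols]) >= 0))
  expect_true(all(ts$adult_count >= 0))
  expect_true(all(ts$infectious_bites >= 0))
  # phenotype proportions are derivable from genotype frequencies
  expect_equal(ts$phen_susceptible, ts$freq_rr_dd, tolerance = 1e-12)
  expect_equal(ts$phen_deflected + ts$phen_resistant_deflected +
                 ts$phen_susceptible + ts$phen_resistant,
               rep(1, nrow(ts)), tolerance = 1e-12)
})

test_that("equal-fitness runs conserve allele frequencies for 300 cycles", {
  s <- scenario(suppressWarnings(phenotype_fitness(0.55, 0.55, 0.55, 0.55)),
                init_R_freq = 0.17, init_D_freq = 0.39,
                intervention_mode = "esr_plus_insecticide")
  ts <- run_scenario(s)
  expect_equal(nrow(ts), 301)
  expect_lt(max(abs(ts$allele_R_freq - 0.17)), 1e-9)
  expect_lt(max(abs(ts$allele_D_freq - 0.39)), 1e-9)
  # mode "none" gives flat phenotype proportions too
  s2 <- baseline_scenario()
  s2$intervention_mode <- "none"
  ts2 <- run_scenario(s2, 100)
  for (col in grep("^phen_", names(ts2))) {
    expect_lt(diff(range(ts2[[col]])), 1e-12)
  }
})

test_that("adult population converges to recruits/(1 - survival) under uniform survival", {
  s <- scenario(suppressWarnings(phenotype_fitness(0.35, 0.35, 0.35, 0.35)),
                init_R_freq = 0.1, init_D_freq = 0.2, U = 0.5,
                life_history = life_history_params(3L, 80, 200L))
  ts <- run_scenario(s)
  expect_equal(ts$adult_count[1], 80 / (1 - 0.5))
  expect_equal(tail(ts$adult_count, 1), 80 / (1 - 0.35), tolerance = 1e-9)
})

test_that("per-cycle survival under each intervention mode follows the treatment table", {
  s <- baseline_scenario()
  expect_equal(unname(phenotype_survival(s)), c(0.20, 0.60, 0.45, 0.45))
  expect_equal(phenotype_survival(s, "Susceptible")[[1]], 0.20)
  s$intervention_mode <- "none"
  expect_equal(unname(phenotype_survival(s)), rep(0.6, 4))
  # without the repellent, deflected phenotypes revert to their exposure class
  s$intervention_mode <- "insecticide_only"
  surv <- phenotype_survival(s)
  expect_equal(surv[["Deflected"]], surv[["Susceptible"]])
  expect_equal(surv[["ResistantDeflected"]], surv[["Resistant"]])
})

test_that("deflection allele rises under the reference scenario and infection machinery behaves", {
  ts <- run_scenario(baseline_scenario(), 60)
  expect_true(all(diff(ts$allele_D_freq[4:61]) > 0))
  expect_gt(ts$allele_D_freq[61], 0.25)
  # no acquisition, no infectious bites
  s0 <- baseline_scenario()
  s0$infection$p_acquire_nondeflected <- 0
  s0$infection$p_acquire_deflected <- 0
  expect_equal(max(run_scenario(s0, 30)$infectious_bites), 0)
  # adults infected at their first feed (cycle 1) become infectious at
  # feed 1 + incubation_cycles = 4
  s1 <- baseline_scenario()
  ts1 <- run_scenario(s1, 10)
  expect_equal(ts1$infectious_bites[1:4], rep(0, 4))  # cycles 0-3
  expect_gt(ts1$infectious_bites[5], 0)               # cycle 4
})

test_that("an empty population reaches a zero-emission steady state without error", {
  s <- scenario(suppressWarnings(phenotype_fitness(0, 0, 0, 0)),
                init_R_freq = 0.2, init_D_freq = 0.2, U = 0.5,
                life_history = life_history_params(2L, 50, 20L))
  ts <- run_scenario(s)
  expect_equal(tail(ts$adult_count, 10), rep(0, 10))
  expect_equal(tail(ts$infectious_bites, 10), rep(0, 10))
})

test_that("no-resistance runs drive deflection to fixation monotonically after the recruitment transient", {
  s <- scenario(phenotype_fitness(0.20, 0.60, 0.45),
                init_R_freq = 0, init_D_freq = 0.25)
  ts <- run_scenario(s)
  dev <- s$life_history$development_cycles
  # monotone non-decreasing once the pre-filled juvenile queue has cleared
  expect_true(all(diff(ts$allele_D_freq[(dev + 1):301]) >= -1e-12))
  expect_gt(ts$allele_D_freq[301], 0.95)
  expect_gt(deflected_proportion(ts)[301], 0.99)
  # the non-overlapping-generations recursion crosses 0.99 within 300 generations
  h <- le_haplotypes(0, 0.25)
  f <- phenotype_fitness(0.20, 0.60, 0.45)
  for (g in 1:300) h <- generation_step(h, f)
  expect_gt(hap_marginals(h)$D, 0.99)
})

test_that("with deflection fixed, resistance spreads in simulation iff F_RD > F_D", {
  base <- function(frd) scenario(phenotype_fitness(0.2, 0.6, 0.45, frd),
                                 init_R_freq = 0.01, init_D_freq = 1,
                                 life_history = life_history_params(3L, 100, 150L))
  up <- run_scenario(base(0.50))
  flat <- run_scenario(base(0.45))
  down <- run_scenario(base(0.40))
  expect_gt(tail(up$allele_R_freq, 1), 0.01)
  expect_equal(tail(flat$allele_R_freq, 1), 0.01, tolerance = 1e-9)
  expect_lt(tail(down$allele_R_freq, 1), 0.01)
})

test_that("runs are deterministic and relative bites behave at the limits", {
  s <- example_scenario("transient")
  s$life_history$n_cycles <- 80L
  ts1 <- run_scenario(s)
  ts2 <- run_scenario(s)
  expect_identical(ts1, ts2)
  base_s <- s
  base_s$intervention_mode <- "none"
  baseline <- run_scenario(base_s)
  # a series relative to itself is exactly 1 outside the transient
  self <- relative_infectious_bites(baseline, baseline)
  expect_equal(self$relative_bites[!self$transient],
               rep(1, sum(!self$transient)))
  expect_true(all(self$transient == (baseline$infectious_bites == 0)))
  expect_error(relative_infectious_bites(ts1[1:10, ], baseline), "equal length")
})

test_that("deflection near fixation with zero deflected acquisition suppresses infectious bites", {
  s <- baseline_scenario()
  s$infection$p_acquire_deflected <- 0
  s$init_D_freq <- 0.999
  ts <- run_scenario(s, 150)
  base_s <- s
  base_s$intervention_mode <- "none"
  rel <- relative_infectious_bites(ts, run_scenario(base_s, 150))
  expect_lt(tail(rel$relative_bites, 1), 0.01)
})
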