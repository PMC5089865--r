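#' JSON serialization of haplotype proportions and phenotype fitness
#'
#' Fixed-key plain JSON objects: haplotype pools use keys `rd`, `rD`, `Rd`,
#' `RD`; fitness vectors use `F_S`, `F_R`, `F_D`, `F_RD`.
#'
#' @param x A `"hap_prop"` or `"phenotype_fitness"` vector.
#' @return A JSON string.
#' @export
esr_to_json <- function(x) {
  stopifnot(inherits(x, "hap_prop") || inherits(x, "phenotype_fitness"))
  jsonlite::toJSON(as.list(unclass(x)), auto_unbox = TRUE, digits = NA)
}

#' @rdname esr_to_json
#' @param json A JSON string produced by [esr_to_json()].
#' @return `esr_from_json()` returns the reconstructed vector, classed by
#'   its key set.
#' @export
esr_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  keys <- names(x)
  if (setequal(keys, .HAP_NAMES)) {
    haplotype_proportions(unlist(x))
  } else if (setequal(keys, c("F_S", "F_R", "F_D", "F_RD"))) {
    x <- unlist(x)
    suppressWarnings(phenotype_fitness(x[["F_S"]], x[["F_R"]],
                                       x[["F_D"]], x[["F_RD"]]))
  } else {
    stop("unrecognized key set: ", paste(keys, collapse = ", "))
  }
}

.CONFIG_KEYS <- c("scenario", "F_S", "F_R", "F_D", "F_RD", "U",
                  "init_R_freq", "init_D_freq",
                  "p_acquire_nondeflected", "p_acquire_deflected",
                  "p_infectious_bite", "incubation_cycles",
                  "development_cycles", "recruits_per_cycle", "n_cycles",
                  "intervention_mode", "name")

#' Build a scenario from a YAML configuration file or a flat key list
#'
#' The configuration either names a fixture (`scenario: baseline`) or gives
#' parameters directly; explicit keys override the named fixture's values.
#' Unknown keys are rejected and range errors name the offending field.
#'
#' @param path Path to a YAML file, or `NULL` when `overrides` carries the
#'   whole configuration.
#' @param overrides Named list applied on top of the file's keys (last
#'   wins), e.g. parsed command-line flags.
#' @return An `"esr_scenario"`.
#' @export
read_scenario_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  s <- if (!is.null(cfg$scenario)) example_scenario(cfg$scenario)
       else baseline_scenario()
  f <- as.list(s$fitness)
  for (k in c("F_S", "F_R", "F_D", "F_RD")) if (!is.null(cfg[[k]])) f[[k]] <- cfg[[k]]
  fitness <- suppressWarnings(
    phenotype_fitness(f$F_S, f$F_R, f$F_D, f$F_RD)
  )
  inf <- s$infection
  for (k in c("p_acquire_nondeflected", "p_acquire_deflected",
              "p_infectious_bite", "incubation_cycles")) {
    if (!is.null(cfg[[k]])) inf[[k]] <- cfg[[k]]
  }
  infection <- infection_params(inf$p_acquire_nondeflected,
                                inf$p_acquire_deflected,
                                inf$p_infectious_bite,
                                inf$incubation_cycles)
  lh <- s$life_history
  for (k in c("development_cycles", "recruits_per_cycle", "n_cycles")) {
    if (!is.null(cfg[[k]])) lh[[k]] <- cfg[[k]]
  }
  life_history <- life_history_params(lh$development_cycles,
                                      lh$recruits_per_cycle, lh$n_cycles)
  scenario(
    fitness = fitness,
    init_R_freq = if (!is.null(cfg$init_R_freq)) cfg$init_R_freq else s$init_R_freq,
    init_D_freq = if (!is.null(cfg$init_D_freq)) cfg$init_D_freq else s$init_D_freq,
    infection = infection,
    life_history = life_history,
    intervention_mode = if (!is.null(cfg$intervention_mode)) cfg$intervention_mode else s$intervention_mode,
    U = if (!is.null(cfg$U)) cfg$U else if (is.null(cfg$F_R)) s$U else NULL,
    name = if (!is.null(cfg$name)) cfg$name else s$name
  )
}

# flat parameter echo of a scenario (for metadata and round-tripping)
.scenario_to_config <- function(s) {
  list(F_S = s$fitness[["F_S"]], F_R = s$fitness[["F_R"]],
       F_D = s$fitness[["F_D"]], F_RD = s$fitness[["F_RD"]],
       U = s$U,
       init_R_freq = s$init_R_freq, init_D_freq = s$init_D_freq,
       p_acquire_nondeflected = s$infection$p_acquire_nondeflected,
       p_acquire_deflected = s$infection$p_acquire_deflected,
       p_infectious_bite = s$infection$p_infectious_bite,
       incubation_cycles = s$infection$incubation_cycles,
       development_cycles = s$life_history$development_cycles,
       recruits_per_cycle = s$life_history$recruits_per_cycle,
       n_cycles = s$life_history$n_cycles,
       intervention_mode = s$intervention_mode,
       name = if (is.null(s$name)) "unnamed" else s$name)
}

# proportions written at 12 significant digits so byte-identity of repeat
# runs is a meaningful determinism check
.write_csv12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a run's outputs to a directory
#'
#' Writes `timeseries.csv` (or `grid.csv` / `bite_comparison.csv` for grid and
#' comparison results) plus a `metadata.json` echoing every model parameter,
#' the design flags in force, and the package version, sufficient to
#' reproduce the files bit-for-bit.
#'
#' @param result An `"esr_timeseries"`, `"esr_grid"`, or the data frame
#'   returned by [relative_bites_experiment()].
#' @param s The `"esr_scenario"` (or template) that produced it.
#' @param dir Output directory, created if needed.
#' @param extra Named list merged into the metadata (e.g. ratchet settings).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, s, dir, extra = list()) {
  stopifnot(inherits(s, "esr_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file <- if (inherits(result, "esr_grid")) "grid.csv"
          else if (inherits(result, "esr_timeseries")) "timeseries.csv"
          else "bite_comparison.csv"
  csv_path <- file.path(dir, file)
  .write_csv12(as.data.frame(result), csv_path)
  meta <- c(list(package = "esrsim",
                 version = as.character(utils::packageVersion("esrsim")),
                 output = file,
                 bites_counted = "after survival and incubation advance, by infectious surviving feeders",
                 scenario = .scenario_to_config(s)),
            extra)
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, meta_path))
}
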