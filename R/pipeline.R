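# End-to-end orchestration: generate -> describe -> compare -> risk, driven
# by one root seed, with a manifest of checksummed outputs written last.

#' Default study configuration
#'
#' The package's shipped configuration: the default [generator_config()],
#' the default [exposure_params()], and the simulation settings (1e5
#' iterations). Also available serialised as
#' `system.file("extdata", "study_config.yaml", package = "naphrisk")`.
#'
#' @param seed Root seed; drives generation and every simulation cell.
#' @param n_iterations Monte-Carlo iterations per simulation cell.
#' @return A list of class `naphrisk_config` with elements `generator`,
#'   `exposure`, `simulation`.
#' @export
default_study_config <- function(seed = 1L, n_iterations = 100000L) {
  structure(
    list(
      generator = generator_config(seed = seed),
      exposure = exposure_params(),
      simulation = list(n_iterations = as.integer(n_iterations),
                        seed = as.integer(seed))
    ),
    class = "naphrisk_config"
  )
}

#' Read a pipeline configuration file
#'
#' YAML with optional sections `generator:`, `exposure:` and `simulation:`;
#' keys override the shipped defaults (unknown keys are rejected).
#'
#' @param path Path to a YAML configuration file.
#' @return A `naphrisk_config` list.
#' @export
#' @examples
#' cfg <- read_config(system.file("extdata", "study_config.yaml",
#'                                package = "naphrisk"))
read_config <- function(path) {
  if (!file.exists(path)) stop_param(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("generator", "exposure", "simulation")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_schema(sprintf("unknown config section(s): %s",
                        paste(extra, collapse = ", ")))
  }
  check_keys <- function(given, allowed, section) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) {
      stop_schema(sprintf("unknown key(s) in `%s`: %s", section,
                          paste(extra, collapse = ", ")))
    }
  }
  gen_args <- raw$generator %||% list()
  check_keys(gen_args, names(formals(generator_config)), "generator")
  exp_args <- raw$exposure %||% list()
  check_keys(exp_args, names(formals(exposure_params)), "exposure")
  sim_args <- raw$simulation %||% list()
  check_keys(sim_args, c("n_iterations", "seed"), "simulation")
  structure(
    list(
      generator = do.call(generator_config, gen_args),
      exposure = do.call(exposure_params, exp_args),
      simulation = list(
        n_iterations = as.integer(sim_args$n_iterations %||% 100000L),
        seed = as.integer(sim_args$seed %||% gen_args$seed %||% 1L)
      )
    ),
    class = "naphrisk_config"
  )
}

#' Risk summary over the full reporting grid
#'
#' Runs [run_mcs()] for every combination of route (original, creatinine)
#' and stratum (male, female, all) and stacks the results: one row per
#' quantity in \{EDI, HQ, CR\} per cell (18 rows), with P5/mean/P95 in
#' ug/kg-bw/day for EDI (plus `p5_per_day`/`mean_per_day`/`p95_per_day` in
#' ug/day on the EDI rows) and the exceedance fractions on the HQ and CR
#' rows.
#'
#' @param params An [exposure_params()] object.
#' @param n_iterations Iterations per simulation cell.
#' @param seed Root seed; each cell derives its own offset stream.
#' @return A list with `summary` (the 18-row tibble) and `runs` (the six
#'   `naphrisk_mcs` objects, named `route.stratum`).
#' @export
study_risk_summary <- function(params = exposure_params(),
                               n_iterations = 100000L, seed = 1L) {
  grid <- tidyr::expand_grid(route = c("original", "creatinine"),
                             stratum = c("male", "female", "all"))
  runs <- purrr::pmap(grid, function(route, stratum) {
    offset <- 100L * match(route, c("original", "creatinine")) +
      match(stratum, c("male", "female", "all"))
    run_mcs(study_simulation_config(route, stratum,
                                    n_iterations = n_iterations,
                                    seed = seed + offset, params = params))
  })
  names(runs) <- paste(grid$route, grid$stratum, sep = ".")
  summary <- purrr::map(runs, function(m) {
    s <- m$summary
    edi <- s[s$quantity == "EDI_per_kg", ]
    edi_day <- s[s$quantity == "EDI_per_day", ]
    edi <- edi |>
      dplyr::mutate(quantity = "EDI",
                    p5_per_day = edi_day$p5, mean_per_day = edi_day$mean,
                    p95_per_day = edi_day$p95)
    hqcr <- s[s$quantity %in% c("HQ", "CR"), ] |>
      dplyr::mutate(p5_per_day = NA_real_, mean_per_day = NA_real_,
                    p95_per_day = NA_real_)
    exc <- m$exceedance |>
      tidyr::pivot_wider(names_from = "threshold", values_from = "fraction",
                         names_prefix = "frac_above_") |>
      dplyr::select(-"route", -"stratum")
    dplyr::bind_rows(edi, hqcr) |>
      dplyr::left_join(exc, by = "quantity")
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("route", "stratum", "quantity")
  list(summary = summary, runs = runs)
}

# Fig-1-style export: binned histograms of the simulated HQ (linear bins)
# and CR (log10 bins) distributions, 50 equal-width bins each.
histogram_bins <- function(mcs, bins = 50L) {
  bin_tbl <- function(x, quantity, transform = identity) {
    z <- transform(x)
    br <- seq(min(z), max(z), length.out = bins + 1L)
    counts <- hist(z, breaks = br, plot = FALSE)$counts
    tibble(quantity = quantity,
           bin_lower = br[-length(br)], bin_upper = br[-1L],
           count = counts)
  }
  dplyr::bind_rows(
    bin_tbl(mcs$draws$hq, "HQ"),
    bin_tbl(mcs$draws$cr, "log10_CR", transform = log10)
  ) |>
    dplyr::mutate(route = mcs$config$route, stratum = mcs$config$stratum,
                  .before = 1L)
}

#' Run the full pipeline
#'
#' Executes generate, describe, compare and risk with one root seed, and
#' writes five CSV outputs plus a JSON manifest to `out_dir`:
#' `cohort.csv` (the synthetic cohort), `concentration_summary.csv`
#' (Table-3-style descriptives), `group_comparisons.csv` (the subgroup
#' statistics grid), `risk_summary.csv` (the 18-row EDI/HQ/CR grid of
#' [study_risk_summary()]), `risk_histograms.csv` (binned HQ/CR draws for
#' both routes, all-participants stratum) and `manifest.json` (config hash,
#' seed, package version, timestamp, per-file MD5 checksums; written last).
#' A stage failure aborts with the stage name; outputs already written are
#' left intact.
#'
#' @param config A `naphrisk_config`, as from [default_study_config()] or
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_study_config(), out_dir) {
  stopifnot(inherits(config, "naphrisk_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "naphrisk_pipeline_error", parent = e)
    })
  }
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path, progress = FALSE)
    files <<- c(files, path)
    path
  }

  cohort <- stage("generate", generate_cohort(config$generator))
  stage("generate", write_cohort(cohort, file.path(out_dir, "cohort.csv")))
  files <- c(files, file.path(out_dir, "cohort.csv"))

  stage("describe", emit(describe_cohort(cohort), "concentration_summary.csv"))
  stage("compare", emit(compare_subgroups(cohort), "group_comparisons.csv"))

  risk <- stage("risk", study_risk_summary(
    params = config$exposure,
    n_iterations = config$simulation$n_iterations,
    seed = config$simulation$seed
  ))
  stage("risk", emit(risk$summary, "risk_summary.csv"))
  hist_tbl <- stage("risk", dplyr::bind_rows(
    histogram_bins(risk$runs[["original.all"]]),
    histogram_bins(risk$runs[["creatinine.all"]])
  ))
  stage("risk", emit(hist_tbl, "risk_histograms.csv"))

  manifest <- list(
    package = "naphrisk",
    version = as.character(utils::packageVersion("naphrisk")),
    seed = config$simulation$seed,
    config_hash = unname(tools::md5sum(
      local({
        tmp <- tempfile(fileext = ".rds.txt")
        writeLines(paste(deparse(unclass(config)), collapse = "\n"), tmp)
        tmp
      })
    )),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = purrr::map(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
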