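# Hazard quotient / carcinogenic risk and the Monte-Carlo engine that
# propagates concentration and body-weight variability through the
# reverse-dosimetry formulas.

#' Hazard quotient
#'
#' `HQ = EDI / RfD`, dimensionless. HQ < 1 is read, per USEPA convention, as
#' no significant non-carcinogenic concern.
#'
#' @param edi_per_kg EDI, ug/kg-bw/day. Vectorised.
#' @param rfd Reference dose, ug/kg-bw/day.
#' @return HQ, dimensionless.
#' @export
#' @examples
#' hazard_quotient(20, 20)  # the decision boundary, HQ = 1
hazard_quotient <- function(edi_per_kg, rfd) {
  check_number(rfd, "rfd", positive = TRUE)
  edi_per_kg / rfd
}

#' Benzo[a]pyrene-equivalent dose
#'
#' `EDI_BaPeq = TEF * EDI`, converted from ug to mg: the intermediate of the
#' carcinogenic-risk formula, in mg/kg-bw/day.
#'
#' @param edi_per_kg EDI, ug/kg-bw/day. Vectorised.
#' @param tef Toxic equivalency factor, dimensionless.
#' @return B\[a\]P-equivalent dose, mg/kg-bw/day.
#' @export
bap_equivalent <- function(edi_per_kg, tef) {
  check_number(tef, "tef", nonneg = TRUE)
  edi_per_kg * 1e-3 * tef
}

#' Carcinogenic risk
#'
#' `CR = EDI_BaPeq * CSF` with `EDI_BaPeq = TEF * EDI` in mg/kg-bw/day
#' (see [bap_equivalent()]). CR between 1e-6 and 1e-4 is conventionally
#' acceptable; below 1e-6 negligible.
#'
#' @inheritParams bap_equivalent
#' @param csf Cancer slope factor, (mg/kg-bw/day)^-1.
#' @return CR, dimensionless lifetime risk.
#' @export
#' @examples
#' cancer_risk(0.5401, tef = 0.001, csf = 7.3)
cancer_risk <- function(edi_per_kg, tef, csf) {
  check_number(csf, "csf", nonneg = TRUE)
  bap_equivalent(edi_per_kg, tef) * csf
}

#' Fraction of draws above a threshold
#'
#' Strict "greater than" counting: `count(x > threshold) / n`.
#'
#' @param draws Non-empty numeric vector.
#' @param threshold Scalar threshold.
#' @return Fraction in \[0, 1\].
#' @export
exceedance_fraction <- function(draws, threshold) {
  if (length(draws) == 0L) stop_param("`draws` must be non-empty")
  check_number(threshold, "threshold")
  mean(draws > threshold)
}

#' P5 / mean / P95 of a draw vector
#'
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the spreadsheet convention); the mean is
#' arithmetic.
#'
#' @param draws Non-empty numeric vector.
#' @return A one-row tibble with columns `p5`, `mean`, `p95`.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) == 0L) stop_param("`draws` must be non-empty")
  q <- unname(quantile(draws, c(0.05, 0.95), type = 7, names = FALSE))
  tibble(p5 = q[1], mean = mean(draws), p95 = q[2])
}

#' Monte-Carlo simulation configuration
#'
#' One simulation cell: an EDI route, a population stratum, a lognormal
#' concentration distribution (moment-matched to an arithmetic mean/SD) and
#' a truncated-normal body-weight distribution. On the original route the
#' concentration is the uncorrected urinary level (ug/L); on the creatinine
#' route it is the corrected level (ug/g creatinine) and the stratum selects
#' the daily creatinine excretion C_c (the `"all"` stratum splits iterations
#' equally between the male and female C_c, an equal-weight mixture).
#'
#' @param n_iterations Number of Monte-Carlo iterations (default 1e5).
#' @param seed Integer RNG seed.
#' @param route `"original"` or `"creatinine"`.
#' @param stratum `"male"`, `"female"` or `"all"`.
#' @param conc_mean,conc_sd Concentration distribution (arithmetic scale);
#'   `conc_sd = 0` gives a point mass.
#' @param bw_mean,bw_sd,bw_lower Body-weight truncated normal, kg.
#' @param params An [exposure_params()] object.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_iterations = 1000, seed = 1,
#'                          conc_mean = 20.38, conc_sd = 25.94,
#'                          bw_mean = 67.1, bw_sd = 12.3)
#' run_mcs(cfg)
simulation_config <- function(n_iterations = 100000L, seed = 1L,
                              route = c("original", "creatinine"),
                              stratum = c("all", "male", "female"),
                              conc_mean, conc_sd,
                              bw_mean, bw_sd, bw_lower = 30,
                              params = exposure_params()) {
  route <- match.arg(route)
  stratum <- match.arg(stratum)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop_param("n_iterations must be >= 1")
  check_number(conc_mean, "conc_mean", positive = TRUE)
  check_number(conc_sd, "conc_sd", nonneg = TRUE)
  check_number(bw_mean, "bw_mean", positive = TRUE)
  check_number(bw_sd, "bw_sd", nonneg = TRUE)
  stopifnot(inherits(params, "exposure_params"))
  structure(
    list(n_iterations = n_iterations, seed = as.integer(seed),
         route = route, stratum = stratum,
         conc_mean = conc_mean, conc_sd = conc_sd,
         bw_mean = bw_mean, bw_sd = bw_sd, bw_lower = bw_lower,
         params = params),
    class = "simulation_config"
  )
}

#' Study-default simulation configuration
#'
#' Fills [simulation_config()] with the published study inputs for a given
#' route and stratum. Original route: pooled uncorrected urinary lognormal
#' (20.38, 25.94) ug/L. Creatinine route: corrected lognormals, 10.87 +/-
#' 16.44 (male), 22.43 +/- 25.44 (female), 16.65 +/- 21.98 ug/g (all).
#' Body weight: 71.4 +/- 14.2 (male), 62.8 +/- 8.4 (female), 67.1 +/- 12.3
#' kg (all), truncated at 30 kg.
#'
#' @inheritParams simulation_config
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
study_simulation_config <- function(route = c("original", "creatinine"),
                                    stratum = c("all", "male", "female"),
                                    n_iterations = 100000L, seed = 1L,
                                    params = exposure_params(), ...) {
  route <- match.arg(route)
  stratum <- match.arg(stratum)
  bw <- switch(stratum,
               male = c(71.4, 14.2),
               female = c(62.8, 8.4),
               all = c(67.1, 12.3))
  conc <- if (route == "original") {
    c(20.38, 25.94)
  } else {
    switch(stratum,
           male = c(10.87, 16.44),
           female = c(22.43, 25.44),
           all = c(16.65, 21.98))
  }
  simulation_config(n_iterations = n_iterations, seed = seed, route = route,
                    stratum = stratum, conc_mean = conc[1], conc_sd = conc[2],
                    bw_mean = bw[1], bw_sd = bw[2], params = params, ...)
}

#' Run the Monte-Carlo risk simulation
#'
#' Draws `n_iterations` independent (concentration, body weight) pairs, maps
#' each through the selected EDI route, then through the hazard-quotient and
#' carcinogenic-risk formulas, and summarises each quantity by P5 / mean /
#' P95 plus exceedance fractions (HQ at 0.1 and 1; CR at 1e-6 and 1e-4).
#' Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `naphrisk_mcs`: a list with `draws` (tibble:
#'   `iteration`, `conc`, `bw`, `edi_per_kg`, `edi_per_day`, `hq`, `cr`),
#'   `summary` (tidy P5/mean/P95 per quantity), `exceedance` (tidy
#'   quantity/threshold/fraction) and the `config`. Use [tidy()],
#'   [glance()] and [autoplot()] on it.
#' @export
run_mcs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_iterations
  p <- config$params
  draws <- with_seed(config$seed, {
    conc <- rlnorm_mm(n, config$conc_mean, config$conc_sd)
    bw <- rtnorm_rej(n, config$bw_mean, config$bw_sd, lower = config$bw_lower)
    list(conc = conc, bw = bw)
  })
  conc <- draws$conc
  bw <- draws$bw
  edi <- if (config$route == "original") {
    edi_original(conc, p, bw)
  } else {
    gender <- switch(config$stratum,
                     male = rep("male", n),
                     female = rep("female", n),
                     all = rep(c("male", "female"), length.out = n))
    edi_creatinine(conc, p, gender)
  }
  per_day <- edi_mass_per_day(edi, bw)
  hq <- hazard_quotient(edi, p$rfd)
  cr <- cancer_risk(edi, p$tef, p$csf)

  draws_tbl <- tibble(iteration = seq_len(n), conc = conc, bw = bw,
                      edi_per_kg = edi, edi_per_day = per_day,
                      hq = hq, cr = cr)
  qlist <- list(EDI_per_kg = edi, EDI_per_day = per_day, HQ = hq, CR = cr)
  summary <- purrr::imap(qlist, function(x, nm) {
    dplyr::bind_cols(tibble(quantity = nm), summarize_draws(x))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(route = config$route, stratum = config$stratum,
                  n_iterations = n, seed = config$seed)
  thresholds <- list(HQ = c(0.1, 1), CR = c(1e-6, 1e-4))
  exceedance <- purrr::imap(thresholds, function(th, nm) {
    tibble(quantity = nm, threshold = th,
           fraction = purrr::map_dbl(th, ~ exceedance_fraction(qlist[[nm]], .x)))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(route = config$route, stratum = config$stratum)
  structure(list(draws = draws_tbl, summary = summary,
                 exceedance = exceedance, config = config),
            class = "naphrisk_mcs")
}

#' @export
print.naphrisk_mcs <- function(x, ...) {
  cat(sprintf("Monte-Carlo risk simulation: %s route, %s stratum, %d iterations (seed %d)\n",
              x$config$route, x$config$stratum, x$config$n_iterations,
              x$config$seed))
  print(x$summary)
  cat("Exceedance fractions:\n")
  print(x$exceedance)
  invisible(x)
}

#' @describeIn run_mcs Tidy P5/mean/P95 summary, one row per quantity.
#' @param x A `naphrisk_mcs` object.
#' @param ... Unused.
#' @method tidy naphrisk_mcs
#' @export
tidy.naphrisk_mcs <- function(x, ...) x$summary

#' @describeIn run_mcs One-row overview: mean HQ, mean CR and the headline
#'   exceedance fractions.
#' @method glance naphrisk_mcs
#' @export
glance.naphrisk_mcs <- function(x, ...) {
  tibble(
    route = x$config$route,
    stratum = x$config$stratum,
    n_iterations = x$config$n_iterations,
    seed = x$config$seed,
    mean_hq = mean(x$draws$hq),
    mean_cr = mean(x$draws$cr),
    frac_hq_above_0.1 = exceedance_fraction(x$draws$hq, 0.1),
    frac_cr_above_1e6 = exceedance_fraction(x$draws$cr, 1e-6)
  )
}

#' @describeIn run_mcs Histograms of the simulated HQ (linear scale) and CR
#'   (log10 scale) distributions.
#' @param object A `naphrisk_mcs` object.
#' @method autoplot naphrisk_mcs
#' @export
autoplot.naphrisk_mcs <- function(object, ...) {
  d <- object$draws |>
    dplyr::transmute(HQ = .data$hq, `log10(CR)` = log10(.data$cr)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "draws",
      title = sprintf("Simulated risk distributions (%s route, %s stratum)",
                      object$config$route, object$config$stratum)
    )
}
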