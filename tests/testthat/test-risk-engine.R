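params <- exposure_params()

test_that("hazard quotient and carcinogenic risk formulas", {
  expect_equal(hazard_quotient(20, 20), 1)  # USEPA decision boundary
  expect_equal(hazard_quotient(0, 20), 0)
  expect_equal(hazard_quotient(0.5401, 20), 0.027, tolerance = 1e-3)
  expect_error(hazard_quotient(1, 0), class = "naphrisk_parameter_error")

  expect_equal(cancer_risk(0, 0.001, 7.3), 0)
  expect_equal(cancer_risk(123, 0, 7.3), 0)
  # hand: 0.5401 ug -> 5.401e-4 mg, x TEF 0.001 x CSF 7.3
  expect_equal(cancer_risk(0.5401, 0.001, 7.3), 3.94e-6, tolerance = 1e-3)
  # the B[a]P-equivalent intermediate is exposed in mg/kg-bw/day
  expect_equal(bap_equivalent(0.5401, 0.001), 5.401e-7)
})

test_that("CR is HQ times a fixed constant under the study parameters", {
  # CR = HQ * RfD * 1e-3 * TEF * CSF = HQ * 1.46e-4 with the defaults
  set.seed(3)
  edi <- runif(100, 0, 5)
  hq <- hazard_quotient(edi, params$rfd)
  cr <- cancer_risk(edi, params$tef, params$csf)
  expect_equal(cr, hq * 1.46e-4, tolerance = 1e-12)
})

test_that("exceedance fractions count strictly and match closed-form tails", {
  expect_equal(exceedance_fraction(c(1, 2, 3), 2.5), 1 / 3)
  expect_equal(exceedance_fraction(c(1, 2, 3), 0), 1)
  expect_equal(exceedance_fraction(c(1, 2, 3), 5), 0)
  expect_equal(exceedance_fraction(c(1, 2, 3), 3), 0)  # strict inequality
  expect_error(exceedance_fraction(numeric(0), 1),
               class = "naphrisk_parameter_error")
  # brute-force equivalence on small instances
  set.seed(5)
  for (i in 1:10) {
    x <- runif(sample(1:10, 1))
    t0 <- runif(1)
    expect_equal(exceedance_fraction(x, t0), sum(x > t0) / length(x))
  }
  # lognormal tail oracle: fraction within 3 binomial SEs of 1 - Phi
  mu <- 2.5; sigma <- 1; n <- 1e5
  x <- withr::with_seed(8, rlnorm(n, mu, sigma))
  for (t0 in c(5, 20, 75)) {
    p <- 1 - pnorm((log(t0) - mu) / sigma)
    expect_lt(abs(exceedance_fraction(x, t0) - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("draw summaries use linear-interpolation percentiles", {
  expect_equal(summarize_draws(rep(4.2, 10)),
               tibble::tibble(p5 = 4.2, mean = 4.2, p95 = 4.2))
  s <- summarize_draws(1:100)  # position (n - 1) q + 1
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  z <- withr::with_seed(21, rnorm(1e5))
  expect_equal(summarize_draws(z)$p5, qnorm(0.05), tolerance = 0.02)
  expect_error(summarize_draws(numeric(0)),
               class = "naphrisk_parameter_error")
})

test_that("degenerate simulation equals the closed-form point calculation", {
  cfg <- simulation_config(n_iterations = 100, seed = 1,
                           conc_mean = 20.38, conc_sd = 0,
                           bw_mean = 67.1, bw_sd = 0)
  m <- run_mcs(cfg)
  edi <- edi_original(20.38, params, 67.1)
  s <- m$summary
  for (col in c("p5", "mean", "p95")) {
    expect_equal(s[[col]][s$quantity == "EDI_per_kg"], edi)
    expect_equal(s[[col]][s$quantity == "HQ"], edi / 20)
    expect_equal(s[[col]][s$quantity == "CR"], edi * 1e-3 * 0.001 * 7.3)
  }
  expect_true(all(m$exceedance$fraction %in% c(0, 1)))

  # degenerate creatinine route, gendered stratum
  cfgc <- simulation_config(n_iterations = 50, seed = 1, route = "creatinine",
                            stratum = "female", conc_mean = 16.65,
                            conc_sd = 0, bw_mean = 62.8, bw_sd = 0)
  mc <- run_mcs(cfgc)
  edic <- edi_creatinine(16.65, params, "female")
  expect_equal(mc$summary$mean[mc$summary$quantity == "EDI_per_kg"], edic)
})

test_that("simulations are reproducible and convergent across seeds", {
  cfg1 <- study_simulation_config("original", "all", n_iterations = 2e4,
                                  seed = 11)
  a <- run_mcs(cfg1)
  b <- run_mcs(cfg1)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  cfg2 <- study_simulation_config("original", "all", n_iterations = 2e4,
                                  seed = 12)
  c <- run_mcs(cfg2)
  mc_se <- sd(a$draws$edi_per_kg) / sqrt(2e4)
  expect_lt(abs(mean(a$draws$edi_per_kg) - mean(c$draws$edi_per_kg)),
            5 * mc_se)
})

test_that("mean HQ and CR are monotone in the concentration mean", {
  base <- run_mcs(simulation_config(n_iterations = 5e3, seed = 4,
                                    conc_mean = 20.38, conc_sd = 25.94,
                                    bw_mean = 67.1, bw_sd = 12.3))
  for (m0 in c(25, 40, 80)) {
    up <- run_mcs(simulation_config(n_iterations = 5e3, seed = 4,
                                    conc_mean = m0, conc_sd = 25.94,
                                    bw_mean = 67.1, bw_sd = 12.3))
    expect_gte(mean(up$draws$hq), mean(base$draws$hq))
    expect_gte(mean(up$draws$cr), mean(base$draws$cr))
  }
})

test_that("simulated mean EDI matches the analytic expectation", {
  # E[EDI] = E[C] * V_u * ratio * E[1/BW] / f, with E[1/BW] computed by
  # numerical integration over the truncated normal (independent oracle)
  cfg <- study_simulation_config("original", "all", n_iterations = 1e5,
                                 seed = 42)
  m <- run_mcs(cfg)
  dens_norm <- function(x) dnorm(x, 67.1, 12.3)
  z <- integrate(dens_norm, 30, Inf)$value
  e_inv_bw <- integrate(function(x) dens_norm(x) / x, 30, Inf)$value / z
  expected <- 20.38 * 2 * (128.17 / 144.17) * e_inv_bw
  mc_se <- sd(m$draws$edi_per_kg) / sqrt(1e5)
  expect_lt(abs(mean(m$draws$edi_per_kg) - expected), 3 * mc_se)
})

test_that("mcs objects expose tidy, glance and autoplot views", {
  m <- run_mcs(study_simulation_config("creatinine", "all",
                                       n_iterations = 1e3, seed = 2))
  td <- tidy(m)
  expect_identical(td$quantity, c("EDI_per_kg", "EDI_per_day", "HQ", "CR"))
  expect_true(all(td$p5 <= td$p95))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$mean_hq > 0 && gl$mean_cr > 0)
  # exceedance fractions nonincreasing in the threshold
  exc <- m$exceedance |> dplyr::arrange(quantity, threshold)
  by_q <- split(exc$fraction, exc$quantity)
  for (f in by_q) expect_true(all(diff(f) <= 0))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
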