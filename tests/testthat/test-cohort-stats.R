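test_that("descriptive summaries use n-1 SD and middle-order medians", {
  one <- describe_values(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_false(one$sd_defined)
  expect_equal(one[c("median", "min", "max")],
               tibble::tibble(median = 5, min = 5, max = 5))
  s <- describe_values(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(5 / 3))
  expect_equal(s$median, 2.5)
  expect_equal(c(s$min, s$max), c(1, 4))
  expect_error(describe_values(numeric(0)),
               class = "naphrisk_parameter_error")
})

test_that("spearman correlation: ranks, exact small-sample p, symmetry", {
  up <- spearman_rho(1:6, exp(1:6))
  expect_equal(up$statistic, 1)
  r <- spearman_rho(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$statistic, -0.5)  # 1 - 6 * 6 / (3 * 8)
  expect_equal(r$p.value, brute_force_spearman_p(c(1, 2, 3), c(3, 1, 2)))
  # exact branch matches brute-force enumeration on random small samples
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(6)
    expect_equal(spearman_rho(x, y)$p.value, brute_force_spearman_p(x, y))
  }
  # symmetry and range
  set.seed(17)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_rho(x, y)$statistic, spearman_rho(y, x)$statistic)
  expect_lte(abs(spearman_rho(x, y)$statistic), 1)
  expect_error(spearman_rho(rep(1, 5), rnorm(5)),
               class = "naphrisk_degenerate_error")
})

test_that("mann-whitney: U statistic, exact p, tie behaviour", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.1)  # 2 / choose(6, 3)
  expect_match(r$note, "exact")
  # identical samples sit at the U = n_a n_b / 2 symmetry point, p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p.value, 1)
  # exact p equals brute-force enumeration over labelings, total n <= 10
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(sample(3:5, 1))
    b <- rnorm(sample(3:5, 1))
    expect_equal(mann_whitney_u(a, b)$p.value, brute_force_mw_p(a, b))
  }
})

test_that("kruskal-wallis H and its degenerate/degenerate-free behaviour", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-10)  # 12/42 * 16
  # two groups: p consistent with the mann-whitney normal approximation
  set.seed(19)
  a <- rnorm(15); b <- rnorm(15, 0.8)
  expect_lt(abs(kruskal_wallis(list(a, b))$p.value -
                  mann_whitney_u(a, b)$p.value), 0.05)
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))),
               class = "naphrisk_degenerate_error")
  expect_error(kruskal_wallis(list(1:3)), class = "naphrisk_parameter_error")
})

test_that("rank procedures are invariant under monotone transforms", {
  set.seed(53)
  x <- rlnorm(30); y <- rlnorm(30)
  g <- list(rlnorm(10), rlnorm(10, 0.5), rlnorm(10, 1))
  expect_equal(spearman_rho(exp(x), exp(y))$statistic,
               spearman_rho(x, y)$statistic)
  expect_equal(mann_whitney_u(exp(x), exp(y))$statistic,
               mann_whitney_u(x, y)$statistic)
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic,
               kruskal_wallis(g)$statistic)
})

test_that("KS distance matches brute-force evaluation at the jump points", {
  # hand case: jumps at -1, 0, 1 against the standard normal CDF
  expect_equal(naphrisk:::ks_distance(c(-1, 0, 1)), 1 / 3 - pnorm(-1),
               tolerance = 1e-12)
  expect_equal(round(naphrisk:::ks_distance(c(-1, 0, 1)), 4), 0.1747)
  # agreement with the stats::ks.test statistic on random data
  set.seed(61)
  for (i in 1:5) {
    x <- rnorm(20, 2, 3)
    expect_equal(naphrisk:::ks_distance(x, 2, 3),
                 unname(suppressWarnings(
                   stats::ks.test(x, "pnorm", 2, 3)$statistic)))
  }
})

test_that("normality screening accepts normal and rejects lognormal data", {
  x <- withr::with_seed(71, rnorm(50, 10, 2))
  expect_gt(normality_check(x)$p.value, 0.05)
  # power against the study's right-skewed concentrations: >= 90% of seeds
  rejected <- vapply(1:50, function(s) {
    y <- withr::with_seed(1000 + s, {
      p <- fit_lognormal_moments(20.38, 25.94)
      rlnorm(50, p$mu, p$sigma)
    })
    normality_check(y)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
  expect_error(normality_check(rep(3, 10)),
               class = "naphrisk_degenerate_error")
  expect_error(normality_check(rnorm(4)), class = "naphrisk_parameter_error")
})

test_that("the subgroup grid reproduces the study's comparison structure", {
  cohort <- generate_cohort(generator_config(seed = 81))
  grid <- compare_subgroups(cohort)
  expect_setequal(
    unique(grid$comparison),
    c("gender", "age", "bmi", "urine_vs_hair", "polluted_vs_control")
  )
  expect_identical(nrow(grid), 9L)
  # polluted vs control urine separates sharply (two far-apart lognormals)
  pvc <- grid[grid$comparison == "polluted_vs_control" &
                grid$matrix == "urine", ]
  expect_lt(pvc$p.value, 0.001)
  # independent urine and hair draws: weak correlation at this sample size
  uvh <- grid[grid$comparison == "urine_vs_hair", ]
  expect_lt(abs(uvh$statistic), 0.5)
})

test_that("bmi classes follow half-open clinical intervals", {
  expect_equal(as.character(bmi_class(c(18.4, 18.5, 24.9, 25, 30))),
               c("underweight", "normal", "normal", "overweight", "obese"))
})
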