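# Descriptive and inferential statistics used in biomonitoring cohorts:
# summaries, normality screening (Lilliefors-corrected KS), rank-based
# two-group and multi-group tests, and Spearman correlations. All tests are
# two-sided. Results come back as one-row tibbles with broom-style column
# names (`statistic`, `p.value`) so they bind into tidy comparison tables.

stat_result <- function(method, statistic_name, statistic, p.value, n, note) {
  tibble(method = method, statistic_name = statistic_name,
         statistic = statistic, p.value = p.value, n = n, note = note)
}

#' Descriptive summary of a value vector
#'
#' Mean, sample SD (n - 1 denominator), median (average of the two middle
#' order statistics for even n), min and max. A single observation yields an
#' NA standard deviation, flagged in `sd_defined`.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `sd_defined`.
#' @export
#' @examples
#' describe_values(c(1, 2, 3, 4))
describe_values <- function(values) {
  if (length(values) == 0L) stop_param("`values` must be non-empty")
  n <- length(values)
  tibble(
    n = n,
    mean = mean(values),
    sd = if (n > 1L) sd(values) else NA_real_,
    median = median(values),
    min = min(values),
    max = max(values),
    sd_defined = n > 1L
  )
}

#' Spearman rank correlation
#'
#' Ties receive average ranks; rho is the Pearson correlation of the ranks.
#' The two-sided p-value comes from exact permutation enumeration for
#' n <= 8 and from the t approximation with n - 2 degrees of freedom
#' otherwise.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return A one-row result tibble (`statistic` is rho).
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_param("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop_param("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_degenerate("correlation undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    note <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    note <- "t approximation, n - 2 df"
  }
  stat_result("Spearman rank correlation", "rho", rho, min(p, 1), n, note)
}

# All permutations of 1:n as a matrix (n! rows); recursion is fine for the
# n <= 8 exact branch.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_a, U_b)` with a two-sided p-value: exact when the
#' pooled sample size is <= 12 and tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A one-row result tibble (`statistic` is U; `n` is the pooled
#'   size).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_param("both samples must be non-empty")
  }
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u <- min(u_a, n_a * n_b - u_a)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (n_a + n_b) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  note <- if (exact) "exact enumeration" else
    "normal approximation, tie-corrected"
  stat_result("Mann-Whitney U", "U", u, wt$p.value, n_a + n_b, note)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A one-row result tibble (`statistic` is H).
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_param("`groups` must be a list of >= 2 samples")
  }
  if (any(lengths(groups) == 0L)) stop_param("all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (sd(values) == 0) {
    stop_degenerate("all values identical: H is undefined")
  }
  kt <- stats::kruskal.test(groups)
  stat_result("Kruskal-Wallis", "H", unname(kt$statistic),
              kt$p.value, length(values),
              sprintf("chi-square, %d df", unname(kt$parameter)))
}

# Kolmogorov-Smirnov sup-norm distance between the empirical CDF of `values`
# and Normal(mean, sd), evaluated at the jump points from both sides.
ks_distance <- function(values, mean = 0, sd = 1) {
  x <- sort(values)
  n <- length(x)
  f <- stats::pnorm(x, mean, sd)
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}

#' Normality screening (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS distance against a normal with the sample mean and SD; the
#' p-value uses the Lilliefors correction, since the naive KS p is
#' anticonservative when the reference parameters are estimated from the
#' data.
#'
#' @param values Numeric vector, n >= 5, non-constant.
#' @return A one-row result tibble (`statistic` is the KS distance D).
#' @export
normality_check <- function(values) {
  if (length(values) < 5L) stop_param("need n >= 5")
  if (sd(values) == 0) stop_degenerate("constant vector: normality undefined")
  lt <- nortest::lillie.test(values)
  stat_result("Kolmogorov-Smirnov (Lilliefors)", "D",
              unname(lt$statistic), lt$p.value, length(values),
              "Lilliefors-corrected, parameters estimated")
}

#' Subgroup comparison grid for a cohort
#'
#' Reproduces the biomonitoring comparison grid on the analysis values
#' (LOD/2-substituted; urine on the creatinine-corrected scale): gender
#' differences by Mann-Whitney, age and BMI associations by Spearman, the
#' hair-urine association by Spearman, and polluted-vs-control differences
#' by Mann-Whitney (when controls are present).
#'
#' @param cohort A cohort tibble.
#' @return A tidy tibble: `comparison`, `matrix`, `method`, `statistic`,
#'   `p.value`, `n`, `note`.
#' @export
compare_subgroups <- function(cohort) {
  vals <- analysis_values(cohort)
  wide <- vals |>
    dplyr::transmute(
      id = .data$id, matrix = .data$matrix,
      value = dplyr::if_else(.data$matrix == "urine",
                             .data$corrected_ug_per_g, .data$working_value)
    ) |>
    tidyr::pivot_wider(names_from = "matrix", values_from = "value") |>
    dplyr::left_join(
      dplyr::select(cohort, "id", "group", "gender", "age_years", "bmi"),
      by = "id"
    )
  pol <- dplyr::filter(wide, .data$group == "polluted")
  ctl <- dplyr::filter(wide, .data$group == "control")

  add <- function(res, comparison, matrix) {
    dplyr::bind_cols(tibble(comparison = comparison, matrix = matrix), res)
  }
  rows <- list(
    add(mann_whitney_u(pol$urine[pol$gender == "male"],
                       pol$urine[pol$gender == "female"]),
        "gender", "urine"),
    add(mann_whitney_u(pol$hair[pol$gender == "male"],
                       pol$hair[pol$gender == "female"]),
        "gender", "hair"),
    add(spearman_rho(pol$age_years, pol$urine), "age", "urine"),
    add(spearman_rho(pol$age_years, pol$hair), "age", "hair"),
    add(spearman_rho(pol$bmi, pol$urine), "bmi", "urine"),
    add(spearman_rho(pol$bmi, pol$hair), "bmi", "hair"),
    add(spearman_rho(pol$urine, pol$hair), "urine_vs_hair", "both")
  )
  if (nrow(ctl) > 0L) {
    rows <- c(rows, list(
      add(mann_whitney_u(pol$urine, ctl$urine), "polluted_vs_control",
          "urine"),
      add(mann_whitney_u(pol$hair, ctl$hair), "polluted_vs_control", "hair")
    ))
  }
  purrr::list_rbind(rows)
}

#' Table-style concentration summary of a cohort
#'
#' Mean/SD/median/min/max of the polluted-group analysis values on the three
#' reported scales: uncorrected urine (ug/L), creatinine-corrected urine
#' (ug/g creatinine), hair (ng/g dw).
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per scale.
#' @export
describe_cohort <- function(cohort) {
  vals <- analysis_values(cohort)
  pid <- cohort$id[cohort$group == "polluted"]
  u <- vals[vals$matrix == "urine" & vals$id %in% pid, ]
  h <- vals[vals$matrix == "hair" & vals$id %in% pid, ]
  dplyr::bind_rows(
    dplyr::bind_cols(tibble(scale = "urine_ug_per_L"),
                     describe_values(u$working_value)),
    dplyr::bind_cols(tibble(scale = "urine_ug_per_g_creatinine"),
                     describe_values(u$corrected_ug_per_g)),
    dplyr::bind_cols(tibble(scale = "hair_ng_per_g"),
                     describe_values(h$working_value))
  )
}

#' BMI weight classes
#'
#' Half-open intervals: underweight `< 18.5`, normal `[18.5, 25)`,
#' overweight `[25, 30)`, obese `>= 30`.
#'
#' @param bmi Numeric vector of BMI values, kg/m2.
#' @return A factor with the four class labels.
#' @export
bmi_class <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}
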