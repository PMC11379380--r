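# Shared fixtures, built in code.

# A small hand-written cohort (3 polluted + 1 control) with one hair
# non-detect, used where generated randomness would get in the way.
tiny_cohort <- function() {
  tibble::tibble(
    id = c("P001", "P002", "P003", "C001"),
    group = c("polluted", "polluted", "polluted", "control"),
    gender = c("male", "female", "male", "female"),
    age_years = c(46, 30, 62, 51),
    bmi = c(25.2, 22.1, 28.9, 24.0),
    body_weight_kg = c(71.4, 62.8, 80.0, 60.0),
    urine_conc_ug_per_L = c(7.6, 20.38, 89.07, 0.26),
    urine_detect = c(TRUE, TRUE, TRUE, TRUE),
    urine_creatinine_mg_per_dL = c(144.326, 100, 180, 120),
    hair_conc_ng_per_g = c(6.68, 0.15, 47.11, 0.7),
    hair_detect = c(TRUE, FALSE, TRUE, TRUE)
  )
}

write_tiny_cohort <- function(path = tempfile(fileext = ".csv")) {
  write_cohort(tiny_cohort(), path)
  path
}

# Brute-force two-sided Mann-Whitney p over all C(n_a + n_b, n_a) labelings
# of the pooled sample (independent of wilcox.test): counts labelings whose
# U statistic is at least as extreme on either side.
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  m <- n_a * (length(b))
  lo <- min(u_obs, m - u_obs)
  sets <- utils::combn(n, n_a)
  us <- apply(sets, 2L, u_of)
  mean(us <= lo | us >= m - lo)
}

# Brute-force two-sided Spearman permutation p; permutations enumerated
# here independently of the package (insertion construction).
enumerate_perms <- function(n) {
  perms <- list(1L)
  for (k in 2L:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  perms
}

brute_force_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rhos <- vapply(enumerate_perms(length(x)),
                 function(idx) stats::cor(rx, ry[idx]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
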