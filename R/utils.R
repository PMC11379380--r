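# Internal helpers shared across modules.

# Error constructors: every user-facing failure carries a subclass so callers
# (and tests) can distinguish schema, parse, integrity and parameter errors.
stop_schema <- function(msg) abort(msg, class = "naphrisk_schema_error")
stop_parse <- function(msg) abort(msg, class = "naphrisk_parse_error")
stop_integrity <- function(msg) abort(msg, class = "naphrisk_integrity_error")
stop_param <- function(msg) abort(msg, class = "naphrisk_parameter_error")
stop_degenerate <- function(msg) abort(msg, class = "naphrisk_degenerate_error")

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards. Used to give each variable block of the synthetic
# generator its own stream, so e.g. changing the control-group size does not
# perturb the polluted-group draws.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_param(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_param(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
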