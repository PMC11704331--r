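#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All generator functions route their randomness through this, so a
# config (seed included) pins the output exactly and no global state leaks.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a global seed; kept below 2^31 - 1 so it is a
# valid R integer. Documented so stages can be re-run in isolation.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage_index) %% 2147483647)
}

stop_spatsig <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_spatsig(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop_spatsig(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_spatsig(sprintf("'%s' must be >= 0", name))
  invisible(x)
}

check_fraction <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) stop_spatsig(sprintf("'%s' must be in [0, 1]", name))
  invisible(x)
}
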