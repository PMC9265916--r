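# Rounding helpers used for report tables.
#
# Per-class prediction rates are rounded half-up at one decimal (73.077 ->
# 73.1); pooled totals are truncated at two decimals (56/57 -> 98.24). Both
# conventions are fixed by the reference report tables this package
# reproduces, and differ from R's round-half-even.

#' Round half-up on the magnitude
#'
#' Rounds `|x|` half-way cases away from zero (5.05 -> 5.1 at one decimal),
#' unlike [round()]'s banker's rounding. Used for per-class prediction
#' percentages and fixture summary tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon so values that are .x4999999 only through binary round-off
  # of an intended .x5 still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Truncate (floor toward zero on the magnitude) at `digits` decimals.
trunc_decimals <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

# stop() with sprintf formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# usable for name-based column matching: non-NULL, non-empty, unique
valid_names <- function(nm) {
  !is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers global reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stopf("'seed' must be a single finite integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
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
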