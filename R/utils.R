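#' Round a percentage half-up to one decimal
#'
#' Coverage percentages are conventionally reported to one decimal with
#' halves rounded up (so 36.25 prints as 36.3). R's [round()] uses
#' round-half-to-even, which would print 36.2; this helper implements the
#' reporting convention used throughout the package's tables.
#'
#' @param x numeric vector of percentages (or any numeric).
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_pct(100 * 58 / 160)  # 36.3
#' round_pct(100 * 7 / 16)    # 43.8
#' @export
round_pct <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# stopifnot-style check with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
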