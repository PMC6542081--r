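#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when printing audit percentages.
#' Base [round()] rounds half to even, which does not reproduce printed
#' one-decimal tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves rounded away from zero.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against 0.49999... binary representations
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator
#'
#' @param count,denom non-negative counts; `denom` may be zero, giving `NA`.
#' @param digits decimal places (half-up).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct(24, 386) # 6.2
pct <- function(count, denom, digits = 1) {
  out <- ifelse(denom > 0, round_half_up(100 * count / denom, digits), NA_real_)
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with a stage prefix so pipeline failures name the failing stage
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
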