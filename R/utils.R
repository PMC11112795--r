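#' Round half away from zero
#'
#' Report tables round half away from zero (so 4.2215 -> 4.222 at 3
#' decimals), unlike [base::round()]'s round-half-to-even. Used for all
#' printed summary values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values stored just below .5 (floating
  # point) still round away from zero, e.g. 4.2215 * 1000
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# internal: stop with a consistent message prefix
ms_stop <- function(...) stop(..., call. = FALSE)

# internal: scalar checks
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

# internal: seeded evaluation that does not disturb the caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
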