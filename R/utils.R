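#' Round half away from zero
#'
#' Rounding convention used when comparing computed summaries against
#' published tables, which are printed with conventional half-up rounding
#' rather than IEEE round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(12.75, 1)  # 12.8, where round() may give 12.8 or 12.7
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_invalid("`", name, "` must be a non-empty numeric vector")
  }
  if (finite && any(!is.finite(x))) {
    stop_invalid("`", name, "` must contain only finite values")
  }
  if (positive && any(x <= 0)) {
    stop_invalid("`", name, "` must be strictly positive")
  }
  invisible(x)
}
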