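#' Multi-echo acquisition protocol
#'
#' Describes the echo train of a multi-echo T2 acquisition (e.g. a 32-echo
#' 3D GRASE sequence). Echo times drive both the forward decay model used in
#' simulation and the decay basis used in spectrum fitting.
#'
#' @param echo_times numeric vector of echo times in ms, strictly increasing
#'   and positive. Default: 32 echoes at 10, 20, ..., 320 ms.
#' @param repetition_time repetition time in ms (carried as metadata only).
#' @return An object of class `acquisition_protocol`.
#' @export
#' @examples
#' acquisition_protocol()
acquisition_protocol <- function(echo_times = seq(10, 320, by = 10),
                                 repetition_time = 1000) {
  check_numeric(echo_times, "echo_times", positive = TRUE)
  if (is.unsorted(echo_times, strictly = TRUE)) {
    stop_invalid("`echo_times` must be strictly increasing")
  }
  structure(
    list(echo_times = as.numeric(echo_times),
         repetition_time = as.numeric(repetition_time)),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  te <- x$echo_times
  cat(sprintf("Multi-echo protocol: %d echoes, TE %g-%g ms (TR %g ms)\n",
              length(te), min(te), max(te), x$repetition_time))
  invisible(x)
}

#' T2 grid for spectrum fitting
#'
#' The discrete set of candidate T2 relaxation times over which the NNLS
#' inversion distributes amplitude. The default covers the total-signal
#' window 15-2000 ms with 40 logarithmically spaced points, a conventional
#' density for 32-echo data.
#'
#' @param n number of grid points.
#' @param range length-2 numeric, grid limits in ms.
#' @param values optional explicit grid (overrides `n`/`range`); must be
#'   strictly increasing and positive.
#' @return An object of class `t2_grid` (numeric vector of T2 values in ms).
#' @export
#' @examples
#' t2_grid()
#' t2_grid(values = c(20, 80, 2000))
t2_grid <- function(n = 40, range = c(15, 2000), values = NULL) {
  if (is.null(values)) {
    if (n < 2) stop_invalid("`n` must be at least 2")
    check_numeric(range, "range", positive = TRUE)
    values <- exp(seq(log(range[1]), log(range[2]), length.out = n))
  }
  check_numeric(values, "values", positive = TRUE)
  if (is.unsorted(values, strictly = TRUE)) {
    stop_invalid("T2 grid values must be strictly increasing")
  }
  structure(as.numeric(values), class = "t2_grid")
}

#' @export
print.t2_grid <- function(x, ...) {
  cat(sprintf("T2 grid: %d points, %g-%g ms\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Exponential decay basis
#'
#' Builds the n_echoes x n_grid design matrix with entries
#' `exp(-TE_i / T2_j)` linking a discrete T2 spectrum to the measured
#' multi-echo decay. This is the linear operator inverted by the NNLS fit.
#'
#' @param protocol an [acquisition_protocol()].
#' @param grid a [t2_grid()].
#' @return An object of class `decay_basis`: list with `matrix`, `protocol`,
#'   `grid`.
#' @export
#' @examples
#' basis <- build_decay_basis(acquisition_protocol(), t2_grid())
#' dim(basis$matrix)
build_decay_basis <- function(protocol = acquisition_protocol(),
                              grid = t2_grid()) {
  if (!inherits(protocol, "acquisition_protocol")) {
    protocol <- acquisition_protocol(protocol)
  }
  if (!inherits(grid, "t2_grid")) grid <- t2_grid(values = grid)
  if (length(protocol$echo_times) == 0L || length(grid) == 0L) {
    stop_invalid("protocol and grid must be non-empty")
  }
  A <- exp(-outer(protocol$echo_times, unclass(grid), "/"))
  structure(list(matrix = A, protocol = protocol, grid = grid),
            class = "decay_basis")
}

#' @export
print.decay_basis <- function(x, ...) {
  cat(sprintf("Decay basis: %d echoes x %d T2 grid points\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
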