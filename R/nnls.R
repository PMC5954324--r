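#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min ||A x - b||_2 subject to x >= 0`. This is the inversion
#' engine behind the T2 spectrum fit: the active-set iteration terminates at
#' the exact constrained minimiser (up to floating tolerance), with no
#' randomised initialisation, so results are bit-reproducible.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol dual-feasibility tolerance; defaults to a scale-aware multiple
#'   of machine epsilon.
#' @return List with `x` (the non-negative solution), `residual_norm`
#'   (`||A x - b||_2`), and `passive` (logical, support of the solution).
#' @export
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 3)
#' nnls_solve(A, c(1, -1, 1))$x
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) stop_invalid("nrow(A) must equal length(b)")
  if (any(!is.finite(A)) || any(!is.finite(b))) {
    stop_invalid("`A` and `b` must be finite")
  }
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(tol)) {
    tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n) *
      max(1, max(abs(b)))
  }
  x <- numeric(n)
  passive <- logical(n)
  Atb <- drop(crossprod(A, b))
  max_outer <- 3L * n + 30L
  for (outer in seq_len(max_outer)) {
    w <- Atb - drop(crossprod(A, A %*% x))
    cand <- which(!passive & w > tol)
    if (length(cand) == 0L) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      ip <- which(passive)
      z <- numeric(n)
      z[ip] <- qr.coef(qr(A[, ip, drop = FALSE]), b)
      z[ip][is.na(z[ip])] <- 0  # rank-deficient passive set
      if (all(z[ip] > 0)) {
        x <- z
        break
      }
      q <- ip[z[ip] <= 0]
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      drop_idx <- ip[z[ip] <= 0 & x[ip] <= tol]
      passive[drop_idx] <- FALSE
      x[drop_idx] <- 0
      x[x < 0] <- 0
    }
  }
  list(x = x,
       residual_norm = sqrt(sum((A %*% x - b)^2)),
       passive = passive)
}

# Tikhonov-augmented NNLS: min ||A x - b||^2 + mu ||x||^2, x >= 0,
# solved as plain NNLS on the stacked system [A; sqrt(mu) I].
nnls_tikhonov <- function(A, b, mu) {
  n <- ncol(A)
  Aaug <- rbind(A, diag(sqrt(mu), n))
  baug <- c(b, numeric(n))
  fit <- nnls_solve(Aaug, baug)
  fit$residual_norm <- sqrt(sum((A %*% fit$x - b)^2))
  fit
}

# Chi^2-constrained regularised NNLS: bisection on the Tikhonov weight mu so
# the data misfit chi^2(mu) = chi2_factor * chi^2(0). Among non-negative
# solutions with that misfit the Tikhonov solution has minimal ||x||_2.
nnls_chi2 <- function(A, b, chi2_factor = 1.02, max_iter = 100L,
                      rel_tol = 1e-6) {
  if (chi2_factor < 1) stop_invalid("`chi2_factor` must be >= 1")
  base <- nnls_solve(A, b)
  chi0 <- base$residual_norm^2
  if (chi2_factor == 1 || chi0 == 0) {
    base$mu <- 0
    return(base)
  }
  target <- chi2_factor * chi0
  chi_at <- function(mu) {
    fit <- nnls_tikhonov(A, b, mu)
    fit$mu <- mu
    fit
  }
  # bracket the weight
  hi <- chi0 / max(sum(b^2), .Machine$double.xmin) * 1e-6 + 1e-300
  fit_hi <- chi_at(hi)
  grow <- 0L
  while (fit_hi$residual_norm^2 < target) {
    hi <- hi * 10
    fit_hi <- chi_at(hi)
    grow <- grow + 1L
    if (grow > 400L) stop_invalid("chi2 bisection failed to bracket the target misfit")
  }
  lo <- 0
  best <- fit_hi
  for (i in seq_len(max_iter)) {
    mid <- if (lo == 0) hi / 10 else sqrt(lo * hi)
    fit <- chi_at(mid)
    chi <- fit$residual_norm^2
    if (chi < target) lo <- mid else hi <- mid
    if (abs(chi - target) < abs(best$residual_norm^2 - target)) best <- fit
    if (abs(chi - target) <= rel_tol * target) return(fit)
  }
  if (abs(best$residual_norm^2 - target) > 0.05 * target) {
    stop_invalid(sprintf(
      "chi2-constrained NNLS did not converge in %d iterations (achieved misfit ratio %.6g, target %.6g)",
      max_iter, best$residual_norm^2 / chi0, chi2_factor))
  }
  best
}
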