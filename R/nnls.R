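# Non-negative least squares on the normal equations.
#
# MCR-ALS spends its time in thousands of small NNLS problems per
# half-step, all sharing one design matrix. Working from the Gram matrix
# AtA (k x k) and the projected right-hand sides AtB lets the whole batch
# reuse one crossproduct, and the active-set iteration then only touches
# k x k systems.

# Lawson-Hanson active-set NNLS for a single right-hand side, given
# AtA = t(A) %*% A and Atb = t(A) %*% b. Guarded against singular passive
# subsystems and degenerate zero-step cycles.
nnls_normal_single <- function(AtA, Atb, tol) {
  k <- length(Atb)
  x <- numeric(k)
  passive <- logical(k)
  budget <- 30L * k + 30L
  iter <- 0L
  repeat {
    w <- Atb - drop(AtA %*% x)
    cand <- which(!passive)
    if (length(cand) == 0 || max(w[cand]) <= tol) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > budget) return(pmax(x, 0)) # anti-cycling exit
      p <- which(passive)
      if (length(p) == 0) {
        x[] <- 0
        break
      }
      z <- numeric(k)
      sol <- tryCatch(solve(AtA[p, p, drop = FALSE], Atb[p]),
                      error = function(e) NULL)
      if (is.null(sol)) {
        sol <- qr.coef(qr(AtA[p, p, drop = FALSE]), Atb[p])
        sol[is.na(sol)] <- 0
      }
      z[p] <- sol
      if (all(z[p] > 0)) {
        x <- z
        break
      }
      neg <- p[z[p] <= 0]
      denom <- x[neg] - z[neg]
      ratio <- ifelse(denom > 0, x[neg] / denom, 0)
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      drop_idx <- p[x[p] <= tol]
      if (length(drop_idx) == 0) drop_idx <- neg[which.min(ratio)]
      passive[drop_idx] <- FALSE
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

# Batched NNLS: solve min ||A X - B|| with X >= 0 column-wise, for a shared
# A. Takes the unconstrained solution where it is already feasible and runs
# the active-set solver only on the remaining columns.
nnls_batch <- function(AtA, AtB, tol = 1e-10) {
  X <- tryCatch(solve(AtA, AtB), error = function(e) NULL)
  k <- nrow(AtA)
  n <- ncol(AtB)
  if (is.null(X)) X <- matrix(-1, k, n) # force the constrained path
  bad <- which(apply(X < -tol, 2, any))
  X[X < 0] <- 0
  scale_tol <- tol * max(abs(diag(AtA)), 1)
  for (j in bad) {
    X[, j] <- nnls_normal_single(AtA, AtB[, j], scale_tol)
  }
  X
}

#' Non-negative least-squares regression of spectra on component profiles
#'
#' Solves `min ||x - S^T a||` subject to `a >= 0` for each spectrum row,
#' with a shared profile matrix `S` (components x channels). This is the
#' abundance-estimation primitive used by the MCR score updates and by
#' [project_scores()].
#'
#' @param S Component profile matrix, components x channels.
#' @param X Spectrum matrix, spectra x channels.
#' @return Non-negative coefficient matrix, spectra x components.
#' @export
nnls_coefficients <- function(S, X) {
  S <- as.matrix(S)
  X <- as.matrix(X)
  if (ncol(S) != ncol(X)) stop("S and X must share the channel axis")
  AtA <- tcrossprod(S) # t(t(S)) %*% t(S)
  AtB <- S %*% t(X)
  t(nnls_batch(AtA, AtB))
}
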