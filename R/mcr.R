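#' MCR-ALS decomposition of a spectral dataset
#'
#' Multivariate curve resolution by alternating least squares factorizes the
#' spectrum matrix `D` (spectra x channels) into non-negative scores `C`
#' (spectra x k) and non-negative component spectra `S` (k x channels),
#' `D ~ C S`, without reference spectra. Both half-steps are non-negative
#' least-squares problems; after each iteration rows of `S` are rescaled to
#' unit Euclidean norm with the scale absorbed into `C`, so all magnitude
#' lives in the scores and score distributions are comparable across groups.
#' Convergence is monitored through the lack of fit,
#' `LOF(%) = 100 * sqrt(sum(E^2) / sum(D^2))` with `E = D - C S`.
#'
#' Initialization is a deterministic SIMPLISMA-style purest-variable
#' selection (the k most mutually independent high-purity channels seed the
#' initial scores); a seeded random non-negative initialization is available
#' as a fallback. Negative intensities (small undershoots left by background
#' subtraction) are clipped to zero with a warning, since the bilinear model
#' assumes a non-negative data matrix.
#'
#' @param d A [spectra_dataset()], normally preprocessed.
#' @param k Number of components (the study design here uses 5).
#' @param init `"purest"` (deterministic) or `"random"`.
#' @param max_iter Maximum ALS iterations.
#' @param tol Absolute change in LOF percentage that stops iteration.
#' @param seed Seed for `init = "random"`.
#' @param negative_tol Most negative allowed input intensity before clipping
#'   is refused.
#' @return An object of class `mcr_model` with `S` (k x channels, rows unit
#'   norm), `C` (spectra x k), `lof_history` (% per iteration), `k`,
#'   `wavenumbers`, `labels` (filled by [label_components()]) and
#'   `converged`.
#' @export
fit_mcr_als <- function(d, k = 5L, init = c("purest", "random"),
                        max_iter = 500L, tol = 1e-6, seed = 1L,
                        negative_tol = 0.2) {
  stopifnot(inherits(d, "spectra_dataset"))
  init <- match.arg(init)
  D <- d$intensities
  if (k < 1 || k >= min(nrow(D), ncol(D))) {
    stop(sprintf("k must satisfy 1 <= k < min(n_spectra, n_channels) = %d",
                 min(nrow(D), ncol(D))))
  }
  dscale <- max(abs(D))
  if (min(D) < -negative_tol * dscale) {
    stop("data matrix has large negative entries; background subtraction ",
         "appears inconsistent with a non-negative bilinear model")
  }
  if (min(D) < 0) {
    warning("clipping ", sum(D < 0), " negative intensities to zero for MCR")
    D <- pmax(D, 0)
  }
  d_ss <- sum(D^2)
  if (d_ss == 0) stop("data matrix is identically zero")

  C <- switch(init,
    purest = D[, purest_variables(D, k), drop = FALSE],
    random = withr::with_seed(seed,
      matrix(stats::runif(nrow(D) * k), nrow(D), k))
  )
  lof <- numeric(0)
  S <- NULL
  for (it in seq_len(max_iter)) {
    # S given C: channels regressed on the score columns
    S <- nnls_batch(crossprod(C), crossprod(C, D))        # k x channels
    rn <- sqrt(rowSums(S^2))
    if (any(rn == 0)) {
      # dead component: reseed it with the worst-fit spectrum's residual
      for (j in which(rn == 0)) {
        res <- D - C %*% S
        S[j, ] <- pmax(res[which.max(rowSums(res^2)), ], 0)
        if (all(S[j, ] == 0)) S[j, ] <- 1
      }
      rn <- sqrt(rowSums(S^2))
    }
    S <- S / rn
    # C given S: spectra regressed on the (unit-norm) component spectra
    C <- t(nnls_batch(tcrossprod(S), S %*% t(D)))
    resid <- D - C %*% S
    lof <- c(lof, 100 * sqrt(sum(resid^2) / d_ss))
    if (it > 1 && abs(lof[it - 1] - lof[it]) < tol) break
  }
  # order components by decreasing total score mass
  ord <- order(colSums(C), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  comp_names <- sprintf("MC%d", seq_len(k))
  rownames(S) <- comp_names
  colnames(C) <- comp_names
  rownames(C) <- d$meta$spectrum_id
  structure(
    list(S = S, C = C, lof_history = lof, k = as.integer(k),
         wavenumbers = d$wavenumbers, labels = NULL,
         converged = length(lof) < max_iter, init = init),
    class = "mcr_model"
  )
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model> k = %d, %d channels, LOF = %.3f%% after %d iterations\n",
              x$k, ncol(x$S), utils::tail(x$lof_history, 1),
              length(x$lof_history)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%s=%s", names(x$labels), x$labels),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# SIMPLISMA-style purest-variable selection: channels with high
# relative standard deviation that are mutually independent, judged by the
# determinant of the correlation-around-origin matrix of the candidates.
purest_variables <- function(D, k, offset_frac = 0.05) {
  n <- nrow(D)
  mu <- colMeans(D)
  sdev <- sqrt(colMeans(D^2) - mu^2)
  offset <- offset_frac * max(mu)
  purity <- sdev / (mu + offset)
  # length-scaled channels for the independence determinant
  Z <- sweep(D, 2, sqrt(colMeans(D^2) + (offset)^2), "/") / sqrt(n)
  picked <- integer(0)
  for (j in seq_len(k)) {
    if (length(picked) == 0) {
      w <- rep(1, ncol(D))
    } else {
      Zp <- Z[, picked, drop = FALSE]
      G <- crossprod(Zp)
      w <- vapply(seq_len(ncol(D)), function(v) {
        gv <- crossprod(Zp, Z[, v])
        det(rbind(cbind(crossprod(Z[, v]), t(gv)), cbind(gv, G)))
      }, numeric(1))
      w <- pmax(w, 0)
    }
    score <- purity * w
    score[picked] <- -Inf
    picked <- c(picked, which.max(score))
  }
  picked
}

#' Project new spectra onto a fitted MCR model
#'
#' Non-negative least-squares regression of each spectrum on the model's
#' component spectra; returns score surrogates on the same scale as the
#' training `C`.
#'
#' @param model A fitted `mcr_model`.
#' @param d A [spectra_dataset()] on the same wavenumber axis.
#' @return Non-negative score matrix, spectra x k.
#' @export
project_scores <- function(model, d) {
  stopifnot(inherits(model, "mcr_model"), inherits(d, "spectra_dataset"))
  if (length(d$wavenumbers) != length(model$wavenumbers) ||
      any(d$wavenumbers != model$wavenumbers)) {
    stop("wavenumber axis of the dataset does not match the model")
  }
  scores <- nnls_coefficients(model$S, pmax(d$intensities, 0))
  dimnames(scores) <- list(d$meta$spectrum_id, rownames(model$S))
  scores
}

#' Label MCR components by cosine match against a reference library
#'
#' Greedy injective assignment: component-profile pairs are considered in
#' decreasing cosine-similarity order (ties broken by component index); a
#' component gets the best still-unused library label if the cosine reaches
#' `min_cosine`, otherwise it is labeled `"mixed"`.
#'
#' @param model A fitted `mcr_model`.
#' @param library A [build_component_library()] on the same axis.
#' @param min_cosine Minimum cosine similarity for a named label.
#' @return The model with `labels` filled (named character vector, one entry
#'   per component).
#' @export
label_components <- function(model, library = build_component_library(),
                             min_cosine = 0.7) {
  stopifnot(inherits(model, "mcr_model"), inherits(library, "component_library"))
  if (length(model$wavenumbers) != length(library$wavenumbers) ||
      any(model$wavenumbers != library$wavenumbers)) {
    stop("wavenumber axis of the library does not match the model")
  }
  Sn <- model$S / sqrt(rowSums(model$S^2))
  cosine <- Sn %*% t(library$profiles) # k x n_library
  labels <- rep("mixed", model$k)
  used <- character(0)
  pairs <- expand.grid(comp = seq_len(model$k),
                       lib = seq_along(library$names))
  pairs$cos <- cosine[as.matrix(pairs)]
  pairs <- pairs[order(-pairs$cos, pairs$comp), ]
  for (i in seq_len(nrow(pairs))) {
    if (pairs$cos[i] < min_cosine) break
    comp <- pairs$comp[i]
    lib <- library$names[pairs$lib[i]]
    if (labels[comp] == "mixed" && !(lib %in% used)) {
      labels[comp] <- lib
      used <- c(used, lib)
    }
  }
  names(labels) <- rownames(model$S)
  model$labels <- labels
  model
}

#' Lack of fit of an MCR model on a dataset
#'
#' `LOF(%) = 100 * sqrt(sum((D - C S)^2) / sum(D^2))`; 0 for a perfect
#' reconstruction, 100 when the model explains nothing.
#'
#' @param model A fitted `mcr_model`.
#' @param d A [spectra_dataset()] whose spectra match the rows of `model$C`,
#'   or any dataset if `C` is supplied.
#' @param C Optional score matrix to use instead of `model$C`.
#' @return LOF percentage (scalar).
#' @export
lack_of_fit <- function(model, d, C = model$C) {
  D <- pmax(d$intensities, 0)
  if (nrow(C) != nrow(D) || ncol(model$S) != ncol(D)) {
    stop("dimensions of model and dataset do not agree")
  }
  d_ss <- sum(D^2)
  if (d_ss == 0) stop("dataset has zero norm")
  100 * sqrt(sum((D - C %*% model$S)^2) / d_ss)
}

#' Per-component scores joined with spectrum metadata
#'
#' Convenience accessor used by the statistics stage: returns a long-format
#' data.frame of scores with `spectrum_id`, `mouse_id`, `group`, `cohort`,
#' component name (model label where available) and score.
#'
#' @param model A fitted (optionally labeled) `mcr_model`.
#' @param d The dataset the model was fitted on (for metadata).
#' @return data.frame with one row per (spectrum, component).
#' @export
score_table <- function(model, d) {
  stopifnot(inherits(model, "mcr_model"), inherits(d, "spectra_dataset"))
  C <- model$C
  if (nrow(C) != nrow(d$meta)) stop("model and dataset sizes differ")
  comp <- rownames(model$S)
  lab <- if (is.null(model$labels)) comp else unname(model$labels)
  out <- do.call(rbind, lapply(seq_along(comp), function(j) {
    cbind(d$meta,
          data.frame(component = comp[j], label = lab[j], score = C[, j],
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
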