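#' Label schemes for phenotype classification
#'
#' Maps tumor groups to classification targets. Built-in schemes follow the
#' metastatic cascade of the isogenic panel:
#' * `multiclass` — each group is its own class;
#' * `intravasation` — 67NR negative, all other groups positive (67NR cells
#'   fail to enter the circulation);
#' * `extravasation` — 67NR and FARN negative, 4T07 and 4T1 positive;
#' * `growth` — only 4T1 positive for overt metastatic colonization;
#' * `custom` — any user map.
#'
#' @param name One of `"multiclass"`, `"intravasation"`, `"extravasation"`,
#'   `"growth"`, `"custom"`.
#' @param map Named character vector `group -> class` (required for
#'   `"custom"`, ignored otherwise).
#' @param groups Group names the built-in schemes apply to, in cascade
#'   order.
#' @return Object of class `label_scheme` with `name`, `map`, and `classes`
#'   (class levels in a stable order; used for tie-breaking).
#' @export
label_scheme <- function(name = c("multiclass", "intravasation",
                                  "extravasation", "growth", "custom"),
                         map = NULL,
                         groups = c("67NR", "FARN", "4T07", "4T1")) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(map) || is.null(names(map))) {
      stop("custom scheme requires a named group -> class map")
    }
  } else {
    map <- switch(name,
      multiclass = stats::setNames(groups, groups),
      intravasation = stats::setNames(
        ifelse(groups == groups[1], "negative", "positive"), groups),
      extravasation = stats::setNames(
        ifelse(groups %in% groups[1:2], "negative", "positive"), groups),
      growth = stats::setNames(
        ifelse(groups == groups[length(groups)], "positive", "negative"),
        groups)
    )
  }
  classes <- unique(unname(map))
  if (length(classes) < 2) {
    stop("a label scheme must define at least 2 classes")
  }
  structure(list(name = name, map = map, classes = classes),
            class = "label_scheme")
}

#' Attach class labels to a dataset under a label scheme
#'
#' @param d A [spectra_dataset()].
#' @param scheme A [label_scheme()] covering every group present.
#' @return The dataset with a `class` column added to its metadata (a factor
#'   with the scheme's class levels).
#' @export
make_labels <- function(d, scheme) {
  stopifnot(inherits(d, "spectra_dataset"), inherits(scheme, "label_scheme"))
  unmapped <- setdiff(unique(d$meta$group), names(scheme$map))
  if (length(unmapped) > 0) {
    stop("scheme does not map group(s): ", paste(unmapped, collapse = ", "))
  }
  d$meta$class <- factor(unname(scheme$map[d$meta$group]),
                         levels = scheme$classes)
  attr(d, "scheme") <- scheme$name
  d
}

# deterministic child seeds below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647L) + 1L
}

# Undersample each class to the minimum class spectrum count (without
# replacement); returns row indices.
equalize_classes <- function(class_vec) {
  counts <- table(class_vec)
  m <- min(counts)
  unlist(lapply(names(counts), function(cl) {
    rows <- which(class_vec == cl)
    if (length(rows) == m) rows else sample(rows, m)
  }), use.names = FALSE)
}

# Train one balanced-ensemble of forests and predict the test matrix.
# Returns a (n_test x n_balance_iter) character matrix of hard labels.
balanced_ensemble_predict <- function(train_x, train_class, test_x,
                                      n_trees, n_balance_iter, seed) {
  pred <- matrix(NA_character_, nrow(test_x), n_balance_iter)
  colnames(train_x) <- paste0("ch", seq_len(ncol(train_x)))
  colnames(test_x) <- colnames(train_x)
  for (b in seq_len(n_balance_iter)) {
    it_seed <- derive_seed(seed, b)
    rows <- withr::with_seed(it_seed, equalize_classes(train_class))
    fit <- ranger::ranger(
      x = train_x[rows, , drop = FALSE],
      y = droplevels(train_class[rows]),
      num.trees = n_trees,
      seed = it_seed,
      num.threads = 1
    )
    pred[, b] <- as.character(
      stats::predict(fit, data = test_x, num.threads = 1,
                     seed = it_seed)$predictions
    )
  }
  pred
}

# mode with ties broken by class-level order
label_mode <- function(labels, levels) {
  counts <- table(factor(labels, levels = levels))
  levels[which.max(counts)]
}

#' Leave-one-mouse-out random-forest classification
#'
#' For each mouse, all of its spectra form the test fold and every other
#' mouse's spectra the training pool — no spectrum of a test mouse ever
#' enters a training set, preventing subject-level leakage. Within each
#' fold, `n_balance_iter` forests of `n_trees` trees are trained on
#' class-equalized (randomly undersampled) training sets; each test spectrum
#' receives the mode of its `n_balance_iter` predictions, and the mouse
#' receives the majority label over its spectra. Mouse-level vote ties are
#' broken toward the class with the higher mean ensemble vote fraction,
#' then by scheme class order.
#'
#' @param d A labeled dataset (see [make_labels()]).
#' @param n_trees Trees per forest.
#' @param n_balance_iter Class-equalization iterations per fold.
#' @param seed Integer seed; results are deterministic given it.
#' @return Object of class `lomo_result` with `mouse` (per-mouse data.frame:
#'   `mouse_id`, `true_class`, `predicted`, one vote-fraction column per
#'   class), `spectrum` (per-spectrum predicted labels), `confusion`
#'   (true x predicted mouse counts), `folds` (per-mouse training spectrum
#'   ids, so leakage-freedom can be audited structurally) and `settings`.
#' @export
lomo_random_forest <- function(d, n_trees = 100L, n_balance_iter = 100L,
                               seed = 1L) {
  stopifnot(inherits(d, "spectra_dataset"))
  if (is.null(d$meta$class)) stop("dataset has no class labels; run make_labels()")
  classes <- levels(d$meta$class)
  mice <- unique(d$meta$mouse_id)
  mouse_class <- d$meta$class[match(mice, d$meta$mouse_id)]
  per_class_mice <- table(mouse_class)
  if (any(per_class_mice < 2)) {
    stop("leave-one-mouse-out requires >= 2 mice per class; class(es) ",
         paste(names(per_class_mice)[per_class_mice < 2], collapse = ", "),
         " would vanish from some training fold")
  }
  spectrum_pred <- rep(NA_character_, n_spectra(d))
  folds <- stats::setNames(vector("list", length(mice)), mice)
  vote_frac <- matrix(0, length(mice), length(classes),
                      dimnames = list(mice, classes))
  ens_frac <- vote_frac
  predicted <- character(length(mice))
  for (mi in seq_along(mice)) {
    m <- mice[mi]
    test_rows <- which(d$meta$mouse_id == m)
    train_rows <- which(d$meta$mouse_id != m)
    folds[[mi]] <- d$meta$spectrum_id[train_rows]
    train_class <- droplevels(d$meta$class[train_rows])
    if (nlevels(train_class) < length(classes)) {
      stop("class vanished from the training fold for mouse ", m)
    }
    pred <- balanced_ensemble_predict(
      d$intensities[train_rows, , drop = FALSE], train_class,
      d$intensities[test_rows, , drop = FALSE],
      n_trees, n_balance_iter, derive_seed(seed, mi * 100003L)
    )
    spectrum_mode <- apply(pred, 1, label_mode, levels = classes)
    spectrum_pred[test_rows] <- spectrum_mode
    vf <- table(factor(spectrum_mode, levels = classes)) / length(test_rows)
    ef <- table(factor(pred, levels = classes)) / length(pred)
    vote_frac[mi, ] <- as.numeric(vf)
    ens_frac[mi, ] <- as.numeric(ef)
    top <- which(vf == max(vf))
    if (length(top) > 1) top <- top[which.max(ef[top])]
    predicted[mi] <- classes[top[1]]
  }
  mouse_df <- data.frame(
    mouse_id = mice,
    true_class = as.character(mouse_class),
    predicted = predicted,
    stringsAsFactors = FALSE
  )
  mouse_df <- cbind(mouse_df, as.data.frame(vote_frac))
  rownames(mouse_df) <- NULL
  confusion <- table(
    true = factor(mouse_df$true_class, levels = classes),
    predicted = factor(mouse_df$predicted, levels = classes)
  )
  structure(
    list(
      mouse = mouse_df,
      spectrum = data.frame(spectrum_id = d$meta$spectrum_id,
                            mouse_id = d$meta$mouse_id,
                            true_class = as.character(d$meta$class),
                            predicted = spectrum_pred,
                            stringsAsFactors = FALSE),
      confusion = confusion,
      folds = folds, # per-mouse training spectrum ids, for leakage audits
      settings = list(n_trees = n_trees, n_balance_iter = n_balance_iter,
                      seed = seed, classes = classes)
    ),
    class = "lomo_result"
  )
}

#' @export
print.lomo_result <- function(x, ...) {
  acc <- sum(diag(x$confusion)) / sum(x$confusion)
  cat(sprintf("<lomo_result> %d mice, per-mouse accuracy %.1f%%\n",
              nrow(x$mouse), 100 * acc))
  print(x$confusion)
  invisible(x)
}

# round half away from zero, the convention of most printed tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion-matrix metrics (accuracy, one-vs-rest sensitivity/specificity)
#'
#' Overall accuracy is `trace / total`. For each class `c`, one-vs-rest
#' sensitivity is the fraction of class-`c` subjects predicted `c`, and
#' specificity the fraction of non-`c` subjects not predicted `c`. All
#' metrics are percentages rounded half-up to one decimal, the precision at
#' which such tables are conventionally reported.
#'
#' @param x A `lomo_result`, or a square confusion matrix (rows = true,
#'   columns = predicted).
#' @return List with `accuracy` (scalar, %) and `per_class` (data.frame:
#'   `class`, `n`, `sensitivity`, `specificity`, %).
#' @export
confusion_metrics <- function(x) {
  cm <- if (inherits(x, "lomo_result")) unclass(x$confusion) else as.matrix(x)
  if (length(cm) == 0 || sum(cm) == 0) stop("confusion matrix is empty")
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  per_class <- data.frame(
    class = classes,
    n = rowSums(cm),
    sensitivity = vapply(seq_len(nrow(cm)), function(i) {
      round_half_up(100 * cm[i, i] / sum(cm[i, ]))
    }, numeric(1)),
    specificity = vapply(seq_len(nrow(cm)), function(i) {
      not_i <- setdiff(seq_len(nrow(cm)), i)
      round_half_up(100 * sum(cm[not_i, not_i, drop = FALSE]) /
                      sum(cm[not_i, ]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_class) <- NULL
  list(accuracy = round_half_up(100 * sum(diag(cm)) / total),
       per_class = per_class)
}

#' Out-of-bag permutation importance per wavenumber channel
#'
#' Trains one forest on the class-equalized full dataset and returns the
#' out-of-bag permutation importance of every wavenumber channel: the
#' increase in OOB error when that channel is permuted, averaged over trees.
#'
#' @param d A labeled dataset (see [make_labels()]).
#' @param n_trees Trees in the forest.
#' @param seed Integer seed.
#' @param equalize Undersample classes to equal size before training.
#' @return Object of class `importance_profile`: data.frame with
#'   `wavenumber` and `importance`, plus the settings as attributes.
#' @export
feature_importance <- function(d, n_trees = 500L, seed = 1L, equalize = TRUE) {
  stopifnot(inherits(d, "spectra_dataset"))
  if (is.null(d$meta$class)) stop("dataset has no class labels; run make_labels()")
  if (nlevels(droplevels(d$meta$class)) < 2) {
    stop("feature importance requires >= 2 classes")
  }
  rows <- if (equalize) {
    withr::with_seed(derive_seed(seed, 1L), equalize_classes(d$meta$class))
  } else {
    seq_len(n_spectra(d))
  }
  x <- d$intensities[rows, , drop = FALSE]
  colnames(x) <- paste0("ch", seq_along(d$wavenumbers))
  fit <- ranger::ranger(
    x = x, y = droplevels(d$meta$class[rows]),
    num.trees = n_trees, importance = "permutation",
    seed = derive_seed(seed, 2L), num.threads = 1
  )
  out <- data.frame(wavenumber = d$wavenumbers,
                    importance = unname(fit$variable.importance))
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  attr(out, "oob_error") <- fit$prediction.error
  class(out) <- c("importance_profile", "data.frame")
  out
}

#' Select the top non-neighboring marker peaks from an importance profile
#'
#' Greedy selection: repeatedly take the highest-importance channel lying at
#' least `min_separation` cm^-1 from every already-selected channel, until
#' `n` peaks are found or no candidate remains (a shortfall is flagged with
#' a warning).
#'
#' @param profile An `importance_profile` (or data.frame with `wavenumber`
#'   and `importance`).
#' @param n Number of peaks to select.
#' @param min_separation Minimum pairwise distance between selected peaks,
#'   cm^-1.
#' @return data.frame `wavenumber`, `importance`, in decreasing importance
#'   order.
#' @export
top_peaks <- function(profile, n = 5L, min_separation = 16) {
  stopifnot(n >= 1)
  w <- profile$wavenumber
  imp <- profile$importance
  selected <- integer(0)
  available <- rep(TRUE, length(w))
  while (length(selected) < n && any(available)) {
    cand <- which(available)
    pick <- cand[which.max(imp[cand])]
    selected <- c(selected, pick)
    available <- available & abs(w - w[pick]) >= min_separation
  }
  if (length(selected) < n) {
    warning(sprintf("only %d of %d requested peaks satisfy the separation rule",
                    length(selected), n))
  }
  data.frame(wavenumber = w[selected], importance = imp[selected])
}

#' Train on the full labeled cohort and predict external mice
#'
#' Same balanced-ensemble construction as [lomo_random_forest()], but the
#' ensemble is trained once on all training mice and applied to an external
#' dataset (e.g. gene-silenced analog tumors). Each external spectrum gets
#' the mode over the ensemble; each external mouse gets vote fractions and
#' the majority label.
#'
#' @param train A labeled training dataset (see [make_labels()]).
#' @param external A [spectra_dataset()] on the same wavenumber axis.
#' @param n_trees,n_balance_iter,seed Ensemble settings as in
#'   [lomo_random_forest()].
#' @return data.frame with one row per external mouse: `mouse_id`, `group`,
#'   `predicted`, and one vote-fraction column per training class.
#' @export
train_full_predict_external <- function(train, external, n_trees = 100L,
                                        n_balance_iter = 100L, seed = 1L) {
  stopifnot(inherits(train, "spectra_dataset"),
            inherits(external, "spectra_dataset"))
  if (is.null(train$meta$class)) stop("training dataset has no class labels")
  if (length(train$wavenumbers) != length(external$wavenumbers) ||
      any(train$wavenumbers != external$wavenumbers)) {
    stop("training and external datasets are on different wavenumber axes")
  }
  classes <- levels(train$meta$class)
  if (n_spectra(external) == 0) {
    out <- data.frame(mouse_id = character(0), group = character(0),
                      predicted = character(0), stringsAsFactors = FALSE)
    for (cl in classes) out[[cl]] <- numeric(0)
    return(out)
  }
  pred <- balanced_ensemble_predict(
    train$intensities, train$meta$class, external$intensities,
    n_trees, n_balance_iter, seed
  )
  spectrum_mode <- apply(pred, 1, label_mode, levels = classes)
  mice <- unique(external$meta$mouse_id)
  rows <- lapply(mice, function(m) which(external$meta$mouse_id == m))
  vote <- t(vapply(rows, function(r) {
    as.numeric(table(factor(spectrum_mode[r], levels = classes)) / length(r))
  }, numeric(length(classes))))
  colnames(vote) <- classes
  predicted <- vapply(seq_along(mice), function(i) {
    top <- which(vote[i, ] == max(vote[i, ]))
    classes[top[1]]
  }, character(1))
  out <- data.frame(
    mouse_id = mice,
    group = external$meta$group[match(mice, external$meta$mouse_id)],
    predicted = predicted,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(vote))
}
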