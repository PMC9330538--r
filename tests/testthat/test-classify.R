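test_that("label schemes map the cascade correctly and reject degenerate maps", {
  co <- cohort_small()
  intr <- make_labels(co$clean, label_scheme("intravasation"))
  expect_equal(nlevels(intr$meta$class), 2)
  expect_true(all(intr$meta$group[intr$meta$class == "negative"] == "67NR"))
  growth <- make_labels(co$clean, label_scheme("growth"))
  mouse_class <- growth$meta$class[!duplicated(growth$meta$mouse_id)]
  expect_equal(sum(mouse_class == "positive"), 8)
  expect_equal(sum(mouse_class == "negative"), 19)
  expect_error(label_scheme("custom", map = c(a = "one", b = "one")),
               "at least 2 classes")
  expect_error(
    make_labels(co$clean, label_scheme("custom", map = c(`67NR` = "x", FARN = "y"))),
    "does not map"
  )
})

test_that("perfectly separable classes are classified with full votes", {
  lib <- default_library()
  # disjoint constant spectra: every mouse of a class carries its class
  # profile exactly, with no within- or between-mouse variation
  n_per <- 8
  mk <- function(profile, cls, mouse) {
    spectra_dataset(
      lib$wavenumbers,
      matrix(rep(profile, n_per), nrow = n_per, byrow = TRUE),
      data.frame(spectrum_id = sprintf("%s_s%d", mouse, 1:n_per),
                 mouse_id = mouse, group = cls)
    )
  }
  parts <- c(
    lapply(sprintf("neg_m%02d", 1:3), mk, profile = lib$profiles[1, ], cls = "neg"),
    lapply(sprintf("pos_m%02d", 1:3), mk, profile = lib$profiles[2, ], cls = "pos")
  )
  d <- spectra_dataset(
    lib$wavenumbers,
    do.call(rbind, lapply(parts, function(p) p$intensities)),
    do.call(rbind, lapply(parts, function(p) p$meta))
  )
  lab <- make_labels(d, label_scheme("custom", map = c(neg = "neg", pos = "pos")))
  res <- lomo_random_forest(lab, n_trees = 20, n_balance_iter = 3, seed = 1)
  expect_equal(res$mouse$predicted, res$mouse$true_class)
  expect_true(all(apply(res$mouse[, c("neg", "pos")], 1, max) == 1))
  expect_equal(sum(diag(res$confusion)), 6)
})

test_that("no test-mouse spectrum ever enters its training fold", {
  lab <- tiny_two_class()
  res <- lomo_random_forest(lab, n_trees = 10, n_balance_iter = 2, seed = 2)
  for (m in names(res$folds)) {
    own <- lab$meta$spectrum_id[lab$meta$mouse_id == m]
    expect_length(intersect(res$folds[[m]], own), 0)
    # training fold contains every other mouse's spectra
    expect_setequal(res$folds[[m]],
                    setdiff(lab$meta$spectrum_id, own))
  }
})

test_that("vote fractions are normalized and results are seed-deterministic", {
  lab <- tiny_two_class()
  res1 <- lomo_random_forest(lab, n_trees = 10, n_balance_iter = 3, seed = 7)
  res2 <- lomo_random_forest(lab, n_trees = 10, n_balance_iter = 3, seed = 7)
  expect_identical(res1$mouse, res2$mouse)
  expect_identical(res1$spectrum$predicted, res2$spectrum$predicted)
  expect_equal(rowSums(res1$mouse[, c("neg", "pos")]), rep(1, 6),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(res1$confusion)),
               as.integer(table(factor(res1$mouse$true_class,
                                       levels = c("neg", "pos")))))
})

test_that("class equalization undersamples every class to the minimum count", {
  cls <- factor(rep(c("a", "b", "c"), times = c(30, 12, 20)))
  set.seed(3)
  rows <- ramanpheno:::equalize_classes(cls)
  expect_equal(as.vector(table(cls[rows])), rep(12, 3))
  expect_false(any(duplicated(rows)))
})

test_that("a vanished training class raises a named error", {
  lab <- tiny_two_class()
  # keep a single positive mouse: leaving it out empties the class
  keep <- lab$meta$mouse_id %in% c("neg_m01", "neg_m02", "pos_m01")
  small <- subset_spectra(lab, keep)
  small$meta$class <- droplevels(small$meta$class)
  expect_error(lomo_random_forest(small, n_trees = 5, n_balance_iter = 2),
               ">= 2 mice per class")
})

test_that("confusion metrics match an independent brute-force counter", {
  set.seed(11)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("a", "b", "c"), 60, TRUE))
  cm <- table(true = factor(truth), predicted = factor(pred, levels = c("a", "b", "c")))
  met <- confusion_metrics(cm)
  for (cl in c("a", "b", "c")) {
    sens <- 100 * sum(truth == cl & pred == cl) / sum(truth == cl)
    spec <- 100 * sum(truth != cl & pred != cl) / sum(truth != cl)
    row <- met$per_class[met$per_class$class == cl, ]
    expect_equal(row$sensitivity, floor(sens * 10 + 0.5) / 10)
    expect_equal(row$specificity, floor(spec * 10 + 0.5) / 10)
  }
  expect_equal(met$accuracy,
               floor(100 * mean(truth == pred) * 10 + 0.5) / 10)
  ident <- diag(4); dimnames(ident) <- list(letters[1:4], letters[1:4])
  met2 <- confusion_metrics(ident)
  expect_equal(met2$accuracy, 100)
  expect_true(all(met2$per_class$sensitivity == 100))
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("a single informative channel dominates permutation importance", {
  w <- default_grid()
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * length(w), 1, 0.1), n)
  cls <- rep(c("a", "b"), each = n / 2)
  X[cls == "b", 300] <- X[cls == "b", 300] + 1.5
  d <- make_labels(
    spectra_dataset(w, X, data.frame(
      spectrum_id = sprintf("s%02d", 1:n),
      mouse_id = rep(sprintf("m%d", 1:6), each = 10),
      group = cls
    )),
    label_scheme("custom", map = c(a = "a", b = "b"))
  )
  imp <- feature_importance(d, n_trees = 100, seed = 13)
  expect_equal(which.max(imp$importance), 300)
  # shuffled labels destroy the signal
  shuffled <- d
  shuffled$meta$class <- withr::with_seed(14, sample(d$meta$class))
  imp0 <- feature_importance(shuffled, n_trees = 100, seed = 13)
  expect_gte(max(imp$importance), 5 * max(imp0$importance))
  one_class <- d
  one_class$meta$class <- factor(rep("a", n))
  expect_error(feature_importance(one_class), ">= 2 classes")
})

test_that("top_peaks enforces the non-neighboring rule and matches a greedy oracle", {
  w <- default_grid()
  imp <- rep(0, length(w))
  spikes <- c(50, 150, 250, 350, 450)
  imp[spikes] <- c(5, 4, 3, 2, 1)
  prof <- data.frame(wavenumber = w, importance = imp)
  pk <- top_peaks(prof, n = 5, min_separation = 16)
  expect_equal(sort(pk$wavenumber), sort(w[spikes]))
  # two high channels 4 cm^-1 apart: only the higher survives
  imp2 <- rep(0, length(w)); imp2[100] <- 10; imp2[102] <- 9
  pk2 <- suppressWarnings(
    top_peaks(data.frame(wavenumber = w, importance = imp2), n = 2,
              min_separation = 16)
  )
  expect_equal(pk2$wavenumber[1], w[100])
  expect_false(w[102] %in% pk2$wavenumber)
  # random profile equals a step-by-step greedy oracle
  set.seed(15)
  rimp <- runif(length(w))
  got <- top_peaks(data.frame(wavenumber = w, importance = rimp), n = 5,
                   min_separation = 16)
  oracle <- c()
  avail <- rep(TRUE, length(w))
  for (i in 1:5) {
    j <- which(avail)[which.max(rimp[avail])]
    oracle <- c(oracle, w[j])
    avail <- avail & abs(w - w[j]) >= 16
  }
  expect_equal(got$wavenumber, oracle)
})

test_that("external prediction memorizes duplicated training spectra and handles empty input", {
  lab <- tiny_two_class()
  pos_rows <- which(lab$meta$group == "pos")[1:10]
  ext <- spectra_dataset(
    lab$wavenumbers, lab$intensities[pos_rows, ],
    data.frame(spectrum_id = sprintf("e%02d", 1:10),
               mouse_id = rep(c("e1", "e2"), each = 5), group = "ext")
  )
  pred <- train_full_predict_external(lab, ext, n_trees = 20,
                                      n_balance_iter = 3, seed = 4)
  expect_true(all(pred$predicted == "pos"))
  empty <- spectra_dataset(
    lab$wavenumbers, matrix(numeric(0), 0, length(lab$wavenumbers)),
    data.frame(spectrum_id = character(0), mouse_id = character(0),
               group = character(0))
  )
  expect_equal(nrow(train_full_predict_external(lab, empty, 5, 2, 1)), 0)
  shifted <- ext
  shifted$wavenumbers <- shifted$wavenumbers + 2
  expect_error(train_full_predict_external(lab, shifted, 5, 2, 1), "axes")
})

test_that("accuracy never decreases as class separation grows", {
  lib <- default_library()
  run_at <- function(sep, seed) {
    groups <- data.frame(
      group = c("neg", "pos"), n_mice = c(3L, 3L),
      lipid_like = c(0.5 - sep / 2, 0.5 + sep / 2),
      collagen_like = c(0.5 + sep / 2, 0.5 - sep / 2),
      formalin_like = 0.3, mixed_1 = 0.5, mixed_2 = 0.4
    )
    design <- cohort_design(groups = groups, spectra_per_mouse = 10,
                            spectra_per_mouse_sd = 0, baseline_scale = 0,
                            noise_sd = 0.02, seed = seed)
    lab <- make_labels(simulate_cohort(design, lib)$dataset,
                       label_scheme("custom", map = c(neg = "neg", pos = "pos")))
    res <- lomo_random_forest(lab, n_trees = 15, n_balance_iter = 3,
                              seed = seed)
    mean(res$mouse$predicted == res$mouse$true_class)
  }
  acc <- vapply(c(0.02, 0.15, 0.5), function(sep) {
    mean(vapply(1:5, function(s) run_at(sep, 200 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
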