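#' Two-sided Wilcoxon rank-sum comparison of two samples
#'
#' Computes the Mann-Whitney statistics with midranks for ties
#' (`U1 + U2 = n1 * n2` always holds) and a two-sided p-value: exact by
#' enumeration when the combined sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `group_comparison` with `n1`, `n2`, `U1`, `U2`,
#'   `p_value`, `r` (Wendt rank-biserial effect size), `direction` (sign of
#'   `median(x) - median(y)`), `significant` and `alpha`.
#' @export
wilcoxon_rank_sum <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y)) # midranks for ties
  U1 <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 12) && !has_ties
  p <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE
  )$p.value)
  p <- min(max(p, .Machine$double.xmin), 1)
  r <- rank_biserial_wendt(x, y)
  structure(
    list(n1 = n1, n2 = n2, U1 = U1, U2 = U2, p_value = p, r = r,
         direction = sign(stats::median(x) - stats::median(y)),
         significant = p < alpha, alpha = alpha, exact = exact),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> n1=%d n2=%d U=%g p=%.3g r=%.3f%s\n",
    x$n1, x$n2, min(x$U1, x$U2), x$p_value, x$r,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Wendt rank-biserial effect size
#'
#' `r = 1 - 2 * min(U1, U2) / (n1 * n2)`, the unsigned rank-biserial
#' correlation derived from the Mann-Whitney U statistic. On tie-free data
#' it equals the net proportion of favorable cross-group pairs,
#' `|#(x > y) - #(x < y)| / (n1 * n2)`; it lies in [0, 1], reaching 1 at
#' complete separation and 0 when the samples interleave symmetrically.
#'
#' @param x,y Numeric samples.
#' @return Scalar effect size in [0, 1].
#' @export
rank_biserial_wendt <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y))
  U1 <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  1 - 2 * min(U1, U2) / (n1 * n2)
}

#' Compare component scores of every group against a reference group
#'
#' One Wilcoxon rank-sum comparison (with Wendt effect size) per
#' non-reference group versus the reference, on per-spectrum scores of one
#' component. No multiplicity adjustment is applied; each comparison is
#' flagged at the per-comparison `alpha`.
#'
#' @param scores Score matrix (spectra x components) such as `model$C` or
#'   [project_scores()] output, or a [score_table()] data.frame.
#' @param groups Character vector of group memberships, one per spectrum
#'   (ignored when `scores` is a score table).
#' @param component Component column name (or label in a score table).
#' @param reference_group The group every other group is compared against.
#' @param alpha Per-comparison significance level.
#' @return data.frame with one row per comparison: `group`,
#'   `reference`, `n1`, `n2`, `U`, `p_value`, `r`, `direction` (+1 when the
#'   group median exceeds the reference median), `significant`.
#' @export
compare_scores <- function(scores, groups = NULL, component,
                           reference_group, alpha = 0.05) {
  if (is.data.frame(scores) && all(c("score", "group") %in% names(scores))) {
    key <- if (component %in% scores$label) "label" else "component"
    sub <- scores[scores[[key]] == component, ]
    if (nrow(sub) == 0) stop("unknown component: ", component)
    values <- sub$score
    groups <- sub$group
  } else {
    scores <- as.matrix(scores)
    if (!component %in% colnames(scores)) {
      stop("unknown component: ", component)
    }
    if (is.null(groups) || length(groups) != nrow(scores)) {
      stop("groups must give one membership per spectrum row")
    }
    values <- scores[, component]
  }
  if (!reference_group %in% groups) {
    stop("unknown reference group: ", reference_group)
  }
  ref <- values[groups == reference_group]
  others <- setdiff(unique(groups), reference_group)
  out <- do.call(rbind, lapply(others, function(g) {
    cmp <- wilcoxon_rank_sum(values[groups == g], ref, alpha = alpha)
    data.frame(group = g, reference = reference_group,
               n1 = cmp$n1, n2 = cmp$n2, U = min(cmp$U1, cmp$U2),
               p_value = cmp$p_value, r = cmp$r, direction = cmp$direction,
               significant = cmp$significant, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey box-and-whisker summary
#'
#' Five-number summary with quartiles by linear interpolation
#' (`stats::quantile` type 7) and whiskers at the most extreme data points
#' within 1.5 IQR of the box; points beyond the whiskers are counted as
#' outliers.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Object of class `box_summary`: `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("need at least one value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3],
         whisker_lo = min(inside), whisker_hi = max(inside),
         n_outliers = sum(values < lo_fence | values > hi_fence),
         n = length(values)),
    class = "box_summary"
  )
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n=%d  [%g | %g (%g) %g | %g]  outliers=%d\n",
    x$n, x$whisker_lo, x$q1, x$median, x$q3, x$whisker_hi, x$n_outliers
  ))
  invisible(x)
}
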