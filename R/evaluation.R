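#' Diagnostic metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/total, evaluated exactly. A metric
#' whose denominator is zero is returned as `NA` rather than an error.
#' Data-frame-first: pass a tibble of per-class counts (as produced by
#' [som_evaluate()]) and get the metrics appended per row.
#'
#' @param cm Data frame with columns `TP`, `TN`, `FP`, `FN`.
#' @return The input with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` columns appended (proportions in \[0, 1\]).
#' @export
#' @examples
#' confusion_metrics(tibble::tibble(TP = 20, TN = 21, FP = 0, FN = 1))
confusion_metrics <- function(cm) {
  cm <- tibble::as_tibble(cm)
  req <- c("TP", "TN", "FP", "FN")
  if (!all(req %in% names(cm))) {
    stop("cm needs columns TP, TN, FP, FN", call. = FALSE)
  }
  if (any(cm[req] < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(cm,
    sensitivity = safe_div(.data$TP, .data$TP + .data$FN),
    specificity = safe_div(.data$TN, .data$TN + .data$FP),
    ppv = safe_div(.data$TP, .data$TP + .data$FP),
    npv = safe_div(.data$TN, .data$TN + .data$FN),
    accuracy = safe_div(.data$TP + .data$TN,
                        .data$TP + .data$TN + .data$FP + .data$FN))
}

#' Mann-Whitney U / Wilcoxon rank-sum test
#'
#' U is computed from midranks (ties share their average rank). The
#' two-sided p-value is exact — by enumeration of all rank splits — when
#' n1 + n2 <= `exact_max`, and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined size for exact enumeration (default 10).
#' @return One-row tibble: `U`, `p.value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))
rank_sum_test <- function(a, b, exact_max = 10) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    dev <- abs(U - mu)
    p <- mean(abs(u_all - mu) >= dev - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble::tibble(U = U, p.value = p, n1 = n1, n2 = n2, method = method)
}

#' ROC curve, AUC and Hanley-McNeil confidence interval
#'
#' Sweeps every unique score as a decision threshold (score >= threshold
#' called positive), anchors the curve at (0,0) and (1,1), and integrates
#' by the trapezoid rule. On tie-free data the trapezoid AUC equals the
#' rank statistic U/(n1 n2). The 95% CI uses the Hanley-McNeil normal
#' approximation, clipped to \[0, 1\].
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Vector of true labels.
#' @param positive The label counted as positive (default the larger of the
#'   two sorted labels).
#' @return A tibble of class `ev_roc` with columns `threshold`, `tpr`,
#'   `fpr`; attributes `auc`, `ci95`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- ev_roc(c(0.9, 0.8, 0.3, 0.1), c("cvd", "cvd", "healthy", "healthy"), "cvd")
#' attr(r, "auc")
ev_roc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("both classes must be present", call. = FALSE)
  if (length(ulab) > 2) stop("ROC needs exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- ulab[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, 1)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, 1)
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  thr <- c(Inf, thr, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  A <- auc
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
               (n_pos * n_neg))
  ci <- c(max(0, A - 1.96 * se), min(1, A + 1.96 * se))
  out <- tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
  class(out) <- c("ev_roc", class(out))
  attr(out, "auc") <- auc
  attr(out, "ci95") <- ci
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "positive") <- positive
  out
}

#' Five-number box-plot summary
#'
#' Quartiles by linear interpolation (type 7), whiskers at the minimum and
#' maximum, plus the mean — the summary behind the box-and-whisker panels.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return One-row tibble: `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_low`, `whisker_high`, `mean`, `n`.
#' @export
box_stats <- function(values) {
  if (length(values) < 1) stop("values must be non-empty", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(values), whisker_low = min(values),
                 whisker_high = max(values), mean = mean(values),
                 n = length(values))
}

#' Per-band intensity report with group comparison
#'
#' For each requested band, averages intensity over a +/- `half_window`
#' cm^-1 window per spectrum, then compares the two groups of the `group`
#' column: group means, box statistics, Mann-Whitney p-value, and
#' Benjamini-Hochberg adjusted p across bands (set `adjust = "none"` to
#' report raw per-band p only).
#'
#' @param ds An [ev_dataset()].
#' @param bands Numeric band centers, cm^-1, all within the axis.
#' @param group Grouping column with exactly two levels (default `"state"`).
#' @param half_window Integration half-width in cm^-1 (default 4).
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Tibble with one row per band x group plus shared `p.value`,
#'   `p.adjusted` columns.
#' @export
band_report <- function(ds, bands, group = "state", half_window = 4,
                        adjust = "BH") {
  wn <- ev_wavenumbers(ds)
  if (any(bands < min(wn) | bands > max(wn))) {
    stop("band outside the wavenumber axis", call. = FALSE)
  }
  g <- ev_labels(ds, group)
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("group column must have exactly two levels", call. = FALSE)
  m <- ev_intensities(ds)
  rows <- list()
  pvals <- numeric(length(bands))
  for (bi in seq_along(bands)) {
    sel <- abs(wn - bands[bi]) <= half_window
    band_int <- rowMeans(m[, sel, drop = FALSE])
    pvals[bi] <- rank_sum_test(band_int[g == lv[1]], band_int[g == lv[2]])$p.value
    for (l in lv) {
      bs <- box_stats(band_int[g == l])
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(band = bands[bi], group = l), bs)
    }
  }
  out <- dplyr::bind_rows(rows)
  padj <- stats::p.adjust(pvals, method = adjust)
  out$p.value <- rep(pvals, each = 2)
  out$p.adjusted <- rep(padj, each = 2)
  out
}
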