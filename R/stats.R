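#' Two-group pooled-variance Student's t-test with group summaries
#'
#' Two-sided Student's t-test assuming equal variances (Welch's correction
#' available behind `var_equal = FALSE`), reported alongside the group
#' means and standard deviations.
#'
#' @param x,y numeric vectors, n >= 2 each.
#' @param var_equal pooled variance (default TRUE, classical Student test).
#' @return List: `t`, `df`, `p`, `mean_x`, `sd_x`, `n_x`, `mean_y`, `sd_y`,
#'   `n_y`.
#' @export
two_group_test <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    stop("zero pooled variance: both groups constant and equal")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_x = mean(x), sd_x = sd(x), n_x = length(x),
       mean_y = mean(y), sd_y = sd(y), n_y = length(y))
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way F-test (equal-variance decomposition).
#' With exactly two groups, F equals the square of the pooled t statistic.
#'
#' @param groups list of numeric vectors, one per group.
#' @return List: `F`, `df1`, `df2`, `p`, `group_means`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) - length(groups) < 1L) stop("not enough residual df")
  if (var(values) == 0) {
    # identical constant observations: no between- or within-group variance
    return(list(F = 0, df1 = length(groups) - 1L,
                df2 = length(values) - length(groups), p = 1,
                group_means = vapply(groups, mean, numeric(1))))
  }
  tab <- summary(aov(values ~ fac))[[1]]  # handles singleton groups
  list(F = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p = tab[["Pr(>F)"]][1],
       group_means = vapply(groups, mean, numeric(1)))
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation with the usual t-transform p-value.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Empirical ROC curve with Mann-Whitney AUC
#'
#' Builds the full empirical ROC curve and computes the AUC as the
#' Mann-Whitney concordance probability (ties receive half credit, via
#' midranks), which equals the trapezoidal area under the tie-grouped
#' curve. The p-value for AUC different from 0.5 uses the tie-corrected
#' normal approximation of the Mann-Whitney statistic. When
#' `direction = "auto"` and the positive class scores lower, scores are
#' negated before curve construction so the reported AUC is >= 0.5 and the
#' recorded direction is `"<"` (positive calls are scores below threshold).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; TRUE = positive class.
#' @param direction `">"` (positives score high), `"<"`, or `"auto"`.
#' @return A `roc_result`: `auc`, `p_value`, `curve` data frame
#'   (`threshold`, `fpr`, `tpr`), `direction`, `n_pos`, `n_neg`, and the
#'   stored `scores`/`labels` for threshold queries.
#' @export
roc_curve <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc_of <- function(s) {
    rk <- rank(s)
    (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  oriented <- scores
  dir <- ">"
  auc <- auc_of(oriented)
  if (direction == "<" || (direction == "auto" && auc < 0.5)) {
    oriented <- -scores
    dir <- "<"
    auc <- auc_of(oriented)
  }
  # tie-corrected normal approximation for U
  N <- n1 + n0
  u <- auc * n1 * n0
  ties <- table(oriented)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs((u - n1 * n0 / 2) / sqrt(sigma2)))
  # empirical curve over unique thresholds (classification: oriented >= c)
  thr <- sort(unique(oriented), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(oriented[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(oriented[!labels] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, p_value = p, curve = curve, direction = dir,
                 n_pos = n1, n_neg = n0, scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (p = %.4g), direction '%s', %d pos / %d neg\n",
              x$auc, x$p_value, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity (and specificity) at a fixed score cutoff
#'
#' Applies the strict cutoff convention: a case is called positive when its
#' score is strictly above the threshold (or strictly below, if the ROC
#' direction is `"<"`).
#'
#' @param roc a `roc_result`.
#' @param threshold cutoff on the original score scale.
#' @return List: `threshold`, `sensitivity`, `specificity` (proportions).
#' @export
roc_sensitivity_at <- function(roc, threshold) {
  stopifnot(inherits(roc, "roc_result"))
  called <- if (roc$direction == ">") roc$scores > threshold
            else roc$scores < threshold
  list(threshold = threshold,
       sensitivity = mean(called[roc$labels]),
       specificity = mean(!called[!roc$labels]))
}
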