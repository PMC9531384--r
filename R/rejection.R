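texture_feature_names <- function() {
  c("energy", "contrast", "entropy", "homogeneity", "correlation",
    "sum_average", "variance", "dissimilarity", "autocorrelation")
}

# grade string ("0R", "1R", "2R", ...) -> positive biopsy indicator
biopsy_positive <- function(grade) {
  num <- suppressWarnings(as.integer(sub("R$", "", grade)))
  if (anyNA(num)) stop("unparseable biopsy grade(s): ",
                       paste(unique(grade[is.na(num)]), collapse = ", "))
  num > 0L
}

#' Cohort-level rejection analysis
#'
#' Runs the full statistical layer on a cohort table: two-group Student
#' t-tests of mean T1, peak T1, each texture feature and fibrosis percent
#' under both rejection dichotomies (clinical: group A vs B+C; biopsy:
#' grade 0R vs > 0R); one-way ANOVA of mean/peak T1 across the three
#' groups with a monotone-trend check of group means; ROC curves (with
#' Mann-Whitney AUC and p-value) for mean T1, peak T1 and each texture
#' feature under the clinical dichotomy, orienting features that score
#' lower in rejection (e.g. energy) so AUC >= 0.5 with the direction
#' recorded; sensitivity and specificity of peak T1 at the abnormality
#' cutoff (strictly greater); Pearson correlations of mean/peak T1 against
#' each marker on the full cohort and on the rejection-excluded subset;
#' fibrosis-vs-T1 and fibrosis-vs-marker correlations; and supplementary
#' least-squares regressions of each marker on T1.
#'
#' No multiple-testing correction is applied; p-values are reported raw.
#' Cases are treated as independent even though surveillance cohorts
#' contain repeat encounters per patient; this caveat is recorded in the
#' report notes.
#'
#' @param table cohort data frame; required columns: `group` (A/B/C),
#'   `biopsy_grade`, `mean_t1`, `peak_t1`. Texture features, markers and
#'   `fibrosis_percent` are analyzed when present.
#' @param cutoff abnormal peak T1 cutoff in ms (default 1050, strict `>`).
#' @param markers character vector of marker column names (default: those
#'   of [marker_definitions()] present in the table).
#' @return A `rejection_report` (nested lists and data frames).
#' @export
rejection_analysis <- function(table, cutoff = 1050, markers = NULL) {
  required <- c("group", "biopsy_grade", "mean_t1", "peak_t1")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(table$group %in% c("A", "B", "C"))) {
    stop("group must be one of A, B, C")
  }
  clinical <- table$group %in% c("B", "C")
  biopsy <- biopsy_positive(table$biopsy_grade)
  feats <- intersect(texture_feature_names(), names(table))
  if (is.null(markers)) {
    markers <- intersect(marker_definitions()$name, names(table))
  }
  measures <- c("mean_t1", "peak_t1", feats,
                intersect("fibrosis_percent", names(table)))

  # group summary: n, mean +/- SD of mean/peak T1 per group
  group_summary <- do.call(rbind, lapply(c("A", "B", "C"), function(g) {
    idx <- table$group == g
    data.frame(group = g, n = sum(idx),
               mean_t1_mean = mean(table$mean_t1[idx]),
               mean_t1_sd = sd(table$mean_t1[idx]),
               peak_t1_mean = mean(table$peak_t1[idx]),
               peak_t1_sd = sd(table$peak_t1[idx]),
               stringsAsFactors = FALSE)
  }))

  dichotomies <- list(clinical = clinical, biopsy = biopsy)
  t_tests <- do.call(rbind, lapply(names(dichotomies), function(dn) {
    pos <- dichotomies[[dn]]
    do.call(rbind, lapply(measures, function(m) {
      res <- tryCatch(two_group_test(table[[m]][!pos], table[[m]][pos]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(measure = m, dichotomy = dn,
                 n_neg = res$n_x, mean_neg = res$mean_x, sd_neg = res$sd_x,
                 n_pos = res$n_y, mean_pos = res$mean_y, sd_pos = res$sd_y,
                 t = res$t, p = res$p, stringsAsFactors = FALSE)
    }))
  }))

  anova <- do.call(rbind, lapply(c("mean_t1", "peak_t1"), function(m) {
    groups <- split(table[[m]], factor(table$group, levels = c("A", "B", "C")))
    groups <- groups[lengths(groups) > 0]
    res <- tryCatch(one_way_anova(groups), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(measure = m, F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  }))

  trend <- lapply(c(mean_t1 = "mean_t1", peak_t1 = "peak_t1"), function(m) {
    gm <- tapply(table[[m]], factor(table$group, levels = c("A", "B", "C")),
                 mean)
    list(group_means = gm,
         monotone_increasing = !anyNA(gm) && all(diff(gm) > 0))
  })

  roc_measures <- c("mean_t1", "peak_t1", feats)
  rocs <- list()
  roc_table <- NULL
  for (m in roc_measures) {
    r <- tryCatch(roc_curve(table[[m]], clinical, direction = "auto"),
                  error = function(e) NULL)
    if (is.null(r)) next
    rocs[[m]] <- r
    roc_table <- rbind(roc_table,
                       data.frame(measure = m, auc = r$auc, p = r$p_value,
                                  direction = r$direction,
                                  stringsAsFactors = FALSE))
  }

  sensitivity <- if (!is.null(rocs$peak_t1)) {
    c(roc_sensitivity_at(rocs$peak_t1, cutoff), list(measure = "peak_t1"))
  } else NULL

  cor_rows <- list()
  subsets <- list(full = rep(TRUE, nrow(table)), no_rejection = !clinical)
  for (sn in names(subsets)) {
    idx <- subsets[[sn]]
    for (tm in c("mean_t1", "peak_t1")) {
      for (mk in markers) {
        res <- tryCatch(pearson_cor(table[[tm]][idx], table[[mk]][idx]),
                        error = function(e) NULL)
        if (is.null(res)) next
        cor_rows[[length(cor_rows) + 1L]] <-
          data.frame(t1_measure = tm, marker = mk, subset = sn,
                     r = res$r, p = res$p, n = res$n,
                     stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, cor_rows)

  fibrosis <- NULL
  if ("fibrosis_percent" %in% names(table)) {
    fib_cor <- list()
    for (v in c("mean_t1", "peak_t1", markers)) {
      res <- tryCatch(pearson_cor(table$fibrosis_percent, table[[v]]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        fib_cor[[length(fib_cor) + 1L]] <-
          data.frame(variable = v, r = res$r, p = res$p,
                     stringsAsFactors = FALSE)
      }
    }
    fibrosis <- list(
      t_test = t_tests[t_tests$measure == "fibrosis_percent" &
                         t_tests$dichotomy == "clinical", ],
      correlations = do.call(rbind, fib_cor))
  }

  regression <- do.call(rbind, lapply(c("mean_t1", "peak_t1"), function(tm) {
    do.call(rbind, lapply(markers, function(mk) {
      fit <- tryCatch(lm(table[[mk]] ~ table[[tm]]), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(t1_measure = tm, marker = mk,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(group_summary = group_summary, t_tests = t_tests,
                 anova = anova, trend = trend, roc_table = roc_table,
                 rocs = rocs, sensitivity = sensitivity,
                 correlations = correlations, fibrosis = fibrosis,
                 regression = regression,
                 notes = c(
                   "p-values are raw; no multiple-testing correction applied",
                   "cases treated as independent; surveillance cohorts contain repeat encounters per patient",
                   sprintf("abnormality cutoff: strictly > %g ms", cutoff))),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report>\n")
  cat("Group summary (T1, ms):\n")
  print(x$group_summary, row.names = FALSE, digits = 5)
  head_t <- x$t_tests[x$t_tests$measure %in% c("mean_t1", "peak_t1") &
                        x$t_tests$dichotomy == "clinical", ]
  cat("\nA vs B+C t-tests:\n")
  print(head_t[, c("measure", "mean_neg", "sd_neg", "mean_pos", "sd_pos", "p")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$roc_table)) {
    cat("\nROC (clinical rejection):\n")
    print(x$roc_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("\nPeak T1 > %g ms: sensitivity %.0f%%, specificity %.0f%%\n",
                x$sensitivity$threshold, 100 * x$sensitivity$sensitivity,
                100 * x$sensitivity$specificity))
  }
  invisible(x)
}
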