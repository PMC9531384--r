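test_that("pooled t-test degenerates correctly for identical samples", {
  res <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(two_group_test(rep(1, 3), rep(1, 3)), "variance")
  expect_error(two_group_test(1, c(1, 2)), "n >= 2")
})

test_that("t-test has near-unit power at effect size d = 1, n = 1000", {
  set.seed(3)
  reject <- vapply(1:100, function(i) {
    two_group_test(rnorm(1000), rnorm(1000, 1))$p < 0.05
  }, logical(1))
  expect_equal(mean(reject), 1)
})

test_that("one-way ANOVA reduces to F = t^2 with two groups", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    tt <- two_group_test(x, y)
    an <- one_way_anova(list(x, y))
    expect_equal(an$F, tt$t^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p, tolerance = 1e-9)
  }
  expect_equal(one_way_anova(list(1:3, 1:3, 1:3))$F, 0)
  expect_error(one_way_anova(list(1:3)), "2 groups")
})

test_that("Pearson correlation handles exact linear relations and degeneracies", {
  x <- c(1, 2, 4, 8)
  expect_equal(pearson_cor(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(2, 4)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("ROC AUC equals pair-enumeration concordance, with tie credit", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1), direction = ">")$auc, 1)
  expect_equal(roc_curve(c(3, 1, 2, 4), c(0, 1, 0, 1), direction = ">")$auc, 0.5)
  set.seed(23)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels, direction = ">")
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    # AUC equals the trapezoidal area of the empirical curve
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # curve is monotone in both coordinates
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(29)
  scores <- rnorm(40)
  labels <- runif(40) < 0.4
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  a <- roc_curve(scores, labels, direction = ">")$auc
  expect_equal(roc_curve(exp(scores), labels, direction = ">")$auc, a)
  expect_equal(roc_curve(qnorm(pnorm(scores))^3 + 2 * scores, labels,
                         direction = ">")$auc, a, tolerance = 1e-12)
  expect_equal(roc_curve(scores, !labels, direction = ">")$auc, 1 - a)
  expect_error(roc_curve(scores, rep(TRUE, 40)), "both classes")
})

test_that("ROC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    scores <- round(rnorm(30), 1)
    labels <- runif(30) < 0.5
    if (length(unique(labels)) < 2) next
    ours <- roc_curve(scores, labels, direction = ">")$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                     quiet = TRUE))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("auto direction orients low-scoring positive classes and records it", {
  set.seed(37)
  scores <- c(rnorm(20, 0), rnorm(20, 2))
  labels <- rep(c(TRUE, FALSE), each = 20)  # positives score LOW
  r <- roc_curve(scores, labels)
  expect_equal(r$direction, "<")
  expect_gt(r$auc, 0.5)
  # sensitivity honors the recorded direction and the strict inequality
  s <- roc_sensitivity_at(r, 1)
  expect_equal(s$sensitivity, mean(scores[labels] < 1))
  rr <- roc_curve(c(1, 1, 2, 3), c(0, 0, 1, 1), direction = ">")
  expect_equal(roc_sensitivity_at(rr, 1)$sensitivity, 1)   # 2,3 > 1
  expect_equal(roc_sensitivity_at(rr, 1)$specificity, 1)   # 1,1 not > 1
})

make_cohort_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  group <- sample(c("A", "B", "C"), n, replace = TRUE,
                  prob = c(0.6, 0.2, 0.2))
  shift <- c(A = 0, B = 40, C = 80)[group]
  peak <- rnorm(n, 1000, 25) + shift
  tab <- data.frame(case_id = seq_len(n), group = group,
                    biopsy_grade = sample(c("0R", "1R"), n, replace = TRUE),
                    mean_t1 = peak - 20, peak_t1 = peak,
                    fibrosis_percent = pmax(0.2, rnorm(n, 8, 4)))
  for (f in c("energy", "contrast", "entropy", "homogeneity", "correlation",
              "sum_average", "variance", "dissimilarity", "autocorrelation")) {
    tab[[f]] <- rnorm(n)
  }
  tab$bnp <- 800 + 2 * (peak - mean(peak)) + rnorm(n, 0, 100)
  tab$ra_mean <- rnorm(n, 10, 4)
  tab
}

test_that("rejection analysis assembles every section and names missing columns", {
  tab <- make_cohort_table()
  rpt <- rejection_analysis(tab)
  expect_s3_class(rpt, "rejection_report")
  expect_equal(nrow(rpt$group_summary), 3L)
  expect_setequal(unique(rpt$t_tests$dichotomy), c("clinical", "biopsy"))
  expect_true(all(c("mean_t1", "peak_t1", "entropy", "fibrosis_percent") %in%
                    rpt$t_tests$measure))
  expect_equal(nrow(rpt$anova), 2L)
  expect_true(rpt$trend$mean_t1$monotone_increasing)  # built with A<B<C shifts
  expect_true(all(rpt$roc_table$auc >= 0.5))          # auto-oriented
  expect_equal(rpt$sensitivity$threshold, 1050)
  expect_true(all(c("full", "no_rejection") %in% rpt$correlations$subset))
  expect_false(is.null(rpt$fibrosis))
  expect_error(rejection_analysis(tab[, setdiff(names(tab), "peak_t1")]),
               "peak_t1")
})

test_that("strongly separated cohorts give 100% sensitivity at the strict cutoff", {
  tab <- make_cohort_table(seed = 5)
  tab$peak_t1 <- ifelse(tab$group == "A",
                        1000 + 10 * seq_len(nrow(tab)) %% 9,
                        1100 + seq_len(nrow(tab)))
  rpt <- rejection_analysis(tab)
  expect_equal(rpt$sensitivity$sensitivity, 1)
  expect_equal(rpt$roc_table$auc[rpt$roc_table$measure == "peak_t1"], 1)
})
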