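test_that("majority voting aggregates tiles with the screening tie-break", {
  tp <- tibble::tibble(
    patient = c(rep("a", 5), rep("b", 3), rep("c", 4)),
    prob_msi = c(0.9, 0.8, 0.6, 0.2, 0.1,   # a: 3/5 positive
                 0.1, 0.2, 0.3,             # b: all negative
                 0.9, 0.8, 0.2, 0.1)        # c: 2/4 tie
  )
  agg <- aggregate_patients(tp)
  expect_identical(agg$label[agg$patient == "a"], "MSI-H")
  expect_identical(agg$label[agg$patient == "b"], "MSS")
  expect_identical(agg$label[agg$patient == "c"], "MSI-H")  # tie -> MSI-H
  expect_equal(agg$prob_mean[agg$patient == "a"], mean(c(0.9, 0.8, 0.6, 0.2, 0.1)))
  # mean tie-break resolves by thresholding the mean probability (0.5 here)
  agg2 <- aggregate_patients(tp, tie = "mean")
  expect_identical(agg2$label[agg2$patient == "c"], "MSI-H")
  tp3 <- tibble::tibble(patient = "d", prob_msi = c(0.9, 0.6, 0.2, 0.1))
  expect_identical(aggregate_patients(tp3, tie = "mean")$label, "MSS")
  expect_error(aggregate_patients(tp[0, ]), "zero tiles")
})

test_that("aggregation is permutation-invariant and majority-duplication safe", {
  set.seed(8)
  tp <- tibble::tibble(patient = "p", prob_msi = runif(9))
  a1 <- aggregate_patients(tp)
  a2 <- aggregate_patients(tp[sample(9), ])
  expect_identical(a1, a2)
  # duplicating a majority-class tile never flips the label
  maj_pos <- a1$label == "MSI-H"
  extra <- tibble::tibble(patient = "p", prob_msi = if (maj_pos) 0.99 else 0.01)
  a3 <- aggregate_patients(dplyr::bind_rows(tp, extra))
  expect_identical(a3$label, a1$label)
})

test_that("rank AUC matches the all-pairs counting oracle", {
  pair_auc <- function(s, l) {
    pos <- which(l); neg <- which(!l)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    tot / (length(pos) * length(neg))
  }
  # 4-point toy set with a tie
  s <- c(0.9, 0.4, 0.4, 0.1)
  l <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_rank(s, l), pair_auc(s, l), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_equal(auc_rank(s, l), pair_auc(s, l), tolerance = 1e-12)
  }
  # perfect separation and label-string interface
  expect_equal(auc_rank(c(3, 2, 1), c("MSI-H", "MSS", "MSS")), 1)
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("prevalence-adjusted metrics reproduce the worked example", {
  m <- prevalence_adjusted_metrics(0.87, 0.883, 0.15)
  expect_equal(m$accuracy, 0.87 * 0.15 + 0.883 * 0.85, tolerance = 1e-12)
  expect_identical(round(m$accuracy * 100), 88)           # prints as 88%
  expect_equal(m$ppv, 0.5675, tolerance = 5e-3)           # printed as 56.5%
  expect_equal(m$npv, 0.9726, tolerance = 5e-3)           # printed as 97.3%
  # boundary: a perfect test
  m1 <- prevalence_adjusted_metrics(1, 1, 0.15)
  expect_equal(unlist(m1), c(accuracy = 1, ppv = 1, npv = 1))
  expect_error(prevalence_adjusted_metrics(1.2, 0.5), "lie in")
})

test_that("total-probability identity holds across random operating points", {
  set.seed(31)
  for (i in 1:20) {
    s <- runif(1, 0.05, 0.95); e <- runif(1, 0.05, 0.95); p <- runif(1, 0.05, 0.95)
    m <- prevalence_adjusted_metrics(s, e, p)
    lhs <- m$accuracy
    rhs <- m$ppv * (s * p + (1 - e) * (1 - p)) +
      m$npv * (e * (1 - p) + (1 - s) * p)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson matches binom.test and handles boundaries", {
  # independent oracle: stats::binom.test computes the same exact interval
  oracle <- as.numeric(stats::binom.test(87, 100)$conf.int)
  expect_equal(as.numeric(clopper_pearson_ci(87, 100)), oracle,
    tolerance = 1e-9)
  expect_identical(unname(clopper_pearson_ci(0, 20)["lo"]), 0)
  expect_identical(unname(clopper_pearson_ci(20, 20)["hi"]), 1)
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:200, 1); k <- sample(0:n, 1)
    expect_equal(as.numeric(clopper_pearson_ci(k, n)),
      as.numeric(stats::binom.test(k, n)$conf.int), tolerance = 1e-9)
  }
  expect_error(clopper_pearson_ci(3, 0), "positive")
})

test_that("logit intervals bracket the predictive values and shrink with n", {
  ci <- logit_ci_predictive("ppv", 0.87, 0.883, 0.15, n_pos = 100, n_neg = 900)
  val <- prevalence_adjusted_metrics(0.87, 0.883, 0.15)$ppv
  expect_lt(ci["lo"], val)
  expect_gt(ci["hi"], val)
  expect_true(all(ci > 0 & ci < 1))
  wide <- logit_ci_predictive("npv", 0.87, 0.883, 0.15, 50, 450)
  narrow <- logit_ci_predictive("npv", 0.87, 0.883, 0.15, 500, 4500)
  expect_lt(diff(narrow), diff(wide))
  expect_error(logit_ci_predictive("ppv", 1, 0.9, 0.15, 10, 10), "strictly")
})

test_that("screening report combines counts, adjustment and intervals", {
  set.seed(5)
  truth <- tibble::tibble(patient = sprintf("p%03d", 1:200),
    msi_label = rep(c("MSI-H", "MSS"), c(30, 170)))
  # predictions: sensitivity ~0.9, specificity ~0.88
  pred <- tibble::tibble(
    patient = truth$patient,
    n_tiles = 10L, n_pos = 5L,
    prob_mean = ifelse(truth$msi_label == "MSI-H",
      rbeta(200, 8, 2), rbeta(200, 2, 8)),
    label = ifelse(runif(200) < ifelse(truth$msi_label == "MSI-H", 0.9, 0.12),
      "MSI-H", "MSS")
  )
  rep <- screening_metrics(pred, truth, prevalence = 0.15)
  expect_s3_class(rep, "metrics_report")
  expect_true(all(rep$value >= 0 & rep$value <= 1))
  cnt <- attr(rep, "counts")
  s <- rep$value[rep$metric == "sensitivity"]
  e <- rep$value[rep$metric == "specificity"]
  expect_equal(s, cnt["tp"] / (cnt["tp"] + cnt["fn"]), ignore_attr = TRUE)
  expect_equal(rep$value[rep$metric == "accuracy"],
    s * 0.15 + e * 0.85, tolerance = 1e-12)
  expect_equal(rep$value[rep$metric == "balanced_accuracy"], (s + e) / 2)
  expect_gt(rep$value[rep$metric == "auc_patient"], 0.8)
})

test_that("stratified error rates match hand-computed confusion counts", {
  tp <- tibble::tibble(
    tissue = c("TUM", "TUM", "TUM", "TUM", "LYM", "LYM"),
    magnification = "x40",
    msi_label = c("MSI-H", "MSI-H", "MSS", "MSS", "MSS", "MSS"),
    prob_msi = c(0.9, 0.2, 0.8, 0.1, 0.7, 0.6)
  )
  r <- stratified_error_rates(tp, strata = "tissue")
  # TUM: FP=1, TN=1 -> FPR 0.5; FN=1, TP=1 -> FNR 0.5
  expect_equal(r$fpr[r$level == "TUM"], 0.5)
  expect_equal(r$fnr[r$level == "TUM"], 0.5)
  # LYM: both MSS predicted positive -> FPR 1, FNR undefined
  expect_equal(r$fpr[r$level == "LYM"], 1)
  expect_true(is.na(r$fnr[r$level == "LYM"]))
  # all correct -> zero rates everywhere
  tp2 <- tp
  tp2$prob_msi <- ifelse(tp2$msi_label == "MSI-H", 0.9, 0.1)
  r2 <- stratified_error_rates(tp2, strata = c("tissue", "magnification"))
  expect_true(all(r2$fpr == 0, na.rm = TRUE))
  expect_true(all(r2$fnr == 0, na.rm = TRUE))
  expect_error(stratified_error_rates(tp, strata = "nope"), "missing stratum")
})
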