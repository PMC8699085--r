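#' Aggregate tile predictions to patient level by majority vote
#'
#' The patient's hard label is the majority of its tile hard labels at the
#' given probability threshold; even splits are decided towards MSI-H (a
#' screening-oriented tie-break favouring sensitivity). The patient's
#' continuous score is the mean tile MSI-H probability, used for
#' patient-level AUC.
#'
#' @param tile_predictions Tibble with columns `patient` and `prob_msi`
#'   (per-tile MSI-H probability).
#' @param threshold Tile-level operating threshold (default 0.5).
#' @param tie Either `"MSI-H"` (default: ties called positive) or `"mean"`
#'   (ties resolved by thresholding the mean probability).
#' @return Tibble with one row per patient: `patient, n_tiles, n_pos,
#'   prob_mean, label`.
#' @export
aggregate_patients <- function(tile_predictions, threshold = 0.5,
                               tie = c("MSI-H", "mean")) {
  tie <- match.arg(tie)
  assert_that(all(c("patient", "prob_msi") %in% names(tile_predictions)),
    "tile_predictions needs columns patient and prob_msi")
  assert_that(nrow(tile_predictions) > 0, "zero tiles supplied")
  out <- dplyr::summarise(
    dplyr::group_by(tile_predictions, .data$patient),
    n_tiles = dplyr::n(),
    n_pos = sum(.data$prob_msi >= threshold),
    prob_mean = mean(.data$prob_msi),
    .groups = "drop"
  )
  maj <- out$n_pos * 2 - out$n_tiles # > 0 majority positive; == 0 tie
  out$label <- ifelse(maj > 0, "MSI-H",
    ifelse(maj < 0, "MSS",
      if (tie == "MSI-H") "MSI-H" else NA))
  if (tie == "mean") {
    t_idx <- maj == 0
    out$label[t_idx] <- ifelse(out$prob_mean[t_idx] >= threshold, "MSI-H", "MSS")
  }
  out
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative, with
#' midranks for ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or `"MSI-H"`/`"MSS"` labels; `TRUE`/`"MSI-H"` is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "MSI-H"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prevalence-adjusted screening metrics
#'
#' Closed-form accuracy and predictive values at an assumed population
#' prevalence `P`: `accuracy = S*P + E*(1-P)`,
#' `PPV = S*P / (S*P + (1-E)*(1-P))`, `NPV = E*(1-P) / (E*(1-P) + (1-S)*P)`.
#' The default prevalence of 15% reflects the MSI-H rate assumed in the real
#' screening population.
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @param prevalence Assumed population prevalence in `[0, 1]` (default 0.15).
#' @return Tibble with columns `accuracy, ppv, npv`.
#' @export
#' @examples
#' prevalence_adjusted_metrics(0.87, 0.883) # accuracy 0.881 -> 88%
prevalence_adjusted_metrics <- function(sensitivity, specificity,
                                        prevalence = 0.15) {
  for (v in c(sensitivity, specificity, prevalence)) {
    assert_that(is.numeric(v) && v >= 0 && v <= 1,
      "sensitivity, specificity and prevalence must lie in [0, 1]")
  }
  s <- sensitivity; e <- specificity; p <- prevalence
  tibble::tibble(
    accuracy = s * p + e * (1 - p),
    ppv = if (s * p + (1 - e) * (1 - p) > 0)
      s * p / (s * p + (1 - e) * (1 - p)) else NA_real_,
    npv = if (e * (1 - p) + (1 - s) * p > 0)
      e * (1 - p) / (e * (1 - p) + (1 - s) * p) else NA_real_
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile construction; the lower bound is 0 when `k = 0` and the
#' upper bound 1 when `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  assert_that(n > 0, "n must be positive")
  assert_that(k >= 0 && k <= n, "k must lie in [0, n]")
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Standard logit confidence interval for prevalence-adjusted predictive values
#'
#' Delta-method interval on the logit scale for PPV / NPV computed from
#' sensitivity (estimated from `n_pos` positives) and specificity (from
#' `n_neg` negatives) at an assumed prevalence:
#' `Var(logit PPV) = (1-S)/(S*n_pos) + E/((1-E)*n_neg)` and
#' `Var(logit NPV) = (1-E)/(E*n_neg) + S/((1-S)*n_pos)`.
#'
#' @param kind `"ppv"` or `"npv"`.
#' @param sensitivity,specificity Point estimates in `(0, 1)`.
#' @param prevalence Assumed prevalence.
#' @param n_pos,n_neg Numbers of true positives-class and negatives-class
#'   subjects behind the sensitivity and specificity estimates.
#' @param conf Confidence level.
#' @return Named numeric `c(lo, hi)`.
#' @export
logit_ci_predictive <- function(kind = c("ppv", "npv"), sensitivity,
                                specificity, prevalence = 0.15,
                                n_pos, n_neg, conf = 0.95) {
  kind <- match.arg(kind)
  assert_that(n_pos > 0 && n_neg > 0, "n_pos and n_neg must be positive")
  s <- sensitivity; e <- specificity
  assert_that(s > 0 && s < 1 && e > 0 && e < 1,
    "logit interval requires sensitivity and specificity strictly inside (0, 1)")
  m <- prevalence_adjusted_metrics(s, e, prevalence)
  value <- if (kind == "ppv") m$ppv else m$npv
  var_logit <- if (kind == "ppv") {
    (1 - s) / (s * n_pos) + e / ((1 - e) * n_neg)
  } else {
    (1 - e) / (e * n_neg) + s / ((1 - s) * n_pos)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lg <- log(value / (1 - value))
  ci <- lg + c(-1, 1) * z * sqrt(var_logit)
  stats::setNames(1 / (1 + exp(-ci)), c("lo", "hi"))
}

#' Patient-level screening report with confidence intervals
#'
#' Computes sensitivity, specificity (with exact Clopper-Pearson intervals),
#' balanced accuracy, patient-level AUC, and the prevalence-adjusted
#' accuracy, PPV and NPV (accuracy with an exact interval on the adjusted
#' effective counts; predictive values with standard logit intervals).
#'
#' @param patient_predictions Output of [aggregate_patients()].
#' @param truth Tibble with columns `patient` and `msi_label` (true labels).
#' @param prevalence Assumed population prevalence (default 0.15).
#' @param conf Confidence level.
#' @return A tibble of class `metrics_report`: one row per metric with
#'   `metric, value, lo, hi`.
#' @export
screening_metrics <- function(patient_predictions, truth, prevalence = 0.15,
                              conf = 0.95) {
  d <- dplyr::inner_join(patient_predictions, truth, by = "patient")
  assert_that(nrow(d) == nrow(patient_predictions),
    "every predicted patient needs a true label")
  pos <- d$msi_label == "MSI-H"
  tp <- sum(pos & d$label == "MSI-H")
  fn <- sum(pos & d$label == "MSS")
  tn <- sum(!pos & d$label == "MSS")
  fp <- sum(!pos & d$label == "MSI-H")
  s <- tp / (tp + fn)
  e <- tn / (tn + fp)
  adj <- prevalence_adjusted_metrics(s, e, prevalence)
  auc <- auc_rank(d$prob_mean, d$msi_label)
  ci_s <- clopper_pearson_ci(tp, tp + fn, conf)
  ci_e <- clopper_pearson_ci(tn, tn + fp, conf)
  # accuracy CI: exact interval on the prevalence-weighted effective counts
  n_eff <- tp + fn + tn + fp
  ci_acc <- clopper_pearson_ci(round(adj$accuracy * n_eff), n_eff, conf)
  ci_ppv <- tryCatch(logit_ci_predictive("ppv", s, e, prevalence,
    tp + fn, tn + fp, conf), error = function(err) c(lo = NA_real_, hi = NA_real_))
  ci_npv <- tryCatch(logit_ci_predictive("npv", s, e, prevalence,
    tp + fn, tn + fp, conf), error = function(err) c(lo = NA_real_, hi = NA_real_))
  out <- tibble::tibble(
    metric = c("auc_patient", "accuracy", "sensitivity", "specificity",
      "balanced_accuracy", "ppv", "npv"),
    value = c(auc, adj$accuracy, s, e, (s + e) / 2, adj$ppv, adj$npv),
    lo = c(NA, ci_acc["lo"], ci_s["lo"], ci_e["lo"], NA, ci_ppv["lo"],
      ci_npv["lo"]),
    hi = c(NA, ci_acc["hi"], ci_s["hi"], ci_e["hi"], NA, ci_ppv["hi"],
      ci_npv["hi"])
  )
  class(out) <- c("metrics_report", class(out))
  attr(out, "counts") <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  attr(out, "prevalence") <- prevalence
  out
}

#' Stratified false positive / false negative rates at tile level
#'
#' Per-stratum (tissue type or magnification) `FPR = FP / (FP + TN)` and
#' `FNR = FN / (FN + TP)`, optionally averaged across folds (mean and sd).
#' Strata with no negatives (for FPR) or no positives (for FNR) are marked
#' undefined (`NA`).
#'
#' @param tile_predictions Tibble with `prob_msi`, `msi_label`, the stratum
#'   columns, and optionally `fold`.
#' @param strata Stratum columns (subset of `c("tissue", "magnification")`).
#' @param threshold Operating threshold.
#' @return Tibble with columns `stratum, level, fpr, fnr` (and `fpr_sd,
#'   fnr_sd, n_folds` when a `fold` column is present).
#' @export
stratified_error_rates <- function(tile_predictions,
                                   strata = c("tissue", "magnification"),
                                   threshold = 0.5) {
  missing_cols <- setdiff(strata, names(tile_predictions))
  assert_that(length(missing_cols) == 0,
    paste0("missing stratum column(s): ", paste(missing_cols, collapse = ", ")))
  d <- tile_predictions
  d$pred_pos <- d$prob_msi >= threshold
  d$pos <- d$msi_label == "MSI-H"
  has_fold <- "fold" %in% names(d)
  if (!has_fold) d$fold <- 1L

  one <- function(sub) {
    fp <- sum(sub$pred_pos & !sub$pos)
    tn <- sum(!sub$pred_pos & !sub$pos)
    fn <- sum(!sub$pred_pos & sub$pos)
    tp <- sum(sub$pred_pos & sub$pos)
    tibble::tibble(
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_
    )
  }
  res <- list()
  for (st in strata) {
    per_fold <- dplyr::group_by(d, level = as.character(.data[[st]]), .data$fold)
    rates <- dplyr::reframe(per_fold, one(dplyr::pick(dplyr::everything())))
    agg <- dplyr::summarise(dplyr::group_by(rates, .data$level),
      fpr_sd = stats::sd(.data$fpr), fnr_sd = stats::sd(.data$fnr),
      fpr = mean(.data$fpr, na.rm = TRUE), fnr = mean(.data$fnr, na.rm = TRUE),
      n_folds = dplyr::n(), .groups = "drop")
    agg$stratum <- st
    res[[st]] <- agg
  }
  out <- dplyr::bind_rows(res)
  cols <- c("stratum", "level", "fpr", "fnr")
  if (has_fold) cols <- c(cols, "fpr_sd", "fnr_sd", "n_folds")
  out[, cols]
}
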