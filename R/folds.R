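#' Patient-grouped k-fold split
#'
#' Partitions patients (not tiles) into k folds so that all images of a
#' patient belong to exactly one fold's validation set and never to both the
#' training and validation set of the same fold. Fold sizes differ by at most
#' one patient. Deterministic under the seed.
#'
#' @param manifest Tibble with a `patient` column (one row per tile).
#' @param k Number of folds (default 5, i.e. 80/20 splits).
#' @param seed Integer seed.
#' @return A `fold_plan` tibble with columns `patient` and `fold`.
#' @export
grouped_kfold_split <- function(manifest, k = 5, seed = 1L) {
  assert_that("patient" %in% names(manifest), "manifest needs a patient column")
  patients <- sort(unique(manifest$patient))
  assert_that(k <= length(patients),
    paste0("k = ", k, " exceeds the number of patients (", length(patients), ")"))
  shuffled <- with_seed(seed, sample(patients))
  plan <- tibble::tibble(
    patient = shuffled,
    fold = rep_len(seq_len(k), length(shuffled))
  )
  plan <- dplyr::arrange(plan, .data$patient)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Row indices of the training / validation split of one fold
#'
#' @param manifest Tile manifest with a `patient` column.
#' @param fold_plan A [grouped_kfold_split()] plan.
#' @param fold Fold number whose patients form the validation set.
#' @return List with integer row indices `train` and `val`.
#' @export
fold_indices <- function(manifest, fold_plan, fold = 1L) {
  val_patients <- fold_plan$patient[fold_plan$fold == fold]
  val <- which(manifest$patient %in% val_patients)
  list(train = setdiff(seq_len(nrow(manifest)), val), val = val)
}

#' Composite patient/class-balancing sampling weights
#'
#' Per-tile weights proportional to
#' `1 / (tiles of the patient * patients in the MSI class)`, so that
#' with-replacement sampling draws each class with probability 1/2 and, within
#' a class, each patient with equal probability regardless of its tile count.
#'
#' @param manifest Tibble with columns `patient` and `msi_label`.
#' @return Numeric weight vector (sums to 1) aligned with the manifest rows.
#' @export
composite_weights <- function(manifest) {
  assert_that(all(c("patient", "msi_label") %in% names(manifest)),
    "manifest needs patient and msi_label columns")
  classes <- unique(manifest$msi_label)
  assert_that(all(c("MSI-H", "MSS") %in% classes) || length(classes) >= 1,
    "manifest is empty")
  counts <- dplyr::count(manifest, .data$patient, .data$msi_label,
    name = "tiles_of_patient")
  by_class <- dplyr::count(dplyr::distinct(manifest, .data$patient,
    .data$msi_label), .data$msi_label, name = "patients_in_class")
  if (any(by_class$patients_in_class == 0)) {
    stop("empty MSI class in manifest", call. = FALSE)
  }
  joined <- dplyr::left_join(
    dplyr::left_join(manifest[, c("patient", "msi_label")], counts,
      by = c("patient", "msi_label")),
    by_class, by = "msi_label")
  w <- 1 / (joined$tiles_of_patient * joined$patients_in_class)
  w / sum(w)
}
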