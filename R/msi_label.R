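#' Ground-truth evidence record for MSI status
#'
#' Bundles the molecular evidence used to assign the microsatellite-instability
#' label of a tumour: mismatch-repair protein loss on immunohistochemistry
#' (MLH1, PMS2, MSH2, MSH6), PCR-based MSI testing, BRAF mutation status and
#' MLH1 promoter methylation status.
#'
#' BRAF testing is only performed when the tumour shows MSI by PCR or MLH1
#' loss; accordingly `braf_mutant` may be `NA` (unknown) only when neither of
#' those findings is present.
#'
#' @param ihc_loss Character vector: subset of `c("MLH1","PMS2","MSH2","MSH6")`
#'   naming proteins with lost expression (may be empty).
#' @param msi_pcr_positive Logical flag: tumour is MSI by PCR testing.
#' @param braf_mutant Logical or `NA`: BRAF V600E mutation present.
#' @param mlh1_promoter_methylated Logical or `NA`: MLH1 promoter
#'   hypermethylation present. Recorded but does not change the label.
#'
#' @return An object of class `ground_truth_record`.
#' @seealso [label_msi_status()]
#' @export
#' @examples
#' rec <- ground_truth_record(ihc_loss = "MSH6", msi_pcr_positive = FALSE)
#' label_msi_status(rec)
ground_truth_record <- function(ihc_loss = character(),
                                msi_pcr_positive = FALSE,
                                braf_mutant = NA,
                                mlh1_promoter_methylated = NA) {
  proteins <- c("MLH1", "PMS2", "MSH2", "MSH6")
  ihc_loss <- unique(as.character(ihc_loss))
  bad <- setdiff(ihc_loss, proteins)
  assert_that(length(bad) == 0,
    paste0("unknown MMR protein(s) in ihc_loss: ", paste(bad, collapse = ", ")))
  assert_that(is.logical(msi_pcr_positive) && length(msi_pcr_positive) == 1 &&
    !is.na(msi_pcr_positive), "msi_pcr_positive must be TRUE or FALSE")
  assert_that(is.logical(braf_mutant) && length(braf_mutant) == 1,
    "braf_mutant must be TRUE, FALSE or NA")
  assert_that(is.logical(mlh1_promoter_methylated) &&
    length(mlh1_promoter_methylated) == 1,
    "mlh1_promoter_methylated must be TRUE, FALSE or NA")
  braf_required <- msi_pcr_positive || "MLH1" %in% ihc_loss
  if (is.na(braf_mutant) && braf_required) {
    stop("braf_mutant may be unknown only when neither MSI by PCR nor ",
      "MLH1 loss is present", call. = FALSE)
  }
  structure(
    list(
      ihc_loss = ihc_loss,
      msi_pcr_positive = msi_pcr_positive,
      braf_mutant = braf_mutant,
      mlh1_promoter_methylated = mlh1_promoter_methylated
    ),
    class = "ground_truth_record"
  )
}

#' Assign the MSI-H / MSS label from molecular evidence
#'
#' Applies the universal-screening decision rule: tumours with MSH2, MSH6 or
#' isolated PMS2 loss (PMS2 lost while MLH1 retained) are MSI-H; tumours with
#' MLH1 loss or MSI by PCR are MSI-H when no BRAF mutation is found
#' (regardless of MLH1 promoter methylation) and MSS when BRAF is mutated;
#' all tumours without mismatch-repair deficiency evidence are MSS.
#'
#' @param record A [ground_truth_record()].
#' @return `"MSI-H"` or `"MSS"`.
#' @export
#' @examples
#' label_msi_status(ground_truth_record(ihc_loss = "MSH2", msi_pcr_positive = FALSE))
#' label_msi_status(ground_truth_record(ihc_loss = "MLH1", braf_mutant = TRUE))
label_msi_status <- function(record) {
  assert_that(inherits(record, "ground_truth_record"),
    "record must be a ground_truth_record")
  loss <- record$ihc_loss
  direct <- "MSH2" %in% loss || "MSH6" %in% loss ||
    ("PMS2" %in% loss && !("MLH1" %in% loss))
  if (direct) return("MSI-H")
  braf_path <- "MLH1" %in% loss || record$msi_pcr_positive
  if (braf_path) {
    if (is.na(record$braf_mutant)) {
      stop("incomplete evidence: BRAF result required for MLH1 loss or ",
        "MSI by PCR", call. = FALSE)
    }
    return(if (record$braf_mutant) "MSS" else "MSI-H")
  }
  "MSS"
}
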