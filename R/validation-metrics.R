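#' Detection precision of a validation experiment
#'
#' The fraction of assay-successful validations in which the variant was
#' confirmed present in the sample, irrespective of its mosaic/germline
#' classification.
#'
#' @param outcomes Data frame of per-variant validation outcomes with
#'   logical columns `assay_success` and `variant_present`.
#' @return Fraction in [0, 1].
#' @export
detection_precision <- function(outcomes) {
  ok <- outcomes$assay_success
  if (sum(ok) == 0) {
    stop("detection_precision: no successful assays", call. = FALSE)
  }
  sum(outcomes$variant_present[ok], na.rm = TRUE) / sum(ok)
}

#' Classification precision of a validation experiment
#'
#' The fraction of informative validations of variants with a given
#' predicted label in which the variant was present and its observed label
#' matched the prediction.
#'
#' @param outcomes Data frame with columns `predicted_label`,
#'   `observed_label` (`"mosaic"`, `"germline_denovo"` or `"unknown"`) and
#'   `informative` (logical; assays whose outcome resolves the label).
#' @param predicted_label The predicted class to evaluate.
#' @return Fraction in [0, 1].
#' @export
classification_precision <- function(outcomes, predicted_label) {
  sel <- outcomes$predicted_label == predicted_label & outcomes$informative
  if (sum(sel) == 0) {
    stop("classification_precision: no informative outcomes for label '",
         predicted_label, "'", call. = FALSE)
  }
  sum(outcomes$observed_label[sel] == predicted_label) / sum(sel)
}

#' Summarise validation outcomes as a precision table
#'
#' Reproduces the bookkeeping of published validation tables: one row per
#' (filter stage, predicted label, assay) with the number of variants
#' chosen, assay successes, variants confirmed present, detection precision,
#' variants confirmed mosaic among informative assays, and classification
#' precision. Precisions are reported at full precision; round for display.
#'
#' @param outcomes Data frame with columns `stage`, `predicted_label`,
#'   `assay`, `assay_success`, `variant_present`, `informative`,
#'   `observed_label`.
#' @return Data frame keyed by (`stage`, `predicted_label`, `assay`).
#' @export
summarize_validation <- function(outcomes) {
  if (nrow(outcomes) == 0) {
    return(data.frame(stage = character(0), predicted_label = character(0),
                      assay = character(0), chosen = integer(0),
                      assay_success = integer(0), variant_present = integer(0),
                      detection_precision = numeric(0),
                      informative = integer(0),
                      label_confirmed = integer(0),
                      classification_precision = numeric(0),
                      stringsAsFactors = FALSE))
  }
  groups <- unique(outcomes[, c("stage", "predicted_label", "assay")])
  groups <- groups[order(groups$stage, groups$predicted_label, groups$assay), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- outcomes[outcomes$stage == groups$stage[i] &
                    outcomes$predicted_label == groups$predicted_label[i] &
                    outcomes$assay == groups$assay[i], , drop = FALSE]
    n_success <- sum(g$assay_success)
    n_present <- sum(g$variant_present & g$assay_success, na.rm = TRUE)
    n_informative <- sum(g$informative)
    n_confirmed <- sum(g$informative &
                         g$observed_label == g$predicted_label, na.rm = TRUE)
    data.frame(
      stage = groups$stage[i], predicted_label = groups$predicted_label[i],
      assay = groups$assay[i], chosen = nrow(g), assay_success = n_success,
      variant_present = n_present,
      detection_precision = if (n_success > 0) n_present / n_success else NA_real_,
      informative = n_informative,
      label_confirmed = n_confirmed,
      classification_precision =
        if (n_informative > 0) n_confirmed / n_informative else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand marginal validation-table cells into per-variant outcomes
#'
#' Utility for re-deriving printed precision ratios from a table's integer
#' cells: builds a per-variant outcome list consistent with the marginal
#' counts (chosen, successful, present, label-confirmed).
#'
#' @param stage,predicted_label,assay Group keys.
#' @param chosen Variants chosen for validation.
#' @param success Assay successes (also taken as the number of informative
#'   outcomes unless `informative` is given).
#' @param present Variants confirmed present.
#' @param confirmed Variants whose observed label matched the prediction.
#' @param informative Number of informative outcomes, when it differs from
#'   `success`.
#' @return A per-variant outcome data frame as consumed by
#'   [summarize_validation()].
#' @export
expand_validation_cells <- function(stage, predicted_label, assay,
                                    chosen, success, present, confirmed,
                                    informative = success) {
  stopifnot(success <= chosen, present <= success, confirmed <= informative,
            informative <= chosen)
  other <- setdiff(c("mosaic", "germline_denovo"), predicted_label)
  observed <- rep("unknown", chosen)
  observed[seq_len(confirmed)] <- predicted_label
  if (informative > confirmed) {
    observed[(confirmed + 1):informative] <- other
  }
  data.frame(
    stage = stage, predicted_label = predicted_label, assay = assay,
    assay_success = rep(c(TRUE, FALSE), c(success, chosen - success)),
    variant_present = rep(c(TRUE, FALSE), c(present, chosen - present)),
    informative = rep(c(TRUE, FALSE), c(informative, chosen - informative)),
    observed_label = observed,
    stringsAsFactors = FALSE)
}

#' Allelic noise at a site
#'
#' For each alternate allele, the fraction of reads supporting that allele
#' summed over all samples genotyped homozygous for the reference allele
#' (excluding specified samples, e.g. those with a called variant), relative
#' to their total read count. The maximum across alternate alleles is
#' returned.
#'
#' @param site_counts Data frame with columns `sample`, `allele`,
#'   `alt_reads`, `total_reads`; one row per (sample, alternate allele).
#' @param hom_ref_samples Samples genotyped homozygous reference.
#' @param excluded_samples Samples to exclude (default none).
#' @return Maximum per-allele noise fraction.
#' @export
allelic_noise <- function(site_counts, hom_ref_samples,
                          excluded_samples = character(0)) {
  use <- site_counts$sample %in% setdiff(hom_ref_samples, excluded_samples)
  counts <- site_counts[use, , drop = FALSE]
  if (nrow(counts) == 0 || sum(counts$total_reads) == 0) {
    stop("allelic_noise: no informative homozygous-reference samples",
         call. = FALSE)
  }
  per_allele <- vapply(split(counts, counts$allele), function(a) {
    sum(a$alt_reads) / sum(a$total_reads)
  }, numeric(1))
  max(per_allele)
}
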