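#' Parameters for mosaic classification
#'
#' @param expected_fraction Expected fraction of reads supporting a
#'   heterozygous de novo allele (0.5 under the diploid germline model).
#' @param fdr False-discovery rate for the Benjamini-Hochberg procedure.
#' @param aarf_max Maximum alternate-allele read fraction for a mosaic call;
#'   calls at higher AARF are treated as germline since preferential capture
#'   of the reference allele can mimic weak mosaicism at high depth.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(expected_fraction = 0.5, fdr = 0.05,
                              aarf_max = 0.34) {
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop("classifier_params: expected_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (fdr <= 0 || fdr >= 1) {
    stop("classifier_params: fdr must lie in (0, 1)", call. = FALSE)
  }
  if (aarf_max <= 0 || aarf_max > 1) {
    stop("classifier_params: aarf_max must lie in (0, 1]", call. = FALSE)
  }
  structure(list(expected_fraction = expected_fraction, fdr = fdr,
                 aarf_max = aarf_max),
            class = "classifier_params")
}

#' Lower-tail binomial p-value for mosaicism
#'
#' Tests the alternative hypothesis that a de novo allele is supported by
#' fewer reads than expected from the read depth under the heterozygous
#' germline model: the exact lower-tail probability
#' `P(X <= alt_depth | n = total_depth, p = expected_fraction)`.
#'
#' @param alt_depth Alternate-supporting reads (vectorised).
#' @param total_depth Total reads.
#' @param expected_fraction Expected alternate read fraction under the
#'   germline model.
#' @return Lower-tail p-value(s).
#' @export
binomial_mosaic_p <- function(alt_depth, total_depth, expected_fraction = 0.5) {
  if (any(!is.finite(alt_depth)) || any(!is.finite(total_depth)) ||
      any(total_depth <= 0) || any(alt_depth < 0) ||
      any(alt_depth > total_depth)) {
    stop("binomial_mosaic_p: require 0 <= alt_depth <= total_depth, total_depth > 0",
         call. = FALSE)
  }
  pbinom(alt_depth, total_depth, expected_fraction)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up q-values, returned in the input order.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Classify de novo calls as mosaic or germline
#'
#' Computes the lower-tail binomial p-value for every call, adjusts jointly
#' across the whole callset (probands and siblings together) with the
#' Benjamini-Hochberg procedure, and labels a call mosaic iff its q-value is
#' below the FDR and its alternate-allele read fraction is below `aarf_max`.
#' All other calls are labelled germline de novo.
#'
#' @param calls De novo call table with `alt_depth`, `total_depth` and
#'   `aarf` columns (as from [find_denovo()]).
#' @param params A [classifier_params()].
#' @param confirmed Optional logical vector (or call table from
#'   [intersect_confirmation()]): calls not confirmed are ineligible for the
#'   mosaic label and excluded from the final callset, mirroring the
#'   requirement that mosaic variants appear jointly in an independent
#'   callset.
#' @return The call table with added columns `p_mosaic`, `q_value`, `label`
#'   and `in_final_callset`.
#' @export
classify_mosaic <- function(calls, params = classifier_params(),
                            confirmed = NULL) {
  stopifnot(inherits(params, "classifier_params"))
  if (nrow(calls) == 0) {
    calls$p_mosaic <- numeric(0)
    calls$q_value <- numeric(0)
    calls$label <- character(0)
    calls$in_final_callset <- logical(0)
    return(calls)
  }
  calls$p_mosaic <- binomial_mosaic_p(calls$alt_depth, calls$total_depth,
                                      params$expected_fraction)
  calls$q_value <- bh_adjust(calls$p_mosaic)
  mosaic <- calls$q_value < params$fdr & calls$aarf < params$aarf_max
  if (!is.null(confirmed)) {
    if (is.data.frame(confirmed)) {
      keys <- paste(confirmed$chrom, confirmed$pos, confirmed$ref,
                    confirmed$alt, confirmed$child_id, sep = ":")
      confirmed <- paste(calls$chrom, calls$pos, calls$ref, calls$alt,
                         calls$child_id, sep = ":") %in% keys
    }
    stopifnot(is.logical(confirmed), length(confirmed) == nrow(calls))
    calls$in_final_callset <- !mosaic | confirmed
  } else {
    calls$in_final_callset <- TRUE
  }
  calls$label <- ifelse(mosaic, "mosaic", "germline_denovo")
  calls
}

#' Summarise a classified callset
#'
#' @param classified Output of [classify_mosaic()], or explicit counts via
#'   `n_mosaic` and `n_total`.
#' @param n_mosaic,n_total Optional explicit counts overriding `classified`.
#' @return A list with `n_total`, `n_mosaic`, `n_germline` and
#'   `mosaic_fraction_pct` (percentage of the callset classified mosaic).
#' @export
callset_summary <- function(classified = NULL, n_mosaic = NULL, n_total = NULL) {
  if (is.null(n_mosaic) || is.null(n_total)) {
    stopifnot(!is.null(classified))
    final <- classified[classified$in_final_callset, , drop = FALSE]
    n_total <- nrow(final)
    n_mosaic <- sum(final$label == "mosaic")
  }
  list(n_total = n_total, n_mosaic = n_mosaic,
       n_germline = n_total - n_mosaic,
       mosaic_fraction_pct = 100 * n_mosaic / n_total)
}
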