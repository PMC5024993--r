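#' Parameters for trio de novo calling
#'
#' Defaults mirror the filters of the original trio caller: minimum depth 20
#' in every trio member, at least 3 reads supporting the alternate allele in
#' the child, phred-scaled confidence of at least 20 for presence of the
#' allele in the child and for its absence in each parent, and at most 2
#' individuals in the whole cohort genotyped with the allele.
#'
#' @param min_trio_depth Minimum total depth (reads) required in the child
#'   and both parents.
#' @param min_child_alt_reads Minimum alternate-supporting reads in the child.
#' @param min_child_presence_phred Minimum phred-scaled likelihood gap
#'   supporting the presence of the allele in the child (PL of hom-ref minus
#'   PL of the best allele-carrying genotype).
#' @param min_parent_absence_phred Minimum phred-scaled likelihood gap
#'   supporting the absence of the allele in each parent (best
#'   allele-carrying PL minus hom-ref PL).
#' @param max_carriers_in_cohort Maximum number of individuals (parents and
#'   children, across all families) genotyped with the allele.
#' @param family_exclusion_threshold De novo calls per child above which the
#'   whole family is treated as a technical artifact and excluded.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(min_trio_depth = 20,
                          min_child_alt_reads = 3,
                          min_child_presence_phred = 20,
                          min_parent_absence_phred = 20,
                          max_carriers_in_cohort = 2,
                          family_exclusion_threshold = 10) {
  vals <- c(min_trio_depth, min_child_alt_reads, min_child_presence_phred,
            min_parent_absence_phred, max_carriers_in_cohort,
            family_exclusion_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("caller_params: all thresholds must be positive and finite", call. = FALSE)
  }
  structure(list(min_trio_depth = min_trio_depth,
                 min_child_alt_reads = min_child_alt_reads,
                 min_child_presence_phred = min_child_presence_phred,
                 min_parent_absence_phred = min_parent_absence_phred,
                 max_carriers_in_cohort = max_carriers_in_cohort,
                 family_exclusion_threshold = family_exclusion_threshold),
            class = "caller_params")
}

REQUIRED_MEMBER_FIELDS <- as.vector(outer(c("fa", "mo", "p1", "s1"),
                                          c("dp", "ad", "pl0", "pl1", "pl2"),
                                          paste, sep = "_"))

variant_type <- function(ref, alt) {
  type <- character(length(ref))
  type[nchar(ref) < nchar(alt)] <- "insertion"
  type[nchar(ref) > nchar(alt)] <- "deletion"
  snv <- nchar(ref) == 1 & nchar(alt) == 1
  ti <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  type[snv & ti] <- "transition"
  type[snv & !ti] <- "transversion"
  type
}

#' Identify de novo alleles in children of quad families
#'
#' For every (site, child) pair, a de novo call is emitted iff all of the
#' following hold: the most-likely genotype of each parent excludes the
#' alternate allele while the child's includes it; the phred-scaled
#' likelihood gaps for presence in the child and absence in each parent meet
#' their thresholds; all three trio members reach the minimum depth; the
#' child has the minimum number of alternate-supporting reads; and no more
#' than the maximum number of individuals across the whole cohort are
#' genotyped with the allele. Each child of a quad family is evaluated
#' against both parents independently.
#'
#' @param records Multi-sample variant records as produced by
#'   [generate_cohort()] (columns `chrom`, `pos`, `ref`, `alt`, `family_id`
#'   and per-member `*_dp`, `*_ad`, `*_pl0..2`).
#' @param params A [caller_params()].
#' @return A data frame of de novo calls with columns `chrom`, `pos`, `ref`,
#'   `alt`, `family_id`, `child_id`, `child_role`, `total_depth`,
#'   `alt_depth`, `aarf`, `variant_type` and `functional_class`.
#' @export
find_denovo <- function(records, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  need <- c("chrom", "pos", "ref", "alt", "family_id", REQUIRED_MEMBER_FIELDS)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("find_denovo: records are missing required fields: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(records[REQUIRED_MEMBER_FIELDS]))
  if (length(bad)) {
    stop("find_denovo: missing per-member data at ",
         records$chrom[bad[1]], ":", records$pos[bad[1]], call. = FALSE)
  }
  if (nrow(records) == 0) return(empty_call_table())

  dos <- sapply(c("fa", "mo", "p1", "s1"), function(m) {
    dosage_from_pl(records[[paste0(m, "_pl0")]],
                   records[[paste0(m, "_pl1")]],
                   records[[paste0(m, "_pl2")]])
  })
  dos <- matrix(dos, ncol = 4, dimnames = list(NULL, c("fa", "mo", "p1", "s1")))

  # cohort-wide carrier counts per unique allele, over all four members
  allele_key <- paste(records$chrom, records$pos, records$ref, records$alt,
                      sep = ":")
  carriers_per_record <- rowSums(dos > 0)
  carriers <- tapply(carriers_per_record, allele_key, sum)
  cohort_carriers <- as.vector(carriers[allele_key])

  calls <- lapply(c("p1", "s1"), function(child) {
    dp_c <- records[[paste0(child, "_dp")]]
    ad_c <- records[[paste0(child, "_ad")]]
    pl0_c <- records[[paste0(child, "_pl0")]]
    presence <- pl0_c - pmin(records[[paste0(child, "_pl1")]],
                             records[[paste0(child, "_pl2")]])
    absent_fa <- pmin(records$fa_pl1, records$fa_pl2) - records$fa_pl0
    absent_mo <- pmin(records$mo_pl1, records$mo_pl2) - records$mo_pl0
    keep <- dos[, "fa"] == 0 & dos[, "mo"] == 0 & dos[, child] > 0 &
      dp_c >= params$min_trio_depth &
      records$fa_dp >= params$min_trio_depth &
      records$mo_dp >= params$min_trio_depth &
      ad_c >= params$min_child_alt_reads &
      presence >= params$min_child_presence_phred &
      absent_fa >= params$min_parent_absence_phred &
      absent_mo >= params$min_parent_absence_phred &
      cohort_carriers <= params$max_carriers_in_cohort
    if (!any(keep)) return(NULL)
    out <- records[keep, c("chrom", "pos", "ref", "alt", "family_id"),
                   drop = FALSE]
    out$child_id <- paste0(out$family_id, ".", child)
    out$child_role <- unname(CHILD_ROLES[child])
    out$total_depth <- dp_c[keep]
    out$alt_depth <- ad_c[keep]
    out$aarf <- out$alt_depth / out$total_depth
    out$variant_type <- variant_type(out$ref, out$alt)
    out$functional_class <- if ("functional_class" %in% names(records)) {
      records$functional_class[keep]
    } else NA_character_
    out
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) return(empty_call_table())
  calls <- calls[order(calls$family_id, calls$child_id, calls$pos), ]
  rownames(calls) <- NULL
  calls
}

empty_call_table <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), family_id = character(0),
             child_id = character(0), child_role = character(0),
             total_depth = integer(0), alt_depth = integer(0),
             aarf = numeric(0), variant_type = character(0),
             functional_class = character(0), stringsAsFactors = FALSE)
}

#' Exclude families with an excess of de novo calls in any child
#'
#' Families in which any child carries more than `threshold` de novo calls
#' are removed wholesale (both children's calls), as such an excess is most
#' plausibly a technical artifact.
#'
#' @param calls De novo call table from [find_denovo()].
#' @param threshold Calls per child above which the family is dropped.
#' @return A list with `calls` (kept calls) and `excluded_families`
#'   (character vector of family ids removed).
#' @export
exclude_families <- function(calls, threshold = 10) {
  if (nrow(calls) == 0) {
    return(list(calls = calls, excluded_families = character(0)))
  }
  per_child <- table(calls$child_id)
  bad_children <- names(per_child)[per_child > threshold]
  bad_families <- unique(calls$family_id[calls$child_id %in% bad_children])
  list(calls = calls[!calls$family_id %in% bad_families, , drop = FALSE],
       excluded_families = bad_families)
}

#' Keep calls present in at least one external confirmation callset
#'
#' Intended for mosaic candidates: requiring joint presence in an
#' independent callset removes low-support artifacts that mimic mosaicism.
#'
#' @param calls De novo call table.
#' @param confirmation_sets List of data frames, each with columns `chrom`,
#'   `pos`, `ref`, `alt`, `child_id` keying confirmed variants.
#' @return The subset of `calls` present in the union of the sets.
#' @export
intersect_confirmation <- function(calls, confirmation_sets) {
  if (nrow(calls) == 0 || length(confirmation_sets) == 0) {
    return(calls[0, , drop = FALSE])
  }
  keys <- unique(unlist(lapply(confirmation_sets, function(s) {
    paste(s$chrom, s$pos, s$ref, s$alt, s$child_id, sep = ":")
  })))
  call_keys <- paste(calls$chrom, calls$pos, calls$ref, calls$alt,
                     calls$child_id, sep = ":")
  calls[call_keys %in% keys, , drop = FALSE]
}

#' Reference-allele balance annotation
#'
#' The fraction of sequencing reads supporting the reference allele relative
#' to the total read count at a site, used as a site-level filtration
#' annotation.
#'
#' @param ref_reads Reads supporting the reference allele.
#' @param total_reads Total reads at the site.
#' @return `ref_reads / total_reads`.
#' @export
abhet <- function(ref_reads, total_reads) {
  if (any(total_reads == 0)) {
    stop("abhet: undefined for total_reads == 0", call. = FALSE)
  }
  if (any(ref_reads < 0) || any(ref_reads > total_reads)) {
    stop("abhet: ref_reads must lie in [0, total_reads]", call. = FALSE)
  }
  ref_reads / total_reads
}
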