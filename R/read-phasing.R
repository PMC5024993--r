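#' Read-configuration counts at a (de novo, inherited het) site pair
#'
#' The four configurations count reads spanning both sites by the inherited
#' allele they carry (alternate or reference at the linked het) crossed with
#' presence of the de novo allele.
#'
#' @param alt_alt Reads carrying the inherited alternate allele and the de
#'   novo allele.
#' @param alt_ref Inherited alternate, de novo absent.
#' @param ref_alt Inherited reference, de novo present.
#' @param ref_ref Inherited reference, de novo absent.
#' @param parent_of_inherited_alt Which parent (`"father"`, `"mother"` or
#'   `NA`) transmitted the inherited alternate allele; used to assign
#'   parental origin.
#' @return An object of class `phase_observation`.
#' @export
phase_observation <- function(alt_alt, alt_ref, ref_alt, ref_ref,
                              parent_of_inherited_alt = NA_character_) {
  counts <- c(alt_alt, alt_ref, ref_alt, ref_ref)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("phase_observation: counts must be non-negative", call. = FALSE)
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE,
              dimnames = list(inherited = c("alt", "ref"),
                              denovo = c("alt", "ref")))
  structure(list(counts = m,
                 parent_of_inherited_alt = parent_of_inherited_alt),
            class = "phase_observation")
}

#' @export
print.phase_observation <- function(x, ...) {
  cat("Phase observation (rows: inherited allele, cols: de novo allele)\n")
  print(x$counts)
  if (!is.na(x$parent_of_inherited_alt)) {
    cat("inherited alt transmitted by:", x$parent_of_inherited_alt, "\n")
  }
  invisible(x)
}

#' Tabulate phasing reads into configuration counts
#'
#' Reads with base quality below `min_base_quality` at either site are
#' dropped before counting.
#'
#' @param reads Data frame with columns `het_allele`, `dn_allele` (values
#'   `"alt"`/`"ref"`) and optionally `het_qual`, `dn_qual`.
#' @param min_base_quality Quality floor applied at both sites.
#' @param parent_of_inherited_alt Parental origin of the inherited alternate
#'   allele; defaults to the generator's truth attribute when present.
#' @return A [phase_observation()].
#' @export
count_phase_configurations <- function(reads, min_base_quality = 20,
                                       parent_of_inherited_alt = NULL) {
  if (is.null(parent_of_inherited_alt)) {
    parent_of_inherited_alt <- attr(reads, "parent_of_het_alt")
    if (is.null(parent_of_inherited_alt)) parent_of_inherited_alt <- NA_character_
  }
  if (!is.null(reads$het_qual)) {
    reads <- reads[reads$het_qual >= min_base_quality &
                     reads$dn_qual >= min_base_quality, , drop = FALSE]
  }
  n <- function(h, d) sum(reads$het_allele == h & reads$dn_allele == d)
  phase_observation(n("alt", "alt"), n("alt", "ref"),
                    n("ref", "alt"), n("ref", "ref"),
                    parent_of_inherited_alt)
}

#' Confirm or refute mosaicism from phased read configurations
#'
#' Let X be the inherited allele observed together with the de novo allele
#' (at least `min_support` reads). Three distinct parental haplotypes --
#' (X, de novo present), (X, de novo absent) and the other inherited allele
#' -- demonstrate post-zygotic origin: the verdict is mosaic iff the
#' (X, de-novo-absent) configuration also reaches `min_support` reads.
#' Perfect co-segregation of the de novo allele with X is the germline
#' pattern. The observation is uninformative when the de novo allele
#' co-occurs with both inherited alleles at `min_support` (inconsistent
#' phasing) or when no allele-carrying configuration reaches support.
#'
#' @param obs A [phase_observation()].
#' @param min_support Minimum reads for a haplotype to count as observed.
#' @return A list of class `phasing_result` with elements `informative`,
#'   `mosaic`, `mosaic_frac` (fraction of cells carrying the variant, only
#'   when mosaic) and `parent` (`"father"`, `"mother"` or
#'   `"undetermined"`).
#' @export
phase_denovo <- function(obs, min_support = 2) {
  stopifnot(inherits(obs, "phase_observation"), min_support >= 1)
  cnt <- obs$counts
  res <- list(informative = FALSE, mosaic = NA, mosaic_frac = NA_real_,
              parent = "undetermined")
  class(res) <- "phasing_result"
  dn_with <- cnt[, "alt"]
  supported <- dn_with >= min_support
  if (sum(supported) != 1L) {
    # no support, or the de novo allele rides on both inherited alleles
    return(res)
  }
  x <- names(which(supported))
  res$informative <- TRUE
  res$mosaic <- cnt[x, "ref"] >= min_support
  if (isTRUE(res$mosaic)) {
    res$mosaic_frac <- cnt[x, "alt"] / (cnt[x, "alt"] + cnt[x, "ref"])
  }
  origin <- obs$parent_of_inherited_alt
  if (!is.na(origin)) {
    other <- setdiff(c("father", "mother"), origin)
    res$parent <- if (x == "alt") origin else other
  }
  res
}

#' @export
print.phasing_result <- function(x, ...) {
  if (!x$informative) {
    cat("Phasing: uninformative\n")
  } else if (isTRUE(x$mosaic)) {
    cat(sprintf("Phasing: mosaic (three haplotypes); cell fraction %.3f; %s origin\n",
                x$mosaic_frac, x$parent))
  } else {
    cat(sprintf("Phasing: germline pattern (two haplotypes); %s origin\n",
                x$parent))
  }
  invisible(x)
}

#' Fraction of cells carrying a phased mosaic variant
#'
#' Among reads from the mutant parental haplotype, the fraction carrying the
#' de novo allele estimates the fraction of cells heterozygous for the
#' variant (assuming a diploid region).
#'
#' @param obs A [phase_observation()] for which [phase_denovo()] returned
#'   mosaic.
#' @param min_support Passed through to [phase_denovo()] to identify the
#'   mutant haplotype.
#' @return Fraction of cells in (0, 1).
#' @export
estimate_mosaic_fraction <- function(obs, min_support = 2) {
  res <- phase_denovo(obs, min_support)
  if (!res$informative || !isTRUE(res$mosaic)) {
    stop("estimate_mosaic_fraction: observation is not a confirmed mosaic",
         call. = FALSE)
  }
  res$mosaic_frac
}

#' Select an informative inherited heterozygous variant near a de novo site
#'
#' Scans candidate variants within the window for one that is heterozygous
#' in the child and whose parental origin is resolvable, i.e. the alternate
#' allele is present in exactly one parent. Among eligible candidates the
#' nearest to the de novo site is returned (ties break upstream).
#'
#' @param dn_pos Position of the de novo variant.
#' @param candidates Data frame with columns `pos`, `child_gt`, `fa_gt`,
#'   `mo_gt` (alternate-allele dosages 0/1/2).
#' @param window Maximum distance in bp.
#' @return The selected candidate row, or `NULL` when none qualifies.
#' @export
select_informative_het <- function(dn_pos, candidates, window = 500) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  d <- abs(candidates$pos - dn_pos)
  ok <- d <= window & d > 0 &
    candidates$child_gt == 1 &
    xor(candidates$fa_gt > 0, candidates$mo_gt > 0)
  if (!any(ok)) return(NULL)
  eligible <- candidates[ok, , drop = FALSE]
  d <- d[ok]
  eligible <- eligible[order(d, eligible$pos), , drop = FALSE]
  out <- eligible[1, , drop = FALSE]
  out$parent_of_alt <- if (out$fa_gt > 0) "father" else "mother"
  out
}
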