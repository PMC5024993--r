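#' @importFrom GenomicRanges GRanges reduce intersect width start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
NULL

intervals_to_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(GenomicRanges::reduce(x))
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x <- x[x$end > x$start, , drop = FALSE]
  GenomicRanges::reduce(GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end)))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Regions at or above a depth threshold in a piecewise-constant track
#'
#' @param track Coverage track data frame (`chrom`, `start`, `end`,
#'   `depth`), 0-based half-open intervals.
#' @param threshold Minimum depth (reads).
#' @return Data frame of maximal merged intervals with depth at or above the
#'   threshold (`chrom`, `start`, `end`, 0-based half-open).
#' @export
regions_at_depth <- function(track, threshold = 40) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(track)),
            all(track$depth >= 0))
  granges_to_intervals(intervals_to_granges(
    track[track$depth >= threshold, , drop = FALSE]))
}

#' Joint high-coverage region of a trio within the capture target
#'
#' Four-way intersection of the child's, father's and mother's coverage
#' intervals with the capture region, merged, with total length. Mutation
#' rates are measured inside this region because only there does every trio
#' member have enough depth for a de novo call.
#'
#' @param child,father,mother Interval data frames (`chrom`, `start`, `end`)
#'   of per-member regions at the depth threshold.
#' @param capture Capture-target interval data frame.
#' @param family_id,child_id Optional identifiers carried through.
#' @return A list of class `joint_region` with `intervals` (merged interval
#'   data frame) and `total_length` (bp), plus any identifiers.
#' @export
joint_region <- function(child, father, mother, capture,
                         family_id = NA_character_, child_id = NA_character_) {
  gr <- Reduce(GenomicRanges::intersect,
               list(intervals_to_granges(child), intervals_to_granges(father),
                    intervals_to_granges(mother),
                    intervals_to_granges(capture)))
  gr <- GenomicRanges::reduce(gr)
  structure(list(intervals = granges_to_intervals(gr),
                 total_length = sum(GenomicRanges::width(gr)),
                 family_id = family_id, child_id = child_id),
            class = "joint_region")
}

positions_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  gr <- intervals_to_granges(intervals)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, gr)
}

#' Per-class mutation counts extrapolated from a joint region to the exome
#'
#' Counts calls falling inside the child's joint high-coverage region, by
#' classification label and functional class, then extrapolates linearly to
#' the full capture region: `count * capture_length / joint_length`.
#'
#' @param calls Classified call table for one child (columns `chrom`, `pos`,
#'   `label`, `functional_class`).
#' @param region A [joint_region()] for the child.
#' @param capture_length Length of the capture region (bp).
#' @param functional_classes Functional classes to tabulate in addition to
#'   `"all"`.
#' @return Data frame with one row per (label, functional class):
#'   `count_in_joint`, `joint_length`, `capture_length`,
#'   `extrapolated_count`; or `NULL` (with a warning) when the joint region
#'   is empty.
#' @export
mutation_rate <- function(calls, region, capture_length,
                          functional_classes = c("LGD", "missense", "synonymous")) {
  stopifnot(inherits(region, "joint_region"))
  if (region$total_length == 0) {
    warning("mutation_rate: empty joint region for child ", region$child_id,
            "; child excluded", call. = FALSE)
    return(NULL)
  }
  in_region <- positions_in_intervals(calls$chrom, calls$pos, region$intervals)
  grid <- expand.grid(label = c("mosaic", "germline_denovo"),
                      functional_class = c(functional_classes, "all"),
                      stringsAsFactors = FALSE)
  grid$count_in_joint <- mapply(function(lab, fc) {
    sel <- in_region & calls$label == lab
    if (fc != "all") sel <- sel & calls$functional_class == fc
    sum(sel)
  }, grid$label, grid$functional_class)
  grid$joint_length <- region$total_length
  grid$capture_length <- capture_length
  grid$extrapolated_count <- grid$count_in_joint * capture_length /
    region$total_length
  grid$family_id <- region$family_id
  grid$child_id <- region$child_id
  grid
}

#' Compare per-exome mutation rates between probands and siblings
#'
#' Reports per-group means with normal-approximation 95% confidence
#' intervals for the mean, and a one-sided p-value for enrichment in
#' probands from a permutation test over child labels. Small groups are
#' handled by exhaustive enumeration of all label assignments.
#'
#' @param proband,sibling Numeric vectors of per-child extrapolated counts.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation draw.
#' @param exhaustive_limit Enumerate all assignments exhaustively when the
#'   number of distinct assignments is at most this many.
#' @return A list with `mean_proband`, `mean_sibling`, `ci_proband`,
#'   `ci_sibling`, `difference` and `p_value`.
#' @export
compare_rates <- function(proband, sibling, n_perm = 10000, seed = 1,
                          exhaustive_limit = 50000) {
  stopifnot(length(proband) >= 2, length(sibling) >= 2)
  ci <- function(x) {
    m <- mean(x)
    half <- qnorm(0.975) * sd(x) / sqrt(length(x))
    c(m - half, m + half)
  }
  obs <- mean(proband) - mean(sibling)
  pooled <- c(proband, sibling)
  n_p <- length(proband)
  n_tot <- length(pooled)
  n_assign <- choose(n_tot, n_p)
  if (n_assign <= exhaustive_limit) {
    idx <- utils::combn(n_tot, n_p)
    stats <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(stats >= obs - 1e-12)
  } else {
    set.seed(seed)
    stats <- replicate(n_perm, {
      i <- sample.int(n_tot, n_p)
      mean(pooled[i]) - mean(pooled[-i])
    })
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
  }
  list(mean_proband = mean(proband), mean_sibling = mean(sibling),
       ci_proband = ci(proband), ci_sibling = ci(sibling),
       difference = obs, p_value = p)
}
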