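#' @importFrom methods as is new
#' @importFrom utils write.table read.table combn
NULL

#' Write a synthetic cohort as a multi-sample VCF
#'
#' Emits one VCF (v4.2) column per family member with per-sample GT, DP, AD
#' and PL fields; samples from other families are missing at sites private
#' to a family. Positions are 1-based as in the records.
#'
#' @param cohort A `synthetic_cohort` (or a list with `records` and
#'   `members`).
#' @param path Output path (`.vcf`).
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  records <- cohort$records
  members <- cohort$members
  samples <- members$member_id
  n_var <- nrow(records)
  n_smp <- length(samples)

  rr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(start = records$pos, width = nchar(records$ref)))
  names(rr) <- sprintf("var%06d", seq_len(n_var))

  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(records$ref),
    ALT = Biostrings::DNAStringSetList(as.list(records$alt)),
    QUAL = rep(NA_real_, n_var),
    FILTER = rep("PASS", n_var))

  gt <- matrix("./.", n_var, n_smp, dimnames = list(names(rr), samples))
  dp <- matrix(NA_integer_, n_var, n_smp, dimnames = list(names(rr), samples))
  ad <- matrix(list(NA_integer_), n_var, n_smp,
               dimnames = list(names(rr), samples))
  pl <- matrix(list(NA_integer_), n_var, n_smp,
               dimnames = list(names(rr), samples))

  gt_string <- c("0/0", "0/1", "1/1")
  for (role in names(MEMBER_ROLES)) {
    col_idx <- match(paste0(records$family_id, ".", role), samples)
    rows <- seq_len(n_var)
    dpv <- records[[paste0(role, "_dp")]]
    adv <- records[[paste0(role, "_ad")]]
    pls <- cbind(records[[paste0(role, "_pl0")]],
                 records[[paste0(role, "_pl1")]],
                 records[[paste0(role, "_pl2")]])
    dos <- dosage_from_pl(pls[, 1], pls[, 2], pls[, 3])
    idx <- cbind(rows, col_idx)
    gt[idx] <- gt_string[dos + 1L]
    dp[idx] <- dpv
    ad[idx] <- lapply(seq_len(n_var), function(i) c(dpv[i] - adv[i], adv[i]))
    pl[idx] <- lapply(seq_len(n_var), function(i) pls[i, ])
  }

  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "R", "G"),
    Type = c("String", "Integer", "Integer", "Integer"),
    Description = c("Genotype", "Read depth",
                    "Allelic depths (ref, alt)",
                    "Phred-scaled genotype likelihoods"),
    row.names = c("GT", "DP", "AD", "PL"))

  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(n_smp),
                                   row.names = samples),
    exptData = list(header = hdr),
    fixed = fixed,
    geno = S4Vectors::SimpleList(GT = gt, DP = dp, AD = ad, PL = pl))
  VariantAnnotation::writeVcf(vcf, path)
  # htslib requires ##fileformat to be the first header line
  lines <- readLines(path)
  ff <- grepl("^##fileformat=", lines)
  writeLines(c(lines[ff][1], lines[!ff]), path)
  invisible(path)
}

#' Read a multi-sample cohort VCF back into the records layout
#'
#' Inverse of [write_cohort_vcf()]: expects sample names of the form
#' `<family>.<fa|mo|p1|s1>` and per-sample DP/AD/PL fields.
#'
#' @param path VCF path.
#' @return A records data frame as produced by [generate_cohort()] (without
#'   the `functional_class` annotation column).
#' @export
read_cohort_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  records <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(alt), function(i) as.character(alt[[i]][1]),
                 character(1)),
    stringsAsFactors = FALSE)
  samples <- colnames(vcf)
  fam <- sub("\\.(fa|mo|p1|s1)$", "", samples)
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  pl <- VariantAnnotation::geno(vcf)$PL
  # at each site exactly one family has data
  present <- !is.na(dp)
  fam_of_var <- apply(present, 1, function(row) unique(fam[row])[1])
  records$family_id <- fam_of_var
  for (role in names(MEMBER_ROLES)) {
    col_idx <- match(paste0(records$family_id, ".", role), samples)
    idx <- cbind(seq_len(nrow(records)), col_idx)
    records[[paste0(role, "_dp")]] <- dp[idx]
    adv <- ad[idx]
    plv <- pl[idx]
    records[[paste0(role, "_ad")]] <- vapply(adv, function(x) as.integer(x[2]),
                                             integer(1))
    records[[paste0(role, "_pl0")]] <- vapply(plv, function(x) as.integer(x[1]),
                                              integer(1))
    records[[paste0(role, "_pl1")]] <- vapply(plv, function(x) as.integer(x[2]),
                                              integer(1))
    records[[paste0(role, "_pl2")]] <- vapply(plv, function(x) as.integer(x[3]),
                                              integer(1))
  }
  records
}

#' Write a coverage track as BedGraph
#'
#' @param track Data frame with `chrom`, `start`, `end`, `depth` (0-based
#'   half-open intervals).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(start = track$start + 1, end = track$end),
    score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BedGraph coverage track
#'
#' @param path BedGraph path.
#' @return Data frame with `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- sort(rtracklayer::import(path, format = "bedGraph"))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = gr$score,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file as an interval data frame
#'
#' @param path BED path.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  granges_to_intervals(rtracklayer::import(path, format = "bed"))
}

#' Write a tab-delimited table (truth sidecars, call tables, summaries)
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
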