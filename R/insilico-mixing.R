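#' Specification for in-silico read mixing and subsampling
#'
#' @param target_depth Reads per region after subsampling.
#' @param fraction_a Proportion of reads drawn from source A: a number in
#'   [0, 1], or `"random"` to draw a uniform fraction per region.
#' @param regions Character vector of region identifiers to mix.
#' @param seed Random seed.
#' @param pair_units Sample read pairs as units (both mates kept or
#'   dropped); set `FALSE` to sample single reads.
#' @return An object of class `mix_spec`.
#' @export
mix_spec <- function(target_depth, fraction_a = "random", regions,
                     seed = 1, pair_units = TRUE) {
  if (!is.numeric(target_depth) || target_depth <= 0) {
    stop("mix_spec: target_depth must be > 0", call. = FALSE)
  }
  if (is.numeric(fraction_a) && (fraction_a < 0 || fraction_a > 1)) {
    stop("mix_spec: fraction_a must lie in [0, 1]", call. = FALSE)
  }
  structure(list(target_depth = as.integer(target_depth),
                 fraction_a = fraction_a, regions = regions,
                 seed = seed, pair_units = isTRUE(pair_units)),
            class = "mix_spec")
}

sample_reads_from_source <- function(reads, n_wanted, pair_units) {
  if (n_wanted == 0) return(reads[0, , drop = FALSE])
  if (!pair_units || is.null(reads$pair_id)) {
    idx <- sample.int(nrow(reads), n_wanted)
    return(reads[idx, , drop = FALSE])
  }
  pairs <- sample(unique(reads$pair_id))
  sizes <- cumsum(table(reads$pair_id)[pairs])
  take <- pairs[seq_len(which(sizes >= n_wanted)[1])]
  reads[reads$pair_id %in% take, , drop = FALSE]
}

#' Mix two read collections and subsample to a target depth per region
#'
#' Per region, the number of reads drawn from source A is binomial with the
#' specified fraction so that the expected source-A proportion equals the
#' specification while the total equals the target depth; sampling is
#' without replacement within each source. With paired units the realized
#' depth can exceed the target by at most one read per source (a pair is
#' never split).
#'
#' @param reads_a,reads_b Read tables with columns `region`, `read_id` and
#'   optionally `pair_id` (defaulting to `read_id`).
#' @param spec A [mix_spec()].
#' @return A list with `reads` (mixed table, with a `source` column) and
#'   `realized` (per-region data frame of realized depth and source-A
#'   fraction).
#' @export
mix_and_subsample <- function(reads_a, reads_b, spec) {
  stopifnot(inherits(spec, "mix_spec"))
  set.seed(spec$seed)
  out <- vector("list", length(spec$regions))
  realized <- data.frame(region = spec$regions,
                         target_fraction_a = NA_real_,
                         depth = NA_integer_, fraction_a = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(spec$regions)) {
    reg <- spec$regions[i]
    a <- reads_a[reads_a$region == reg, , drop = FALSE]
    b <- reads_b[reads_b$region == reg, , drop = FALSE]
    frac <- if (identical(spec$fraction_a, "random")) runif(1) else spec$fraction_a
    n_a <- rbinom(1, spec$target_depth, frac)
    n_b <- spec$target_depth - n_a
    if (nrow(a) < n_a || nrow(b) < n_b) {
      stop("mix_and_subsample: insufficient source depth in region '", reg,
           "'", call. = FALSE)
    }
    sa <- sample_reads_from_source(a, n_a, spec$pair_units)
    sb <- sample_reads_from_source(b, n_b, spec$pair_units)
    if (nrow(sa)) sa$source <- "A"
    if (nrow(sb)) sb$source <- "B"
    mixed <- rbind(sa, sb)
    out[[i]] <- mixed
    realized$target_fraction_a[i] <- frac
    realized$depth[i] <- nrow(mixed)
    realized$fraction_a[i] <- if (nrow(mixed)) nrow(sa) / nrow(mixed) else NA_real_
  }
  list(reads = do.call(rbind, out), realized = realized)
}

#' Caller sensitivity by simulated allele-fraction bin
#'
#' Sensitivity (`TP / (TP + FN)`) for variants private to one mixture
#' source, stratified by the simulated allele fraction.
#'
#' @param called Character vector of called variant keys.
#' @param truth Data frame of source-private truth variants with columns
#'   `key` and `allele_fraction`.
#' @param bins Numeric vector of bin boundaries over [0, 1].
#' @return Data frame with one row per bin: `bin`, `n_truth`, `n_called`,
#'   `sensitivity`.
#' @export
evaluate_sensitivity <- function(called, truth,
                                 bins = seq(0, 0.5, by = 0.1)) {
  bin <- cut(truth$allele_fraction, breaks = bins, include.lowest = TRUE)
  found <- truth$key %in% called
  out <- data.frame(bin = levels(bin),
                    n_truth = as.vector(table(bin)),
                    n_called = as.vector(tapply(found, bin, sum,
                                                default = 0)),
                    stringsAsFactors = FALSE)
  out$n_called[is.na(out$n_called)] <- 0
  out$sensitivity <- ifelse(out$n_truth > 0, out$n_called / out$n_truth,
                            NA_real_)
  out
}
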