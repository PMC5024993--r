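# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and where possible the library
# calls) used by the package itself.

# exact lower-tail binomial CDF by direct summation of the probability mass
binom_lower_tail_oracle <- function(k, n, p) {
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Benjamini-Hochberg step-up q-values, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# two-sided exact binomial p-value, minimum-likelihood method, by direct
# summation (no stats::binom.test)
two_sided_binom_oracle <- function(x, n, p) {
  d <- exp(lchoose(n, 0:n) + (0:n) * log(p) + (n - (0:n)) * log1p(-p))
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# per-record application of all six de novo filters, one child at a time
find_denovo_oracle <- function(records, params) {
  gt_of <- function(pl) which.min(pl) - 1L
  carriers_at <- function(key) {
    total <- 0L
    for (i in seq_len(nrow(records))) {
      k <- paste(records$chrom[i], records$pos[i], records$ref[i],
                 records$alt[i], sep = ":")
      if (k != key) next
      for (m in c("fa", "mo", "p1", "s1")) {
        pl <- c(records[[paste0(m, "_pl0")]][i],
                records[[paste0(m, "_pl1")]][i],
                records[[paste0(m, "_pl2")]][i])
        if (gt_of(pl) > 0) total <- total + 1L
      }
    }
    total
  }
  hits <- list()
  for (i in seq_len(nrow(records))) {
    key <- paste(records$chrom[i], records$pos[i], records$ref[i],
                 records$alt[i], sep = ":")
    fa_pl <- c(records$fa_pl0[i], records$fa_pl1[i], records$fa_pl2[i])
    mo_pl <- c(records$mo_pl0[i], records$mo_pl1[i], records$mo_pl2[i])
    for (child in c("p1", "s1")) {
      ch_pl <- c(records[[paste0(child, "_pl0")]][i],
                 records[[paste0(child, "_pl1")]][i],
                 records[[paste0(child, "_pl2")]][i])
      pass <-
        gt_of(fa_pl) == 0 &&
        gt_of(mo_pl) == 0 &&
        gt_of(ch_pl) > 0 &&
        records[[paste0(child, "_dp")]][i] >= params$min_trio_depth &&
        records$fa_dp[i] >= params$min_trio_depth &&
        records$mo_dp[i] >= params$min_trio_depth &&
        records[[paste0(child, "_ad")]][i] >= params$min_child_alt_reads &&
        (ch_pl[1] - min(ch_pl[2], ch_pl[3])) >= params$min_child_presence_phred &&
        (min(fa_pl[2], fa_pl[3]) - fa_pl[1]) >= params$min_parent_absence_phred &&
        (min(mo_pl[2], mo_pl[3]) - mo_pl[1]) >= params$min_parent_absence_phred &&
        carriers_at(key) <= params$max_carriers_in_cohort
      if (pass) {
        hits[[length(hits) + 1L]] <- data.frame(
          pos = records$pos[i], family_id = records$family_id[i],
          child_id = paste0(records$family_id[i], ".", child),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(pos = integer(0), family_id = character(0),
                      child_id = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$family_id, out$child_id, out$pos), ]
}

# scalar restatement of the three-haplotype phasing rule
phase_rule_oracle <- function(aa, ar, ra, rr, min_support) {
  dn_with <- c(alt = aa, ref = ra)
  supported <- names(dn_with)[dn_with >= min_support]
  if (length(supported) != 1) {
    return(list(informative = FALSE, mosaic = NA))
  }
  without <- if (supported == "alt") ar else rr
  list(informative = TRUE, mosaic = without >= min_support)
}

# base-by-base depth thresholding over a small region
regions_at_depth_oracle <- function(track, threshold, region_end) {
  depth <- integer(region_end)
  for (i in seq_len(nrow(track))) {
    if (track$end[i] > track$start[i]) {
      depth[(track$start[i] + 1):track$end[i]] <- track$depth[i]
    }
  }
  above <- depth >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = rep("1", sum(r$values)), start = starts[r$values],
             end = ends[r$values])
}

# base-by-base membership intersection of interval sets
intersect_oracle <- function(sets, region_end) {
  member <- rep(TRUE, region_end)
  for (s in sets) {
    m <- rep(FALSE, region_end)
    for (i in seq_len(nrow(s))) {
      if (s$end[i] > s$start[i]) m[(s$start[i] + 1):s$end[i]] <- TRUE
    }
    member <- member & m
  }
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = rep("1", sum(r$values)), start = starts[r$values],
             end = ends[r$values])
}

# exhaustive enumeration of the recurrence null for tiny instances:
# probability-weighted count of genes hit >= 2, and P(count >= observed)
recurrence_enum_oracle <- function(n_hits, probs, observed) {
  n_genes <- length(probs)
  grids <- rep(list(seq_len(n_genes)), n_hits)
  assignments <- as.matrix(expand.grid(grids))
  expected <- 0
  p_ge <- 0
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    pr <- prod(probs[a])
    rec <- sum(tabulate(a, n_genes) >= 2)
    expected <- expected + pr * rec
    if (rec >= observed) p_ge <- p_ge + pr
  }
  list(expected = expected, p_ge = min(1, max(0, p_ge)))
}

# exhaustive label-permutation distribution of the rank-sum statistic
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(n, nx)
  stats <- apply(combos, 2, function(i) sum(rank(pooled)[i]))
  mu <- mean(stats)
  # two-sided: as extreme in either direction
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# independent group-by tabulation for validation summaries
validation_summary_oracle <- function(outcomes) {
  keys <- unique(outcomes[, c("stage", "predicted_label", "assay")])
  keys <- keys[order(keys$stage, keys$predicted_label, keys$assay), ]
  res <- list()
  for (i in seq_len(nrow(keys))) {
    g <- outcomes
    for (col in c("stage", "predicted_label", "assay")) {
      g <- g[g[[col]] == keys[[col]][i], ]
    }
    res[[i]] <- c(chosen = nrow(g),
                  success = sum(g$assay_success),
                  present = sum(g$variant_present & g$assay_success),
                  confirmed = sum(g$informative &
                                    g$observed_label == g$predicted_label))
  }
  cbind(keys, do.call(rbind, res))
}
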