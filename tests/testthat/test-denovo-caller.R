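# a single-family record with explicit counts; likelihoods are regenerated
# from the counts via the package's symmetric error model
make_record <- function(fa = c(60, 0), mo = c(60, 0), p1 = c(60, 28),
                        s1 = c(60, 0), pos = 1000L, family = "fam00001") {
  rec <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "G",
                    family_id = family, functional_class = "missense",
                    stringsAsFactors = FALSE)
  for (m in c("fa", "mo", "p1", "s1")) {
    cnt <- get(m)
    pl <- quadmosaic:::pl_from_counts(cnt[1], cnt[2])
    rec[[paste0(m, "_dp")]] <- cnt[1]
    rec[[paste0(m, "_ad")]] <- cnt[2]
    rec[[paste0(m, "_pl0")]] <- pl[, "pl0"]
    rec[[paste0(m, "_pl1")]] <- pl[, "pl1"]
    rec[[paste0(m, "_pl2")]] <- pl[, "pl2"]
  }
  rec
}

test_that("clean de novo records are called and boundary filters hold", {
  rec <- make_record()
  calls <- find_denovo(rec)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$child_id, "fam00001.p1")
  expect_equal(calls$aarf, 28 / 60)

  # child depth below the trio minimum: no call
  expect_equal(nrow(find_denovo(make_record(p1 = c(19, 9)))), 0)
  # a parent below the trio minimum: no call
  expect_equal(nrow(find_denovo(make_record(fa = c(19, 0)))), 0)
  # no alternate reads in the child: no call
  expect_equal(nrow(find_denovo(make_record(p1 = c(60, 0)))), 0)
  # fewer than the minimum alternate reads: no call even with forced PLs
  rec2 <- make_record()
  rec2$p1_ad <- 2
  expect_equal(nrow(find_denovo(rec2)), 0)
  # allele present in a parent genotype: no call
  expect_equal(nrow(find_denovo(make_record(mo = c(60, 30)))), 0)
})

test_that("carrier counting across families enforces the cohort maximum", {
  # same allele de novo in three families: 3 carriers > 2, all suppressed
  recs <- rbind(make_record(family = "fam00001"),
                make_record(family = "fam00002"),
                make_record(family = "fam00003"))
  expect_equal(nrow(find_denovo(recs)), 0)
  # two carriers are allowed
  recs2 <- rbind(make_record(family = "fam00001"),
                 make_record(family = "fam00002"))
  expect_equal(nrow(find_denovo(recs2)), 2)
  # an inherited het elsewhere in the cohort at the same allele adds two
  # carriers (parent + child), pushing the count over the maximum
  recs3 <- rbind(make_record(family = "fam00001"),
                 make_record(family = "fam00002", fa = c(60, 30),
                             p1 = c(60, 31)))
  expect_equal(nrow(find_denovo(recs3)), 0)
})

test_that("missing per-member fields raise an error naming the site", {
  rec <- make_record(pos = 4242L)
  rec$mo_pl1 <- NULL
  expect_error(find_denovo(rec), "mo_pl1")
  rec2 <- make_record(pos = 4242L)
  rec2$fa_dp <- NA_integer_
  expect_error(find_denovo(rec2), "4242")
})

test_that("find_denovo matches the six-filter brute-force oracle on a synthetic cohort", {
  cfg <- cohort_config(n_families = 50, seed = 31, mosaic_rate = 0.3)
  sim <- generate_cohort(cfg)
  params <- caller_params()
  calls <- find_denovo(sim$records, params)
  oracle <- find_denovo_oracle(sim$records, params)
  expect_equal(nrow(calls), nrow(oracle))
  expect_equal(calls$pos, oracle$pos)
  expect_equal(calls$child_id, oracle$child_id)
})

test_that("calling is monotone in thresholds and independent of record order", {
  cfg <- cohort_config(n_families = 40, seed = 17, mosaic_rate = 0.3)
  sim <- generate_cohort(cfg)
  base <- find_denovo(sim$records)
  key <- function(x) sort(paste(x$pos, x$child_id))
  for (stricter in list(caller_params(min_trio_depth = 40),
                        caller_params(min_child_alt_reads = 8),
                        caller_params(min_child_presence_phred = 60),
                        caller_params(min_parent_absence_phred = 60),
                        caller_params(max_carriers_in_cohort = 1))) {
    expect_true(all(key(find_denovo(sim$records, stricter)) %in% key(base)))
  }
  shuffled <- sim$records[sample.int(nrow(sim$records)), ]
  expect_identical(key(find_denovo(shuffled)), key(base))
})

test_that("planted germline de novo variants are recovered and inherited hets never called", {
  cfg <- cohort_config(n_families = 80, seed = 23)
  sim <- generate_cohort(cfg)
  calls <- find_denovo(sim$records)
  key_calls <- paste(calls$family_id, calls$pos, calls$child_id)
  tr <- sim$truth
  key_truth <- paste(tr$family_id, tr$pos, tr$carrier_id)
  # no inherited het is ever called de novo
  het_keys <- key_truth[tr$truth_class == "inherited_het"]
  expect_length(intersect(key_calls, het_keys), 0)
  # sensitivity for germline de novo variants at adequate depth is complete
  germ <- tr[tr$truth_class == "germline_denovo", ]
  rec <- merge(germ, sim$records, by = c("family_id", "pos"))
  child <- ifelse(grepl("p1$", rec$carrier_id), "p1", "s1")
  dp_ok <- rec$fa_dp >= 40 & rec$mo_dp >= 40 &
    ifelse(child == "p1", rec$p1_dp, rec$s1_dp) >= 40
  deep_keys <- paste(rec$family_id, rec$pos, rec$carrier_id)[dp_ok]
  expect_gt(length(deep_keys), 50)
  expect_true(all(deep_keys %in% key_calls))
})

test_that("family exclusion removes whole families over the call threshold", {
  calls <- data.frame(
    chrom = "1", pos = 1:14, ref = "A", alt = "G",
    family_id = c(rep("famA", 12), "famB", "famB"),
    child_id = c(rep("famA.p1", 11), "famA.s1", "famB.p1", "famB.s1"),
    stringsAsFactors = FALSE)
  res <- exclude_families(calls, threshold = 10)
  # famA.p1 has 11 > 10 calls: the sibling's calls go too
  expect_equal(res$excluded_families, "famA")
  expect_setequal(unique(res$calls$family_id), "famB")
  # at the threshold exactly, nothing is removed
  res10 <- exclude_families(calls[calls$family_id == "famB", ], threshold = 10)
  expect_equal(nrow(res10$calls), 2)
  expect_length(res10$excluded_families, 0)
})

test_that("family exclusion equals a count-then-filter oracle on random tables", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 200
    calls <- data.frame(
      chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
      family_id = sample(sprintf("fam%02d", 1:12), n, replace = TRUE),
      stringsAsFactors = FALSE)
    calls$child_id <- paste0(calls$family_id, ".",
                             sample(c("p1", "s1"), n, replace = TRUE))
    thr <- sample(5:12, 1)
    res <- exclude_families(calls, thr)
    counts <- table(calls$child_id)
    bad_fams <- unique(sub("\\..*", "", names(counts)[counts > thr]))
    expect_setequal(res$excluded_families, bad_fams)
    expect_equal(nrow(res$calls), sum(!calls$family_id %in% bad_fams))
  }
})

test_that("confirmation-set intersection keeps union members only", {
  calls <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                      family_id = "famA",
                      child_id = paste0("famA.", c("p1", "p1", "s1", "s1")),
                      stringsAsFactors = FALSE)
  set1 <- calls[1, c("chrom", "pos", "ref", "alt", "child_id")]
  set2 <- calls[3, c("chrom", "pos", "ref", "alt", "child_id")]
  kept <- intersect_confirmation(calls, list(set1, set2))
  expect_equal(kept$pos, c(1, 3))
  # present in exactly one set is enough
  expect_equal(intersect_confirmation(calls, list(set1))$pos, 1)
  # empty confirmation sets leave nothing
  expect_equal(nrow(intersect_confirmation(calls, list())), 0)
})

test_that("reference-allele balance is the ref fraction with guarded input", {
  expect_equal(abhet(10, 20), 0.5)
  expect_equal(abhet(20, 20), 1.0)
  expect_equal(abhet(13, 40), 0.325)
  expect_error(abhet(1, 0), "total_reads")
  expect_error(abhet(5, 4), "ref_reads")
})
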