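test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_families = 20, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_families = 20, seed = 102))
  expect_false(identical(a$records, c$records))
})

test_that("configuration validation rejects invalid values", {
  expect_error(cohort_config(depth_mean = -1), "depth_mean")
  expect_error(cohort_config(reference_bias = 0.6), "reference_bias")
  expect_error(cohort_config(mosaic_rate = -0.1), "rates")
  expect_error(cohort_config(depth_mean = NaN), "finite")
  expect_error(
    cohort_config(cell_fraction_distribution = function(n) rep(1.5, n)),
    "cell_fraction")
})

test_that("truth labels respect the planted-variant invariants", {
  cfg <- cohort_config(n_families = 200, seed = 7)
  sim <- generate_cohort(cfg)
  tr <- sim$truth
  expect_true(all(tr$cell_fraction[tr$truth_class == "mosaic"] < 1))
  expect_true(all(tr$cell_fraction[tr$truth_class == "germline_denovo"] == 1))
  expect_true(all(tr$cell_fraction > 0 & tr$cell_fraction <= 1))
  # no site is planted twice within a family (so no mosaic is ever shared
  # between a sibling pair)
  expect_false(anyDuplicated(paste(tr$family_id, tr$pos)) > 0)
  # every de novo variant has a linked inherited het within the window
  dn <- tr[tr$truth_class != "inherited_het", ]
  het_key <- paste(tr$family_id, tr$pos)[tr$truth_class == "inherited_het"]
  linked <- tr[!is.na(tr$linked_to_pos), ]
  expect_true(all(paste(dn$family_id, dn$pos) %in%
                    paste(linked$family_id, linked$linked_to_pos)))
  expect_true(all(abs(linked$pos - linked$linked_to_pos) <=
                    cfg$phasing_window + 5))
  # read-count sanity over every member
  for (m in c("fa", "mo", "p1", "s1")) {
    expect_true(all(sim$records[[paste0(m, "_ad")]] <=
                      sim$records[[paste0(m, "_dp")]]))
    pls <- as.matrix(sim$records[paste0(m, c("_pl0", "_pl1", "_pl2"))])
    expect_true(all(pls >= 0))
    expect_true(all(apply(pls, 1, min) == 0))
  }
})

test_that("zero planted rates leave only inherited hets", {
  cfg <- cohort_config(n_families = 30, mosaic_rate = 0,
                       germline_denovo_rate = 0,
                       contributory_mosaic_rate = 0,
                       contributory_germline_rate = 0, seed = 3)
  sim <- generate_cohort(cfg)
  expect_setequal(unique(sim$truth$truth_class), "inherited_het")
})

test_that("mean AARF of full-fraction de novo variants matches the analytic value", {
  # with cell fraction 1 the carrier child draws alt reads at
  # 0.5 * (1 - reference_bias); the mean AARF over many planted variants
  # must agree with that analytic mean within Monte-Carlo error
  bias <- 0.05
  cfg <- cohort_config(n_families = 800, germline_denovo_rate = 3,
                       mosaic_rate = 0, contributory_mosaic_rate = 0,
                       contributory_germline_rate = 0,
                       background_het_rate = 0, inherited_het_density = 1,
                       reference_bias = bias, seed = 11)
  sim <- generate_cohort(cfg)
  dn <- sim$truth[sim$truth$truth_class == "germline_denovo", ]
  rec <- merge(dn, sim$records, by = c("family_id", "pos"))
  child <- substr(rec$carrier_id, nchar(rec$carrier_id) - 1, 1e6)
  ad <- ifelse(child == "p1", rec$p1_ad, rec$s1_ad)
  dp <- ifelse(child == "p1", rec$p1_dp, rec$s1_dp)
  aarf <- ad / dp
  expect_gt(length(aarf), 2000)
  se <- sd(aarf) / sqrt(length(aarf))
  expect_lt(abs(mean(aarf) - 0.5 * (1 - bias)), 4 * se + 1e-3)
})

test_that("planted counts per child are Poisson-consistent with the configured rates", {
  cfg <- cohort_config(n_families = 1000, germline_denovo_rate = 1,
                       mosaic_rate = 0.06, contributory_mosaic_rate = 0,
                       contributory_germline_rate = 0, seed = 5)
  sim <- generate_cohort(cfg)
  dn <- sim$truth[sim$truth$truth_class == "germline_denovo", ]
  counts <- table(factor(dn$carrier_id,
                         levels = paste0(rep(unique(sim$members$family_id),
                                             each = 2), ".",
                                         c("p1", "s1"))))
  # chi-square goodness of fit against Poisson(1), binning the tail
  breaks <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(as.vector(counts), breaks))
  expected_p <- c(dpois(0:2, 1), 1 - ppois(2, 1))
  chi <- sum((as.vector(obs) - 2000 * expected_p)^2 / (2000 * expected_p))
  expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("mosaic AARFs are stochastically below germline de novo AARFs", {
  cfg <- cohort_config(n_families = 400, seed = 13, mosaic_rate = 0.5)
  sim <- generate_cohort(cfg)
  rec <- merge(sim$truth, sim$records, by = c("family_id", "pos"))
  child <- substr(rec$carrier_id, nchar(rec$carrier_id) - 1, 1e6)
  ad <- ifelse(child == "p1", rec$p1_ad, rec$s1_ad)
  dp <- pmax(1, ifelse(child == "p1", rec$p1_dp, rec$s1_dp))
  aarf <- ad / dp
  mos <- aarf[rec$truth_class == "mosaic"]
  germ <- aarf[rec$truth_class == "germline_denovo"]
  expect_gt(length(mos), 100)
  expect_lt(median(mos), median(germ))
  expect_lt(wilcox.test(mos, germ, alternative = "less")$p.value, 1e-6)
})

test_that("phasing read sets reflect cell fraction and co-segregation", {
  cfg <- cohort_config(n_families = 2, seed = 21)
  truth <- data.frame(
    family_id = "fam00001", carrier_id = "fam00001.p1", child_role = "proband",
    chrom = "1", pos = c(5000L, 5200L), ref = "A", alt = "T",
    truth_class = c("mosaic", "inherited_het"), cell_fraction = c(0.5, 1),
    parental_haplotype = c("paternal", "paternal"),
    functional_class = "missense", linked_to_pos = c(NA, 5000L),
    stringsAsFactors = FALSE)
  # mosaic at cell fraction 0.5: about half the mutant-haplotype reads carry
  # the de novo allele (binomial around 0.5)
  reads <- generate_phasing_reads(truth[1, ], truth, cfg, depth = 4000,
                                  seed = 1)
  mut <- reads[reads$haplotype == "mut", ]
  frac <- mean(mut$dn_allele == "alt")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(mut)) + 0.01)
  # germline with zero error: perfect co-segregation, no (mutant-background,
  # dn-ref) reads
  cfg0 <- cohort_config(n_families = 2, seed = 21, error_rate = 1e-12)
  truth$truth_class[1] <- "germline_denovo"
  truth$cell_fraction[1] <- 1
  reads0 <- generate_phasing_reads(truth[1, ], truth, cfg0, depth = 500,
                                   seed = 2)
  mut0 <- reads0[reads0$haplotype == "mut", ]
  expect_true(all(mut0$dn_allele == "alt"))
  # cell fraction -> 0 limit: de novo alt reads absent
  truth$truth_class[1] <- "mosaic"
  truth$cell_fraction[1] <- 1e-9
  reads_null <- generate_phasing_reads(truth[1, ], truth, cfg0, depth = 500,
                                       seed = 3)
  expect_true(all(reads_null$dn_allele == "ref"))
})

test_that("coverage tracks are piecewise-constant, deterministic and tile the capture", {
  cfg <- cohort_config(n_families = 2, capture_length = 1e5, seed = 9)
  tracks <- generate_coverage_tracks(1, cfg, segment_length = 1000)
  expect_named(tracks, c("fa", "mo", "p1", "s1"))
  t1 <- tracks$fa
  expect_equal(t1$start[1], 0)
  expect_equal(t1$end[nrow(t1)], 1e5)
  expect_true(all(t1$start[-1] == t1$end[-nrow(t1)]))
  expect_identical(tracks, generate_coverage_tracks(1, cfg,
                                                    segment_length = 1000))
  expect_false(identical(tracks$fa$depth,
                         generate_coverage_tracks(2, cfg,
                                                  segment_length = 1000)$fa$depth))
})
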