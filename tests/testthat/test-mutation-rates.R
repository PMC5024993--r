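test_that("depth thresholding matches a base-wise oracle", {
  # constant depth above threshold: whole region
  uniform <- data.frame(chrom = "1", start = 0, end = 1000, depth = 94.6)
  expect_equal(regions_at_depth(uniform, 40),
               data.frame(chrom = "1", start = 0, end = 1000))
  # constant depth below: nothing
  low <- data.frame(chrom = "1", start = 0, end = 1000, depth = 30)
  expect_equal(nrow(regions_at_depth(low, 40)), 0)
  # alternating segments keep only the high ones
  alt <- data.frame(chrom = "1", start = seq(0, 900, 100),
                    end = seq(100, 1000, 100), depth = rep(c(30, 50), 5))
  got <- regions_at_depth(alt, 40)
  expect_equal(got$start, seq(100, 900, 200))
  # random tracks against the brute-force scan
  set.seed(4)
  for (rep in 1:20) {
    n_seg <- 30
    bounds <- sort(sample(0:300, n_seg + 1))
    track <- data.frame(chrom = "1", start = bounds[-(n_seg + 1)],
                        end = bounds[-1], depth = rpois(n_seg, 45))
    thr <- sample(30:60, 1)
    got <- regions_at_depth(track, thr)
    want <- regions_at_depth_oracle(track, thr, 300)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("joint regions are four-way intersections with correct lengths", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(chrom = "1", start = m[, 1], end = m[, 2])
  }
  cap <- iv(0, 1000)
  # identical inputs: identity
  same <- joint_region(iv(100, 400), iv(100, 400), iv(100, 400), cap)
  expect_equal(same$intervals$start, 100)
  expect_equal(same$total_length, 300)
  # disjoint inputs: empty
  disj <- joint_region(iv(0, 100), iv(200, 300), iv(400, 500), cap)
  expect_equal(disj$total_length, 0)
  # random sets versus a base-wise membership oracle, plus commutativity
  set.seed(6)
  rand_set <- function() {
    b <- sort(sample(0:500, 8))
    data.frame(chrom = "1", start = b[c(1, 3, 5, 7)], end = b[c(2, 4, 6, 8)])
  }
  for (rep in 1:20) {
    a <- rand_set(); b <- rand_set(); c <- rand_set(); k <- rand_set()
    got <- joint_region(a, b, c, k)
    want <- intersect_oracle(list(a, b, c, k), 500)
    expect_equal(got$intervals$start, want$start)
    expect_equal(got$intervals$end, want$end)
    expect_equal(got$total_length, sum(want$end - want$start))
    perm <- joint_region(c, a, b, k)
    expect_equal(perm$intervals, got$intervals)
    # result always lies within the capture set
    in_cap <- intersect_oracle(list(got$intervals, k), 500)
    expect_equal(sum(in_cap$end - in_cap$start), got$total_length)
  }
})

test_that("rate extrapolation is linear arithmetic with empty-region guard", {
  region <- structure(list(
    intervals = data.frame(chrom = "1", start = 0, end = 30e6),
    total_length = 30e6, family_id = "famA", child_id = "famA.p1"),
    class = "joint_region")
  calls <- data.frame(chrom = "1", pos = c(5e6, 10e6), label = "mosaic",
                      functional_class = c("LGD", "missense"),
                      stringsAsFactors = FALSE)
  rates <- mutation_rate(calls, region, capture_length = 60e6)
  all_mosaic <- rates[rates$label == "mosaic" & rates$functional_class == "all", ]
  expect_equal(all_mosaic$count_in_joint, 2)
  expect_equal(all_mosaic$extrapolated_count, 4.0)
  # no calls: zero everywhere
  none <- mutation_rate(calls[0, ], region, 60e6)
  expect_true(all(none$extrapolated_count == 0))
  # doubling in-joint counts doubles the extrapolation
  rates2 <- mutation_rate(rbind(calls, transform(calls, pos = pos + 1)),
                          region, 60e6)
  expect_equal(rates2$extrapolated_count, 2 * rates$extrapolated_count)
  # empty joint region: child excluded with a warning
  empty <- structure(list(intervals = region$intervals[0, ], total_length = 0,
                          family_id = "famA", child_id = "famA.p1"),
                     class = "joint_region")
  expect_warning(res <- mutation_rate(calls, empty, 60e6), "excluded")
  expect_null(res)
})

test_that("extrapolated counts are unbiased for the planted per-exome rate", {
  # uniform mutation placement over the capture; each child has a random
  # joint region covering ~60% of it
  set.seed(44)
  capture_length <- 1e6
  rate <- 4
  n_children <- 1000
  est <- vapply(seq_len(n_children), function(i) {
    bounds <- sort(sample(seq(0, capture_length, 1e4), 8))
    region_df <- data.frame(chrom = "1", start = bounds[c(1, 3, 5, 7)],
                            end = bounds[c(2, 4, 6, 8)])
    jl <- sum(region_df$end - region_df$start)
    if (jl == 0) return(NA_real_)
    region <- structure(list(intervals = region_df, total_length = jl,
                             family_id = "f", child_id = "c"),
                        class = "joint_region")
    n_mut <- rpois(1, rate)
    calls <- data.frame(chrom = rep("1", n_mut),
                        pos = sample.int(capture_length, n_mut),
                        label = rep("mosaic", n_mut),
                        functional_class = rep("missense", n_mut),
                        stringsAsFactors = FALSE)
    r <- mutation_rate(calls, region, capture_length)
    r$extrapolated_count[r$label == "mosaic" & r$functional_class == "all"]
  }, numeric(1))
  est <- est[!is.na(est)]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rate), 2 * se + 0.02)
})

test_that("rate comparison is exchangeable for identical groups and exact for small n", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  res <- compare_rates(x, x)
  expect_equal(res$difference, 0)
  expect_gt(res$p_value, 0.3)
  expect_lt(res$p_value, 0.7)
  expect_equal(res$mean_proband, res$mean_sibling)

  # exact enumeration on a tiny instance: all proband values exceed all
  # sibling values, p = 1 / choose(8, 4)
  pro <- c(10, 11, 12, 13)
  sib <- c(1, 2, 3, 4)
  res2 <- compare_rates(pro, sib)
  expect_equal(res2$p_value, 1 / choose(8, 4))

  # a clear planted shift is detected at moderate n
  set.seed(10)
  pro3 <- rpois(200, 6)
  sib3 <- rpois(200, 4)
  expect_lt(compare_rates(pro3, sib3, seed = 2)$p_value, 0.01)
})

test_that("proband enrichment is detected on a contributory synthetic cohort", {
  cfg <- cohort_config(n_families = 1000, seed = 61,
                       contributory_mosaic_rate = 0.051,
                       contributory_germline_rate = 0.056)
  sim <- generate_cohort(cfg)
  calls <- find_denovo(sim$records)
  classified <- classify_mosaic(calls)
  rates <- quadmosaic:::cohort_mutation_rates(sim, classified)
  test_one <- function(lab) {
    sub <- rates[rates$label == lab & rates$functional_class == "all", ]
    compare_rates(sub$extrapolated_count[sub$role == "proband"],
                  sub$extrapolated_count[sub$role == "sibling"], seed = 1)
  }
  # the planted mosaic excess (0.051 over a 0.06 baseline) is a large
  # relative effect and must be detected; the germline excess (0.056 over
  # 1.0) is a small relative effect with modest power at this cohort size,
  # so only the direction of its group means is checked
  expect_lt(test_one("mosaic")$p_value, 0.05)
  germ <- test_one("germline_denovo")
  expect_gt(germ$difference, 0)
})

test_that("the aligned-grid rate path agrees with the general interval route", {
  cfg <- cohort_config(n_families = 4, capture_length = 2e6, seed = 71,
                       mosaic_rate = 0.5, germline_denovo_rate = 3)
  sim <- generate_cohort(cfg)
  classified <- classify_mosaic(find_denovo(sim$records))
  fast <- quadmosaic:::cohort_mutation_rates(sim, classified,
                                             segment_length = 1e4)
  capture <- data.frame(chrom = "1", start = 0, end = cfg$capture_length)
  for (i in 1:4) {
    fam <- sprintf("fam%05d", i)
    tracks <- generate_coverage_tracks(i, cfg, segment_length = 1e4)
    regions <- lapply(tracks, regions_at_depth, threshold = 40)
    for (child in c("p1", "s1")) {
      child_id <- paste0(fam, ".", child)
      jr <- joint_region(regions[[child]], regions$fa, regions$mo, capture,
                         family_id = fam, child_id = child_id)
      slow <- mutation_rate(
        classified[classified$child_id == child_id, , drop = FALSE],
        jr, cfg$capture_length)
      f <- fast[fast$child_id == child_id, ]
      expect_equal(f$joint_length[1], jr$total_length)
      expect_equal(f$count_in_joint[order(f$label, f$functional_class)],
                   slow$count_in_joint[order(slow$label,
                                             slow$functional_class)])
    }
  }
})
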