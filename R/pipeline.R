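PIPELINE_SECTIONS <- c("cohort", "caller", "classifier", "phasing", "rates",
                       "contribution", "seed", "out_dir", "write_vcf",
                       "verbose")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file with the same structure)
#' with per-stage sections mirroring each stage's parameter constructor:
#' `cohort` ([cohort_config()] arguments), `caller` ([caller_params()]),
#' `classifier` ([classifier_params()]), `phasing` (`min_support`,
#' `min_base_quality`), `rates` (`depth_threshold`, `segment_length`),
#' `contribution` (`n_perm`, `prior`), plus a global `seed`, an `out_dir`
#' and flags `write_vcf` and `verbose`. Unknown keys, at the top level or
#' inside a section, are an error before any stage runs. All stage
#' randomness derives from the global seed via fixed per-stage offsets.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated configuration with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("run_pipeline: reading YAML configurations requires the 'yaml' package",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_SECTIONS)
  if (length(unknown)) {
    stop("run_pipeline: unknown config keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_section <- function(section, allowed) {
    extra <- setdiff(names(config[[section]]), allowed)
    if (length(extra)) {
      stop("run_pipeline: unknown keys in '", section, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_section("cohort", names(formals(cohort_config)))
  check_section("caller", names(formals(caller_params)))
  check_section("classifier", names(formals(classifier_params)))
  check_section("phasing", c("min_support", "min_base_quality"))
  check_section("rates", c("depth_threshold", "segment_length"))
  check_section("contribution", c("n_perm", "prior"))
  defaults <- list(seed = 1L, out_dir = NULL, write_vcf = FALSE,
                   verbose = TRUE,
                   phasing = list(min_support = 2, min_base_quality = 20),
                   rates = list(depth_threshold = 40, segment_length = 1e5),
                   contribution = list(n_perm = 10000, prior = "uniform"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      config[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    }
  }
  config
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order: simulate a quad-family cohort,
#' call de novo variants and exclude artifact families, classify calls as
#' mosaic or germline, phase calls against linked inherited heterozygous
#' variants, measure per-exome mutation rates inside joint high-coverage
#' regions, and fit the misclassification-aware contribution model using
#' phasing-derived error rates. When `out_dir` is set, every table is
#' written as a tab-delimited file and a manifest with md5 checksums and a
#' parameter echo accompanies the outputs; identical configurations yield
#' identical tables.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_run_config()].
#' @return A list of class `pipeline_result` with the stage outputs
#'   (`cohort`, `calls`, `excluded_families`, `classified`, `phasing`,
#'   `rates`, `rate_comparison`, `error_counts`, `contribution`,
#'   `summary`) and a `manifest` data frame when files were written.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  say <- function(...) if (isTRUE(config$verbose)) message(...)

  cohort_args <- config$cohort
  cohort_args$seed <- config$seed
  cohort <- do.call(cohort_config, cohort_args)

  say("simulate: generating ", cohort$n_families, " quad families")
  sim <- generate_cohort(cohort)

  say("call-denovo: applying trio filters")
  params <- do.call(caller_params, as.list(config$caller))
  calls <- find_denovo(sim$records, params)
  excl <- exclude_families(calls, params$family_exclusion_threshold)
  calls <- excl$calls

  say("classify-mosaic: binomial test + BH over ", nrow(calls), " calls")
  cparams <- do.call(classifier_params, as.list(config$classifier))
  classified <- classify_mosaic(calls, cparams)

  say("phase-mosaic: read-backed phasing of de novo calls")
  phasing <- phase_pipeline_calls(classified, sim,
                                  min_support = config$phasing$min_support,
                                  min_base_quality = config$phasing$min_base_quality)
  error_counts <- phasing_error_counts(classified, phasing)

  say("rates: joint ", config$rates$depth_threshold, "x regions and extrapolation")
  rates <- cohort_mutation_rates(sim, classified,
                                 depth_threshold = config$rates$depth_threshold,
                                 segment_length = config$rates$segment_length)
  rate_comparison <- lapply(stats::setNames(nm = c("mosaic", "germline_denovo")),
                            function(lab) {
    sub <- rates[rates$label == lab & rates$functional_class == "all", ]
    compare_rates(sub$extrapolated_count[sub$role == "proband"],
                  sub$extrapolated_count[sub$role == "sibling"],
                  seed = config$seed + 3L)
  })

  contribution <- NULL
  if (all(error_counts$informative > 0)) {
    say("contribution: solving the misclassification-aware model")
    obs <- observed_rates(
      proband_mosaic = rate_comparison$mosaic$mean_proband,
      proband_germline = rate_comparison$germline_denovo$mean_proband,
      sibling_mosaic = rate_comparison$mosaic$mean_sibling,
      sibling_germline = rate_comparison$germline_denovo$mean_sibling)
    contribution <- contribution_model(
      obs, classification_errors(error_counts),
      n_perm = config$contribution$n_perm,
      seed = config$seed + 4L,
      prior = config$contribution$prior)
  } else {
    warning("run_pipeline: some phasing error cells have no informative ",
            "calls; contribution stage skipped", call. = FALSE)
  }

  summary <- callset_summary(classified)
  result <- list(cohort = sim, calls = calls,
                 excluded_families = excl$excluded_families,
                 classified = classified, phasing = phasing,
                 rates = rates, rate_comparison = rate_comparison,
                 error_counts = error_counts, contribution = contribution,
                 summary = summary, config = config, manifest = NULL)
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pipeline result: %d de novo calls in final callset, %d mosaic (%.1f%%)\n",
              s$n_total, s$n_mosaic, s$mosaic_fraction_pct))
  if (!is.null(x$contribution)) print(x$contribution)
  invisible(x)
}

# phase every call that corresponds to a planted de novo variant; calls
# without a planted counterpart (or without a linked het) are uninformative
phase_pipeline_calls <- function(classified, sim, min_support = 2,
                                 min_base_quality = 20) {
  truth_dn <- sim$truth[sim$truth$truth_class %in%
                          c("mosaic", "germline_denovo"), , drop = FALSE]
  key_truth <- paste(truth_dn$family_id, truth_dn$pos, truth_dn$ref,
                     truth_dn$alt, truth_dn$carrier_id, sep = ":")
  key_calls <- paste(classified$family_id, classified$pos, classified$ref,
                     classified$alt, classified$child_id, sep = ":")
  idx <- match(key_calls, key_truth)
  out <- classified[, c("chrom", "pos", "ref", "alt", "family_id", "child_id",
                        "child_role", "label")]
  out$informative <- FALSE
  out$phase_mosaic <- NA
  out$mosaic_frac <- NA_real_
  out$parent <- "undetermined"
  for (i in which(!is.na(idx))) {
    variant <- truth_dn[idx[i], , drop = FALSE]
    reads <- generate_phasing_reads(variant, sim$truth, sim$config)
    obs <- count_phase_configurations(reads,
                                      min_base_quality = min_base_quality)
    res <- phase_denovo(obs, min_support = min_support)
    out$informative[i] <- res$informative
    out$phase_mosaic[i] <- if (res$informative) res$mosaic else NA
    out$mosaic_frac[i] <- res$mosaic_frac
    out$parent[i] <- res$parent
  }
  out
}

# per-cohort, per-classified-class misclassification counts from phasing
phasing_error_counts <- function(classified, phasing) {
  grid <- expand.grid(cohort = c("proband", "sibling"),
                      class = c("mosaic", "germline"),
                      stringsAsFactors = FALSE)
  final <- classified$in_final_callset
  grid$misclassified <- NA_integer_
  grid$informative <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    lab <- if (grid$class[i] == "mosaic") "mosaic" else "germline_denovo"
    sel <- phasing$informative & final &
      phasing$child_role == grid$cohort[i] & classified$label == lab
    verdict_mosaic <- phasing$phase_mosaic[sel]
    grid$informative[i] <- sum(sel)
    grid$misclassified[i] <- if (lab == "mosaic") {
      sum(!verdict_mosaic)
    } else {
      sum(verdict_mosaic)
    }
  }
  grid
}

# per-child joint regions and extrapolated per-class rates; tracks generated
# by generate_coverage_tracks share one segment grid, so the four-way
# intersection reduces to a logical AND over segment depth vectors (verified
# against the general interval route in the test suite)
cohort_mutation_rates <- function(sim, classified, depth_threshold = 40,
                                  segment_length = 1e5) {
  config <- sim$config
  final <- classified[classified$in_final_callset, , drop = FALSE]
  fams <- unique(sim$members$family_id)
  grid0 <- expand.grid(label = c("mosaic", "germline_denovo"),
                       functional_class = c("LGD", "missense", "synonymous",
                                            "all"),
                       stringsAsFactors = FALSE)
  out <- vector("list", 2L * length(fams))
  k <- 0L
  for (i in seq_along(fams)) {
    tracks <- generate_coverage_tracks(i, config,
                                       segment_length = segment_length)
    seg_widths <- tracks$fa$end - tracks$fa$start
    ok <- lapply(tracks, function(t) t$depth >= depth_threshold)
    for (child in c("p1", "s1")) {
      child_id <- paste0(fams[i], ".", child)
      mask <- ok[[child]] & ok$fa & ok$mo
      joint_length <- sum(seg_widths[mask])
      if (joint_length == 0) {
        warning("cohort_mutation_rates: empty joint region for child ",
                child_id, "; child excluded", call. = FALSE)
        next
      }
      calls <- final[final$child_id == child_id, , drop = FALSE]
      seg_idx <- pmin(length(mask),
                      ((calls$pos - 1L) %/% as.integer(segment_length)) + 1L)
      in_region <- mask[seg_idx]
      rates <- grid0
      rates$count_in_joint <- mapply(function(lab, fc) {
        sel <- in_region & calls$label == lab
        if (fc != "all") sel <- sel & calls$functional_class == fc
        sum(sel)
      }, rates$label, rates$functional_class)
      rates$joint_length <- joint_length
      rates$capture_length <- config$capture_length
      rates$extrapolated_count <- rates$count_in_joint *
        config$capture_length / joint_length
      rates$family_id <- fams[i]
      rates$child_id <- child_id
      rates$role <- unname(CHILD_ROLES[child])
      k <- k + 1L
      out[[k]] <- rates
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(x, path)
    files <<- c(files, path)
  }
  emit(result$cohort$truth, "truth.tsv")
  emit(result$calls, "denovo_calls.tsv")
  emit(result$classified, "classified_calls.tsv")
  emit(result$phasing, "phasing.tsv")
  emit(result$rates, "rates.tsv")
  emit(result$error_counts, "phasing_error_counts.tsv")
  if (!is.null(result$contribution)) {
    emit(summary(result$contribution), "contribution.tsv")
  }
  if (isTRUE(config$write_vcf)) {
    vcf_path <- file.path(config$out_dir, "cohort.vcf")
    write_cohort_vcf(result$cohort, vcf_path)
    files <- c(files, vcf_path)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write_tsv(manifest, manifest_path)
  manifest
}
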