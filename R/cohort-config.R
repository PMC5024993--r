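#' Configuration for the synthetic quad-family cohort generator
#'
#' Bundles and validates all parameters of the synthetic exome cohort. The
#' defaults emulate the read-count structure of a large simplex-autism
#' whole-exome study: mean depth 94.6x at variant sites, roughly one germline
#' de novo coding mutation per child exome of which ~5-6% are post-zygotic
#' (mosaic), an excess of both classes in probands, and a mild capture/alignment
#' bias against non-reference alleles.
#'
#' @param n_families Number of quad families (father, mother, proband,
#'   unaffected sibling).
#' @param depth_mean Mean sequencing depth at variant sites (reads).
#' @param depth_dispersion Negative-binomial size parameter for per-site,
#'   per-sample depth; variance is `mu + mu^2/size`.
#' @param germline_denovo_rate Expected germline de novo variants per child
#'   exome (baseline, both probands and siblings).
#' @param mosaic_rate Expected mosaic (post-zygotic) variants per child exome
#'   (baseline).
#' @param contributory_mosaic_rate Additional mosaic variants per proband
#'   exome, on top of the baseline rate.
#' @param contributory_germline_rate Additional germline de novo variants per
#'   proband exome.
#' @param cell_fraction_distribution Function of `n` returning `n` draws in
#'   (0, 1]: the fraction of cells carrying each planted mosaic variant.
#' @param reference_bias Fractional under-representation of alternate-allele
#'   reads at heterozygous sites, in [0, 0.5).
#' @param inherited_het_density Number of linked inherited heterozygous
#'   variants planted within the phasing window of each de novo variant
#'   (at least one is always planted).
#' @param background_het_rate Expected unlinked inherited heterozygous
#'   variants planted per family, exercising the caller's rejection of
#'   transmitted variation.
#' @param capture_length Length of the synthetic capture region (bp).
#' @param error_rate Symmetric per-read base error used both when sampling
#'   non-carrier alternate reads and in the genotype-likelihood model.
#' @param phasing_window Phasing window half-width (bp) used when placing
#'   linked heterozygous variants.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_families = 100,
                          depth_mean = 94.6,
                          depth_dispersion = 10,
                          germline_denovo_rate = 1.0,
                          mosaic_rate = 0.06,
                          contributory_mosaic_rate = 0.051,
                          contributory_germline_rate = 0.056,
                          cell_fraction_distribution = function(n) stats::runif(n, 0.1, 0.7),
                          reference_bias = 0.05,
                          inherited_het_density = 1,
                          background_het_rate = 5,
                          capture_length = 36e6,
                          error_rate = 0.001,
                          phasing_window = 500,
                          seed = 1L) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("n_families", "depth_mean", "depth_dispersion",
               "germline_denovo_rate", "mosaic_rate",
               "contributory_mosaic_rate", "contributory_germline_rate",
               "reference_bias", "inherited_het_density",
               "background_het_rate", "capture_length", "error_rate",
               "phasing_window", "seed")) {
    val <- get(nm)
    if (!num_ok(val)) {
      stop("cohort_config: '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (n_families < 1) stop("cohort_config: n_families must be >= 1", call. = FALSE)
  if (depth_mean <= 0) stop("cohort_config: depth_mean must be > 0", call. = FALSE)
  if (depth_dispersion <= 0) stop("cohort_config: depth_dispersion must be > 0", call. = FALSE)
  rates <- c(germline_denovo_rate, mosaic_rate, contributory_mosaic_rate,
             contributory_germline_rate, background_het_rate)
  if (any(rates < 0)) stop("cohort_config: rates must be >= 0", call. = FALSE)
  if (reference_bias < 0 || reference_bias >= 0.5) {
    stop("cohort_config: reference_bias must lie in [0, 0.5)", call. = FALSE)
  }
  if (inherited_het_density < 0) {
    stop("cohort_config: inherited_het_density must be >= 0", call. = FALSE)
  }
  if (capture_length < 1e4) stop("cohort_config: capture_length too small", call. = FALSE)
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("cohort_config: error_rate must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.function(cell_fraction_distribution)) {
    stop("cohort_config: cell_fraction_distribution must be a function", call. = FALSE)
  }
  cf <- cell_fraction_distribution(1000L)
  if (any(!is.finite(cf)) || any(cf <= 0) || any(cf > 1)) {
    stop("cohort_config: cell_fraction_distribution must return values in (0, 1]",
         call. = FALSE)
  }
  structure(
    list(n_families = as.integer(n_families),
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         germline_denovo_rate = germline_denovo_rate,
         mosaic_rate = mosaic_rate,
         contributory_mosaic_rate = contributory_mosaic_rate,
         contributory_germline_rate = contributory_germline_rate,
         cell_fraction_distribution = cell_fraction_distribution,
         reference_bias = reference_bias,
         inherited_het_density = inherited_het_density,
         background_het_rate = background_het_rate,
         capture_length = capture_length,
         error_rate = error_rate,
         phasing_window = phasing_window,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic quad-family cohort configuration\n")
  cat(sprintf("  families: %d   capture: %.1f Mb   depth: %.1fx (NB size %.1f)\n",
              x$n_families, x$capture_length / 1e6, x$depth_mean, x$depth_dispersion))
  cat(sprintf("  rates/child: germline %.3f + mosaic %.3f; proband excess: germline %.3f + mosaic %.3f\n",
              x$germline_denovo_rate, x$mosaic_rate,
              x$contributory_germline_rate, x$contributory_mosaic_rate))
  cat(sprintf("  reference bias: %.3f   per-read error: %.4g   seed: %d\n",
              x$reference_bias, x$error_rate, x$seed))
  invisible(x)
}
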