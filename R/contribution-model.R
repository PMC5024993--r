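#' Observed per-exome mutation rates by cohort and classified class
#'
#' @param proband_mosaic,proband_germline,sibling_mosaic,sibling_germline
#'   Mean mutations per exome in each cohort for each classified class.
#' @return A named list of class `observed_rates`.
#' @export
observed_rates <- function(proband_mosaic, proband_germline,
                           sibling_mosaic, sibling_germline) {
  vals <- c(proband_mosaic, proband_germline, sibling_mosaic,
            sibling_germline)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("observed_rates: rates must be finite and non-negative", call. = FALSE)
  }
  structure(list(proband_mosaic = proband_mosaic,
                 proband_germline = proband_germline,
                 sibling_mosaic = sibling_mosaic,
                 sibling_germline = sibling_germline),
            class = "observed_rates")
}

#' Classification-error counts from phasing validation
#'
#' One error rate per cohort and classified class: the fraction of
#' phasing-informative calls with that classification whose phasing verdict
#' indicated the other true class.
#'
#' @param counts Data frame with columns `cohort` (`"proband"`/`"sibling"`),
#'   `class` (`"mosaic"`/`"germline"`), `misclassified`, `informative`.
#' @return A data frame of class `classification_errors` with an added
#'   `error_rate` column.
#' @export
classification_errors <- function(counts) {
  need <- c("cohort", "class", "misclassified", "informative")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$misclassified < 0) ||
      any(counts$misclassified > counts$informative)) {
    stop("classification_errors: require 0 <= misclassified <= informative",
         call. = FALSE)
  }
  key <- paste(counts$cohort, counts$class)
  expect <- c("proband mosaic", "proband germline", "sibling mosaic",
              "sibling germline")
  if (!setequal(key, expect)) {
    stop("classification_errors: need one row per cohort x class: ",
         paste(expect, collapse = ", "), call. = FALSE)
  }
  counts$error_rate <- counts$misclassified / counts$informative
  class(counts) <- c("classification_errors", "data.frame")
  counts
}

err_lookup <- function(errors, cohort, class) {
  errors$error_rate[errors$cohort == cohort & errors$class == class]
}

# core solver, vectorised over rows of the eps matrix
# eps columns: pm, pg, sm, sg (cohort x classified class error rates)
solve_contribution_eps <- function(obs, eps) {
  eps <- matrix(eps, ncol = 4,
                dimnames = list(NULL, c("pm", "pg", "sm", "sg")))
  B_m <- obs$sibling_mosaic * (1 - eps[, "sm"]) +
    obs$sibling_germline * eps[, "sg"]
  B_g <- obs$sibling_germline * (1 - eps[, "sg"]) +
    obs$sibling_mosaic * eps[, "sm"]
  T_m <- obs$proband_mosaic * (1 - eps[, "pm"]) +
    obs$proband_germline * eps[, "pg"]
  T_g <- obs$proband_germline * (1 - eps[, "pg"]) +
    obs$proband_mosaic * eps[, "pm"]
  C_m <- T_m - B_m
  C_g <- T_g - B_g
  cbind(baseline_mosaic = B_m, baseline_germline = B_g,
        true_proband_mosaic = T_m, true_proband_germline = T_g,
        contributory_mosaic = C_m, contributory_germline = C_g,
        percent_cases_mosaic = 100 * C_m,
        percent_cases_germline = 100 * C_g,
        fraction_contributory_mosaic = C_m / T_m,
        fraction_contributory_germline = C_g / T_g)
}

#' Solve the misclassification-aware model of contributory variation
#'
#' Observed rates of classified mosaic and germline de novo variation are
#' modelled as mixtures of correctly and incorrectly classified true
#' variation. With `e_c` the error rate of classified class `c` (the
#' fraction of class-`c` calls that are truly the other class), the true
#' sibling (baseline) rates are
#' `B_m = O_sm (1 - e_sm) + O_sg e_sg` and
#' `B_g = O_sg (1 - e_sg) + O_sm e_sm`; the true proband totals `T_m`, `T_g`
#' are the analogous combinations of proband observations and proband error
#' rates. The contributory rate of each true class is `C = T - B`, the
#' percentage of cases attributed to it is `100 * C` (expected contributory
#' mutations per proband exome; see `case_model`), and the contributory
#' fraction is `C / T`. Negative point estimates, possible under sampling
#' noise, are reported as-is with a warning rather than clipped.
#'
#' @param observed An [observed_rates()] object.
#' @param errors A [classification_errors()] table.
#' @param case_model `"expected"` reads the percentage of cases as 100 times
#'   the expected contributory mutations per proband exome; `"poisson"` uses
#'   the probability of at least one contributory mutation,
#'   `100 * (1 - exp(-C))`.
#' @return A named list of point estimates, including the decomposition of
#'   each classified class's proband excess into correctly and incorrectly
#'   classified parts.
#' @export
solve_model <- function(observed, errors, case_model = c("expected", "poisson")) {
  stopifnot(inherits(observed, "observed_rates"),
            inherits(errors, "classification_errors"))
  case_model <- match.arg(case_model)
  eps <- c(pm = err_lookup(errors, "proband", "mosaic"),
           pg = err_lookup(errors, "proband", "germline"),
           sm = err_lookup(errors, "sibling", "mosaic"),
           sg = err_lookup(errors, "sibling", "germline"))
  est <- drop(solve_contribution_eps(observed, matrix(eps, nrow = 1)))
  if (case_model == "poisson") {
    est["percent_cases_mosaic"] <- 100 * (1 - exp(-est["contributory_mosaic"]))
    est["percent_cases_germline"] <- 100 * (1 - exp(-est["contributory_germline"]))
  }
  if (est["contributory_mosaic"] < 0 || est["contributory_germline"] < 0) {
    warning("solve_model: negative contributory rate (sampling noise); ",
            "reported as-is", call. = FALSE)
  }
  # forward-map the baseline through the proband error rates to split each
  # classified class's proband excess into correctly/incorrectly classified
  det <- 1 - eps[["pm"]] - eps[["pg"]]
  baseline_classified_m <- (est[["baseline_mosaic"]] * (1 - eps[["pg"]]) -
                              est[["baseline_germline"]] * eps[["pg"]]) / det
  baseline_classified_g <- (est[["baseline_germline"]] * (1 - eps[["pm"]]) -
                              est[["baseline_mosaic"]] * eps[["pm"]]) / det
  excess_m <- observed$proband_mosaic - baseline_classified_m
  excess_g <- observed$proband_germline - baseline_classified_g
  decomposition <- data.frame(
    classified = c("mosaic", "germline"),
    contribution = c(excess_m, excess_g),
    correctly_classified = c(excess_m * (1 - eps[["pm"]]),
                             excess_g * (1 - eps[["pg"]])),
    incorrectly_classified = c(excess_m * eps[["pm"]], excess_g * eps[["pg"]]),
    stringsAsFactors = FALSE)
  c(as.list(est), list(decomposition = decomposition, error_rates = eps))
}

#' Credible intervals for the contribution model via beta-binomial resampling
#'
#' Uncertainty in the classification-error rates is modelled with a Beta
#' posterior per cohort and class, parameterised by the phasing-validation
#' counts (`misclassified` successes of `informative` trials; uniform prior
#' by default). Each permutation draws all four error rates and re-solves
#' the model; the 2.5th and 97.5th percentiles across permutations form the
#' interval. The observed rates themselves are held fixed.
#'
#' @param observed An [observed_rates()] object.
#' @param errors A [classification_errors()] table.
#' @param n_perm Number of permutations.
#' @param seed Random seed (the interval is deterministic given it).
#' @param prior `"uniform"` (Beta(k+1, n-k+1)) or `"jeffreys"`
#'   (Beta(k+0.5, n-k+0.5)).
#' @return A matrix with one row per model quantity and columns `lower`,
#'   `upper`.
#' @export
credible_interval <- function(observed, errors, n_perm = 10000, seed = 1,
                              prior = c("uniform", "jeffreys")) {
  stopifnot(inherits(observed, "observed_rates"),
            inherits(errors, "classification_errors"))
  prior <- match.arg(prior)
  a0 <- if (prior == "uniform") 1 else 0.5
  set.seed(seed)
  draw <- function(cohort, class) {
    row <- errors[errors$cohort == cohort & errors$class == class, ]
    rbeta(n_perm, row$misclassified + a0,
          row$informative - row$misclassified + a0)
  }
  eps <- cbind(pm = draw("proband", "mosaic"),
               pg = draw("proband", "germline"),
               sm = draw("sibling", "mosaic"),
               sg = draw("sibling", "germline"))
  draws <- solve_contribution_eps(observed, eps)
  t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)) |>
    `colnames<-`(c("lower", "upper"))
}

#' Simulate classified mutation-rate data with known contributory rates
#'
#' Generates cohort-level inputs for the contribution model directly at the
#' rate level: per-child true mutation counts are Poisson with the baseline
#' rates (plus the contributory rates in probands), each mutation is
#' misclassified with the given true-class error probabilities, and phasing
#' validation draws the stated number of informative calls per cohort and
#' classified class with binomially distributed misclassification counts.
#' This isolates the model's statistical behaviour (estimator bias, interval
#' coverage) from read-level detection effects.
#'
#' @param n_families Number of quad families (one proband and one sibling
#'   each).
#' @param baseline_mosaic,baseline_germline True baseline rates per exome.
#' @param contributory_mosaic,contributory_germline Additional true rates
#'   per proband exome.
#' @param misclass_mosaic Probability that a true mosaic mutation is
#'   classified germline.
#' @param misclass_germline Probability that a true germline mutation is
#'   classified mosaic.
#' @param n_validation Phasing-informative validations per cohort and
#'   classified class, as `c(mosaic, germline)`.
#' @param seed Random seed.
#' @return A list with `observed` ([observed_rates()]), `errors`
#'   ([classification_errors()]) and `truth` (the planted rates and the
#'   implied true contributory fractions).
#' @export
simulate_classified_rate_cohort <- function(n_families,
                                            baseline_mosaic = 0.06,
                                            baseline_germline = 1.0,
                                            contributory_mosaic = 0.051,
                                            contributory_germline = 0.056,
                                            misclass_mosaic = 0.13,
                                            misclass_germline = 0.066,
                                            n_validation = c(30, 450),
                                            seed = 1) {
  set.seed(seed)
  sim_cohort <- function(rate_m, rate_g) {
    true_m <- rpois(n_families, rate_m)
    true_g <- rpois(n_families, rate_g)
    m_to_g <- rbinom(n_families, true_m, misclass_mosaic)
    g_to_m <- rbinom(n_families, true_g, misclass_germline)
    obs_m <- true_m - m_to_g + g_to_m
    obs_g <- true_g - g_to_m + m_to_g
    # composition of each classified class: fraction truly the other class
    frac_m_wrong <- sum(g_to_m) / max(1, sum(obs_m))
    frac_g_wrong <- sum(m_to_g) / max(1, sum(obs_g))
    list(mean_m = mean(obs_m), mean_g = mean(obs_g),
         frac_m_wrong = frac_m_wrong, frac_g_wrong = frac_g_wrong)
  }
  pro <- sim_cohort(baseline_mosaic + contributory_mosaic,
                    baseline_germline + contributory_germline)
  sib <- sim_cohort(baseline_mosaic, baseline_germline)
  validate <- function(cohort, class) {
    n <- if (class == "mosaic") n_validation[1] else n_validation[2]
    frac <- if (class == "mosaic") cohort$frac_m_wrong else cohort$frac_g_wrong
    data.frame(misclassified = rbinom(1, n, frac), informative = n)
  }
  errs <- rbind(
    cbind(cohort = "proband", class = "mosaic", validate(pro, "mosaic")),
    cbind(cohort = "proband", class = "germline", validate(pro, "germline")),
    cbind(cohort = "sibling", class = "mosaic", validate(sib, "mosaic")),
    cbind(cohort = "sibling", class = "germline", validate(sib, "germline")))
  list(
    observed = observed_rates(pro$mean_m, pro$mean_g, sib$mean_m, sib$mean_g),
    errors = classification_errors(errs),
    truth = list(
      baseline_mosaic = baseline_mosaic,
      baseline_germline = baseline_germline,
      contributory_mosaic = contributory_mosaic,
      contributory_germline = contributory_germline,
      fraction_contributory_mosaic =
        contributory_mosaic / (baseline_mosaic + contributory_mosaic),
      fraction_contributory_germline =
        contributory_germline / (baseline_germline + contributory_germline)))
}

#' Fit the contribution model with credible intervals
#'
#' Convenience fitting interface bundling [solve_model()] and
#' [credible_interval()] into a single classed object with the usual
#' accessor methods.
#'
#' @inheritParams solve_model
#' @inheritParams credible_interval
#' @return An object of class `contribution_fit`.
#' @export
contribution_model <- function(observed, errors, n_perm = 10000, seed = 1,
                               prior = c("uniform", "jeffreys"),
                               case_model = c("expected", "poisson")) {
  est <- solve_model(observed, errors, case_model = case_model)
  ci <- credible_interval(observed, errors, n_perm = n_perm, seed = seed,
                          prior = prior)
  structure(list(estimates = est, intervals = ci, observed = observed,
                 errors = errors, n_perm = n_perm, seed = seed,
                 prior = match.arg(prior)),
            class = "contribution_fit")
}

#' @export
print.contribution_fit <- function(x, ...) {
  e <- x$estimates
  ci <- x$intervals
  fmt <- function(name, scale = 1, unit = "") {
    sprintf("%.3g%s (95%% CI %.3g to %.3g%s)", e[[name]] * scale, unit,
            ci[name, "lower"] * scale, ci[name, "upper"] * scale, unit)
  }
  cat("Contribution of de novo variation (misclassification-aware model)\n")
  cat("  mosaic:   contributes to", fmt("percent_cases_mosaic", unit = "%"),
      "of cases;\n            contributory fraction",
      fmt("fraction_contributory_mosaic", 100, "%"), "\n")
  cat("  germline: contributes to", fmt("percent_cases_germline", unit = "%"),
      "of cases;\n            contributory fraction",
      fmt("fraction_contributory_germline", 100, "%"), "\n")
  invisible(x)
}

#' @export
summary.contribution_fit <- function(object, ...) {
  e <- object$estimates
  nm <- setdiff(names(e), c("decomposition", "error_rates"))
  out <- data.frame(quantity = nm,
                    estimate = unlist(e[nm]),
                    lower = object$intervals[nm, "lower"],
                    upper = object$intervals[nm, "upper"])
  rownames(out) <- NULL
  out
}

#' @export
coef.contribution_fit <- function(object, ...) {
  e <- object$estimates
  unlist(e[setdiff(names(e), c("decomposition", "error_rates"))])
}

#' @export
confint.contribution_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) {
    stop("confint.contribution_fit: intervals are computed at the 95% level",
         call. = FALSE)
  }
  ci <- object$intervals
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
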