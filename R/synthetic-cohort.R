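#' @importFrom stats rpois rbinom rnbinom runif pbinom dbinom p.adjust
#'   binom.test wilcox.test quantile rbeta sd qnorm setNames aggregate
NULL

MEMBER_ROLES <- c(fa = "father", mo = "mother", p1 = "proband", s1 = "sibling")
CHILD_ROLES <- c(p1 = "proband", s1 = "sibling")

#' Phred-scaled genotype likelihoods from a symmetric per-read error model
#'
#' For a biallelic site the three diploid genotypes (hom-ref, het, hom-alt)
#' emit alternate-supporting reads with per-read probabilities `eps`, `0.5`
#' and `1 - eps`. Likelihoods use the binomial kernel and are rescaled so the
#' best genotype has likelihood 0, matching the VCF PL convention
#' (ordering: ref/ref, ref/alt, alt/alt).
#'
#' @param dp Integer vector of total depths.
#' @param ad Integer vector of alternate-allele depths.
#' @param eps Per-read symmetric error probability.
#' @return Integer matrix with columns `pl0`, `pl1`, `pl2`.
#' @keywords internal
pl_from_counts <- function(dp, ad, eps = 0.001) {
  stopifnot(length(dp) == length(ad), all(ad <= dp), all(ad >= 0))
  p_alt <- c(eps, 0.5, 1 - eps)
  ll <- vapply(p_alt, function(p) ad * log10(p) + (dp - ad) * log10(1 - p),
               numeric(length(dp)))
  ll <- matrix(ll, ncol = 3L)
  best <- ll[cbind(seq_len(nrow(ll)), max.col(ll, ties.method = "first"))]
  pl <- round(-10 * (ll - best))
  colnames(pl) <- c("pl0", "pl1", "pl2")
  storage.mode(pl) <- "integer"
  pl
}

#' Most-likely genotype dosage from phred-scaled likelihoods
#'
#' @param pl0,pl1,pl2 Phred-scaled likelihoods for hom-ref, het, hom-alt.
#' @return Integer vector of alternate-allele dosages (0, 1 or 2); ties go to
#'   the lower dosage.
#' @keywords internal
dosage_from_pl <- function(pl0, pl1, pl2) {
  max.col(-cbind(pl0, pl1, pl2), ties.method = "first") - 1L
}

sample_alleles <- function(n, indel_prob = 0.1) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  kind <- sample(c("snv", "ins", "del"), n, replace = TRUE,
                 prob = c(1 - indel_prob, indel_prob / 2, indel_prob / 2))
  ins <- kind == "ins"
  del <- kind == "del"
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1L, 1L)
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

sample_functional_class <- function(n) {
  sample(c("LGD", "missense", "synonymous", "other"), n, replace = TRUE,
         prob = c(0.08, 0.45, 0.25, 0.22))
}

#' Generate a synthetic quad-family exome cohort with known truth labels
#'
#' Plants inherited heterozygous variants, germline de novo variants
#' (cell fraction 1) and mosaic variants (cell fraction drawn from the
#' configured distribution) in children of quad families, then draws
#' per-member read counts: total depth from a negative binomial with mean
#' `depth_mean`, alternate reads binomial with success probability
#' `(cell_fraction / 2) * (1 - reference_bias)` for the carrier and the
#' per-read error rate for non-carriers. Phred-scaled genotype likelihoods
#' come from the symmetric per-read error model of [pl_from_counts()].
#' Each de novo variant is accompanied by at least one linked inherited
#' heterozygous variant within the phasing window so that read-backed phasing
#' is always possible on synthetic data.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements:
#'   \describe{
#'     \item{records}{data frame of multi-sample variant records, one row per
#'       site and family, with per-member `*_dp`, `*_ad`, `*_pl0..2` columns
#'       for the father (`fa`), mother (`mo`), proband (`p1`) and sibling
#'       (`s1`).}
#'     \item{truth}{data frame of planted variants with truth class
#'       (`inherited_het`, `germline_denovo`, `mosaic`), cell fraction,
#'       parental haplotype and, for de novo variants, the position of the
#'       linked inherited het.}
#'     \item{members}{data frame mapping family and role to sample ids.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_fam <- config$n_families
  fam_ids <- sprintf("fam%05d", seq_len(n_fam))
  window <- config$phasing_window

  # planted de novo / mosaic variants per child
  child_tab <- expand.grid(family_id = fam_ids, child = c("p1", "s1"),
                           stringsAsFactors = FALSE)
  child_tab <- child_tab[order(child_tab$family_id), ]
  is_pro <- child_tab$child == "p1"
  n_germ <- rpois(nrow(child_tab), config$germline_denovo_rate +
                    ifelse(is_pro, config$contributory_germline_rate, 0))
  n_mos <- rpois(nrow(child_tab), config$mosaic_rate +
                   ifelse(is_pro, config$contributory_mosaic_rate, 0))

  dn <- data.frame(
    family_id = rep(child_tab$family_id, n_germ + n_mos),
    child = rep(child_tab$child, n_germ + n_mos),
    truth_class = unlist(mapply(function(g, m) {
      rep(c("germline_denovo", "mosaic"), c(g, m))
    }, n_germ, n_mos, SIMPLIFY = FALSE), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  n_dn <- nrow(dn)
  if (n_dn > 0) {
    dn$cell_fraction <- ifelse(dn$truth_class == "mosaic",
                               config$cell_fraction_distribution(n_dn), 1)
    dn$parental_haplotype <- sample(c("paternal", "maternal"), n_dn, replace = TRUE)
  } else {
    dn$cell_fraction <- numeric(0)
    dn$parental_haplotype <- character(0)
  }

  # background inherited hets, one carrier child each
  n_bg <- rpois(n_fam, config$background_het_rate)
  bg <- data.frame(
    family_id = rep(fam_ids, n_bg),
    child = sample(c("p1", "s1"), sum(n_bg), replace = TRUE),
    truth_class = rep("inherited_het", sum(n_bg)),
    cell_fraction = rep(1, sum(n_bg)),
    parental_haplotype = sample(c("paternal", "maternal"), sum(n_bg),
                                replace = TRUE),
    stringsAsFactors = FALSE
  )

  # positions: de novo and background sites uniform over the capture region,
  # clamped away from the edges so phasing windows fit
  lo <- window + 1
  hi <- config$capture_length - window
  dn$pos <- floor(runif(n_dn, lo, hi))
  bg$pos <- if (nrow(bg)) floor(runif(nrow(bg), lo, hi)) else integer(0)

  # linked inherited hets within the phasing window of each de novo variant
  if (n_dn > 0) {
    k <- pmax(1L, rpois(n_dn, config$inherited_het_density))
    off_pool <- c(-window:-1, 1:window)
    linked <- data.frame(
      family_id = rep(dn$family_id, k),
      child = rep(dn$child, k),
      truth_class = rep("inherited_het", sum(k)),
      cell_fraction = rep(1, sum(k)),
      parental_haplotype = sample(c("paternal", "maternal"), sum(k),
                                  replace = TRUE),
      pos = rep(dn$pos, k) + unlist(lapply(k, function(m)
        sample(off_pool, m)), use.names = FALSE),
      linked_to_pos = rep(dn$pos, k),
      stringsAsFactors = FALSE
    )
  } else {
    linked <- dn[0, ]
    linked$pos <- integer(0)
    linked$linked_to_pos <- integer(0)
  }
  dn$linked_to_pos <- rep(NA_integer_, nrow(dn))
  bg$linked_to_pos <- rep(NA_integer_, nrow(bg))

  truth <- rbind(dn, bg, linked)
  if (nrow(truth) == 0) {
    stop("generate_cohort: configuration planted no variants", call. = FALSE)
  }

  # resolve within-family position collisions by shifting one base at a time
  key <- paste(truth$family_id, truth$pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    truth$pos[dup] <- truth$pos[dup] + 1L
    key <- paste(truth$family_id, truth$pos)
  }

  al <- sample_alleles(nrow(truth))
  truth$chrom <- "1"
  truth$ref <- al$ref
  truth$alt <- al$alt
  truth$functional_class <- sample_functional_class(nrow(truth))
  truth$child_role <- unname(CHILD_ROLES[truth$child])
  truth$carrier_id <- paste0(truth$family_id, ".", truth$child)

  # read counts: carrier allele-fraction matrix over the four members
  n_site <- nrow(truth)
  roles <- names(MEMBER_ROLES)
  p_alt <- matrix(config$error_rate, nrow = n_site, ncol = 4,
                  dimnames = list(NULL, roles))
  het_p <- 0.5 * (1 - config$reference_bias)
  is_het <- truth$truth_class == "inherited_het"
  child_col <- match(truth$child, roles)
  p_alt[cbind(seq_len(n_site), child_col)] <-
    (truth$cell_fraction / 2) * (1 - config$reference_bias)
  p_alt[cbind(which(is_het), child_col[is_het])] <- het_p
  parent_col <- match(ifelse(truth$parental_haplotype == "paternal", "fa", "mo"),
                      roles)
  p_alt[cbind(which(is_het), parent_col[is_het])] <- het_p

  records <- data.frame(chrom = truth$chrom, pos = truth$pos,
                        ref = truth$ref, alt = truth$alt,
                        family_id = truth$family_id,
                        functional_class = truth$functional_class,
                        stringsAsFactors = FALSE)
  for (j in seq_along(roles)) {
    dp <- rnbinom(n_site, size = config$depth_dispersion, mu = config$depth_mean)
    ad <- rbinom(n_site, dp, p_alt[, j])
    pl <- pl_from_counts(dp, ad, config$error_rate)
    records[[paste0(roles[j], "_dp")]] <- dp
    records[[paste0(roles[j], "_ad")]] <- ad
    records[[paste0(roles[j], "_pl0")]] <- pl[, "pl0"]
    records[[paste0(roles[j], "_pl1")]] <- pl[, "pl1"]
    records[[paste0(roles[j], "_pl2")]] <- pl[, "pl2"]
  }

  ord <- order(records$family_id, records$pos)
  records <- records[ord, ]
  truth <- truth[ord, c("family_id", "carrier_id", "child_role", "chrom", "pos",
                        "ref", "alt", "truth_class", "cell_fraction",
                        "parental_haplotype", "functional_class",
                        "linked_to_pos")]
  rownames(records) <- rownames(truth) <- NULL

  members <- data.frame(
    family_id = rep(fam_ids, each = 4),
    role = rep(unname(MEMBER_ROLES), n_fam),
    member_id = paste0(rep(fam_ids, each = 4), ".",
                       rep(names(MEMBER_ROLES), n_fam)),
    stringsAsFactors = FALSE
  )

  structure(list(records = records, truth = truth, members = members,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tc <- table(x$truth$truth_class)
  cat(sprintf("Synthetic cohort: %d quad families, %d variant records\n",
              x$config$n_families, nrow(x$records)))
  cat("  planted:", paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  invisible(x)
}

#' Generate linked reads spanning a de novo variant and its inherited het
#'
#' Emulates read evidence across a (de novo, inherited heterozygous) site
#' pair. Each synthetic read originates from one of the child's two parental
#' haplotypes with equal probability; on the mutant haplotype the de novo
#' allele is present with probability equal to the planted cell fraction
#' (1 for germline de novo variants). Reported alleles are flipped
#' independently with the configured per-read error rate, and per-read base
#' qualities are drawn high (Q25-Q40) unless overridden downstream.
#'
#' @param variant One row of a cohort truth table with `truth_class`
#'   `mosaic` or `germline_denovo`.
#' @param truth The cohort truth table (used to locate a linked inherited
#'   het within the window).
#' @param config The [cohort_config()] used to build the cohort.
#' @param window Maximum distance (bp) to the linked het.
#' @param depth Number of spanning reads; defaults to a negative-binomial
#'   draw with mean `config$depth_mean`.
#' @param seed Seed for this read set; defaults to a deterministic function
#'   of the cohort seed and the variant position.
#' @return A data frame with one row per read and columns `haplotype`
#'   (`mut`/`other`), `het_allele` and `dn_allele` (`alt`/`ref`), `het_qual`,
#'   `dn_qual`. Attributes `parent_of_het_alt` (parent that transmitted the
#'   linked het's alternate allele) and `dn_parent` (true parental origin of
#'   the de novo variant) carry the truth used by recovery tests.
#' @export
generate_phasing_reads <- function(variant, truth, config,
                                   window = config$phasing_window,
                                   depth = NULL, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), nrow(variant) == 1)
  if (!variant$truth_class %in% c("mosaic", "germline_denovo")) {
    stop("generate_phasing_reads: variant must be de novo or mosaic", call. = FALSE)
  }
  hets <- truth[truth$family_id == variant$family_id &
                  truth$truth_class == "inherited_het" &
                  abs(truth$pos - variant$pos) <= window &
                  truth$carrier_id == variant$carrier_id, , drop = FALSE]
  if (nrow(hets) == 0) {
    stop("generate_phasing_reads: no linked inherited het within the window",
         call. = FALSE)
  }
  het <- hets[which.min(abs(hets$pos - variant$pos)), ]
  if (is.null(seed)) {
    seed <- (config$seed + as.integer(variant$pos %% 2147480000L)) %% 2147483647L
  }
  set.seed(seed)
  if (is.null(depth)) {
    depth <- max(4L, rnbinom(1L, size = config$depth_dispersion,
                             mu = config$depth_mean))
  }
  eps <- config$error_rate
  hap <- sample(c("mut", "other"), depth, replace = TRUE)
  carries_dn <- hap == "mut" & runif(depth) < variant$cell_fraction
  dn_allele <- ifelse(xor(carries_dn, runif(depth) < eps), "alt", "ref")
  # the het's alternate allele rides on the haplotype transmitted by its
  # carrier parent; that haplotype is the mutant one iff both variants come
  # from the same parent
  same_parent <- het$parental_haplotype == variant$parental_haplotype
  het_is_alt <- if (same_parent) hap == "mut" else hap == "other"
  het_allele <- ifelse(xor(het_is_alt, runif(depth) < eps), "alt", "ref")
  reads <- data.frame(haplotype = hap, het_allele = het_allele,
                      dn_allele = dn_allele,
                      het_qual = sample(25:40, depth, replace = TRUE),
                      dn_qual = sample(25:40, depth, replace = TRUE),
                      stringsAsFactors = FALSE)
  attr(reads, "parent_of_het_alt") <-
    ifelse(het$parental_haplotype == "paternal", "father", "mother")
  attr(reads, "dn_parent") <-
    ifelse(variant$parental_haplotype == "paternal", "father", "mother")
  attr(reads, "het_pos") <- het$pos
  reads
}

#' Generate piecewise-constant coverage tracks for one quad family
#'
#' Depth is constant over consecutive segments tiling the capture region and
#' drawn per member from the same negative-binomial depth model used at
#' variant sites. Intervals follow the BED convention (0-based, half-open).
#'
#' @param family_index Integer index of the family (seeds the track).
#' @param config A [cohort_config()].
#' @param segment_length Segment size in bp.
#' @return Named list (`fa`, `mo`, `p1`, `s1`) of data frames with columns
#'   `chrom`, `start`, `end`, `depth`.
#' @export
generate_coverage_tracks <- function(family_index, config,
                                     segment_length = 10000) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed((config$seed + 7919L * as.integer(family_index)) %% 2147483647L)
  starts <- seq(0, config$capture_length - 1, by = segment_length)
  ends <- pmin(starts + segment_length, config$capture_length)
  lapply(setNames(nm = names(MEMBER_ROLES)), function(role) {
    data.frame(chrom = "1", start = starts, end = ends,
               depth = rnbinom(length(starts), size = config$depth_dispersion,
                               mu = config$depth_mean),
               stringsAsFactors = FALSE)
  })
}
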