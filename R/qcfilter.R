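#' SNP filter-cascade configuration
#'
#' @param het_excess_max loci with observed heterozygote proportion
#'   `>=` this value are removed (0.90).
#' @param maf_min loci with minor allele frequency strictly below this
#'   are removed (0.02).
#' @param missing_max loci missing strictly more than this fraction of
#'   genotypes are removed (0.50).
#' @param hwe_neglog10p_max loci with `-log10` Hardy-Weinberg exact-test
#'   P above this are removed (5).
#' @param require_polymorphic_both keep only loci polymorphic within each
#'   population separately (combined-dataset rule).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(het_excess_max = 0.90, maf_min = 0.02,
                          missing_max = 0.50, hwe_neglog10p_max = 5.0,
                          require_polymorphic_both = FALSE) {
  stopifnot(het_excess_max > 0, het_excess_max < 1,
            maf_min > 0, maf_min < 1,
            missing_max > 0, missing_max < 1,
            hwe_neglog10p_max > 0)
  structure(list(het_excess_max = het_excess_max, maf_min = maf_min,
                 missing_max = missing_max,
                 hwe_neglog10p_max = hwe_neglog10p_max,
                 require_polymorphic_both = require_polymorphic_both),
            class = "filter_config")
}

#' Flag paralogous sequence variants via doubled haploids
#'
#' A doubled haploid has two identical genome copies, so a heterozygous
#' call in one can only be a technical artifact — the diagnostic
#' signature of co-stacked paralogs (PSVs). Any locus at which any
#' doubled-haploid individual is called AB is flagged.
#'
#' @param gm a `genotype_matrix`.
#' @return character vector of flagged locus ids. If no individual is
#'   flagged doubled-haploid, returns an empty set with a warning (stage
#'   skipped).
#' @export
detect_psv_doubled_haploid <- function(gm) {
  dh <- gm$meta$doubled_haploid %in% TRUE
  if (!any(dh)) {
    warning("no doubled-haploid individuals: PSV stage skipped")
    return(character(0))
  }
  het <- gm$calls[, dh, drop = FALSE] == "AB"
  rownames(gm$calls)[rowSums(het, na.rm = TRUE) > 0]
}

# per-locus counts used by several filters; DH reference individuals are
# excluded from population-sample statistics
locus_counts <- function(gm, include_dh = FALSE) {
  use <- if (include_dh) rep(TRUE, ncol(gm$calls))
         else !(gm$meta$doubled_haploid %in% TRUE)
  calls <- gm$calls[, use, drop = FALSE]
  n_aa <- rowSums(calls == "AA", na.rm = TRUE)
  n_ab <- rowSums(calls == "AB", na.rm = TRUE)
  n_bb <- rowSums(calls == "BB", na.rm = TRUE)
  n_called <- n_aa + n_ab + n_bb
  list(n_aa = n_aa, n_ab = n_ab, n_bb = n_bb, n_called = n_called,
       n_total = ncol(calls))
}

#' Heterozygote-excess filter
#'
#' Removes loci whose observed heterozygote proportion among non-missing
#' calls is `>= het_excess_max` (ubiquitous heterozygosity is the other
#' PSV signature). Loci with zero non-missing calls are removed with
#' reason `all_missing`.
#'
#' @param gm a `genotype_matrix`.
#' @param het_excess_max removal threshold (default 0.90).
#' @return logical keep vector (named by locus); attribute `reason`
#'   holds `het_excess`/`all_missing` for removed loci.
#' @export
filter_het_excess <- function(gm, het_excess_max = 0.90) {
  lc <- locus_counts(gm)
  prop <- lc$n_ab / lc$n_called       # NaN when n_called == 0
  all_missing <- lc$n_called == 0
  drop_het <- !all_missing & prop >= het_excess_max
  keep <- !(all_missing | drop_het)
  names(keep) <- rownames(gm$calls)
  reason <- rep(NA_character_, length(keep))
  reason[drop_het] <- "het_excess"
  reason[all_missing] <- "all_missing"
  attr(keep, "reason") <- reason
  keep
}

#' Minor-allele-frequency filter
#'
#' Removes loci with MAF strictly below `maf_min` in the dataset (allele
#' counts over all non-missing calls); monomorphic loci (MAF 0) are
#' removed, MAF exactly at the threshold is retained.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min threshold (default 0.02).
#' @return logical keep vector named by locus.
#' @export
filter_maf <- function(gm, maf_min = 0.02) {
  lc <- locus_counts(gm)
  n_alleles <- 2 * lc$n_called
  count_a <- 2 * lc$n_aa + lc$n_ab
  p <- ifelse(n_alleles > 0, count_a / n_alleles, 0)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & n_alleles > 0
  names(keep) <- rownames(gm$calls)
  keep
}

#' Missingness filter
#'
#' Removes loci missing strictly more than `missing_max` of genotypes
#' (missing fraction exactly at the threshold is retained).
#'
#' @param gm a `genotype_matrix`.
#' @param missing_max threshold (default 0.50).
#' @return logical keep vector named by locus.
#' @export
filter_missing <- function(gm, missing_max = 0.50) {
  lc <- locus_counts(gm)
  frac_missing <- 1 - lc$n_called / lc$n_total
  keep <- frac_missing <= missing_max
  names(keep) <- rownames(gm$calls)
  keep
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic locus: conditional on the
#' observed allele counts, enumerate every heterozygote count of the
#' correct parity, compute each configuration's probability under
#' random union of gametes, and sum the probabilities not exceeding the
#' observed configuration's (no mid-p). Monomorphic input returns P = 1
#' by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts (non-negative, sum >= 1).
#' @return the two-sided exact P-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_ab = h | n, n_a) up to a constant:
  # P ∝ n_ab! over products of genotype factorials, with 2^n_ab phases
  lp <- h_log_prob(hets, n, n_a)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# log unnormalised probability of heterozygote count h given n diploids
# and n_a copies of allele A (Levene/Haldane conditional distribution)
h_log_prob <- function(h, n, n_a) {
  naa <- (n_a - h) / 2
  nbb <- (2 * n - n_a - h) / 2
  h * log(2) - lgamma(h + 1) - lgamma(naa + 1) - lgamma(nbb + 1)
}

#' Hardy-Weinberg filter
#'
#' Removes loci whose exact-test `-log10 P` exceeds the threshold, as
#' measured within the dataset at hand.
#'
#' @param gm a `genotype_matrix`.
#' @param hwe_neglog10p_max threshold (default 5).
#' @return logical keep vector named by locus; attribute `p` holds the
#'   P-values.
#' @export
filter_hwe <- function(gm, hwe_neglog10p_max = 5.0) {
  lc <- locus_counts(gm)
  p <- vapply(seq_along(lc$n_aa), function(i) {
    if (lc$n_called[i] == 0) return(1)
    hwe_exact_test(lc$n_aa[i], lc$n_ab[i], lc$n_bb[i])
  }, numeric(1))
  keep <- -log10(p) <= hwe_neglog10p_max
  names(keep) <- rownames(gm$calls)
  attr(keep, "p") <- p
  keep
}

#' Polymorphic-in-both filter (combined dataset)
#'
#' Keeps loci at which both alleles are observed within each of the two
#' populations separately; loci fixed or all-missing in either
#' population are removed.
#'
#' @param gm a `genotype_matrix`.
#' @param populations two population labels to require; defaults to the
#'   non-reference labels present.
#' @return logical keep vector named by locus.
#' @export
require_polymorphic_both <- function(gm, populations = NULL) {
  pops <- gm$meta$population
  if (is.null(populations))
    populations <- setdiff(unique(pops), "reference")
  if (length(populations) != 2)
    stop("exactly two populations required")
  for (p in populations)
    if (!any(pops == p)) stop("population with zero individuals: ", p)
  poly_in <- function(pop) {
    calls <- gm$calls[, pops == pop, drop = FALSE]
    has_a <- rowSums(calls == "AA" | calls == "AB", na.rm = TRUE) > 0
    has_b <- rowSums(calls == "BB" | calls == "AB", na.rm = TRUE) > 0
    has_a & has_b
  }
  keep <- poly_in(populations[1]) & poly_in(populations[2])
  names(keep) <- rownames(gm$calls)
  keep
}

#' Run the full SNP filter cascade
#'
#' Stages, in fixed order: doubled-haploid PSV screen, heterozygote
#' excess, missingness, minor allele frequency, Hardy-Weinberg exact
#' test, and (optionally) polymorphic-in-both-populations. Each stage
#' sees only the survivors of the previous one.
#'
#' @param gm a `genotype_matrix`.
#' @param config a [filter_config()].
#' @return list: `matrix` (filtered `genotype_matrix`), `report`
#'   (data.frame: stage, n_in, n_removed, n_out), `removed` (data.frame:
#'   locus, stage, reason).
#' @export
run_filter_cascade <- function(gm, config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "filter_config"))
  report <- list(); removed <- list()
  note <- function(stage, keep, reason = NULL) {
    n_in <- length(keep)
    drop <- names(keep)[!keep]
    report[[length(report) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_removed = length(drop),
      n_out = n_in - length(drop), stringsAsFactors = FALSE)
    if (length(drop))
      removed[[length(removed) + 1]] <<- data.frame(
        locus = drop, stage = stage,
        reason = if (is.null(reason)) stage else reason[!keep],
        stringsAsFactors = FALSE)
    keep
  }
  # 1. doubled-haploid PSV screen
  dh_present <- any(gm$meta$doubled_haploid %in% TRUE)
  if (dh_present) {
    psv <- detect_psv_doubled_haploid(gm)
    keep <- !(rownames(gm$calls) %in% psv)
    names(keep) <- rownames(gm$calls)
  } else {
    warning("no doubled haploids: PSV stage skipped")
    keep <- stats::setNames(rep(TRUE, nrow(gm$calls)), rownames(gm$calls))
  }
  keep <- note("dh_psv", keep)
  gm <- subset_loci(gm, keep)
  # 2. heterozygote excess (also drops all-missing loci)
  k <- filter_het_excess(gm, config$het_excess_max)
  k <- note("het_excess", k, attr(k, "reason"))
  gm <- subset_loci(gm, k)
  # 3. missingness
  gm <- subset_loci(gm, note("missing", filter_missing(gm, config$missing_max)))
  # 4. minor allele frequency
  gm <- subset_loci(gm, note("maf", filter_maf(gm, config$maf_min)))
  # 5. Hardy-Weinberg
  gm <- subset_loci(gm, note("hwe", filter_hwe(gm, config$hwe_neglog10p_max)))
  # 6. polymorphic in both populations (combined dataset only)
  if (config$require_polymorphic_both)
    gm <- subset_loci(gm, note("polymorphic_both",
                               require_polymorphic_both(gm)))
  list(matrix = gm,
       report = do.call(rbind, report),
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(locus = character(0), stage = character(0),
                                 reason = character(0)))
}
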