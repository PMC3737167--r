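#' Nei's FST from two population allele frequencies
#'
#' `(H_T - H_S) / H_T` with `H_S` the unweighted mean within-population
#' expected heterozygosity `2 p_k q_k` and `H_T` the expected
#' heterozygosity of the unweighted mean frequency. Vectorised;
#' undefined (NA) where the pooled locus is monomorphic (`H_T = 0`).
#'
#' @param p1,p2 allele-A frequencies in the two populations.
#' @return per-locus FST in `[0, 1]` (NA where undefined).
#' @export
fst_nei <- function(p1, p2) {
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  ifelse(ht > 0, (ht - hs) / ht, NA_real_)
}

#' Weir-Cockerham theta for two populations
#'
#' Variance-components estimator (Weir & Cockerham 1984) for a biallelic
#' locus scored in two samples, using the observed heterozygote
#' frequencies. Vectorised over loci. Can be negative at finite sample
#' size; callers clip for reporting.
#'
#' @param n1,n2 diploid sample sizes (called individuals).
#' @param p1,p2 sample allele-A frequencies.
#' @param h1,h2 observed heterozygote proportions.
#' @return per-locus theta (NA where undefined, e.g. a sample of < 2 or
#'   a monomorphic pooled locus).
#' @export
fst_wc <- function(n1, n2, p1, p2, h1, h2) {
  w <- wc_components(n1, n2, p1, p2, h1, h2)
  denom <- w$a + w$b + w$c
  out <- ifelse(abs(denom) > 0 & (n1 + n2) > 2 & n1 >= 1 & n2 >= 1,
                w$a / denom, NA_real_)
  out[denom == 0] <- NA_real_
  out
}

# Weir-Cockerham (1984) variance components for two populations;
# vectorised over loci
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  list(a = a, b = b, c = hbar / 2)
}

#' Multilocus Weir-Cockerham FST (ratio of summed components)
#'
#' The canonical multilocus estimate: variance components are summed
#' over loci before taking the ratio, which removes the downward bias
#' of averaging per-locus ratios. Loci with undefined components (a
#' population sample of zero) are dropped.
#'
#' @inheritParams fst_wc
#' @return a single multilocus theta estimate.
#' @export
fst_wc_multilocus <- function(n1, n2, p1, p2, h1, h2) {
  w <- wc_components(n1, n2, p1, p2, h1, h2)
  tot <- w$a + w$b + w$c
  keep <- !is.na(tot) & n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  sum(w$a[keep]) / sum(tot[keep])
}

# per-population per-locus sample summaries from a genotype matrix
pop_locus_summary <- function(gm, population) {
  calls <- gm$calls[, gm$meta$population == population, drop = FALSE]
  n_aa <- rowSums(calls == "AA", na.rm = TRUE)
  n_ab <- rowSums(calls == "AB", na.rm = TRUE)
  n_bb <- rowSums(calls == "BB", na.rm = TRUE)
  n <- n_aa + n_ab + n_bb
  p <- ifelse(n > 0, (2 * n_aa + n_ab) / (2 * n), NA_real_)
  list(n = n, p = p, h_obs = ifelse(n > 0, n_ab / n, NA_real_),
       n_aa = n_aa, n_ab = n_ab, n_bb = n_bb)
}

#' Per-locus statistics for a two-population comparison
#'
#' Computes, per locus: sample allele frequencies in each population,
#' observed heterozygosity (pooled), expected heterozygosity of the
#' pooled frequencies (`H_E = H_T`), mean within-population expected
#' heterozygosity (`H_S`), Nei FST `(H_T - H_S)/H_T`, Weir-Cockerham
#' theta, minor allele frequency, and private-allele flags. Reported FST
#' columns are clipped to `[0, 1]`; raw values are kept in `*_raw`
#' columns. Doubled-haploid reference individuals are excluded.
#'
#' @param gm a `genotype_matrix`.
#' @param populations the two population labels (default: the
#'   non-reference labels, in order of appearance).
#' @return data.frame keyed by `locus`.
#' @export
locus_stats <- function(gm, populations = NULL) {
  pops <- gm$meta$population
  if (is.null(populations))
    populations <- setdiff(unique(pops), "reference")
  if (length(populations) != 2) stop("exactly two populations required")
  s1 <- pop_locus_summary(gm, populations[1])
  s2 <- pop_locus_summary(gm, populations[2])
  n_called <- s1$n + s2$n
  p_pool <- ifelse(n_called > 0,
                   (2 * (s1$n_aa + s2$n_aa) + s1$n_ab + s2$n_ab) /
                     (2 * n_called), NA_real_)
  h_o <- ifelse(n_called > 0, (s1$n_ab + s2$n_ab) / n_called, NA_real_)
  h_e1 <- 2 * s1$p * (1 - s1$p)
  h_e2 <- 2 * s2$p * (1 - s2$p)
  h_s <- (h_e1 + h_e2) / 2
  pbar <- (s1$p + s2$p) / 2
  h_t <- 2 * pbar * (1 - pbar)
  fst_nei_raw <- ifelse(!is.na(h_t) & h_t > 0, (h_t - h_s) / h_t, NA_real_)
  wc_raw <- fst_wc(s1$n, s2$n, s1$p, s2$p, s1$h_obs, s2$h_obs)
  has_a <- function(s) s$n_aa + s$n_ab > 0
  has_b <- function(s) s$n_bb + s$n_ab > 0
  data.frame(
    locus = rownames(gm$calls),
    n1 = s1$n, n2 = s2$n, p1 = s1$p, p2 = s2$p,
    h_o1 = s1$h_obs, h_o2 = s2$h_obs,
    h_o = h_o,
    h_e = ifelse(is.na(p_pool), NA_real_, 2 * p_pool * (1 - p_pool)),
    h_s = h_s, h_t = h_t,
    maf = pmin(p_pool, 1 - p_pool),
    fst_nei_raw = fst_nei_raw,
    fst_nei = pmin(pmax(fst_nei_raw, 0), 1),
    fst_wc_raw = wc_raw,
    fst_wc = pmin(pmax(wc_raw, 0), 1),
    private_1 = (has_a(s1) & !has_a(s2)) | (has_b(s1) & !has_b(s2)),
    private_2 = (has_a(s2) & !has_a(s1)) | (has_b(s2) & !has_b(s1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Observed/expected heterozygosity components
#'
#' Convenience wrapper around [locus_stats()] returning only the
#' heterozygosity columns (`h_o`, `h_e`, `h_s`, `h_t`).
#' @inheritParams locus_stats
#' @export
heterozygosities <- function(gm, populations = NULL) {
  locus_stats(gm, populations)[, c("locus", "h_o", "h_e", "h_s", "h_t")]
}

#' Pairwise per-locus FST and its mean
#'
#' @inheritParams locus_stats
#' @param method `"nei"` (default, `(H_T - H_S)/H_T`) or `"wc"`
#'   (Weir-Cockerham theta).
#' @return list: `per_locus` (data.frame locus, fst, fst_raw), `mean`
#'   (mean of raw per-locus values over defined loci), and `global` (for
#'   `"wc"` the multilocus ratio-of-sums estimate, for `"nei"` the ratio
#'   of mean heterozygosities).
#' @export
pairwise_fst <- function(gm, populations = NULL,
                         method = c("nei", "wc")) {
  method <- match.arg(method)
  ls <- locus_stats(gm, populations)
  raw <- if (method == "nei") ls$fst_nei_raw else ls$fst_wc_raw
  clip <- if (method == "nei") ls$fst_nei else ls$fst_wc
  global <- if (method == "wc")
    fst_wc_multilocus(ls$n1, ls$n2, ls$p1, ls$p2, ls$h_o1, ls$h_o2)
  else
    (mean(ls$h_t, na.rm = TRUE) - mean(ls$h_s, na.rm = TRUE)) /
      mean(ls$h_t, na.rm = TRUE)
  list(per_locus = data.frame(locus = ls$locus, fst = clip, fst_raw = raw,
                              stringsAsFactors = FALSE),
       mean = mean(raw, na.rm = TRUE), global = global)
}

#' Private-allele locus lists per population
#'
#' An allele is private to a population when it is observed there and
#' absent (among called genotypes) from the other population.
#'
#' @inheritParams locus_stats
#' @return list with per-population locus-id vectors and totals.
#' @export
private_alleles <- function(gm, populations = NULL) {
  ls <- locus_stats(gm, populations)
  pops <- if (is.null(populations))
    setdiff(unique(gm$meta$population), "reference") else populations
  out <- list(ls$locus[ls$private_1 %in% TRUE],
              ls$locus[ls$private_2 %in% TRUE])
  names(out) <- pops
  out$totals <- lengths(out[1:2])
  out
}

#' Tajima (1989) constants for sample size n
#'
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`, and the derived
#' `b1, b2, c1, c2, e1, e2` used to normalise Tajima's D.
#'
#' @param n number of sampled alleles (>= 2).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be at least 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Watterson's theta from segregating sites
#'
#' @param s number of segregating sites (>= 0).
#' @param n number of sampled alleles (>= 2).
#' @return `theta_w = S / a1(n)`.
#' @export
watterson_theta <- function(s, n) {
  stopifnot(s >= 0)
  s / tajima_constants(n)$a1
}

#' Mean pairwise differences (pi) from per-site allele counts
#'
#' `pi = sum_i 2 k_i (n - k_i) / (n (n - 1))` over sites, where `k_i` is
#' either allele's count among `n` sampled alleles (the term is
#' symmetric in `k` and `n - k`).
#'
#' @param k per-site allele counts.
#' @param n sampled alleles per site (scalar or per-site vector, >= 2).
#' @return pi for the window.
#' @export
pairwise_pi <- function(k, n) {
  if (any(n < 2)) stop("n must be at least 2")
  sum(2 * k * (n - k) / (n * (n - 1)))
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Defined only for
#' `S > 0` and `n >= 4`; otherwise NA.
#'
#' @param pi mean pairwise differences in the window.
#' @param s segregating sites.
#' @param n sampled alleles.
#' @return Tajima's D (NA when undefined).
#' @export
tajimas_d <- function(pi, s, n) {
  if (s <= 0 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  (pi - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Window configuration for the diversity scan
#'
#' @param window_bp window size in bp (tags are 89 bp, so each tag is
#'   one window at the default 100).
#' @param min_rare_count minimum minor-allele count for a site to enter
#'   the window (default 2).
#' @param min_coverage minimum sampled alleles at a site (default 4).
#' @param pool_n nominal pool size; used as the sample size for the
#'   Tajima/Watterson constants when `n_mode = "pool"`.
#' @param n_mode `"sample"` (default) takes n = 2 x called individuals
#'   at the site; `"pool"` uses `pool_n` regardless (emulating a pooled
#'   run at a fixed nominal size).
#' @return list of class `window_config`.
#' @export
window_config <- function(window_bp = 100L, min_rare_count = 2L,
                          min_coverage = 4L, pool_n = 50L,
                          n_mode = c("sample", "pool")) {
  n_mode <- match.arg(n_mode)
  stopifnot(window_bp >= 1, min_rare_count >= 0, min_coverage >= 2,
            pool_n >= 2)
  structure(list(window_bp = as.integer(window_bp),
                 min_rare_count = as.integer(min_rare_count),
                 min_coverage = as.integer(min_coverage),
                 pool_n = as.integer(pool_n), n_mode = n_mode),
            class = "window_config")
}

#' Windowed diversity scan: S, pi, Watterson's theta, Tajima's D
#'
#' Each RAD tag is one window (tags are shorter than the window size).
#' Within the chosen population, a site enters the window only if its
#' minor-allele count reaches `min_rare_count` and its coverage (sampled
#' alleles) reaches `min_coverage`; windows whose every site fails are
#' flagged not evaluable (S = 0).
#'
#' @param gm a `genotype_matrix`.
#' @param population population label to scan.
#' @param config a [window_config()].
#' @return data.frame: locus, n (sampled alleles), s, pi, theta_w,
#'   tajima_d, evaluable.
#' @export
windowed_scan <- function(gm, population, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  if (!any(gm$meta$population == population))
    stop("no individuals in population ", population)
  s <- pop_locus_summary(gm, population)
  n_site <- 2L * s$n
  count_a <- 2 * s$n_aa + s$n_ab
  k_minor <- pmin(count_a, n_site - count_a)
  n_eff <- if (config$n_mode == "pool") rep(config$pool_n, length(n_site))
           else n_site
  pass <- k_minor >= config$min_rare_count & n_site >= config$min_coverage &
    k_minor > 0 & n_eff >= 2
  out <- data.frame(locus = rownames(gm$calls), n = n_eff,
                    s = as.integer(pass), pi = 0, theta_w = 0,
                    tajima_d = NA_real_, evaluable = pass,
                    stringsAsFactors = FALSE, row.names = NULL)
  idx <- which(pass)
  if (length(idx)) {
    # pi from the sampled alleles; the Tajima/Watterson constants use
    # n_eff (nominal pool size in pool mode, sampled alleles otherwise)
    out$pi[idx] <- 2 * k_minor[idx] * (n_site[idx] - k_minor[idx]) /
      (n_site[idx] * (n_site[idx] - 1))
    out$theta_w[idx] <- vapply(idx, function(i)
      watterson_theta(1L, n_eff[i]), numeric(1))
    out$tajima_d[idx] <- vapply(idx, function(i)
      tajimas_d(out$pi[i], 1L, n_eff[i]), numeric(1))
  }
  out
}
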