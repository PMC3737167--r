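#' Gaussian kernel-smoothing configuration
#'
#' @param sigma bandwidth in centimorgans (default 5). Map positions are
#'   genetic, so the bandwidth is genetic too.
#' @param truncation markers beyond this distance get zero weight
#'   (default `3 * sigma`).
#' @param step evaluation-grid spacing in cM (default 0.5).
#' @return list of class `smooth_config`.
#' @export
smooth_config <- function(sigma = 5, truncation = 3 * sigma, step = 0.5) {
  stopifnot(sigma > 0, truncation >= sigma, step > 0)
  structure(list(sigma = sigma, truncation = truncation, step = step),
            class = "smooth_config")
}

#' Gaussian kernel smoothing of a statistic along one chromosome
#'
#' At each grid point c the smoothed value is the weighted mean
#' `sum(w_j v_j) / sum(w_j)` with `w_j = exp(-d_j^2 / (2 sigma^2))` over
#' markers within the truncation distance. Grid points with no marker in
#' range are reported as NA (gaps).
#'
#' @param positions marker positions in cM (one chromosome).
#' @param values statistic values at the markers (same length; NA
#'   markers are dropped).
#' @param config a [smooth_config()].
#' @param grid evaluation positions; default a regular grid spanning the
#'   markers at `config$step`.
#' @return data.frame: `position_cm`, `value`, `n_markers` (markers in
#'   range).
#' @export
kernel_smooth <- function(positions, values, config = smooth_config(),
                          grid = NULL) {
  stopifnot(length(positions) == length(values))
  ok <- !is.na(positions) & !is.na(values)
  positions <- positions[ok]; values <- values[ok]
  if (!length(positions))
    return(data.frame(position_cm = numeric(0), value = numeric(0),
                      n_markers = integer(0)))
  if (is.null(grid))
    grid <- seq(min(positions), max(positions), by = config$step)
  sm <- vapply(grid, function(g) {
    d <- abs(positions - g)
    in_range <- d <= config$truncation
    if (!any(in_range)) return(c(NA_real_, 0))
    w <- exp(-d[in_range]^2 / (2 * config$sigma^2))
    c(sum(w * values[in_range]) / sum(w), sum(in_range))
  }, numeric(2))
  data.frame(position_cm = grid, value = sm[1, ],
             n_markers = as.integer(sm[2, ]))
}

#' Kernel-smoothed tracks for all chromosomes of a map
#'
#' @param map data.frame (`locus`, `chromosome`, `position_cm`).
#' @param stats data.frame with `locus` and the column named by
#'   `value_col`.
#' @param value_col which statistic to smooth.
#' @param config a [smooth_config()].
#' @return data.frame: `chromosome`, `position_cm`, `value`,
#'   `n_markers`.
#' @export
smooth_by_chromosome <- function(map, stats, value_col,
                                 config = smooth_config()) {
  merged <- merge(map, stats[, c("locus", value_col)], by = "locus")
  out <- lapply(split(merged, merged$chromosome), function(d) {
    tr <- kernel_smooth(d$position_cm, d[[value_col]], config)
    if (nrow(tr)) cbind(chromosome = d$chromosome[1], tr)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' EM haplotype-frequency inference for two biallelic loci
#'
#' Standard two-locus EM for unphased diploid genotypes: only double
#' heterozygotes are phase-ambiguous; the E-step splits them between the
#' coupling (AB/ab) and repulsion (Ab/aB) phases in proportion to the
#' current haplotype-frequency products, and the M-step re-counts.
#' Iterates until the largest frequency change is below `tol`.
#'
#' @param g1,g2 allele-A dosage vectors (0/1/2, NA allowed) at the two
#'   loci; individuals missing either locus are dropped
#'   (pairwise-complete).
#' @param tol convergence tolerance (1e-8).
#' @param max_iter iteration cap (1000).
#' @return list: `freq` (named: AB, Ab, aB, ab — A/a at locus 1, B/b at
#'   locus 2), `iterations`, `loglik`, `n` (individuals used).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 1) stop("no individuals with calls at both loci")
  if (length(unique(g1)) == 1 || length(unique(g2)) == 1)
    stop("monomorphic_pair: a locus is monomorphic among complete pairs")
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  # haplotype counts fixed by unambiguous genotypes; x = coupling weight
  # of the n11 double heterozygotes
  n11 <- tab["1", "1"]
  base_AB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
  base_Ab <- 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"]
  base_aB <- 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"]
  base_ab <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
  freq <- rep(0.25, 4)
  tot <- 2 * n
  for (it in seq_len(max_iter)) {
    coup <- freq[1] * freq[4]
    rep_ <- freq[2] * freq[3]
    x <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    new <- c(base_AB + x * n11, base_Ab + (1 - x) * n11,
             base_aB + (1 - x) * n11, base_ab + x * n11) / tot
    delta <- max(abs(new - freq))
    freq <- new
    if (delta < tol) break
  }
  names(freq) <- c("AB", "Ab", "aB", "ab")
  ll <- sum(tab * log(pmax(genotype_probs(freq), 1e-300)))
  list(freq = freq, iterations = it, loglik = ll, n = n)
}

# 3x3 genotype-class probabilities implied by haplotype frequencies
genotype_probs <- function(freq) {
  h <- matrix(0, 3, 3)  # rows: dosage at locus1; cols: locus2
  f <- freq
  h[3, 3] <- f["AB"]^2
  h[3, 2] <- 2 * f["AB"] * f["Ab"]
  h[3, 1] <- f["Ab"]^2
  h[2, 3] <- 2 * f["AB"] * f["aB"]
  h[2, 2] <- 2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"])
  h[2, 1] <- 2 * f["Ab"] * f["ab"]
  h[1, 3] <- f["aB"]^2
  h[1, 2] <- 2 * f["aB"] * f["ab"]
  h[1, 1] <- f["ab"]^2
  h
}

#' Lewontin's D' from four haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D_max` is the tighter of the frequency bounds
#' in the direction of D's sign; `D' = |D| / D_max`.
#'
#' @param freq named haplotype frequencies (AB, Ab, aB, ab) summing to 1.
#' @return list: `d`, `d_max`, `d_prime` (NA when `D_max = 0`, i.e. a
#'   monomorphic locus).
#' @export
d_prime <- function(freq) {
  stopifnot(abs(sum(freq) - 1) < 1e-6)
  p_a <- freq[["AB"]] + freq[["Ab"]]
  p_b <- freq[["AB"]] + freq[["aB"]]
  d <- freq[["AB"]] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  dp <- if (d_max > 0) min(abs(d) / d_max, 1) else NA_real_  # |D| <= D_max
  list(d = d, d_max = d_max, d_prime = dp)
}

#' Chromosome-level D' summaries for one population
#'
#' Computes D' by EM haplotype inference for every pair of mapped loci
#' on the same chromosome (pairwise-complete genotypes), then the mean
#' and standard error per chromosome and the overall mean. Chromosomes
#' with fewer than two mapped markers, and pairs that are monomorphic or
#' have `D_max = 0`, are skipped.
#'
#' @param gm a `genotype_matrix`.
#' @param map data.frame (`locus`, `chromosome`, `position_cm`).
#' @param population population label.
#' @return list: `pairs` (locus_i, locus_j, chromosome, distance_cm,
#'   d, d_prime), `per_chromosome` (chromosome, n_pairs, mean_d_prime,
#'   se), `overall_mean`.
#' @export
chromosome_ld_summary <- function(gm, map, population) {
  dos <- dosage(gm)[, gm$meta$population == population, drop = FALSE]
  map <- map[map$locus %in% rownames(dos), , drop = FALSE]
  pair_rows <- list()
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- utils::combn(nrow(sub), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      gi <- dos[sub$locus[i], ]; gj <- dos[sub$locus[j], ]
      em <- tryCatch(em_haplotype_freqs(gi, gj), error = function(e) NULL)
      if (is.null(em)) next
      dp <- d_prime(em$freq)
      if (is.na(dp$d_prime)) next
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        locus_i = sub$locus[i], locus_j = sub$locus[j], chromosome = chr,
        distance_cm = abs(sub$position_cm[i] - sub$position_cm[j]),
        d = dp$d, d_prime = dp$d_prime, stringsAsFactors = FALSE)
    }
  }
  if (!length(pair_rows))
    return(list(pairs = NULL, per_chromosome = NULL, overall_mean = NA_real_))
  pairs <- do.call(rbind, pair_rows)
  per <- do.call(rbind, lapply(split(pairs, pairs$chromosome), function(d)
    data.frame(chromosome = d$chromosome[1], n_pairs = nrow(d),
               mean_d_prime = mean(d$d_prime),
               se = stats::sd(d$d_prime) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  list(pairs = pairs, per_chromosome = per,
       overall_mean = mean(pairs$d_prime))
}

#' Compare chromosome-wide D' between two populations
#'
#' Welch two-sample, two-tailed t-test on the vectors of per-chromosome
#' mean D'. Degenerate zero-variance inputs with equal means return
#' `t = 0, p = 1`.
#'
#' @param means1,means2 per-chromosome mean D' vectors.
#' @return list: `t`, `p`, `df`, `mean1`, `mean2`.
#' @export
compare_ld_populations <- function(means1, means2) {
  means1 <- means1[!is.na(means1)]; means2 <- means2[!is.na(means2)]
  if (length(means1) < 2 || length(means2) < 2)
    stop("need at least two chromosome means per population")
  if (stats::sd(means1) == 0 && stats::sd(means2) == 0) {
    same <- isTRUE(all.equal(mean(means1), mean(means2)))
    return(list(t = if (same) 0 else sign(mean(means1) - mean(means2)) * Inf,
                p = if (same) 1 else 0,
                df = length(means1) + length(means2) - 2,
                mean1 = mean(means1), mean2 = mean(means2)))
  }
  tt <- stats::t.test(means1, means2, alternative = "two.sided",
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean1 = mean(means1), mean2 = mean(means2))
}

#' Call peak regions on a smoothed track
#'
#' Contiguous grid runs above a percentile of the track's defined values.
#'
#' @param track output of [kernel_smooth()] (one chromosome).
#' @param percentile threshold percentile (default 95).
#' @return data.frame: `start_cm`, `end_cm`, `max_value`, or an empty
#'   frame when nothing exceeds the threshold.
#' @export
track_peaks <- function(track, percentile = 95) {
  v <- track$value
  thr <- stats::quantile(v, percentile / 100, na.rm = TRUE, names = FALSE)
  above <- !is.na(v) & v > thr
  if (!any(above))
    return(data.frame(start_cm = numeric(0), end_cm = numeric(0),
                      max_value = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  data.frame(
    start_cm = track$position_cm[starts[runs]],
    end_cm = track$position_cm[ends[runs]],
    max_value = vapply(runs, function(k)
      max(v[starts[k]:ends[k]]), numeric(1)))
}
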