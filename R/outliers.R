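#' Configuration of the simulation-based FST outlier test
#'
#' Reimplements the FDIST/LOSITAN logic: simulate a large panel of
#' neutral loci under a Balding-Nichols island model calibrated to the
#' observed mean FST, then score each observed locus by the fraction of
#' simulated loci (in its expected-heterozygosity bin) with lower FST.
#'
#' @param n_sims simulated neutral loci (default 55000).
#' @param ci probability threshold for candidate positive selection
#'   (default 0.995).
#' @param fdr Benjamini-Hochberg false-discovery-rate level applied to
#'   `1 - P` (default 0.05).
#' @param neutral_band loci with P strictly inside this band are called
#'   neutral (default `c(0.1, 0.9)`).
#' @param he_bins number of equal-count heterozygosity bins (default
#'   20); bins are merged so that none holds fewer than `min_bin` sims.
#' @param min_bin minimum simulated loci per bin (default 50).
#' @param method FST estimator shared by observed and simulated loci:
#'   `"wc"` (Weir-Cockerham, default — the FDIST convention) or `"nei"`.
#' @param trim envelope quantile used to trim observed outliers from the
#'   calibration target mean (default 0.99).
#' @param tol convergence tolerance on the simulated mean FST (0.002).
#' @param max_iter calibration iteration cap (50).
#' @param calib_sims simulated loci per calibration iteration.
#' @param freq_range ancestral-frequency support of the neutral model.
#' @param seed optional integer seed for the simulation.
#' @return list of class `outlier_config`.
#' @export
outlier_config <- function(n_sims = 55000L, ci = 0.995, fdr = 0.05,
                           neutral_band = c(0.1, 0.9), he_bins = 20L,
                           min_bin = 50L, method = c("wc", "nei"),
                           trim = 0.99, tol = 0.002, max_iter = 50L,
                           calib_sims = 10000L,
                           freq_range = c(0.05, 0.95), seed = NULL) {
  method <- match.arg(method)
  stopifnot(ci > 0, ci < 1, fdr > 0, fdr < 1,
            length(neutral_band) == 2, neutral_band[1] > 0,
            neutral_band[2] < 1, neutral_band[1] < neutral_band[2],
            he_bins >= 1, min_bin >= 1, tol > 0, max_iter >= 1)
  if (n_sims < he_bins * 100)
    stop("n_sims must be at least he_bins * 100")
  structure(list(n_sims = as.integer(n_sims), ci = ci, fdr = fdr,
                 neutral_band = neutral_band, he_bins = as.integer(he_bins),
                 min_bin = as.integer(min_bin), method = method,
                 trim = trim, tol = tol, max_iter = as.integer(max_iter),
                 calib_sims = as.integer(calib_sims),
                 freq_range = freq_range,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "outlier_config")
}

# draw joint genotype counts (nAA, nAB, nBB) for m loci in one population
# of n diploids with per-locus frequency p, by multinomial decomposition
draw_genotype_counts <- function(n, p) {
  m <- length(p)
  paa <- p^2
  n_aa <- stats::rbinom(m, n, paa)
  cond <- ifelse(paa < 1, 2 * p * (1 - p) / (1 - paa), 0)
  n_ab <- stats::rbinom(m, n - n_aa, pmin(cond, 1))
  list(n_aa = n_aa, n_ab = n_ab, n_bb = n - n_aa - n_ab)
}

#' Simulate a neutral (H_E, FST) reference table
#'
#' Each simulated locus draws an ancestral frequency uniformly on
#' `freq_range`, two population frequencies from the Balding-Nichols
#' prior with divergence `f`, and genotype samples of the given sizes;
#' H_E (pooled expected heterozygosity) and FST use the same estimator
#' applied to observed loci.
#'
#' @param f Balding-Nichols divergence parameter of the null.
#' @param n1,n2 diploid sample sizes of the two populations.
#' @param config an [outlier_config()]; `config$n_sims` loci are drawn
#'   unless `n_sims` overrides.
#' @param n_sims optional override of the table size.
#' @return data.frame of class `neutral_sim_table`: `he`, `fst` (clipped
#'   to `[0, 1]`), `fst_raw`.
#' @export
simulate_null <- function(f, n1, n2, config = outlier_config(),
                          n_sims = config$n_sims) {
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- n_sims
  p <- stats::runif(m, config$freq_range[1], config$freq_range[2])
  p1 <- rbalding_nichols(p, f)
  p2 <- rbalding_nichols(p, f)
  g1 <- draw_genotype_counts(n1, p1)
  g2 <- draw_genotype_counts(n2, p2)
  ph1 <- (2 * g1$n_aa + g1$n_ab) / (2 * n1)
  ph2 <- (2 * g2$n_aa + g2$n_ab) / (2 * n2)
  p_pool <- (2 * (g1$n_aa + g2$n_aa) + g1$n_ab + g2$n_ab) / (2 * (n1 + n2))
  he <- 2 * p_pool * (1 - p_pool)
  raw <- if (config$method == "wc")
    fst_wc(n1, n2, ph1, ph2, g1$n_ab / n1, g2$n_ab / n2)
  else
    fst_nei(ph1, ph2)
  raw[is.na(raw)] <- 0  # monomorphic draws carry no divergence signal
  out <- data.frame(he = he, fst = pmin(pmax(raw, 0), 1), fst_raw = raw)
  class(out) <- c("neutral_sim_table", "data.frame")
  out
}

#' Calibrate the neutral divergence parameter to observed FST
#'
#' Iteratively adjusts the Balding-Nichols `F` until the mean simulated
#' FST matches the trimmed mean of the observed per-locus FST (observed
#' loci beyond the current simulated `trim` quantile are excluded from
#' the target, so strong outliers do not inflate the null) to within
#' `tol`.
#'
#' @param obs_fst observed per-locus FST values (raw scale).
#' @param n1,n2 diploid sample sizes.
#' @param config an [outlier_config()].
#' @return list: `f_star`, `sim_mean` (achieved simulated mean),
#'   `target` (final trimmed observed mean), `iterations`, `converged`.
#' @export
calibrate_null <- function(obs_fst, n1, n2, config = outlier_config()) {
  obs_fst <- obs_fst[!is.na(obs_fst)]
  if (!length(obs_fst)) stop("no observed FST values")
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL     # RNG already positioned
  lower <- 1e-4; upper <- 0.9
  f <- min(max(mean(pmax(obs_fst, 0)), lower), upper)
  sim_mean <- NA_real_; target <- NA_real_
  for (it in seq_len(config$max_iter)) {
    sims <- simulate_null(f, n1, n2, cfg, n_sims = config$calib_sims)
    env <- stats::quantile(sims$fst_raw, config$trim, names = FALSE)
    target <- mean(obs_fst[obs_fst <= env])
    target <- max(target, 0)
    sim_mean <- mean(sims$fst_raw)
    if (abs(sim_mean - target) <= config$tol)
      return(list(f_star = f, sim_mean = sim_mean, target = target,
                  iterations = it, converged = TRUE))
    # mean simulated FST is close to linear in F near the root
    adjust <- target - sim_mean
    f <- min(max(f + adjust, lower), upper)
    if (f <= lower && target <= config$tol)
      return(list(f_star = lower, sim_mean = sim_mean, target = target,
                  iterations = it, converged = TRUE))
  }
  stop(sprintf(paste0("calibration did not converge in %d iterations ",
                      "(F = %.4f, simulated mean = %.4f, target = %.4f)"),
               config$max_iter, f, sim_mean, target))
}

# equal-count heterozygosity bin edges over the simulated table,
# merged so every bin holds at least min_bin simulated loci
he_bin_edges <- function(he, he_bins, min_bin) {
  n <- length(he)
  k <- max(1L, min(he_bins, floor(n / min_bin)))
  edges <- unique(stats::quantile(he, probs = seq(0, 1, length.out = k + 1),
                                  names = FALSE))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  edges
}

#' Conditional outlier probability of observed loci
#'
#' For each observed locus, P is the fraction of simulated neutral loci
#' in the locus's expected-heterozygosity bin whose FST lies strictly
#' below the observed value, with ties counted half. The comparison is
#' made on the raw (unclipped) estimator scale: clipping negative
#' estimates to zero would put a probability atom at zero FST and break
#' the uniformity of null P-values. Loci whose H_E falls outside every
#' bin use the nearest bin and are flagged.
#'
#' @param fst observed per-locus FST on the raw estimator scale.
#' @param he observed per-locus expected heterozygosity.
#' @param sims a [simulate_null()] table.
#' @param config an [outlier_config()].
#' @return data.frame: `p` (in `[0, 1]`), `bin`, `out_of_range`.
#' @export
outlier_probability <- function(fst, he, sims,
                                config = outlier_config()) {
  stopifnot(length(fst) == length(he))
  sims$fst <- sims$fst_raw
  edges <- he_bin_edges(sims$he, config$he_bins, config$min_bin)
  sim_bin <- findInterval(sims$he, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  obs_bin <- findInterval(he, edges, rightmost.closed = TRUE)
  out_of_range <- is.na(he) | he < min(sims$he) | he > max(sims$he)
  obs_bin[is.na(obs_bin) | obs_bin < 1] <- 1L
  obs_bin[obs_bin > nb] <- nb
  p <- rep(NA_real_, length(fst))
  for (b in unique(obs_bin)) {
    sf <- sort(sims$fst[sim_bin == b])
    io <- which(obs_bin == b & !is.na(fst))
    if (!length(sf) || !length(io)) next
    below <- findInterval(fst[io], sf, left.open = TRUE)   # strictly below
    at_or_below <- findInterval(fst[io], sf)               # <=
    p[io] <- (below + 0.5 * (at_or_below - below)) / length(sf)
  }
  data.frame(p = p, bin = obs_bin, out_of_range = out_of_range)
}

#' Classify loci from outlier probabilities
#'
#' Candidate for positive selection: `P > ci` and surviving
#' Benjamini-Hochberg at level `fdr` applied to `1 - P`. Neutral:
#' P strictly inside `neutral_band`. Everything else is unclassified
#' (there is no balancing-selection class: such loci cannot be
#' distinguished from zero-FST loci in this design).
#'
#' @param p outlier probabilities.
#' @param config an [outlier_config()].
#' @return data.frame: `p`, `q` (BH-adjusted `1 - P`), `class` in
#'   `candidate_positive/neutral/unclassified`.
#' @export
classify_loci <- function(p, config = outlier_config()) {
  q <- stats::p.adjust(1 - p, method = "BH")
  cls <- rep("unclassified", length(p))
  cls[!is.na(p) & p > config$neutral_band[1] &
        p < config$neutral_band[2]] <- "neutral"
  cls[!is.na(p) & p > config$ci & q <= config$fdr] <- "candidate_positive"
  data.frame(p = p, q = q, class = cls, stringsAsFactors = FALSE)
}

#' End-to-end FST outlier scan
#'
#' Computes per-locus FST and H_E with the configured estimator,
#' calibrates the neutral divergence parameter, simulates the neutral
#' reference table, and classifies every locus.
#'
#' @param gm a `genotype_matrix`.
#' @param populations the two population labels (default non-reference).
#' @param config an [outlier_config()].
#' @return list: `table` (locus, fst, he, p, q, class), `f_star`,
#'   `sim_mean`, `sims` (the neutral table), `calibration`.
#' @export
fst_outlier_scan <- function(gm, populations = NULL,
                             config = outlier_config()) {
  ls <- locus_stats(gm, populations)
  fst <- if (config$method == "wc") ls$fst_wc else ls$fst_nei
  n1 <- round(stats::median(ls$n1)); n2 <- round(stats::median(ls$n2))
  raw <- if (config$method == "wc") ls$fst_wc_raw else ls$fst_nei_raw
  cal <- calibrate_null(raw, n1, n2, config)
  cfg <- config; cfg$seed <- NULL
  sims <- simulate_null(cal$f_star, n1, n2, cfg)
  op <- outlier_probability(raw, ls$h_e, sims, config)
  cl <- classify_loci(op$p, config)
  list(table = data.frame(locus = ls$locus, fst = fst, he = ls$h_e,
                          p = op$p, q = cl$q, class = cl$class,
                          out_of_range = op$out_of_range,
                          stringsAsFactors = FALSE),
       f_star = cal$f_star, sim_mean = cal$sim_mean, sims = sims,
       calibration = cal)
}
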