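#' Run the full analysis pipeline on one synthetic study
#'
#' Simulates a two-population study, calls genotypes, applies the filter
#' cascade, computes per-locus and windowed statistics, runs the FST
#' outlier scan, smooths FST along the linkage map, and summarises
#' chromosome-level LD in both populations. One seed governs every
#' stochastic stage, so two runs with the same arguments are
#' bit-identical.
#'
#' @param config a [sim_config()] (its `seed` field is ignored;
#'   `seed` below governs).
#' @param seed integer seed for the whole run.
#' @param thresholds a [genotype_thresholds()].
#' @param filter a [filter_config()].
#' @param outlier an [outlier_config()].
#' @param window a [window_config()].
#' @param smooth a [smooth_config()].
#' @param run_ld compute LD summaries (EM over all mapped same-chromosome
#'   pairs; the slowest stage).
#' @return list with every stage's outputs: `sim`, `genotypes`,
#'   `filter_report`, `filtered`, `locus_stats`, `windows` (per
#'   population), `outliers`, `fst_track`, `ld` (per population and the
#'   between-population test).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L,
                         thresholds = genotype_thresholds(),
                         filter = filter_config(),
                         outlier = outlier_config(n_sims = 10000L),
                         window = window_config(),
                         smooth = smooth_config(),
                         run_ld = TRUE) {
  set.seed(seed)
  config$seed <- NULL      # a single RNG stream for the whole run
  outlier$seed <- NULL
  sim <- simulate_study(config)
  gm <- call_matrix(sim$counts, thresholds)
  fc <- run_filter_cascade(gm, filter)
  gmf <- fc$matrix
  ls <- locus_stats(gmf)
  pops <- setdiff(unique(gm$meta$population), "reference")
  windows <- lapply(stats::setNames(pops, pops), function(p)
    windowed_scan(gmf, p, window))
  os <- fst_outlier_scan(gmf, pops, outlier)
  fst_stats <- data.frame(locus = ls$locus, fst = ls$fst_wc)
  fst_track <- smooth_by_chromosome(sim$map, fst_stats, "fst", smooth)
  ld <- NULL
  if (run_ld) {
    ld1 <- chromosome_ld_summary(gmf, sim$map, pops[1])
    ld2 <- chromosome_ld_summary(gmf, sim$map, pops[2])
    cmp <- if (!is.null(ld1$per_chromosome) && !is.null(ld2$per_chromosome) &&
               nrow(ld1$per_chromosome) >= 2 && nrow(ld2$per_chromosome) >= 2)
      compare_ld_populations(ld1$per_chromosome$mean_d_prime,
                             ld2$per_chromosome$mean_d_prime)
    ld <- stats::setNames(list(ld1, ld2, cmp), c(pops, "comparison"))
  }
  list(sim = sim, genotypes = gm, filter_report = fc$report,
       removed = fc$removed, filtered = gmf, locus_stats = ls,
       windows = windows, outliers = os, fst_track = fst_track, ld = ld)
}
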