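#' Simulation configuration for a two-population RAD-seq study
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a two-ecotype (migrant vs. resident) sampling design:
#' two population samples drawn from a common ancestral gene pool under a
#' Balding-Nichols island model, a minority of divergently selected loci,
#' collapsed paralogs (PSVs), two doubled-haploid reference individuals,
#' Poisson sequencing depth with a small per-read allele-flip error rate,
#' and a partial linkage map over 29 chromosomes.
#'
#' @param n_loci total number of biallelic RAD loci (one SNP per 89-bp tag).
#' @param n_divergent number of loci drawn with `fst_divergent` instead of
#'   `fst_neutral` (divergent selection analogue).
#' @param n_psv number of paralogous-sequence-variant loci: their reads are
#'   the union of two duplicated, oppositely fixed copies, so nearly every
#'   individual (including doubled haploids) appears heterozygous.
#' @param n_rare number of planted sub-MAF loci, fixed at `rare_freq` in
#'   both populations (diagnostic class for the MAF filter).
#' @param n_lowdepth number of planted low-coverage loci sequenced at
#'   Poisson mean `lowdepth_mean` (diagnostic class for the missingness
#'   filter: most individuals fall under the 8-read calling floor, but
#'   enough are called that no other stage reacts first).
#' @param ancestral_freq_dist `"uniform"` draws ancestral frequencies
#'   uniformly on `freq_range`; `"sfs"` draws them from a neutral-SFS
#'   density proportional to 1/x on `freq_range` (used for allele
#'   frequency-spectrum checks).
#' @param freq_range support of the ancestral frequency distribution.
#' @param fst_neutral,fst_divergent Balding-Nichols divergence parameters
#'   for neutral and divergent loci; `0 < fst_neutral < fst_divergent < 1`.
#' @param n_per_pop diploid individuals sampled per population.
#' @param mean_depth expected total reads per locus per individual.
#' @param depth_dispersion `NULL` for Poisson depth; otherwise the
#'   `size` parameter of a negative binomial (overdispersed) depth model.
#' @param error_rate per-read probability that the read reports the other
#'   allele; must lie in `[0, 0.1]`.
#' @param rare_freq planted frequency of the `n_rare` loci.
#' @param lowdepth_mean Poisson mean depth of the `n_lowdepth` loci.
#' @param n_doubled_haploid doubled-haploid reference individuals
#'   (homozygous everywhere except at PSVs).
#' @param n_chromosomes,map_length_cm,map_fraction linkage-map geometry:
#'   number of chromosomes, per-chromosome length in centimorgans, and the
#'   fraction of loci that receive a map position.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_loci = 2000,
                       n_divergent = 100,
                       n_psv = 100,
                       n_rare = 0,
                       n_lowdepth = 0,
                       ancestral_freq_dist = c("uniform", "sfs"),
                       freq_range = c(0.05, 0.95),
                       fst_neutral = 0.03,
                       fst_divergent = 0.4,
                       n_per_pop = 50,
                       mean_depth = 30,
                       depth_dispersion = NULL,
                       error_rate = 0.005,
                       rare_freq = 0.001,
                       lowdepth_mean = 6,
                       n_doubled_haploid = 2,
                       n_chromosomes = 29,
                       map_length_cm = 100,
                       map_fraction = 0.25,
                       seed = NULL) {
  ancestral_freq_dist <- match.arg(ancestral_freq_dist)
  stopifnot(
    n_loci >= 1, n_divergent >= 0, n_psv >= 0, n_rare >= 0, n_lowdepth >= 0,
    n_per_pop >= 1, n_doubled_haploid >= 0, n_chromosomes >= 1,
    mean_depth > 0, lowdepth_mean > 0, map_length_cm > 0,
    map_fraction >= 0, map_fraction <= 1,
    length(freq_range) == 2, freq_range[1] > 0, freq_range[2] < 1,
    freq_range[1] < freq_range[2],
    rare_freq > 0, rare_freq < 0.5
  )
  if (!(fst_neutral > 0 && fst_divergent > fst_neutral && fst_divergent < 1))
    stop("need 0 < fst_neutral < fst_divergent < 1")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]")
  if (n_divergent + n_psv + n_rare + n_lowdepth > n_loci)
    stop("planted locus classes exceed n_loci")
  if (!is.null(depth_dispersion) && depth_dispersion <= 0)
    stop("depth_dispersion must be positive (or NULL for Poisson)")
  cfg <- list(
    n_loci = as.integer(n_loci), n_divergent = as.integer(n_divergent),
    n_psv = as.integer(n_psv), n_rare = as.integer(n_rare),
    n_lowdepth = as.integer(n_lowdepth),
    ancestral_freq_dist = ancestral_freq_dist, freq_range = freq_range,
    fst_neutral = fst_neutral, fst_divergent = fst_divergent,
    n_per_pop = as.integer(n_per_pop), mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, error_rate = error_rate,
    rare_freq = rare_freq, lowdepth_mean = lowdepth_mean,
    n_doubled_haploid = as.integer(n_doubled_haploid),
    n_chromosomes = as.integer(n_chromosomes),
    map_length_cm = map_length_cm, map_fraction = map_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# density proportional to 1/x on [lo, hi]: inverse-CDF draw
rsfs <- function(n, lo, hi) lo * (hi / lo)^stats::runif(n)

#' Draw one Balding-Nichols population frequency per locus
#'
#' Given ancestral frequency `p` and divergence parameter `F`, the
#' population frequency is Beta(p(1-F)/F, (1-p)(1-F)/F): mean `p`,
#' variance `F p (1-p)` — the island-model prior whose expected
#' Weir-Cockerham FST equals `F`.
#'
#' @param p ancestral frequencies (vector).
#' @param f divergence parameter(s) in (0,1), recycled against `p`.
#' @return sampled population frequencies.
#' @export
rbalding_nichols <- function(p, f) {
  if (any(f <= 0 | f >= 1)) stop("divergence parameter F must lie in (0,1)")
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Draw the per-locus truth table for a two-population simulation
#'
#' Assigns each locus a class (neutral, divergent, psv, rare, lowdepth),
#' draws its ancestral frequency, and draws the two population
#' frequencies independently from the Balding-Nichols prior with the
#' class's divergence parameter. Planted rare loci are fixed at
#' `rare_freq` in both populations (no drift jitter) so the MAF filter
#' can be tested deterministically.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `locus`, `class`, `p_anc`, `p1`, `p2`,
#'   `fst_param`, `fst_true` (Nei FST of the true frequencies).
#' @export
draw_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_loci
  cls <- rep("neutral", n)
  planted <- c(rep("divergent", config$n_divergent),
               rep("psv", config$n_psv),
               rep("rare", config$n_rare),
               rep("lowdepth", config$n_lowdepth))
  if (length(planted))
    cls[sample.int(n, length(planted))] <- sample(planted)
  lo <- config$freq_range[1]; hi <- config$freq_range[2]
  p_anc <- switch(config$ancestral_freq_dist,
                  uniform = stats::runif(n, lo, hi),
                  sfs = rsfs(n, lo, hi))
  p_anc[cls == "rare"] <- config$rare_freq
  f <- ifelse(cls == "divergent", config$fst_divergent, config$fst_neutral)
  p1 <- rbalding_nichols(p_anc, f)
  p2 <- rbalding_nichols(p_anc, f)
  fixed <- cls == "rare"
  p1[fixed] <- config$rare_freq
  p2[fixed] <- config$rare_freq
  data.frame(
    locus = sprintf("L%05d", seq_len(n)),
    class = cls, p_anc = p_anc, p1 = p1, p2 = p2, fst_param = f,
    fst_true = fst_nei(p1, p2),
    stringsAsFactors = FALSE
  )
}

#' Sample true diploid genotypes from a truth table
#'
#' Ordinary individuals carry binomial(2, p_pop) copies of allele A.
#' Doubled haploids carry two identical copies of a single allele draw
#' (never heterozygous at any non-PSV locus); their draws use the
#' ancestral frequency since they are reference fish outside the two
#' study populations.
#'
#' @param truth output of [draw_population_frequencies()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (integer matrix, loci x individuals,
#'   copies of allele A in 0:2), `meta` (data.frame: individual,
#'   population, phenotype, doubled_haploid), and `truth`.
#' @export
sample_genotypes <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  n <- nrow(truth)
  n1 <- config$n_per_pop; n2 <- config$n_per_pop
  ndh <- config$n_doubled_haploid
  ids <- c(sprintf("mig%03d", seq_len(n1)),
           sprintf("res%03d", seq_len(n2)),
           if (ndh) sprintf("dh%02d", seq_len(ndh)))
  meta <- data.frame(
    individual = ids,
    population = c(rep("migrant", n1), rep("resident", n2),
                   rep("reference", ndh)),
    phenotype = c(rep("migrant", n1), rep("resident", n2), rep(NA, ndh)),
    doubled_haploid = c(rep(FALSE, n1 + n2), rep(TRUE, ndh)),
    stringsAsFactors = FALSE
  )
  g1 <- matrix(stats::rbinom(n * n1, 2, rep(truth$p1, n1)), nrow = n)
  g2 <- matrix(stats::rbinom(n * n2, 2, rep(truth$p2, n2)), nrow = n)
  gdh <- if (ndh)
    matrix(2L * stats::rbinom(n * ndh, 1, rep(truth$p_anc, ndh)), nrow = n)
  geno <- cbind(g1, g2, gdh)
  dimnames(geno) <- list(truth$locus, ids)
  structure(list(genotypes = geno, meta = meta, truth = truth),
            class = "rad_genotypes")
}

#' Simulate per-allele read counts from true genotypes
#'
#' Total depth per locus/individual is Poisson(`mean_depth`) (negative
#' binomial if `depth_dispersion` is set); heterozygote reads split
#' binomially 50:50, homozygote reads all support one allele, and each
#' read flips allele with probability `error_rate`. PSV loci emit the
#' union of two oppositely fixed duplicated copies, each at the full
#' depth model, so every individual — doubled haploids included — shows
#' both alleles at roughly 50:50. Planted low-depth loci use
#' `lowdepth_mean`.
#'
#' @param geno output of [sample_genotypes()].
#' @param config the [sim_config()].
#' @return list with integer matrices `count_a`, `count_b` (loci x
#'   individuals), plus `meta` and `truth` carried through.
#' @export
simulate_read_counts <- function(geno, config) {
  stopifnot(inherits(geno, "rad_genotypes"), inherits(config, "sim_config"))
  g <- geno$genotypes
  n <- nrow(g); m <- ncol(g)
  mu <- rep(config$mean_depth, n)
  mu[geno$truth$class == "lowdepth"] <- config$lowdepth_mean
  rdepth <- function(len, mean_vec) {
    if (is.null(config$depth_dispersion))
      stats::rpois(len, mean_vec)
    else
      stats::rnbinom(len, size = config$depth_dispersion, mu = mean_vec)
  }
  depth <- matrix(rdepth(n * m, rep(mu, m)), nrow = n)
  true_a <- matrix(0L, n, m)
  true_a[g == 2L] <- depth[g == 2L]
  het <- g == 1L
  true_a[het] <- stats::rbinom(sum(het), depth[het], 0.5)
  true_b <- depth - true_a
  psv <- geno$truth$class == "psv"
  if (any(psv)) {
    npsv <- sum(psv)
    true_a[psv, ] <- matrix(rdepth(npsv * m, rep(mu[psv], m)), nrow = npsv)
    true_b[psv, ] <- matrix(rdepth(npsv * m, rep(mu[psv], m)), nrow = npsv)
  }
  e <- config$error_rate
  if (e > 0) {
    flip_a <- stats::rbinom(n * m, as.vector(true_a), e)
    flip_b <- stats::rbinom(n * m, as.vector(true_b), e)
    count_a <- true_a - flip_a + flip_b
    count_b <- true_b - flip_b + flip_a
  } else {
    count_a <- true_a; count_b <- true_b
  }
  count_a <- matrix(as.integer(count_a), n, m, dimnames = dimnames(g))
  count_b <- matrix(as.integer(count_b), n, m, dimnames = dimnames(g))
  structure(list(count_a = count_a, count_b = count_b,
                 meta = geno$meta, truth = geno$truth),
            class = "read_counts")
}

#' Build random 89-bp reference tags with one SNP each
#'
#' @param locus_ids character vector of locus ids.
#' @param tag_length tag length in bp (reads are trimmed to 89 bp).
#' @return data.frame: locus, offset (1-based SNP position), allele_a,
#'   allele_b (bases), seq_a, seq_b (full tag sequences).
#' @export
make_reference_tags <- function(locus_ids, tag_length = 89L) {
  bases <- c("A", "C", "G", "T")
  n <- length(locus_ids)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, tag_length, replace = TRUE), collapse = ""),
    character(1))
  offset <- sample.int(tag_length, n, replace = TRUE)
  allele_a <- substr(seqs, offset, offset)
  allele_b <- vapply(allele_a, function(b) sample(setdiff(bases, b), 1),
                     character(1), USE.NAMES = FALSE)
  seq_b <- seqs
  substr(seq_b, offset, offset) <- allele_b
  data.frame(locus = locus_ids, offset = offset,
             allele_a = allele_a, allele_b = allele_b,
             seq_a = seqs, seq_b = seq_b, stringsAsFactors = FALSE)
}

#' Emit simulated 89-bp reads consistent with a read-count matrix
#'
#' One read record per simulated read: `count_a[l, i]` copies of the
#' allele-A tag sequence and `count_b[l, i]` copies of the allele-B
#' sequence for each locus l and individual i. Because reads are emitted
#' from the (already error-perturbed) counts, stacking them recovers the
#' counts exactly; there are no additional off-SNP errors.
#'
#' @param counts a [simulate_read_counts()] result.
#' @param tags reference tags from [make_reference_tags()].
#' @param path optional FASTA path; records are named
#'   `<individual>:<serial>`.
#' @return data.frame with columns `individual`, `sequence` (invisibly if
#'   `path` given).
#' @export
emit_reads <- function(counts, tags, path = NULL) {
  stopifnot(inherits(counts, "read_counts"))
  tags <- tags[match(rownames(counts$count_a), tags$locus), ]
  inds <- colnames(counts$count_a)
  na <- as.vector(counts$count_a); nb <- as.vector(counts$count_b)
  locus_idx <- rep(seq_len(nrow(tags)), times = length(inds))
  ind_idx <- rep(seq_along(inds), each = nrow(tags))
  seqs <- c(rep(tags$seq_a[locus_idx], na), rep(tags$seq_b[locus_idx], nb))
  who <- c(rep(inds[ind_idx], na), rep(inds[ind_idx], nb))
  reads <- data.frame(individual = who, sequence = seqs,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_reads_fasta(reads, path)
    return(invisible(reads))
  }
  reads
}

#' Write/read simulated reads as FASTA
#'
#' Headers are `<individual>:<serial>` so the individual of origin
#' round-trips.
#' @param reads data.frame with `individual`, `sequence`.
#' @param path FASTA file path.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- paste0(reads$individual, ":", seq_len(nrow(reads)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(individual = sub(":.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Assign a fraction of loci to a synthetic linkage map
#'
#' A configurable fraction of loci (default from the config, 0.25) is
#' placed uniformly on `n_chromosomes` chromosomes at uniform positions
#' in `[0, map_length_cm]`; the rest stay unmapped (absent from the
#' returned table). Chromosomes are labelled `Omy1..Omy<k-1>` plus
#' `OmySex`.
#'
#' @param locus_ids character vector of locus ids.
#' @param config a [sim_config()].
#' @param fraction override of `config$map_fraction`.
#' @return data.frame: `locus`, `chromosome`, `position_cm`.
#' @export
generate_linkage_map <- function(locus_ids, config,
                                 fraction = config$map_fraction) {
  stopifnot(inherits(config, "sim_config"), fraction >= 0, fraction <= 1)
  n_map <- round(length(locus_ids) * fraction)
  mapped <- sort(sample.int(length(locus_ids), n_map))
  chroms <- c(paste0("Omy", seq_len(config$n_chromosomes - 1)), "OmySex")
  data.frame(
    locus = locus_ids[mapped],
    chromosome = sample(chroms, n_map, replace = TRUE),
    position_cm = stats::runif(n_map, 0, config$map_length_cm),
    stringsAsFactors = FALSE
  )
}

#' Run the whole generator: truth, genotypes, read counts, map, tags
#'
#' @param config a [sim_config()]; its `seed` (if any) governs all
#'   randomness.
#' @param tags also build reference tag sequences (needed only when
#'   emitting reads).
#' @return list of class `rad_sim`: `config`, `truth`, `genotypes`
#'   (rad_genotypes), `counts` (read_counts), `map`, and optionally
#'   `tags`.
#' @export
simulate_study <- function(config = sim_config(), tags = FALSE) {
  truth <- draw_population_frequencies(config)
  geno <- sample_genotypes(truth, config)
  counts <- simulate_read_counts(geno, config)
  map <- generate_linkage_map(truth$locus, config)
  ref <- if (tags) make_reference_tags(truth$locus)
  structure(list(config = config, truth = truth, genotypes = geno,
                 counts = counts, map = map, tags = ref),
            class = "rad_sim")
}
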