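# Build a genotype_matrix directly from a character matrix of calls,
# without going through the read-count simulator.
gm_fixture <- function(calls, population = NULL, doubled_haploid = NULL) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  n <- ncol(calls)
  if (is.null(population))
    population <- rep(c("migrant", "resident"),
                      c(ceiling(n / 2), floor(n / 2)))
  if (is.null(doubled_haploid)) doubled_haploid <- rep(FALSE, n)
  meta <- data.frame(individual = colnames(calls),
                     population = population,
                     phenotype = population,
                     doubled_haploid = doubled_haploid,
                     stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 reason = ifelse(is.na(calls), "low_depth", "called"),
                 meta = meta),
            class = "genotype_matrix")
}

# A calls matrix in which every individual of each population has the
# stated genotype at a single locus.
one_locus_calls <- function(geno_pop1, geno_pop2, n1 = 10, n2 = 10) {
  m <- matrix(c(rep(geno_pop1, n1), rep(geno_pop2, n2)), nrow = 1)
  rownames(m) <- "L001"
  m
}

# Independent brute-force oracle for Tajima's D: pi by explicit
# enumeration of all pairs of sampled alleles, constants by literal
# harmonic loops. `ks` = per-site counts of one allele among n alleles.
oracle_tajima_d <- function(ks, n) {
  stopifnot(n >= 4, length(ks) >= 1)
  # allele matrix: sites x alleles, 0/1
  alleles <- sapply(ks, function(k) c(rep(1, k), rep(0, n - k)))
  pairs <- utils::combn(n, 2)
  pi_val <- 0
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    pi_val <- pi_val + sum(alleles[a, ] != alleles[b, ])
  }
  pi_val <- pi_val / ncol(pairs)
  s <- sum(ks > 0 & ks < n)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_val - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# Brute-force two-sided exact HWE p-value by enumerating every genotype
# configuration compatible with the observed allele counts, using plain
# factorials (valid at the small n used in tests).
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  configs <- list()
  for (h in 0:n) {
    aa <- (n_a - h) / 2
    bb <- n - h - aa
    if (aa < 0 || bb < 0 || aa != round(aa)) next
    # P(config | n, n_a) under random mating, unnormalised:
    # n! / (aa! h! bb!) * 2^h
    w <- factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
    configs[[length(configs) + 1]] <- c(h = h, w = w)
  }
  tab <- do.call(rbind, configs)
  pr <- tab[, "w"] / sum(tab[, "w"])
  obs <- pr[tab[, "h"] == n_ab]
  sum(pr[pr <= obs * (1 + 1e-9)])
}
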