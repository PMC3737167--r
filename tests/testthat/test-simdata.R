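test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fst_neutral = 0.4, fst_divergent = 0.3),
               "fst_neutral < fst_divergent")
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(n_loci = 100, n_divergent = 80, n_psv = 30),
               "exceed")
  expect_error(rbalding_nichols(0.5, 1.2), "F must lie in")
})

test_that("population frequencies follow the Balding-Nichols model", {
  # F -> 0 limit: population frequencies collapse onto the ancestral ones
  cfg <- sim_config(n_loci = 200, n_divergent = 0, n_psv = 0,
                    fst_neutral = 1e-6, fst_divergent = 0.5, seed = 1)
  tr <- draw_population_frequencies(cfg)
  expect_lt(max(abs(tr$p1 - tr$p_anc)), 0.01)
  expect_lt(max(abs(tr$p2 - tr$p_anc)), 0.01)

  # determinism: same config (incl. seed) gives an identical truth table
  cfg2 <- sim_config(n_loci = 500, n_divergent = 20, n_psv = 10, seed = 7)
  expect_identical(draw_population_frequencies(cfg2),
                   draw_population_frequencies(cfg2))

  # class labels partition the loci as configured
  tr2 <- draw_population_frequencies(cfg2)
  expect_equal(sum(tr2$class == "divergent"), 20)
  expect_equal(sum(tr2$class == "psv"), 10)
  expect_equal(sum(tr2$class == "neutral"), 470)
  expect_true(all(tr2$p1 >= 0 & tr2$p1 <= 1 & tr2$p2 >= 0 & tr2$p2 <= 1))
})

test_that("mean sampled Weir-Cockerham FST recovers the F parameter", {
  cfg <- sim_config(n_loci = 2000, n_divergent = 0, n_psv = 0,
                    fst_neutral = 0.1, fst_divergent = 0.5,
                    n_per_pop = 50, error_rate = 0, seed = 11)
  sim <- simulate_study(cfg)
  gm <- call_matrix(sim$counts)
  wc <- pairwise_fst(gm, method = "wc")
  expect_lt(abs(wc$global - 0.1), 0.02)
})

test_that("true genotypes follow the binomial sampling model", {
  cfg <- sim_config(n_loci = 3, n_divergent = 0, n_psv = 0,
                    n_per_pop = 20, seed = 3)
  tr <- draw_population_frequencies(cfg)
  # frequency 1 -> everyone AA
  tr$p1[] <- 1; tr$p2[] <- 1; tr$p_anc[] <- 1
  g <- sample_genotypes(tr, cfg)
  expect_true(all(g$genotypes == 2L))

  # heterozygote fraction at p = 0.5 matches the binomial expectation
  cfg2 <- sim_config(n_loci = 200, n_divergent = 0, n_psv = 0,
                     n_per_pop = 50, seed = 5)
  tr2 <- draw_population_frequencies(cfg2)
  tr2$p1[] <- 0.5; tr2$p2[] <- 0.5
  g2 <- sample_genotypes(tr2, cfg2)
  pop <- g2$meta$population != "reference"
  het_frac <- mean(g2$genotypes[, pop] == 1L)
  n_draws <- sum(pop) * 200
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / n_draws))

  # doubled haploids are never heterozygous at non-PSV loci
  cfg3 <- sim_config(n_loci = 500, n_divergent = 0, n_psv = 50, seed = 9)
  g3 <- sample_genotypes(draw_population_frequencies(cfg3), cfg3)
  dh <- g3$meta$doubled_haploid
  expect_false(any(g3$genotypes[, dh] == 1L))
})

test_that("read counts follow the depth and error model", {
  cfg <- sim_config(n_loci = 400, n_divergent = 0, n_psv = 20,
                    n_per_pop = 20, mean_depth = 30, error_rate = 0,
                    seed = 13)
  tr <- draw_population_frequencies(cfg)
  g <- sample_genotypes(tr, cfg)
  rc <- simulate_read_counts(g, cfg)
  nonpsv <- tr$class != "psv"
  # error-free homozygotes put every read on one allele
  aa <- g$genotypes[nonpsv, ] == 2L
  expect_true(all(rc$count_b[nonpsv, ][aa] == 0))
  bb <- g$genotypes[nonpsv, ] == 0L
  expect_true(all(rc$count_a[nonpsv, ][bb] == 0))
  # PSV loci show both alleles in (nearly) all individuals, DHs included
  psv_a <- rc$count_a[!nonpsv, ]; psv_b <- rc$count_b[!nonpsv, ]
  expect_gt(mean(psv_a > 0 & psv_b > 0), 0.99)
  ratio <- psv_a / (psv_a + psv_b)
  expect_lt(abs(mean(ratio) - 0.5), 0.01)
  # depth is Poisson: P(total < 8) matches the CDF at 7
  tot <- rc$count_a[nonpsv, ] + rc$count_b[nonpsv, ]
  expect_lt(abs(mean(tot < 8) - ppois(7, 30)), 3e-3 + 3 * sqrt(ppois(7, 30) / length(tot)))
})

test_that("emitted reads are valid tags and round-trip to counts", {
  set.seed(17)
  cfg <- sim_config(n_loci = 40, n_divergent = 0, n_psv = 0,
                    n_per_pop = 5, mean_depth = 10, error_rate = 0,
                    n_doubled_haploid = 0)
  sim <- simulate_study(cfg, tags = TRUE)
  reads <- emit_reads(sim$counts, sim$tags)
  expect_true(all(nchar(reads$sequence) == 89))
  expect_true(all(strsplit(paste(reads$sequence, collapse = ""), "")[[1]]
                  %in% c("A", "C", "G", "T")))
  # stacking recovers per-allele totals exactly when error_rate = 0
  for (i in c(1, 20, 40)) {
    expect_equal(sum(reads$sequence == sim$tags$seq_a[i]),
                 sum(sim$counts$count_a[i, ]))
    expect_equal(sum(reads$sequence == sim$tags$seq_b[i]),
                 sum(sim$counts$count_b[i, ]))
  }
  # FASTA round trip preserves individual of origin
  tmp <- tempfile(fileext = ".fasta")
  write_reads_fasta(reads, tmp)
  back <- read_reads_fasta(tmp)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$individual, reads$individual)
  unlink(tmp)
})

test_that("linkage map assigns the configured fraction of loci", {
  cfg <- sim_config(n_loci = 4000, seed = 19)
  loci <- sprintf("L%05d", 1:4000)
  set.seed(19)
  full <- generate_linkage_map(loci, cfg, fraction = 1)
  expect_equal(nrow(full), 4000)
  expect_true(all(full$position_cm >= 0 &
                    full$position_cm <= cfg$map_length_cm))
  expect_equal(anyDuplicated(full$locus), 0)
  set.seed(19)
  part <- generate_linkage_map(loci, cfg, fraction = 0.25)
  expect_equal(nrow(part), 1000)
  set.seed(19)
  part2 <- generate_linkage_map(loci, cfg, fraction = 0.25)
  expect_identical(part, part2)
  expect_equal(length(unique(full$chromosome)), 29)
})
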