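test_that("heterozygosity components follow the textbook formulas", {
  # pop freqs 0.7 / 0.3: H_S = 0.42, H_T = 0.5, Nei FST = 0.16
  expect_equal(fst_nei(0.7, 0.3), 0.16, tolerance = 1e-12)
  expect_equal(fst_nei(0.5, 0.5), 0, tolerance = 1e-12)
  expect_equal(fst_nei(1, 0), 1, tolerance = 1e-12)
  expect_true(is.na(fst_nei(0, 0)))

  # a two-population fixture with known genotype counts
  calls <- rbind(L1 = c(rep("AA", 7), rep("AB", 6), rep("BB", 2),
                        rep("BB", 7), rep("AB", 6), rep("AA", 2)))
  gm <- gm_fixture(calls, population = rep(c("migrant", "resident"),
                                           each = 15))
  h <- heterozygosities(gm)
  p1 <- (14 + 6) / 30; p2 <- (4 + 6) / 30
  expect_equal(h$h_o, 12 / 30)
  expect_equal(h$h_s, (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2)
  expect_equal(h$h_t, 2 * mean(c(p1, p2)) * (1 - mean(c(p1, p2))))
  ls <- locus_stats(gm)
  expect_equal(ls$fst_nei_raw, (h$h_t - h$h_s) / h$h_t, tolerance = 1e-12)

  # all-AA locus: H_O = H_E = 0, FST undefined
  gm0 <- gm_fixture(one_locus_calls("AA", "AA"))
  ls0 <- locus_stats(gm0)
  expect_equal(ls0$h_o, 0)
  expect_equal(ls0$h_e, 0)
  expect_true(is.na(ls0$fst_nei_raw))
})

test_that("Nei and Weir-Cockerham agree on the degenerate cases", {
  # identical populations: Nei exactly 0, WC approximately 0
  gm_same <- gm_fixture(cbind(one_locus_calls("AB", "AB", 25, 25)))
  ls <- locus_stats(gm_same)
  expect_equal(ls$fst_nei_raw, 0, tolerance = 1e-12)
  expect_lt(abs(ls$fst_wc_raw), 0.05)
  # fixed difference: both estimators at 1 (WC exactly, given no hets)
  gm_fix <- gm_fixture(one_locus_calls("AA", "BB", 30, 30))
  lf <- locus_stats(gm_fix)
  expect_equal(lf$fst_nei_raw, 1, tolerance = 1e-12)
  expect_equal(lf$fst_wc_raw, 1, tolerance = 1e-12)
  # reported values are clipped into [0, 1], raw kept
  expect_true(all(ls$fst_wc >= 0 & ls$fst_wc <= 1))
})

test_that("private alleles require presence in exactly one population", {
  calls <- rbind(
    L1 = c("AA", "AB", "AA", "AA"),   # B only in migrants -> private
    L2 = c("AB", "AB", "AB", "AB"),   # both alleles everywhere -> none
    L3 = c("AB", "AA", "AB", "AA"))   # B seen once in each pop -> none
  colnames(calls) <- c("m1", "m2", "r1", "r2")
  gm <- gm_fixture(calls, population = c("migrant", "migrant",
                                         "resident", "resident"))
  pa <- private_alleles(gm)
  expect_equal(pa$migrant, "L1")
  expect_length(pa$resident, 0)
  expect_equal(unname(pa$totals), c(1L, 0L))
})

test_that("Tajima constants and component estimators are exact", {
  k2 <- tajima_constants(2)
  expect_equal(k2$a1, 1)
  expect_equal(k2$a2, 1)
  expect_equal(tajima_constants(4)$a1, 1 + 1 / 2 + 1 / 3)
  a1s <- vapply(2:30, function(n) tajima_constants(n)$a1, numeric(1))
  expect_true(all(diff(a1s) > 0))
  expect_error(tajima_constants(1), "at least 2")

  expect_equal(watterson_theta(3, 2), 3)
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(3, 4), 3 / (1 + 1 / 2 + 1 / 3))

  expect_equal(pairwise_pi(integer(0), 4), 0)      # monomorphic window
  expect_equal(pairwise_pi(1, 2), 1)
  expect_equal(pairwise_pi(2, 4), 2 * 2 * 2 / 12)
  expect_error(pairwise_pi(1, 1), "at least 2")

  # numerator-zero identity and the sign property for singleton excess
  n <- 10; a1 <- tajima_constants(n)$a1
  s <- 4
  expect_equal(tajimas_d(s / a1, s, n), 0)
  d_singletons <- oracle_tajima_d(rep(1, 8), 20)
  expect_lt(d_singletons, 0)
  expect_true(is.na(tajimas_d(0.5, 0, 10)))
})

test_that("tajimas_d matches the brute-force oracle on all small cases", {
  for (n in 4:6) {
    for (s in 1:5) {
      ks_grid <- expand.grid(rep(list(1:(n - 1)), s))
      # cap the grid: every configuration for s <= 3, a deterministic
      # subsample beyond (the full n = 6, s = 5 grid is 3125 rows)
      rows <- seq_len(nrow(ks_grid))
      if (length(rows) > 300) rows <- rows[seq(1, length(rows), by = 7)]
      for (r in rows) {
        ks <- as.numeric(ks_grid[r, ])
        pi_val <- pairwise_pi(ks, n)
        expect_equal(tajimas_d(pi_val, s, n), oracle_tajima_d(ks, n),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("windowed scan applies site filters and flags windows", {
  # one singleton site: excluded at min_rare_count = 2, window dead
  calls <- rbind(L1 = c("AB", rep("AA", 9)))
  gm <- gm_fixture(calls, population = rep("migrant", 10))
  ws <- windowed_scan(gm, "migrant")
  expect_equal(ws$s, 0L)
  expect_false(ws$evaluable)
  # the same site enters at min_rare_count = 1
  ws1 <- windowed_scan(gm, "migrant", window_config(min_rare_count = 1))
  expect_equal(ws1$s, 1L)
  expect_true(ws1$evaluable)
  expect_equal(ws1$pi, 2 * 1 * 19 / (20 * 19))
  expect_equal(ws1$theta_w, 1 / tajima_constants(20)$a1)
  # coverage gate: one called individual = 2 alleles < 4
  calls2 <- rbind(L1 = c("AB", rep(NA, 9)))
  gm2 <- gm_fixture(calls2, population = rep("migrant", 10))
  expect_false(windowed_scan(gm2, "migrant",
                             window_config(min_rare_count = 1))$evaluable)
  # pool mode uses the nominal n for the constants
  wsp <- windowed_scan(gm, "migrant",
                       window_config(min_rare_count = 1, n_mode = "pool",
                                     pool_n = 50))
  expect_equal(wsp$theta_w, 1 / tajima_constants(50)$a1)
  expect_error(windowed_scan(gm, "absent"), "no individuals")
})

test_that("neutral-SFS panels give mean Tajima's D near zero", {
  cfg <- sim_config(n_loci = 1200, n_divergent = 0, n_psv = 0,
                    ancestral_freq_dist = "sfs",
                    freq_range = c(0.002, 0.998), fst_neutral = 0.001,
                    fst_divergent = 0.5, n_per_pop = 50, seed = 42)
  sim <- simulate_study(cfg)
  gm <- call_matrix(sim$counts)
  ws <- windowed_scan(gm, "migrant", window_config(min_rare_count = 1))
  ev <- ws[ws$evaluable, ]
  expect_gte(nrow(ev), 500)
  expect_lt(abs(mean(ev$tajima_d)), 0.15)
})
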