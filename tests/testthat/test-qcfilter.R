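test_that("doubled-haploid PSV screen flags exactly het-in-DH loci", {
  calls <- rbind(
    L1 = c("AA", "AB", "AB", "AA"),   # DH het -> flagged
    L2 = c("AB", "AA", "BB", "AA"),   # DH hom, others het -> clean
    L3 = c("AA", "AB", NA,   "AA"))   # DH missing -> clean
  colnames(calls) <- c("m1", "m2", "dh1", "dh2")
  gm <- gm_fixture(calls, population = c("migrant", "migrant",
                                         "reference", "reference"),
                   doubled_haploid = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(detect_psv_doubled_haploid(gm), "L1")
  gm2 <- gm_fixture(calls[, 1:2], population = c("migrant", "migrant"))
  expect_warning(out <- detect_psv_doubled_haploid(gm2), "skipped")
  expect_length(out, 0)
})

test_that("het-excess, MAF, and missingness boundaries match the rules", {
  # het excess: >= 0.90 removed
  mk <- function(n_ab, n_hom, n_na = 0)
    matrix(c(rep("AB", n_ab), rep("AA", n_hom), rep(NA, n_na)), nrow = 1,
           dimnames = list("L1", NULL))
  expect_false(filter_het_excess(gm_fixture(mk(95, 5)))[["L1"]])
  expect_true(filter_het_excess(gm_fixture(mk(50, 50)))[["L1"]])
  expect_false(filter_het_excess(gm_fixture(mk(90, 10)))[["L1"]])
  k <- filter_het_excess(gm_fixture(mk(0, 0, 4)))
  expect_false(k[["L1"]])
  expect_equal(attr(k, "reason")[1], "all_missing")

  # MAF: < 0.02 removed, exactly 0.02 retained, monomorphic removed
  maf_calls <- function(n_ab, n_total)
    matrix(c(rep("AB", n_ab), rep("AA", n_total - n_ab)), nrow = 1,
           dimnames = list("L1", NULL))
  expect_false(filter_maf(gm_fixture(maf_calls(3, 100)))[["L1"]])  # 0.015
  expect_true(filter_maf(gm_fixture(maf_calls(4, 100)))[["L1"]])   # 0.020
  expect_false(filter_maf(gm_fixture(maf_calls(0, 50)))[["L1"]])

  # missingness: > 0.50 removed, exactly 0.50 retained
  miss_calls <- function(n_na, n_total)
    matrix(c(rep(NA, n_na), rep("AB", n_total - n_na)), nrow = 1,
           dimnames = list("L1", NULL))
  expect_false(filter_missing(gm_fixture(miss_calls(51, 100)))[["L1"]])
  expect_true(filter_missing(gm_fixture(miss_calls(50, 100)))[["L1"]])
  expect_true(filter_missing(gm_fixture(miss_calls(0, 10)))[["L1"]])
})

test_that("exact HWE test matches full-enumeration oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 1, 10), c(3, 14, 3),
                c(0, 2, 18), c(7, 7, 7), c(1, 1, 1), c(12, 0, 1))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe_p(cs[1], cs[2], cs[3]), tolerance = 1e-9,
                 info = paste(cs, collapse = ","))
  }
  # most probable configuration class: p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  # extreme het deficit at n = 100 is far beyond the -log10 p = 5 gate
  expect_gt(-log10(hwe_exact_test(50, 0, 50)), 5)
  # monomorphic convention
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("polymorphic-in-both keeps only doubly polymorphic loci", {
  calls <- rbind(
    L1 = c("AA", "AA", "AB", "BB"),  # fixed in pop1 -> removed
    L2 = c("AB", "AA", "AB", "BB"),  # polymorphic in both -> kept
    L3 = c(NA,  NA,  "AB", "AB"))    # all-missing in pop1 -> removed
  colnames(calls) <- c("m1", "m2", "r1", "r2")
  gm <- gm_fixture(calls, population = c("migrant", "migrant",
                                         "resident", "resident"))
  keep <- require_polymorphic_both(gm)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE))
  expect_error(require_polymorphic_both(gm, c("migrant", "absent")),
               "zero individuals")
})

test_that("the cascade removes planted classes at the right stages", {
  cfg <- sim_config(n_loci = 2000, n_divergent = 0, n_psv = 60,
                    n_rare = 60, n_lowdepth = 60, seed = 31)
  sim <- simulate_study(cfg)
  gm <- call_matrix(sim$counts)
  fc <- run_filter_cascade(gm)
  tr <- sim$truth

  # report is internally consistent
  rp <- fc$report
  expect_equal(rp$n_in - rp$n_removed, rp$n_out)
  expect_equal(rp$n_in[-1], rp$n_out[-nrow(rp)])
  expect_equal(nrow(fc$matrix$calls), rp$n_out[nrow(rp)])

  stage_of <- fc$removed$stage[match(tr$locus[tr$class == "psv"],
                                     fc$removed$locus)]
  expect_gte(mean(stage_of == "dh_psv", na.rm = TRUE), 0.95)
  rare_stage <- fc$removed$stage[match(tr$locus[tr$class == "rare"],
                                       fc$removed$locus)]
  expect_true(all(rare_stage == "maf"))
  low_rm <- fc$removed[fc$removed$locus %in%
                         tr$locus[tr$class == "lowdepth"], ]
  expect_equal(nrow(low_rm), 60)
  expect_true(all(low_rm$stage == "missing" |
                    low_rm$reason == "all_missing"))

  # false PSV flags among true single-copy loci stay below 1%
  psv_flagged <- fc$removed$locus[fc$removed$stage == "dh_psv"]
  single_copy <- tr$locus[tr$class != "psv"]
  expect_lt(mean(single_copy %in% psv_flagged), 0.01)

  # survivors satisfy every individual filter; second pass removes nothing
  gmf <- fc$matrix
  expect_true(all(filter_het_excess(gmf)))
  expect_true(all(filter_missing(gmf)))
  expect_true(all(filter_maf(gmf)))
  expect_true(all(filter_hwe(gmf)))
  fc2 <- run_filter_cascade(gmf)
  expect_equal(sum(fc2$report$n_removed), 0)
})

test_that("an empty matrix passes through the cascade harmlessly", {
  calls <- matrix(character(0), nrow = 0, ncol = 2,
                  dimnames = list(NULL, c("m1", "dh1")))
  gm <- gm_fixture(calls, population = c("migrant", "reference"),
                   doubled_haploid = c(FALSE, TRUE))
  fc <- run_filter_cascade(gm)
  expect_true(all(fc$report$n_in == 0))
  expect_equal(nrow(fc$matrix$calls), 0)
})
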