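mk_reads <- function(seqs, depths, individual = "i1") {
  data.frame(individual = individual,
             sequence = rep(seqs, depths), stringsAsFactors = FALSE)
}

rand_tag <- function(n = 89) paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = "")

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("stack depth bounds are inclusive on [5, 200]", {
  set.seed(1)
  s <- vapply(1:4, function(i) rand_tag(), character(1))
  reads <- mk_reads(s, c(4, 5, 200, 201))
  st <- stack_reads(reads)
  expect_setequal(st$sequence, s[2:3])
  expect_setequal(st$depth, c(5L, 200L))
})

test_that("wrong-length reads raise an input error naming the record", {
  reads <- data.frame(individual = "i1",
                      sequence = c(strrep("A", 89), strrep("A", 88)))
  expect_error(stack_reads(reads), "read 2 has length 88")
})

test_that("allele pairing respects mismatch and depth rules", {
  set.seed(2)
  base <- rand_tag()
  other <- mutate_at(base, 10, setdiff(c("A", "C", "G", "T"),
                                       substr(base, 10, 10))[1])
  st <- stack_reads(mk_reads(c(base, other), c(10, 10)))
  loci <- pair_alleles(st)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_snps, 1)
  expect_equal(loci$offsets, "10")
  expect_equal(sort(c(loci$allele_a, loci$allele_b)), sort(c(base, other)))

  # four mismatches: two independent monomorphic tags, no locus
  far <- base
  for (p in c(5, 20, 40, 60))
    far <- mutate_at(far, p, setdiff(c("A", "C", "G", "T"),
                                     substr(far, p, p))[1])
  st2 <- stack_reads(mk_reads(c(base, far), c(10, 10)))
  expect_equal(nrow(pair_alleles(st2)), 0)

  # three alleles at one offset: biallelic rule discards the group
  alt <- c("A", "C", "G", "T")
  b10 <- substr(base, 10, 10)
  tri <- vapply(setdiff(alt, b10), function(x) mutate_at(base, 10, x),
                character(1))
  st3 <- stack_reads(mk_reads(c(base, tri[1], tri[2]), c(10, 10, 10)))
  expect_equal(nrow(pair_alleles(st3)), 0)
})

test_that("greedy pairing prefers the deepest partner", {
  set.seed(3)
  base <- rand_tag()
  alts <- setdiff(c("A", "C", "G", "T"), substr(base, 10, 10))
  a1 <- mutate_at(base, 10, alts[1])     # candidate partner, depth 30
  # a1 and base differ at pos 10; a third stack differs from a1 at pos 20
  a2 <- mutate_at(a1, 20, setdiff(c("A", "C", "G", "T"),
                                  substr(a1, 20, 20))[1])
  st <- stack_reads(mk_reads(c(base, a1, a2), c(30, 8, 6)))
  loci <- pair_alleles(st)
  # a1 pairs with base (depth 30 beats depth 6); a2 stays unpaired
  expect_equal(nrow(loci), 1)
  expect_setequal(c(loci$allele_a, loci$allele_b), c(base, a1))
})

test_that("the three-comparison database is deduplicated and stable", {
  set.seed(4)
  base <- rand_tag()
  other <- mutate_at(base, 44, setdiff(c("A", "C", "G", "T"),
                                       substr(base, 44, 44))[1])
  # locus 2 variable only within population 1
  p1base <- rand_tag()
  p1other <- mutate_at(p1base, 3, setdiff(c("A", "C", "G", "T"),
                                          substr(p1base, 3, 3))[1])
  reads <- rbind(
    mk_reads(c(base, other), c(6, 6), "m1"),
    mk_reads(c(base, other), c(6, 6), "r1"),
    mk_reads(c(p1base, p1other), c(6, 6), "m1"))
  subs <- list(all = c("m1", "r1"), pop1 = "m1", pop2 = "r1")
  db <- build_snp_database(reads, subs)
  expect_equal(nrow(db), 2)   # shared locus deduplicated across subsets
  shared <- db[grepl("all", db$found_in), ]
  expect_equal(nrow(shared[grepl("pop1", shared$found_in) &
                             grepl("pop2", shared$found_in), ]), 1)
  # the population-1-private locus is discovered
  expect_true(any(db$found_in == "all,pop1" | db$found_in == "pop1,all" |
                    grepl("pop1", db$found_in)))
  # merging with itself is idempotent: same reads, same ids
  db2 <- build_snp_database(reads, subs)
  expect_identical(db, db2)
  # subset order does not change content
  db3 <- build_snp_database(reads, rev(subs))
  expect_equal(db3[, c("locus", "allele_a", "allele_b")],
               db[, c("locus", "allele_a", "allele_b")])
  expect_error(build_snp_database(reads, list(all = character(0))),
               "empty")
})

test_that("discovery recovers simulated loci without false positives", {
  set.seed(5)
  cfg <- sim_config(n_loci = 300, n_divergent = 0, n_psv = 0,
                    n_per_pop = 10, mean_depth = 15, error_rate = 0,
                    n_doubled_haploid = 0)
  sim <- simulate_study(cfg, tags = TRUE)
  reads <- emit_reads(sim$counts, sim$tags)
  meta <- sim$genotypes$meta
  db <- build_snp_database(reads, list(
    all = meta$individual,
    pop1 = meta$individual[meta$population == "migrant"],
    pop2 = meta$individual[meta$population == "resident"]))
  key_truth <- paste(pmin(sim$tags$seq_a, sim$tags$seq_b),
                     pmax(sim$tags$seq_a, sim$tags$seq_b))
  key_db <- paste(db$allele_a, db$allele_b)
  ca <- rowSums(sim$counts$count_a); cb <- rowSums(sim$counts$count_b)
  eligible <- ca >= 5 & ca <= 200 & cb >= 5 & cb <= 200
  expect_gte(mean(key_truth[eligible] %in% key_db), 0.99)
  expect_equal(sum(!(key_db %in% key_truth)), 0)

  # allele counting round-trips the simulated counts exactly
  cm <- count_alleles(reads, db,
                      individuals = colnames(sim$counts$count_a))
  m <- match(key_db, key_truth)
  for (i in seq_len(nrow(db))) {
    swapped <- db$allele_a[i] != sim$tags$seq_a[m[i]]
    a <- if (swapped) cm$count_b[i, ] else cm$count_a[i, ]
    b <- if (swapped) cm$count_a[i, ] else cm$count_b[i, ]
    expect_equal(unname(a), unname(sim$counts$count_a[m[i], ]))
    expect_equal(unname(b), unname(sim$counts$count_b[m[i], ]))
  }
})

test_that("tag-multiplicity bookkeeping sums SNPs per tag", {
  expect_equal(snp_count_from_multiplicities(c("1" = 10, "2" = 5, "3" = 2)),
               10 + 10 + 6)
  db <- data.frame(n_snps = c(1, 1, 2, 3))
  s <- summarize_database(db)
  expect_equal(s$n_tags, 4)
  expect_equal(s$n_snps, 1 + 1 + 2 + 3)
})
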