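# Per-locus statistics (FST, heterozygosities, private alleles) and the
# windowed diversity scan (S, pi, Watterson's theta, Tajima's D) for
# each population, on the filtered matrix.
source("analysis/00_config.R")

gm <- read_genotype_table(path("genotypes_filtered.tsv"))
ls <- locus_stats(gm)
write_tsv(ls, path("locus_stats.tsv"))

wc <- pairwise_fst(gm, method = "wc")
nei <- pairwise_fst(gm, method = "nei")
cat(sprintf("mean per-locus FST: Nei %.4f, WC %.4f; multilocus WC %.4f\n",
            nei$mean, wc$mean, wc$global))
cat(sprintf("mean H_O %.3f, mean H_E %.3f\n",
            mean(ls$h_o, na.rm = TRUE), mean(ls$h_e, na.rm = TRUE)))
pa <- private_alleles(gm)
cat(sprintf("private-allele loci: %d migrant, %d resident\n",
            pa$totals[1], pa$totals[2]))

for (pop in c("migrant", "resident")) {
  ws <- windowed_scan(gm, pop, rc$window)
  write_tsv(ws, path(sprintf("windows_%s.tsv", pop)))
  ev <- ws[ws$evaluable, ]
  cat(sprintf("%s: %d evaluable windows, mean theta_w %.4f, mean D %+.3f\n",
              pop, nrow(ev), mean(ev$theta_w), mean(ev$tajima_d)))
}
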