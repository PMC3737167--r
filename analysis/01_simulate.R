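# Simulate the two-ecotype study: truth table, genotypes, read counts,
# called genotype matrix and linkage map, all from one seed.
source("analysis/00_config.R")

set.seed(rc$seed)
cfg <- rc$sim; cfg$seed <- NULL
sim <- simulate_study(cfg)
gm <- call_matrix(sim$counts)

write_tsv(sim$truth, path("truth.tsv"))
write_tsv(sim$map, path("map.tsv"))
write_genotype_table(gm, path("genotypes.tsv"))
write_vcf(gm, path("genotypes.vcf"), sim$map)

cat(sprintf("simulated %d loci x %d individuals (%d divergent, %d PSV)\n",
            cfg$n_loci, ncol(gm$calls),
            sum(sim$truth$class == "divergent"),
            sum(sim$truth$class == "psv")))
cat(sprintf("missing call rate: %.2f%%\n", 100 * mean(is.na(gm$calls))))
cat(sprintf("%d of %d loci mapped\n", nrow(sim$map), cfg$n_loci))
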