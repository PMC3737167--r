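# Apply the SNP filter cascade to the called genotypes from
# 01_simulate.R and check the planted PSVs against the truth table.
source("analysis/00_config.R")

gm <- read_genotype_table(path("genotypes.tsv"))
truth <- read_tsv(path("truth.tsv"))
fc <- run_filter_cascade(gm, rc$filter)

write_tsv(fc$report, path("filter_report.tsv"))
write_tsv(fc$removed, path("filter_removed.tsv"))
write_genotype_table(fc$matrix, path("genotypes_filtered.tsv"))

print(fc$report, row.names = FALSE)
psv <- truth$locus[truth$class == "psv"]
flagged <- fc$removed$locus[fc$removed$stage == "dh_psv"]
cat(sprintf("PSV recall %.1f%%; false PSV flags %.2f%%\n",
            100 * mean(psv %in% flagged),
            100 * mean(setdiff(truth$locus, psv) %in% flagged)))
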