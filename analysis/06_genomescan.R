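# Order statistics along the linkage map: Gaussian kernel smoothing of
# per-locus FST, chromosome-level D' in each population, and the
# between-population Welch t-test on chromosome-wide D'.
source("analysis/00_config.R")

gm <- read_genotype_table(path("genotypes_filtered.tsv"))
map <- read_tsv(path("map.tsv"))
ls <- read_tsv(path("locus_stats.tsv"))

track <- smooth_by_chromosome(map, ls, "fst_wc", rc$smooth)
write_tsv(track, path("fst_smoothed_track.tsv"))
peaks <- do.call(rbind, lapply(split(track, track$chromosome), function(d)
  if (nrow(pk <- track_peaks(d)) > 0) cbind(chromosome = d$chromosome[1], pk)))
if (!is.null(peaks)) write_tsv(peaks, path("fst_track_peaks.tsv"))
cat(sprintf("smoothed FST track: %d grid points on %d chromosomes; %d peaks\n",
            nrow(track), length(unique(track$chromosome)),
            if (is.null(peaks)) 0L else nrow(peaks)))

ld_m <- chromosome_ld_summary(gm, map, "migrant")
ld_r <- chromosome_ld_summary(gm, map, "resident")
write_tsv(ld_m$per_chromosome, path("ld_per_chromosome_migrant.tsv"))
write_tsv(ld_r$per_chromosome, path("ld_per_chromosome_resident.tsv"))
cat(sprintf("mean D': migrant %.3f (%d pairs), resident %.3f (%d pairs)\n",
            ld_m$overall_mean, nrow(ld_m$pairs),
            ld_r$overall_mean, nrow(ld_r$pairs)))
cmp <- compare_ld_populations(ld_m$per_chromosome$mean_d_prime,
                              ld_r$per_chromosome$mean_d_prime)
cat(sprintf("chromosome-wide D' difference: t = %.2f, two-tailed p = %.3f\n",
            cmp$t, cmp$p))
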