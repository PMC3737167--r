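# Example run configuration for the radpopgen analysis scripts.
# Any key left out falls back to the package default (shown in the
# documentation of sim_config, filter_config, outlier_config,
# window_config and smooth_config).

seed: 42          # one seed governs every stochastic stage

sim:
  n_loci: 2000          # biallelic RAD loci (one SNP per 89-bp tag)
  n_divergent: 100      # loci drawn with fst_divergent (selection analogue)
  n_psv: 100            # collapsed-paralog loci (apparent heterozygotes)
  fst_neutral: 0.03     # Balding-Nichols F of the neutral background
  fst_divergent: 0.4    # Balding-Nichols F of the divergent class
  n_per_pop: 50         # diploid individuals per population
  mean_depth: 30        # expected reads per locus per individual
  error_rate: 0.005     # per-read allele-flip probability
  n_doubled_haploid: 2  # doubled-haploid reference individuals
  n_chromosomes: 29     # Omy1..Omy28 plus the sex chromosome
  map_length_cm: 100    # per-chromosome map length (centimorgans)
  map_fraction: 0.25    # fraction of loci with a map position

filter:
  het_excess_max: 0.90  # remove loci with >= 90% observed heterozygotes
  maf_min: 0.02         # remove loci with MAF < 2%
  missing_max: 0.50     # remove loci missing > 50% of genotypes
  hwe_neglog10p_max: 5  # remove loci with -log10 HWE exact P > 5

outlier:
  n_sims: 55000         # simulated neutral loci
  ci: 0.995             # candidate threshold on the outlier probability
  fdr: 0.05             # Benjamini-Hochberg level on 1 - P

window:
  window_bp: 100        # window size; 89-bp tags = one window per tag
  min_rare_count: 2     # minimum minor-allele count per site
  min_coverage: 4       # minimum sampled alleles per site
  pool_n: 50            # nominal n for constants in pool mode

smooth:
  sigma: 5              # Gaussian kernel bandwidth (cM)
  step: 0.5             # evaluation-grid spacing (cM)
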