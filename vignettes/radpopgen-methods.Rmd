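---
title: "Methods: a RAD-seq genome scan for ecotype divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a RAD-seq genome scan for ecotype divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpopgen)
```

`radpopgen` implements an end-to-end RAD-seq population-genomics
workflow for contrasting two population samples — the motivating design
is migratory (steelhead-like) versus resident (rainbow-trout-like)
ecotypes of *Oncorhynchus mykiss* sampled from one river system. The
workflow is: synthetic data with known truth → de novo SNP discovery →
read-ratio genotype calling → a quality-filter cascade → per-locus and
windowed statistics → a simulation-based FST outlier test → genome-scan
summaries along a linkage map. Every stage is a plain function, so the
numbered scripts under `analysis/`, the test suite, and the acceptance
script all exercise exactly the same code.

## The synthetic study and its truth model

Real RAD data for such a study are tens of millions of reads; the
generator instead emulates the *statistical* structure of the design at
desk scale, with a truth table that every downstream stage can be
scored against.

**Allele frequencies.** Each locus draws an ancestral frequency $p$
(uniform on $[0.05, 0.95]$ by default) and two population frequencies
independently from the Balding–Nichols prior
$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\ \frac{(1-p)(1-F)}{F}\right),$$
which has mean $p$ and variance $F\,p(1-p)$ — the standard island-model
frequency distribution whose expected Weir–Cockerham FST equals $F$.
Neutral loci use `fst_neutral` (default 0.03, the scale of the
estimated background divergence in strongly structured salmonid
systems), divergent loci `fst_divergent` (default 0.4). Two planted
diagnostic classes exist purely to exercise specific filters: `rare`
loci are fixed at frequency 0.001 in both populations (deterministically
below the 2% MAF gate), and `lowdepth` loci are sequenced at Poisson
mean 6 reads so that roughly three quarters of genotypes fall under the
8-read calling floor while the called remainder looks ordinary.

**Genotypes, depth and error.** Individuals carry
$\mathrm{Binomial}(2, p_k)$ copies of allele A. Sequencing depth per
locus and individual is Poisson with mean `mean_depth` (default 30
reads; a negative-binomial option exposes overdispersion), heterozygote
reads split 50:50 binomially, and each read flips allele with
probability `error_rate` (default 0.005). Two doubled-haploid reference
individuals carry two identical copies of a single allele draw — by
construction they can never be truly heterozygous.

**Paralogs.** Salmonids retain many duplicated loci from an ancestral
whole-genome duplication; co-stacked paralogs masquerade as SNPs
("paralogous sequence variants", PSVs). The generator models a PSV as
the union of two oppositely fixed duplicated copies, each sequenced at
the full depth model, so every individual — doubled haploids included —
shows both alleles near 50:50. This reproduces the diagnostic signature
(ubiquitous apparent heterozygosity) without simulating genome
duplication itself.

**Map.** A quarter of loci (configurable) get positions uniform on 29
chromosomes of 100 cM, mirroring a design in which only ~25% of tags
match published linkage maps. Positions are genetic (cM), so the
smoothing bandwidth below is genetic too.

**What the generator does not emulate.** Loci are unlinked (LD between
mapped loci reflects only sampling noise, not genetic linkage);
each 89-bp tag carries exactly one SNP; there are no indels, no
off-SNP sequencing errors, no allele dropout at the restriction site,
and no library-level depth covariance between individuals. Passing
tests therefore demonstrate correctness of the estimators and decision
rules under a clean generative model, not robustness to every artifact
of real libraries.

## Discovery: stacks, allele pairing, the three-comparison database

Reads (all exactly 89 bp) are stacked by identity; stacks with fewer
than 5 or more than 200 reads are discarded, with the boundary read
inclusively (depths 5 and 200 survive). Stacks differing at 1–3
positions (exact Hamming matching — tags are fixed-length, so no indel
alignment) are candidate allele pairs; both alleles need depth ≥ 5.
Groups whose variable positions show more than two bases are discarded
(biallelic rule). Where one stack could pair with several partners, it
takes the deepest one, ties broken toward the lexicographically smaller
sequence — an arbitrary but deterministic rule. Discovery runs on three
individual subsets (everyone, each population alone) so loci variable
only within one population are still found, and the union is
deduplicated on the allele-sequence pair; locus identifiers are
assigned in lexicographic order of the sorted pair, making the database
independent of subset processing order.

## Genotype calling

With $a$ and $b$ reads on the two alleles, a genotype is scored only
when $a + b \ge 8$. The decision statistic is $r = \log_{10}(a/b)$,
with $b = 0$ mapped to $+\infty$ and $a = 0$ to $-\infty$ (no
pseudocount, so 8 reads on one allele is a confident homozygote):
heterozygote for $r \in [-0.61, 0.61]$, AA for $r > 0.9$, BB for
$r < -0.9$, and the gaps $(0.61, 0.9]$ / $[-0.9, -0.61)$ are recorded
as missing with an explicit `ambiguous_ratio` reason so filter reports
can account for them. The band half-width 0.61 originated as one
standard deviation of an empirical heterozygote ratio distribution; it
is treated here as a fixed constant, not re-estimated.

## The filter cascade

Stages run in a fixed order, each seeing the survivors of the previous
one:

1. **Doubled-haploid PSV screen** — any heterozygous call in a doubled
   haploid flags the locus.
2. **Heterozygote excess** — observed heterozygote proportion ≥ 0.90
   removes the locus (the boundary is inclusive); loci with zero
   non-missing calls are removed here with reason `all_missing`.
3. **Missingness** — strictly more than 50% missing genotypes.
4. **MAF** — minor allele frequency strictly below 2% (exactly 2%
   survives; monomorphic loci are removed here).
5. **Hardy–Weinberg** — two-sided exact test (below), removal when
   $-\log_{10} P > 5$.
6. **Polymorphic-in-both** (combined datasets only) — both alleles
   observed within each population separately.

The order follows the narrative in which the duplication screens come
first and the population-genetic filters after. The HWE test
enumerates, conditional on the observed allele counts, every
heterozygote count of the correct parity, computes each configuration's
probability under random union of gametes in log space, and sums those
not exceeding the observed configuration's probability (no mid-p
correction). An exact test is used rather than chi-square because
expected counts are tiny exactly where the filter matters (low MAF).

## Per-locus and windowed statistics

Per locus the package reports sample frequencies, observed
heterozygosity, expected heterozygosity of the pooled frequencies
($H_T$), the unweighted mean within-population expected heterozygosity
($H_S$), Nei's FST $(H_T - H_S)/H_T$ (the per-locus form spreadsheet
tools report), and the Weir–Cockerham variance-components estimator.
Per-locus reported values are clipped into $[0, 1]$ — published
per-locus ranges start at 0 — but raw values are retained, and every
internal computation that cares about calibration uses the raw scale.
For multilocus summaries the ratio of summed variance components is
provided (`fst_wc_multilocus`): averaging per-locus ratios is biased
downward by a Jensen-type effect, while the ratio-of-sums form recovers
the generating $F$ within Monte-Carlo error (checked at 2,000 loci,
50 diploids per population, $F = 0.1$).

Diversity scans follow pooled-sequencing conventions: window size
100 bp (tags are 89 bp, so each tag is one window), minimum
minor-allele count 2, minimum coverage 4, and a nominal pool size of
50. Allele counts come from called genotypes rather than raw pooled
reads — the pooled-sequencing bias corrections are deliberately *not*
reimplemented, because genotype-derived counts are strictly more
informative at this scale; the nominal pool size is retained as an
optional sample-size override (`n_mode = "pool"`) for the Tajima and
Watterson constants when emulating a pooled run. Per window the package
computes segregating sites $S$, mean pairwise differences
$\pi = \sum_i 2k_i(n-k_i)/(n(n-1))$, Watterson's
$\hat\theta_W = S/a_1(n)$, and Tajima's
$$D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}$$
with the standard constants $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$.
The implementation is verified against a brute-force oracle
(explicit enumeration of all allele pairs) over every site-frequency
configuration with $n \le 6$, $S \le 5$, to $10^{-9}$.

One subtlety is documented because it is easy to get wrong: the
rare-allele filter truncates the frequency spectrum, and since
$E[\pi - S/a_1] = 0$ per segregating site only under the full $1/k$
neutral spectrum, excluding singletons biases windowed $D$ upward. The
neutrality check therefore runs the generator in its neutral-SFS mode
(ancestral density $\propto 1/x$) with `min_rare_count = 1`; under
those settings the mean windowed $D$ over ≥ 500 windows (1,200 loci,
50 diploids) is asserted to lie within ±0.15 of zero. The default
uniform ancestral distribution models an *ascertained* SNP panel
(common variants enriched), which is why windowed $D$ on default
simulations is positive — that is a property of the panel, not an
error.

## The FST outlier test

The test reimplements the FDIST-style logic usually delegated to
LOSITAN. A neutral divergence parameter $F^\*$ is calibrated so that
the mean simulated per-locus FST matches the trimmed mean of the
observed per-locus FST (observed loci beyond the simulated 99% envelope
are excluded from the target so strong outliers do not inflate the
null), to tolerance 0.002 within 50 iterations; each iteration draws
10,000 calibration loci. The production null then draws 55,000 neutral
loci — ancestral frequency uniform, Balding–Nichols population
frequencies, genotype samples at the observed sample sizes — recording
pooled expected heterozygosity and FST *with the same estimator used
for the observed loci* (Weir–Cockerham by default, the FDIST
convention).

Each observed locus is scored by
$P = \Pr(\text{simulated FST} < \text{observed FST})$ within its
expected-heterozygosity bin (20 equal-count bins, merged below 50
simulated loci; equal-count bins stabilise tail quantiles where the
heterozygosity distribution thins out). Ties count half. Two numerical
choices matter:

* **Raw estimator scale.** Per-locus Weir–Cockerham estimates are
  frequently negative under weak divergence; clipping them to zero
  before computing $P$ collapses a third or more of the null onto a tie
  atom and visibly breaks the uniformity of null $P$-values. $P$ is
  therefore computed on the raw scale; clipped values appear only in
  reports. With this choice, null $P$-values pass a Kolmogorov–Smirnov
  uniformity check at $10^4$ loci with statistic well below 0.02.
* **Classification.** Candidate for positive selection requires
  $P > 0.995$ *and* survival of Benjamini–Hochberg at level 0.05
  applied to $1 - P$; neutral means $0.1 < P < 0.9$; everything else is
  unclassified. There is no balancing-selection class — such loci are
  indistinguishable from zero-FST loci in this design.

On fully neutral panels (5,000 loci) the candidate rate stays well
under 1%. Detection power for planted divergent loci is intrinsically
limited by the truth model: a locus "drawn with $F = 0.4$" receives two
*independent* Balding–Nichols draws, so its realized between-population
divergence is highly dispersed (median realized FST ≈ 0.08), and only
about four in ten divergent loci exceed the neutral 99.5% envelope even
with exact frequencies. The measured power of the full scan (~40–45% at
2,000 loci, 5% divergent, 50 diploids per population) sits at that
ceiling; it reflects the truth model, not a calibration defect — the
same scan's null uniformity and false-positive control both pass.

## Genome-scan utilities

**Kernel smoothing.** At each grid point $c$ (0.5 cM spacing) the
smoothed statistic is $\sum_j w_j v_j / \sum_j w_j$ with
$w_j = \exp(-d_j^2 / 2\sigma^2)$ over markers within $3\sigma$. The
bandwidth is $\sigma = 5$ cM: map positions are genetic, so a physical
bandwidth has no direct analogue; 5 cM spans a handful of markers at
the default map density. Grid points with no marker in range are
reported as gaps rather than extrapolated. Peak calling is a contiguous
run of grid points above a percentile (default 95th) of the track.

**LD.** Haplotype frequencies for pairs of biallelic loci come from the
standard two-locus EM for unphased genotypes (only double heterozygotes
are phase-ambiguous; convergence at $10^{-8}$, cap 1,000 iterations;
pairs are used pairwise-complete). Lewontin's $D' = |D|/D_{\max}$ is
computed from the converged frequencies (clamped at 1 against
floating-point overshoot), averaged per chromosome, and the two
populations' chromosome-mean vectors are compared with a Welch
two-tailed t-test; identical zero-variance vectors are special-cased to
$t = 0, p = 1$.

## Reproducibility and problem sizes

All randomness flows through explicit seeds; `run_pipeline()` threads a
single seed through every stage and two runs with the same arguments
are bit-identical (asserted in the tests). The test suite and the
acceptance script use deliberately modest problem sizes — 1,200–5,000
loci, 50 diploids per population, null tables of 10,000–55,000
simulated loci — chosen so that each check has clear statistical
resolution for the property it asserts while the whole suite runs in
well under a minute.

## Known limitations

* The outlier null is a two-deme Balding–Nichols model, not a
  coalescent island model; the two agree in expectation for FST-vs-He
  envelopes but not necessarily in higher moments under strong
  migration structure.
* No bootstrap significance bands on smoothed tracks; peak calling is
  percentile-based.
* The genotype caller is threshold-based by design (fidelity to the
  published rule), not likelihood-based; its thresholds are constants.
* Windowed statistics treat tags as independent windows; there is no
  multi-SNP window support beyond what multi-SNP tags would provide.
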