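---
title: "Scanning for male-female allele frequency divergence across studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for male-female allele frequency divergence across studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Autosomal allele frequencies should be identical in males and females:
autosomes assort independently of the sex chromosomes, so any association
between an autosomal allele and sex is rebuilt from scratch — and expected
to be zero — at every generation. Observed male-female differences in a
study sample therefore have only a few possible sources: sampling noise;
sex-differential selection acting within the sampled generation (on gametes,
on embryonic and later viability); sex-biased study participation; or
bioinformatic artifacts such as cross-mapping with the sex chromosomes.
Because several of these sources are study-specific, a difference seen in
one cohort is weak evidence; a difference that replicates across
independently collected and independently processed cohorts is much
stronger.

`sdscan` implements the complete cross-study scan: per-SNP tests, gene-level
aggregation, a two-study outlier overlap with third-study empirical-null
replication, allele sign-concordance analyses, sex-stratified exact
Hardy-Weinberg (HWE) tests, and a forward simulator of the candidate
mechanisms so that the whole pipeline can be exercised and calibrated
without access to controlled biobank genotypes.

## Per-SNP tests

**Sex-difference chi-square.** For each biallelic SNP the male and female
allele counts form a 2x2 table; `chi_square_sex_diff()` computes the Pearson
statistic without continuity correction and a 1-df upper-tail p-value, plus
`delta_freq`, the male-minus-female frequency of `allele_a`. At biobank
sample sizes the uncorrected statistic is the standard choice; Yates'
correction matters only for tiny cells, and a flagged degenerate path
(statistic 0, p = 1) covers monomorphic sites and absent sexes instead. All
tests are symmetric in the allele labels, so which allele a file happens to
call `allele_a` cannot change any p-value (a property the test suite fuzzes).

**Exact HWE heterozygote test.** Within one sex, deviation from
Hardy-Weinberg genotype proportions is evidence that something — selection
or sampling — acted on genotypes of that sex after fertilization. The test
conditions on the sample size $N$ and allele count $n_A$ and uses the exact
distribution of the heterozygote count,

$$P(N_{AB}=n_{AB}\mid N,n_A)=\frac{2^{n_{AB}}\,N!}{n_{AA}!\,n_{AB}!\,n_{BB}!}\cdot\frac{n_A!\,n_B!}{(2N)!},$$

summing the probabilities of all heterozygote counts no more likely than the
observed one. Numerical choices worth recording:

* All factorials are handled in log space. Tails are assembled by
  log-sum-exp with the smallest terms added first, so p-values around
  1e-300 at $N \sim 10^4$ are still computed to full relative accuracy
  rather than underflowing to zero.
* "No more likely" comparisons use a relative tolerance of 1e-12 so exact
  rational ties are not broken by floating-point rounding.
* Above a cutoff, $\ln n!$ uses Ramanujan's approximation
  $n\ln n-n+\tfrac16\ln(8n^3+4n^2+n+\tfrac1{30})+\tfrac12\ln\pi$. Its
  absolute error decays like $n^{-4}$ and is 5.7e-9 at $n=20$ but below
  1e-12 past $n=500$. Since summing logs exactly is essentially free at
  these sizes, the default cutoff is 500: every factorial is then accurate
  to ~1e-12, enumeration probabilities sum to 1 within 1e-12, and the
  large-$N$ regime (where exactness would actually cost something) still
  uses the closed form. The cutoff is an argument everywhere.
* Probabilities are normalised over the feasible support before the tail is
  summed, so the approximation can never push a p-value above 1.

The test is the exact conditional ("Fisher-style") test on the heterozygote
count; we consistently use the heterozygote-count formulation above, which
is the natural exact test when only genotype counts are available.

## Gene-level aggregation

**Lead SNP.** The primary gene statistic is the smallest SNP p-value in the
gene ("lead SNP"). Exact p-value ties are broken by the larger
$|\Delta f|$, remaining ties by the smaller position, making the choice
deterministic. A gene's SNPs are those inside the gene body or within a
1000-bp window upstream of the annotated transcription start; the window
follows the strand, which is the biologically standard reading of
"upstream", and a SNP falling in several (possibly overlapping) genes
counts toward all of them — the conservative choice for lead-SNP
statistics. Both the window length and the chromosome set are arguments.

**LD-aware gamma aggregation.** Long genes contain more SNPs and win the
min-p race more often, so the scan also provides a length- and LD-aware
statistic in the MAGMA/Brown tradition: transform each SNP p-value to a
$\chi^2_2$ deviate $t_i=-2\ln p_i$, form $T=\sum_i w_i t_i$, and compare $T$
to a gamma distribution matched to its null moments

$$E(T)=2\sum_i w_i,\qquad
\mathrm{Var}(T)=4\sum_i w_i^2+2\sum_{i<j}w_iw_j\,c(r_{ij}),$$

with shape $E(T)^2/\mathrm{Var}(T)$ and scale $\mathrm{Var}(T)/E(T)$. For a
single SNP this collapses exactly to the SNP p-value, and a gene of $k$
perfectly correlated SNPs reproduces the single-SNP p-value — two identities
the acceptance tests assert. Weights default to 1; they are exposed per SNP.

$c(r)$ is the covariance of the two transformed statistics when the
underlying Z scores have correlation $r$. For two-sided p-values it is even
in $r$; we use the polynomial $c(r)=r^2(3.875+0.125r^2)$, which is exact at
$c(0)=0$ and $c(1)=4$ and was fitted against 4-million-draw Monte-Carlo
covariances of correlated two-sided chi-square p-values (within about 1%
for $|r|\ge 0.2$). The Monte-Carlo estimator itself ships as
`transform_covariance(..., monte_carlo = TRUE)` and serves as the oracle in
the tests. A frequently quoted alternative parameterisation of the gamma —
shape $E/\mathrm{Var}$, scale $\mathrm{Var}/E$ with a $-\log_{10}$ transform
and per-SNP mean 1 — cannot be right as printed: its gamma has mean
$\alpha\theta=1$ for every gene regardless of size, so it cannot match
$E(T)$ and destroys calibration. It is retained verbatim behind
`variant = "printed"` purely for comparison, and its output is labelled.

SNP correlations come from `estimate_correlations()` on a dosage panel
(Pearson correlation of 0/1/2 dosages), with monomorphic columns zeroed and
linear shrinkage $\lambda=0.001$ toward the identity so the matrix stays
positive semi-definite; non-PSD input to the aggregator is an error rather
than a silent fix.

## Cross-study outlier replication

No genome-wide significance threshold is imposed. Instead, each discovery
study flags its bottom 1% of genes by gene p-value — a rank cut,
$\lceil 0.01\,G\rceil$ genes, with every gene tied at the boundary included
(at 19,881 protein-coding genes this is 199 genes per study). Genes flagged
in both discovery studies form the candidate overlap. In the third study a
null distribution is built from 200 genes sampled uniformly without
replacement from the non-candidate genes; a candidate replicates when its
gene p-value falls strictly below the 1st percentile of the null p-values
(the $\lceil n/100\rceil$-th order statistic — equality does not count).
The sampled null gene ids are recorded in the report, which is otherwise a
pure function of its inputs, so any report can be replayed bit-for-bit.
All three stages can run on the lead-SNP gene p-value (the primary
analysis) or on the gamma-aggregated one (`p_col = "magma_p"`).

## Sign concordance

If the same causal variant drives the divergence everywhere, the same
allele should be the male-enriched one in every study. Alleles are
polarized by whichever allele has the higher male frequency in a designated
reference study (ties go deterministically to `allele_a` and are flagged);
each lead SNP's sign of (male minus female) frequency is then compared
between its own study and the other two — six pairwise comparisons per
gene. Because each study may have a different lead SNP, the package also
scores every SNP in the gene by the sum over the three leads of its LD with
that lead and evaluates the sign at the top-scoring ("composite") SNP.
LD is $r^2$ by default ($|r|$ selectable), and each lead's LD values come
from a configurable per-study source matrix, so a cohort without individual
genotypes can borrow another cohort's panel. A sign of exactly zero counts
as discordant (flagged); under a complete null the two non-reference signs
are independent fair coins, so full 3/3 concordance occurs at rate 1/4 — a
property the acceptance tests verify.

## The synthetic-data generator

The simulator emits sex-stratified allele and genotype count tables for
several studies from one generation of a Wright-Fisher-style cross, under
four mechanisms:

* **gametic** — among a heterozygous father's fertilizing sperm, X-bearing
  sperm carry allele A with probability $\tau_X$ and Y-bearing with
  $\tau_Y$ (0.5 = fair). Daughters' paternal transmission probability is
  $p^2+2pq\tau_X$, sons' uses $\tau_Y$; mothers transmit at $p$. A
  `shared_bridge` flag models gene products shared between sister sperm
  through cytoplasmic bridges by forcing $\tau_X=\tau_Y$ (haplotype-level
  selection is nullified when phenotypes are pooled).
* **viability** — per-sex genotype fitnesses $(w_{AA},w_{AB},w_{BB})$
  thin the sampled generation; the post-selection genotype distribution is
  the HWE distribution reweighted and renormalised.
* **participation** — identical mathematics, but the weights are
  genotype- and sex-dependent sampling probabilities; keeping it a separate
  mode preserves the semantic distinction in truth tables.
* **hwe distortion** — an inbreeding-like per-sex coefficient $F$ produces
  genotype frequencies $p^2+Fpq,\;2pq(1-F),\;q^2+Fpq$ without moving the
  allele frequency, mimicking within-sex selection signatures.

`expected_sex_freqs()` returns the closed-form post-selection allele and
genotype frequencies for every mechanism; the acceptance suite checks the
sampler against it at $n=50{,}000$ per sex within three binomial standard
errors. Only one generation is ever simulated: the divergence resets at
each meiosis, so nothing accumulates and recursion would be meaningless.

**LD model.** Within a gene, haplotypes follow a single-factor Gaussian
copula: haplotype $h$ has a latent factor $W_h\sim N(0,1)$ and carries
allele A at SNP $j$ iff $\sqrt{\rho}\,W_h+\sqrt{1-\rho}\,\varepsilon_{hj}$
falls below the $p_j$ quantile. This yields exchangeable within-gene LD
governed by one parameter, the simplest structure that exercises both the
gamma aggregation's covariance machinery and hitchhiking: selection at the
target SNP drags correlated neighbours along, and with $\rho=0$ the
spillover vanishes (both directions are tested).

**Two equivalent sampling paths.** Conditional on its factor, a haplotype's
alleles are independent across SNPs, so the distribution over the $2^S$
haplotype classes of an $S$-SNP gene is a one-dimensional integral that
Gauss-Hermite quadrature (48 nodes) evaluates essentially exactly.
Individuals are haplotype pairs, and every selection mode acts as a
reweighting of the $4^S$ pair cells — genotype weights at the target SNP,
an identical-by-descent mixture for $F$, or the $\tau$-biased transmission
law — so per-SNP genotype counts can be drawn as a single multinomial over
pair cells, in time independent of the sample size. When the class space is
small ($S\le 8$) and no per-individual dosages are requested this
marginalised sampler is used; otherwise a compiled per-individual kernel
draws each haplotype explicitly (and can return the dosage matrix needed
for LD estimation). The two paths sample the same distribution, which the
test suite checks against the closed forms on both sides of the switch.
The IBD-mixture construction restricts the simulator to $F\in[0,1)$;
the closed form supports $F\in(-1,1)$, and heterozygote-excess simulation
would need a different device (documented limitation).

**Randomness.** Everything flows from R's RNG: one master seed fixes the
gene/SNP layout and the shared base frequencies (drawn uniformly from
[0.05, 0.95] by default — common variants, where the tests are
well-behaved), and per-study substreams are derived from it, so a single
study can be re-simulated alone and reproduce its slice of a multi-study
run bit-for-bit. Study sample-size presets proportioned like the three
cohorts that motivate the design (186,936/220,062; 79,983/124,205;
14,343/19,686 males/females) ship with a `scale` argument; tests and the
acceptance script run them scaled down.

**What the generator does not emulate.** Real LD is block-structured and
long-ranged, allele frequency spectra are skewed toward rare variants,
cohorts differ in ancestry composition, and genotyping/mapping error is
absent here by construction. Passing the calibration and power tests
therefore shows that the statistics are correct and well-calibrated under
the stated model — not that the pipeline's operating characteristics on
real biobank data are identical. The cross-study design itself (not the
simulator) is what protects against study-specific artifacts.

## Problem sizes used by the checks

The calibration suite runs, per session: a fully null 2-study scan of
1,000 genes x 20 SNPs at n = 2,000/sex (stage-1 flag rate is exactly 1% by
rank construction); exhaustive exact-HWE oracle comparison for every
configuration up to N = 60 plus 1,000 random configurations up to
N = 10,000 for the Ramanujan regime; 10,000 simulated LD genes for gamma
null calibration; 50 three-study pipeline replicates with five planted
shared-selection genes (male-female frequency difference about 0.05 at
n = 5,000/sex, 5 SNPs per gene, copula rho 0.25) among 495 null genes, and
50 replicates with study-specific artifacts; 1,000 null and 100
shared-signal genes for concordance rates; and closed-form agreement at
n = 50,000/sex. The acceptance script simulates 1,000 genes x 6 SNPs in
three studies at one tenth of the preset sample sizes with six shared and
three artifact scenarios. These sizes are the package's chosen desk-scale
study conditions; all of them are arguments.

## Known limitations

* The exact HWE test is conservative (discrete support), so its null
  p-values are stochastically larger than uniform — visible in the
  calibration tests and expected.
* The gamma tail is an approximation; with few, highly correlated SNPs its
  extreme tail (p below ~1e-6) is less accurate than its bulk. The
  cross-study scheme consumes ranks and empirical percentiles, which are
  insensitive to this.
* `empirical_null_threshold()` with fewer than 100 null genes degenerates
  to the minimum order statistic (warned).
* The simulator's participation mode reweights genotypes within a sex; it
  cannot represent participation bias correlated across SNPs genome-wide
  (e.g. via a heritable behavioural trait).
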