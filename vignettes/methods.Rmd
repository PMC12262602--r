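---
title: "Methods: windowed selection scans and temporal contrasts for vector surveillance cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans and temporal contrasts for vector surveillance cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Setting

`hapscan` analyses phased biallelic SNP genotypes from structured field
collections of malaria vectors — typically a cluster-randomised trial of
insecticidal nets in which mosquitoes are collected from households in
two regions, across survey rounds, under two intervention arms.  The
questions it addresses are the standard ones of genomic resistance
surveillance: is the sampled population one genetically connected unit;
is diversity changing over the intervention; which genomic regions carry
selective sweeps; did swept-haplotype frequencies shift between the
pre- and post-intervention rounds, and differently by arm; and are any
individual SNP frequencies changing once household sampling structure is
accounted for.

The data model is deliberately small.  A `hapset` is a sites ×
haplotypes binary matrix (two phased haplotypes per sample) with
strictly ascending 1-based positions on a single contig; a `dipset` is
the corresponding sites × samples matrix of alternate-allele counts
{0, 1, 2}; a `cohort_frame` carries the per-sample trial metadata
(region, round, arm, household, country, year).  All analyses operate on
windows containing a fixed number of consecutive SNPs (default 500),
built with `make_windows()`.  SNP-count windows, rather than fixed-bp
windows, are used because haplotype-homozygosity statistics need a
roughly constant number of segregating sites per window to be comparable
along the genome; a fixed 500 bp window would typically contain a
handful of SNPs at most.  Windows tile the site axis without overlap by
default; a smaller step gives moving windows.

# Diversity statistics

For a window of $L$ sites and $n$ haplotypes with per-site alternate
frequencies $p_j$:

* nucleotide diversity
  $\pi = \tfrac{1}{L}\sum_j 2 p_j (1-p_j)\,\tfrac{n}{n-1}$, the
  unbiased per-site mean pairwise difference;
* Watterson's $\theta_W = S / a_1 / L$ with $S$ segregating sites and
  $a_1 = \sum_{i<n} 1/i$;
* Tajima's $D = (\pi_w - \theta_{W,w}) / \sqrt{e_1 S + e_2 S(S-1)}$ on
  the whole-window scale, with the 1989 normalising constants computed
  from $n$.

$D$ is reported as undefined when $S = 0$ and when the variance term
degenerates (it is identically zero at $n = 2$).  Sites with any
missing call in the analysis cohort are dropped from both the sums and
$L$; the per-site denominator is the window's (retained) site count, so
monomorphic sites dilute $\pi$ exactly as in the usual per-site
convention.

# Haplotype homozygosity and scans

The haplotype frequency spectrum of a window counts distinct
full-window haplotype strings.  From frequencies $p_1 \ge p_2 \ge
\dots$:

$$H1 = \sum_i p_i^2,\quad
H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2,\quad
H123 = (p_1+p_2+p_3)^2 + \sum_{i\ge4} p_i^2,\quad
H2/H1 = \frac{H1 - p_1^2}{H1}.$$

Pooling the top two haplotypes gives H12 power against soft as well as
hard sweeps.  The identity $H12 = H1 + 2p_1p_2$ is asserted internally.
The cross-cohort statistic $H1X = \sum_h f_A(h) f_B(h)$, keyed by
haplotype identity rather than rank, is high only where the *same*
haplotype is at high frequency in both cohorts — the signature of a
shared sweep; it satisfies $H1X(A,A) = H1(A)$ and the Cauchy–Schwarz
bound $H1X \le \sqrt{H1(A)\,H1(B)}$.

Genome-wide scans pool all contigs to set a **top-1% threshold**
(empirical $1-q$ quantile with linear interpolation, $q = 0.01$) and
group above-threshold windows into peaks: maximal runs of windows with
value ≥ threshold, with a configurable below-threshold gap tolerance
(default 0).  Runs never merge across contigs or across genomic
discontinuities in the window list, which makes peak calling idempotent.
A model-free run-merging rule is used because any more elaborate
peak-shape model would add parameters the data here cannot constrain;
the gap tolerance is the single knob.

# The temporal contrast ΔH12

For one arm, H12 tracks are computed for the pre- and post-intervention
cohorts on the same windows and differenced as
$\Delta = H12_{\text{post}} - H12_{\text{pre}}$, so that positive
values mean reduced haplotype diversity (a frequency gain of the swept
haplotype) after the intervention; a flag flips the convention for
readers who prefer the opposite sign.

Two peak/significance layers are provided:

* a **distributional peak rule**: windows whose Δ deviates from the
  genome-wide median by more than $3(P_{98} - \text{median})$ are
  flagged (positive and negative flags separately).  The deviation is
  taken from the median so that a constant track yields no peaks.
* a **label permutation test**: whole individuals (both haplotypes
  moving together, respecting within-individual dependence) are
  reassigned at random between the two rounds, keeping cohort sizes;
  Δ is recomputed per window for each of $B$ permutations (default
  1000) and the two-sided p-value uses the add-one estimator
  $p = (1 + \#\{|\Delta_b| \ge |\Delta_{\text{obs}}|\})/(1 + B)$,
  which is never zero and is conservative under ties.  Windows are
  flagged significant at raw $p < 0.01$ and marginal at $p < 0.05$;
  no multiple-testing correction is applied to the permutation p,
  which should be kept in mind when reading dense scans.

With $B = 1000$ the smallest attainable p is $1/1001$, and under a
continuous exchangeable null $P(p < 0.01) = 10/1001 \approx 0.0100$.
Because H12 values are rationals on a lattice, exact ties between
permuted and observed Δ push the test slightly below this — the
calibration test in the suite (200 windows × 20 seeds, 30 vs 30
individuals, 20-SNP windows) checks the realised rate against the
binomial 95% band around 0.01.

# F_ST and the two-individual resampling null

Per-site moment estimators are aggregated as a **ratio of averages**
$\sum N_j / \sum D_j$ (the standard bias-avoiding aggregation;
per-site ratios are never averaged).  Writing $\hat h = p(1-p)n/(n-1)$:

* Hudson-style: $N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
  \frac{p_2(1-p_2)}{n_2-1}$, $D = p_1(1-p_2) + p_2(1-p_1)$;
* Patterson-style: $N = (p_1-p_2)^2 - \hat h_1/n_1 - \hat h_2/n_2$,
  $D = N + \hat h_1 + \hat h_2$.

These two parameterisations are algebraically identical ($\hat h -
\hat h/n = p(1-p)$ collapses the Patterson denominator to the Hudson
one), so the two functions must and do agree to machine precision;
both names are kept because both circulate in the field.  Sites
monomorphic in both cohorts contribute 0/0 and are excluded; negative
estimates are reported as computed, since a "≤ 0.003" style summary
presumes signed values.

The resampling null emulates the within/between two-individual design:
each iteration draws two random individuals (both from A, both from B,
or one from each) and a fresh random set of `n_snps` sites, and
computes pairwise F_ST treating each individual's two haplotypes as a
population of two alleles (the estimator needs a within-population
heterozygosity, which a single diploid provides).  Mann–Whitney U tests
compare each within distribution to the between distribution.  Because
iterations reuse the same individuals and site pool, the Mann–Whitney
p is only asymptotically uniform under panmixia: with few individuals
the test picks up the *conditional* within/between imbalance of the
realised sample, and with a small site pool iterations are positively
correlated.  The packaged calibration experiment therefore uses 100
individuals per population, a 20,000-site pool, 500 sites and 100
iterations per run — conditions under which the rejection rate at
$\alpha = 0.05$ was measured at its nominal level — and these sizes
should be treated as part of the experiment's definition, not
incidental.

PCA uses Patterson scaling ($\sqrt{p(1-p)}$, configurable off) after
dropping incomplete sites.  Neighbour-joining trees are built with the
Saitou–Nei algorithm; negative branch lengths, which NJ can produce on
non-additive input, are clamped to zero with the excess transferred to
the sibling branch so leaf-to-leaf path lengths through the parent are
preserved.  On additive matrices NJ is exact, which the suite verifies
against randomly generated trees.

# Diplotype clustering

Candidate loci are extracted by bp interval and samples are clustered
on the Manhattan (city-block) distance between allele-count vectors,
computed over sites non-missing in both members of each pair, with
complete linkage (inter-cluster distance = maximum member distance;
merge heights are therefore monotone).  With integer distances tied
merges are resolved by `stats::hclust`'s deterministic convention, so
dendrograms are reproducible but only order-invariant when distances
are tie-free.  Flat clusters are taken at a user-chosen height or
count — the data do not define a canonical cut, so none is imposed.
Cluster summaries report size, tag-SNP allele frequencies, metadata
composition, and mean heterozygosity; a hard-swept cluster is expected
to show a high tag frequency and reduced heterozygosity relative to
wild-type clusters.

# Per-SNP temporal association

Each fully observed segregating site is tested for an allele-frequency
change between rounds with a binomial logit GLM on per-sample allele
counts (0–2 of 2) with round as the only covariate.  Household
dependence is absorbed by a cluster-robust sandwich variance over
households rather than by an explicit random effect: at per-SNP scale a
mixed-model fit per site is numerically fragile and slow, while the
sandwich estimator is asymptotically equivalent for testing the round
fixed effect.  Two finite-sample corrections matter in practice and are
applied: the usual $G/(G-1)$ cluster adjustment, and a **t reference
whose degrees of freedom are the effective cluster count** — the number
of households actually carrying the minor allele, minus one (capped at
$G-1$).  The sandwich variance is informed only by clusters where the
score varies, so a rare variant concentrated in three households gets
$t_2$ tails rather than normal ones.  Without this, type-I error under
strong household effects was measurably inflated at rare sites; with
it, the calibration tests show the robust test holding near its nominal
level while a naive binomial GLM (treating alleles independent)
inflates several-fold.  Complete separation triggers a likelihood-ratio
fallback and a flag.  Benjamini–Hochberg adjustment is applied over the
full tested set and discoveries are reported at adjusted $p < 0.05$.

# The synthetic cohort generator

Every downstream stage is exercised on data from `simulate_cohorts()`,
which emulates the trial design without any external data:

* **Neutral background.**  Per-site derived-allele *counts* are drawn
  from the standard neutral spectrum $P(i) \propto 1/i$,
  $i = 1..2n-1$, and carriers are assigned by sampling without
  replacement.  Drawing counts (not frequencies followed by binomial
  resampling) makes $E[\pi \mid S] = \theta_W$ hold exactly, so
  genome-wide Tajima's D is centred at zero by construction — the
  calibration point against which "consistently negative D" on real
  data is interpreted.  Sites are in linkage equilibrium.
* **Regional differentiation.**  Per-(site, region) normal
  perturbations of variance `d` on the log carrier weight.  `d = 0`
  reproduces exchangeability exactly; the default `d = 0.01` was
  chosen once to land the East/West genome-wide F_ST on the weak
  (≈ 0.003) scale expected of a single connected population.
* **Households.**  Samples are grouped into households of size
  $1 + \text{Poisson}(\mu - 1)$ (default mean 3) nested within
  (region, arm); per-(site, household) normal log-weight effects of SD
  `sigma_h` (default 0.5) induce the within-household allele-frequency
  correlation the GWAS stage must absorb.
* **Sweeps.**  A sweep overwrites a fraction $f$ of a cohort's
  haplotypes with copies of `n_core` core haplotypes (1 = hard,
  ≥ 2 = soft) across a bp interval; a per-site reversion probability
  growing linearly with distance from the center (`erosion`) decays
  core identity toward the flanks, producing peak-shaped H12 signals.
  The tag SNP nearest the center is fixed alternate on every core
  copy.  Core templates are shared across cohorts, so the same sweep
  identity appears in every round and arm at its configured frequency
  — which is what H1X and ΔH12 measure.  Frequencies are configured
  per (round, arm), so pre→post shifts differing by arm are a design
  input, not an emergent property.

Defaults (25 samples per region × round × arm cell, 5,000 sites on one
contig, the parameters above, a fixed seed) are the generator's
statement of realistic desk-scale study conditions.  What the generator
deliberately does **not** emulate: linkage disequilibrium and
recombination structure in the neutral background (the permutation and
resampling tests used here do not require realistic LD, and an
exchangeable-across-windows null is the cleanest for calibration),
sequencing error, and missingness mechanisms.  Passing tests on this
generator therefore validate the estimators and their null
calibrations, not robustness to LD or data-quality artefacts.

# Numerical choices and degenerate inputs

* Multiallelic and non-SNP records are dropped at VCF ingest (counts
  reported); unphased genotypes are an error naming the first
  offending record unless haplotypes are not requested.
* Haplotype statistics use only sites fully observed in the analysis
  cohort; diplotype clustering uses pairwise-complete sites; the GWAS
  uses only sites with no missing data at all.
* Quantiles use linear interpolation (R type 7) everywhere a
  threshold is defined.
* Trailing partial windows are dropped by default (keepable by flag);
  windowing with the default step is a partition of the retained
  sites.
* Permutation and resampling routines take explicit integer seeds and
  are bit-reproducible; pipeline manifests record seeds, parameters
  and a content hash.

# Problem sizes used by the bundled checks

The test-suite calibrations run at sizes chosen to make their
statistical claims sharp on a single CPU: 1,000 random windows for the
H-statistic oracle; 200 replicate cohorts for the F_ST null; 200
windows × 20 seeds × 1,000 permutations for the ΔH12 null; 50 seeds
for ΔH12 power at a 0.3→0.6 sweep shift with 50 samples per round; 20
seeds × 1,000 sites for the GWAS null and 5,000 sites with 10 planted
shifts for its power.  The acceptance script runs the full pipeline on
a 50,000-site, three-contig genome with five sweeps in the field
geometry and 25 samples per design cell.

# Known limitations

* No LD-aware statistics (iHS/XP-EHH are out of scope) and no
  coalescent or forward simulation; the generator's neutral background
  is exchangeable across windows by design.
* The GLM-with-sandwich round test is an approximation to a per-SNP
  binomial GLMM; it targets the same fixed effect and is validated by
  calibration, but it does not produce household variance components.
* Complete-linkage dendrograms are only defined up to tie-breaking on
  integer Manhattan distances.
* The Mann–Whitney comparison of resampled F_ST distributions inherits
  the dependence caveats described above; treat its p-value as
  calibrated only at study sizes comparable to the packaged
  experiment.
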