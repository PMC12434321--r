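---
title: "Indirect detection of chromosomal inversions from low-coverage genotype likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect detection of chromosomal inversions from low-coverage genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low-coverage whole-genome sequencing (lcWGS, ~2-3x per individual) makes
individual genotypes uncertain, so population-genomic analysis works with
genotype *likelihoods* rather than genotype calls. Chromosomal inversions
suppress recombination in heterokaryotypes, which leaves three indirect
footprints that survive the uncertainty of lcWGS:

1. a megabase-scale block of high linkage disequilibrium (a *haploblock*)
   visible on an r&sup2; heatmap;
2. three clusters on the first principal component of a PCA restricted to
   the block -- the two homokaryotypes flanking the heterokaryotypes;
3. an observed-heterozygosity (H_obs) ordering inside the block:
   heterokaryotypes highest, then the ancestral homokaryotype, with the
   derived (inverted) homokaryotype lowest because a young arrangement has
   had little time to accumulate diversity.

`haploscan` implements this chain end to end -- genotype likelihoods from
read counts, depth filtering, EM allele frequencies and likelihood-ratio
SNP calling, two-locus haplotype EM for r&sup2;, windowed heatmap
statistics and block calling, block PCA and karyotype clustering, H_obs
orientation and breakpoint refinement -- together with the surrounding
population-genomic context: windowed FST from the folded 2D site
frequency spectrum, redundancy analysis (RDA) against environmental
predictors, and median-joining mitochondrial haplotype networks. A
forward simulator with a planted inversion supplies ground truth for
every stage.

## The genotype-likelihood model

All estimators share one observation model. At a biallelic site with a
symmetric per-read error rate $\varepsilon$, a genotype with $g \in
\{0,1,2\}$ copies of the minor allele emits a minor-allele read with
probability $\varepsilon + (g/2)(1-2\varepsilon)$, so

$$L(g) \propto \left[(1-\tfrac{g}{2})(1-\varepsilon) + \tfrac{g}{2}\varepsilon\right]^{n_\text{major}}
\left[(1-\tfrac{g}{2})\varepsilon + \tfrac{g}{2}(1-\varepsilon)\right]^{n_\text{minor}}.$$

Triplets are stored normalised to sum one; every downstream quantity is a
likelihood ratio, so the constant is irrelevant. An individual with no
reads carries the uniform triplet and automatically contributes its prior
expectation to every estimator (e.g. dosage $2\hat f$ in the PCA, hence
zero to the centred covariance sum).

The allele frequency at a site is the EM maximiser of
$\sum_i \log \sum_g \binom{2}{g} f^g (1-f)^{2-g} L_i(g)$; a SNP is called
when the likelihood-ratio statistic against $f = 0$ exceeds the
$\chi^2_1$ quantile for the requested p-value (default $10^{-6}$) and
$\hat f \ge$ the MAF floor (default 0.05). No boundary correction is
applied to the $\chi^2$ -- the conservative convention of the
genotype-likelihood toolchain this pipeline re-derives.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `seq_error` | 0.01 | per-read error probability (dimensionless) |
| depth filter `c_sd` | 1 | site total-depth bounds mean &plusmn; c&middot;sd |
| `p_threshold` / `min_maf` | 1e-6 / 0.05 | SNP calling gates |
| LD window / quantile | 250 kb / 0.98 | heatmap cell statistic |
| `r2_min` / `density` | 0.6 / 0.6 | block caller threshold and ON-cell density |
| `min_span` | 1 Mb (10 Mb at study scale) | minimal block span |
| prune `min_weight` / `max_dist` | 0.4 / 15 kb | LD pruning graph |
| `silhouette_min` | 0.75 | karyotype three-cluster acceptance gate |
| orientation `margin` | 0.02 | minimal homokaryotype H_obs difference |
| H_obs window | 10 kb / 10 kb slide | profile resolution |
| FST window | 10 kb / 10 kb slide | ratio-of-sums windows |
| hard-call depth gates | [2, 5] per individual | RDA genotype calls |
| RDA outliers `k_sd` | 3 | per-axis loading outlier threshold |

The "second percentile" convention of LD heatmaps is ambiguous between a
low and a high quantile of cell r&sup2;; a high quantile (default
`q = 0.98`) is what makes haploblocks stand out against the background,
and `q` is exposed for the other reading.

The silhouette gate deserves a note. Clusters on PC1 are found by exact
one-dimensional k-means (a dynamic programme over contiguous segments of
the sorted scores): deterministic, and immune to the bad local optima
that centre-initialised k-means hits when karyotype frequencies are
skewed -- with an inversion at frequency 0.3 in one deme of three, ~85%
of individuals are one homokaryotype and heuristic centres collapse into
that cluster. Because optimal clustering of *unstructured* scores still
attains mean silhouettes around 0.5-0.65, the acceptance gate sits at
0.75: genuine three-cluster karyotype structure in simulation scores
0.9+, featureless PC1 scores stay below the gate and are reported
`unassigned`.

## What the simulator emulates -- and what it does not

`simulate_cohort()` uses a founder-mosaic haplotype model, not a
coalescent. Standard (STD) chromosome copies are recombinant mosaics of a
small founder pool (`n_std_founders`, default 8): crossover counts are
Poisson (`recomb_rate`), locations uniform. Inverted (INV) copies descend
from a single founder inside `inversion_interval` -- carrying
`n_inv_founder_mutations` private mutations absent from the founder pool
-- and recombine freely outside it. Recombination between arrangements
inside the interval is suppressed entirely (no gene flux), the simplest
mechanism that produces the haploblock. Consequences, by construction:

* private mutations are arrangement-diagnostic, so r&sup2; between them
  is 1 on arrangement-pure haplotypes and the block lights up in the
  heatmap;
* INV/INV individuals are homozygous throughout the interval (H_obs ~ 0
  there), heterokaryotypes are maximally heterozygous, STD/STD sit in
  between -- the orientation signal;
* the derived arrangement carries low diversity, encoding the
  lower-H_obs-equals-derived assumption that the orientation step also
  makes explicit in its output.

Because two sites' alleles stay correlated only while *both* copies sit
on one founder segment, r&sup2; decays on the scale of half the expected
segment length; the default `recomb_rate = chrom_length / 30000` (30 kb
segments) therefore targets the ~15 kb r&sup2; decay scale of the presets,
and the decay-fit test checks a factor-two band around it.

The default `n_inv_founder_mutations = NULL` scales the diagnostic
divergence with the interval (one site per ~50 kb), a density at which a
megabase-scale inversion is visible in 250-kb heatmap windows, as real
inversion haploblocks are.

Deme-level environmental covariates (temperature, pH, streamflow) are
linear in the deme's realised inversion frequency plus Gaussian noise,
redrawn until all pairwise |Pearson r| < 0.70 (the standard
constrained-ordination collinearity screen). Mitochondrial haplotypes
radiate 1-7 substitutions from a single central sequence at globally
distinct positions; inversion carriers are assigned to a few non-central
haplotypes that they share with non-carriers, the configuration in which
the arrangement is young relative to the mitochondrial radiation.

What passing tests on these simulations do **not** show about real data:
the generator has no selection, no demographic history, no gene flux or
double crossovers inside the inversion, no mapping artefacts or reference
bias, and its LD background comes from founder sharing rather than a
genealogy. A real high-LD region can also be a fusion, a low-recombination
region or a sweep; the pipeline's labels remain "potential inversions"
and the H_obs orientation is an assumption, flagged as such in its
output.

## FST, the SAF machinery, and a note on spectra

Per population, the likelihood of $j$ minor-allele copies among $2N$
sampled chromosomes is the dynamic programme over individuals with
multivariate-hypergeometric weights,

$$V_i[j] = \sum_{g} V_{i-1}[j-g]\, L_i(g)\, \binom{2}{g}\binom{2(i-1)}{j-g} \Big/ \binom{2i}{j},$$

verified against exhaustive enumeration for $N \le 4$. The joint spectrum
$\Phi[j,k]$ is the EM maximiser of the per-site mixture likelihood
(uniform start, stop at $\max|\Delta\Phi| < 10^{-9}$ or 500 iterations),
optionally folded onto minor-allele orbit representatives after the fit.
Per-site variance components are posterior expectations of Reynolds-type
moment estimators on sample counts $p_i = j_i/m_i$:

$$\alpha = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{m_1-1} - \frac{p_2(1-p_2)}{m_2-1},
\qquad \beta = \alpha + \frac{1}{2}\left[\frac{m_1 p_1(1-p_1)}{m_1-1} + \frac{m_2 p_2(1-p_2)}{m_2-1}\right],$$

which are unbiased for the squared frequency difference and reach
$\alpha/\beta = 1$ at a fixed difference; windowed FST is the ratio of
sums over 10-kb windows. The likelihood route is validated against the
same formulas evaluated on true genotype counts (estimator-consistent
comparison), with per-window agreement to 0.02 at 20x.

Recovering a *known* spectrum by EM is checked at 50k sites, N = 10+10,
10x. The target spectrum is a binomial product with cells of mass below
$10^{-3}$ removed: cells expecting a handful of sites are invisible to
any estimator at that sample size (the Kullback-Leibler divergence
between the truth and the *realised multinomial counts* already exceeds
the 0.01 bound when such cells carry mass), so leaving them in would
measure the sampling floor, not the estimator. On the truncated spectrum
the measured KL is ~2e-3; with noise-free genotypes the EM reproduces
the empirical cell distribution to machine precision.

## Numerical choices

* EM tolerances: allele frequency and genotype-frequency EMs stop at
  $|\Delta| < 10^{-8}$ (200 iterations); the two-locus haplotype EM at
  $10^{-8}$ (500 iterations), relaxed to $10^{-6}$ (200) inside the
  whole-chromosome scan where the statistic is a quantile over hundreds
  of thousands of pairs; the 2D-SFS EM at $10^{-9}$ (500).
* All EMs have monotone log-likelihood, asserted in tests.
* The two-locus EM is the one genuinely hot loop (all site pairs on a
  chromosome) and is implemented in C++.
* Ties: LD pruning deletes the lowest genomic position among
  equally-weighted nodes; modal imputation takes the lower genotype;
  k-means segmentation is exact so needs no tie rule; median-joining
  resolves equal-cost median sets by fewest vectors, then
  lexicographically.
* Block calling binarises heatmap cells at `r2_min` and grows squares
  from each start window while the ON-density of separation->=2 cells
  stays above `density` (with at least half the cells observed). Two
  robustness devices bracket the growth: failing extensions are carried
  provisionally for up to five windows and committed only if the square
  density recovers (a single sparse window must not sever a 10-Mb
  block), and after growth the edge windows whose own marginal density
  falls below the threshold are trimmed off (without the trim, a dense
  core drags low-LD windows along). Maximal non-nested intervals are
  merged when they overlap.
* Breakpoint refinement seeds at the LD block and takes the maximal run
  of windows where the heterokaryotype-minus-inverted-homokaryotype
  H_obs contrast exceeds the margin; the contrast series is computed on
  called SNPs only (monomorphic sites dilute it), smoothed with a
  5-data-window rolling mean, and dips of at most two data windows
  flanked by passing ones are closed, so single noisy windows do not
  split the run. The het-minus-inv contrast is used instead of raw low H_obs
  because runs of low-MAF sites also depress raw H_obs.
* The median-joining search enumerates median subsets exactly up to
  $n-2$ Steiner points whenever the quasi-median closure is small
  (<=128 sequences, <=2e5 subsets), falling back to greedy
  best-improvement beyond that; a spanning tree over $n$ terminals never
  benefits from more than $n-2$ Steiner points.
* One refinement pass: block intervals are refined from H_obs once, and
  the refined interval is reported next to the LD-based one.

## Problem sizes used in the checks

The end-to-end acceptance run simulates 3 demes x 40 individuals on a
40-Mb chromosome with 4,000 candidate sites, a 10-Mb inversion at
frequency 0.3 in one deme, 3x coverage and 1% read error; the LD scan
subsamples 50% of called SNPs. Replicate-based checks (H_obs ordering,
null RDA calibration) use 20 and 500 small replicates respectively. These
sizes make the full suite run in minutes on one core while leaving every
detection margin wide (block Jaccard ~0.93, karyotype accuracy 1.0,
refined-breakpoint Jaccard ~0.98 at the default seed).

## Known limitations

* Indirect evidence only: LD + PCA + H_obs cannot distinguish an
  inversion from other recombination-suppressing variants; long reads
  would be needed to confirm breakpoints.
* The covariance PCA uses global allele frequencies (single pass), not
  the iterative individual-allele-frequency refinement.
* RDA broadcasts deme-level environmental measurements to individuals,
  reproducing the pseudo-replication inherent in stream-level predictors;
  the permutation test treats individuals as exchangeable.
* The simulator's determinism contract is per R version (R's RNG streams
  are stable across platforms for a given version).
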