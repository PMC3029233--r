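---
title: "Parent-specific copy number estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-specific copy number estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscnseg)
```

## The problem

High-density genotyping arrays measure, at every SNP, a bivariate signal
$(x_t, y_t)$ quantifying the two alleles A and B. In a tumor sample each of
the two inherited chromosomes may have gained or lost copies, and the pair
of their copy numbers $\theta_t = (\theta_{t1}, \theta_{t2})$ — the
*parent-specific copy number* (PSCN) — carries strictly more information
than the total: it distinguishes a single-copy gain from an unbalanced
gain/loss, and it is the only way to see copy-neutral loss of
heterozygosity (LOH), where one chromosome is gained and the other lost
with no change in total. Tumor samples are mixtures of tumor and normal
cells, so real events appear as *fractional* shifts; any method committed
to integer copy states degrades quickly with contamination. This package
models $\theta_t$ on a continuous state space and estimates it jointly with
the unknown inherited genotype configurations.

## Model

Each SNP carries an inherited configuration
$g_t \in \{AA, AB, BA, BB\}$ giving the alleles on the two parental
chromosomes ($AB$ and $BA$ differ by which parent carries B; the parents
are exchangeable). Given $g_t$ and $\theta_t$, the observation is

$$u_t = A(g_t)\,\theta_t + \varepsilon_t,\qquad
  \varepsilon_t \sim N_2(0, \Sigma_{g_t}),$$

where $A(AB) = I$, $A(BA)$ swaps the coordinates, $A(AA)$ maps both
parental copies onto the A-allele intensity, $A(BB)$ onto B, and
non-polymorphic intensity markers average the two coordinates so that only
total copy number informs their likelihood. Configurations are a priori
independent multinomials; with a population heterozygosity $h_t$ the prior
is $((1-h_t)/2,\, h_t/2,\, h_t/2,\, (1-h_t)/2)$, and a uniform prior is the
default when no panel is available.

$\theta_t$ follows a Markov jump process with one *normal* state pinned at
the baseline $\mu_0 = (1,1)$ and two interchangeable *variant* states whose
value is redrawn from $N_2(z, V)$ at each entry. Per SNP step the chain
leaves normal with probability $p$ (split over the variant states), returns
with probability $r$, and hops between variant states (a fresh draw) with
probability $s$. Started from its stationary distribution
$(r/(r{+}p),\ p/2(r{+}p),\ p/2(r{+}p))$ the chain is reversible, so
smoothing right-to-left equals smoothing left-to-right — matching the
biology, where aberration events have no directionality.

## Estimation

Conditional on the genotype track, the filtered law of $\theta_t$ is a
point mass at $\mu_0$ plus one Gaussian per candidate most-recent change
time, with conjugate natural-parameter updates; the full-data posterior
combines the forward filter at $t$ with the backward filter at $t{+}1$
through Bayes' rule (a combined component has precision
$V_f^{-1} + V_b^{-1} - V^{-1}$). Bounded-complexity (BCMIX) pruning keeps
at most $M = 20$ components, always retaining the $K = 10$ most recent
change times, giving linear time in the number of SNPs. The implementation
is certified in the test suite against (a) an exact smoother that
enumerates all $3^n$ state sequences at small $n$ and (b) an independently
coded, unpruned $O(n^2)$ reference, both to $10^{-8}$; BCMIX pruning moves
the posterior mean by less than $10^{-2}$ on 500-SNP test tracks.

The full fit alternates:

* **E-step** — $\hat\theta_t$ = posterior mean given the current genotype
  track (the smoother above);
* **M-step** — per-SNP MAP configuration
  $\arg\max_g \pi_g\, N(u_t;\, A(g)\hat\theta_t, \Sigma_g)$, ties broken in
  the fixed order AA, AB, BA, BB;
* **hyperparameter update** — $\Sigma_g$ from per-class residuals, $(z, V)$
  from the variant SNPs, $(p, r)$ from entry/exit counts of deviation runs
  (details below),

starting from a seeded 4-means clustering of $(x, y)$ in which the two
central clusters are heterozygous and AB/BA is assigned by a fair coin (the
orientation is unidentifiable before any copy-number asymmetry exists).
Iteration stops when the mean per-SNP change of $\hat\theta$ falls below
`tol = 1e-4` (copy units), at `max_iter = 20`, or when the change norm has
stopped shrinking over three rounds. The last rule is a cycle detector:
hard genotype assignments can oscillate where configurations are almost
tied — notably complete-LOH regions at near-zero contamination — and the
trace records which rule fired. With genotypes from a matched normal the
M-step is skipped and the track held fixed.

### Numerical choices in the hyperparameter update

Three guards keep the alternating fit stable, all visible in
`estimate_hyperparams()`:

* per-class residual covariances are computed after discarding residuals
  beyond 4 MADs in either coordinate. In complete-LOH regions at low
  contamination a block of SNPs is transiently mislabeled; an unguarded
  covariance would inflate that class into a catch-all and the
  misassignment would then self-reinforce.
* the deviation indicator $\lVert\hat\theta_t - \mu_0\rVert > 0.2$ is
  denoised with a 21-SNP running median before jump entries/exits are
  counted. Per-SNP genotype flicker otherwise inflates $p$ and $r$ by
  orders of magnitude, which in turn lets the smoother chase per-SNP noise.
  Rates are clipped to $[10^{-6}, 0.2]$; $s$ stays at its default
  $10^{-4}$.
* $V$ receives an eigenvalue floor of $0.01$ (prior standard deviation at
  least 0.1 copies per coordinate), so the prior for a *new* segment value
  never collapses onto the variant values already found.

## Segmentation and region typing

The one-step distances
$d_t = \lVert \hat\theta_{t+1} - \hat\theta_t \rVert_2$ are thresholded at
`d_threshold = 0.1` and change points added greedily under a `min_sep = 20`
SNP separation constraint; this deliberately permissive pass is then
cleaned by Wilcoxon rank-sum merging (`alpha = 1e-4`, stringent because the
segment samples are large) applied to *both* the total $x+y$ and the
imbalance magnitude $|x-y|$ — the latter is what defends copy-neutral LOH
boundaries, which are invisible in the total.

Each segment is then characterized by a four-configuration Gaussian
mixture over *all* its SNPs, with component means tied through the
segment's major copy number $M$ and minor copy number $m$: AA at
$(M{+}m, 0)$, AB at $(M, m)$, BA at $(m, M)$, BB at $(0, M{+}m)$, one noise
scale for heterozygotes and one for homozygotes. Because the means are
shared functions of $(M, m)$, the fit is invariant to AB/BA orientation
errors in the per-SNP track, and it remains identified in complete-LOH
segments, where the heterozygote components coincide with the homozygote
ones and the cluster structure alone pins $(M, m)$. Three deterministic
starts are compared by likelihood (ties to the later): the near-diploid
$1.1/0.9$ start, a moment start from the per-SNP max/min coordinates, and
a heterozygote-moment start restricted to SNPs whose smaller coordinate is
well off zero — the only start near the truth for high-copy segments. The
mixture carries a weight-capped uniform background component, parameters
are estimated on the segment interior (up to 25 SNPs trimmed per end,
since breakpoint placement is uncertain at the separation-constraint
scale, and a few SNPs bleeding across a boundary can otherwise hijack an
unused component), and an LOH-aware refinement (`roh_refine()`) splits
segments at overwhelming changes of the heterozygote-call fraction
(two-proportion $z > 6$, both sides $\geq 200$ SNPs) — at exactly 0%
contamination a copy-neutral LOH region leaves the copy-number track flat
and its run of homozygous calls is the only remaining signature. Final
per-SNP genotypes are re-called from the fitted segment mixture. The
classical two-component EM on heterozygous SNPs only (initialized at
$\mu_{major} = 1.1$, $\mu_{minor} = 0.9$, mixing 0.5, unit variances) is
also exported as `fit_region_mixture()`.

Segment calls use Welch $t$-tests of $M$ and $m$ against the per-allele
baseline level (pooled $x$ and $y$ of heterozygotes in segments whose
$\hat\theta$ is within 0.1 of $\mu_0$), plus a third test of the total;
Bonferroni correction uses $3 \times$ the number of segments. A deviation
only counts when it is both significant and *material* —
`min_effect = 0.05` copy units: with thousands of SNPs per segment the
tests resolve deviations of ~0.01 copies, far below any real event and
at the scale of boundary-placement bias, and an unguarded rule would ruin
specificity. The six-way decision table is: major up & minor up →
gain/gain; major up only → gain/normal; major up & minor down → balanced
gain/loss if the total is unchanged, otherwise unbalanced gain/loss; minor
down only → normal/loss; both down → loss/loss; nothing material → normal.
Segments with minor near 0 also get the chance probability
$\prod_i (1-h_i)$ that the LOH is inherited rather than somatic
(independence approximation; linkage disequilibrium is ignored, so the
flag is conservative for long common haplotypes); the flag never deletes a
call.

## The synthetic benchmark

`simulate_chromosome()` emulates a 42,000-SNP Illumina-like chromosome:
genotypes from heterozygosity $h = 0.3$, six imposed aberration regions
(copy-number pairs (3,2), (2,1), (2,0), (3,0), (1,0), (0,0) at fixed SNP
ranges), per-region random parent orientation, dilution
$\theta = c\,(1,1) + (1-c)\,\theta_{tumor}$ at normal-cell fraction $c$
assuming a linear signal response over 0–3 fold change, and diagonal
Gaussian noise with sd 0.15 (heterozygotes) and 0.18 (homozygotes) per
coordinate, a deliberately conservative rendering of 550k-array noise.
Intensities are *not* clamped at zero in the in-memory track, so the error
law is exactly the stated Gaussian (the on-disk logR/BAF columns clamp at
zero the way platforms do). `dilution_series()` reuses identical genotype
and noise draws across contamination levels so sensitivity curves are
paired.

What the generator does **not** emulate: wave/GC artifacts, probe-specific
biases, the asymmetric and much tighter homozygote noise of real Illumina
data, or linkage disequilibrium between SNPs. Consequences worth knowing:

* real homozygote BAF noise is several-fold smaller than the generator's,
  so genotype misclassification under contamination is *harder* here than
  on real arrays; the heterozygote/homozygote error collapses to below 1%
  only once contamination separates the configurations by a few noise
  standard deviations.
* at exactly 0% contamination, complete-LOH regions carry no per-SNP
  het/hom signature at all; copy numbers are still recovered through the
  segment-level cluster structure, but per-SNP heterozygote→homozygote
  confusion there is intrinsic and expected.

## Study conditions used by the shipped checks

The test suite and the acceptance script run the full pipeline on the
42,000-SNP layout at 0% contamination (parameter recovery and six-way
typing), scan contamination in 5% steps with three seeded replicates per
level for the type-tolerance thresholds, check genotype recovery at 10–50%
contamination, and sweep twenty 6,000-SNP pure-normal chromosomes for
null behavior. Oracle comparisons use 7–50 SNPs (exact references) and 500
SNPs (pruning). These sizes are the package's chosen study conditions; the
pipeline itself has no size limit beyond memory linear in the number of
SNPs.

## Known limitations

* The AB/BA orientation of a heterozygous SNP inside an aberrant segment
  is only identified through the segment-level asymmetry; the per-SNP E/M
  track can carry orientation noise, which is why region characterization
  and the final genotype calls go through the segment mixture.
* Whole-chromosome aberrations leave no normal segment to define the
  baseline; a user-supplied baseline is then required, otherwise the
  chromosome is reported unclassifiable.
* Tumor purity is not estimated; fractional copy numbers are reported as
  estimated (e.g. a major copy number of 1.5 is consistent with a
  single-copy gain in half the cells under the linear-response reading).
* Segmentation boundaries at very high contamination (≥ 90%) smear over a
  few SNPs because the posterior-mean track changes smoothly when the
  per-SNP evidence is weak; one-step distances then drop below the
  threshold and short or shallow events are missed — the regime where
  sensitivity is expected to collapse.
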