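---
title: "Sparse parallel ICA fusion of gray matter volume and SNP dosages: models, assumptions, and design choices"
author: "spicafuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse parallel ICA fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Imaging-genetics fusion asks which genomic variation patterns co-vary with
which structural brain patterns across subjects. `spicafuse` implements a
two-block sparse parallel ICA: a gray-matter-volume (GMV) block
$X_g$ (subjects $\times$ voxels) and a minor-allele dosage block $X_s$
(subjects $\times$ SNPs) are each factorized as

$$X_g = A_g S_g, \qquad X_s = A_s S_s,$$

where rows of $S$ are statistically independent feature-space components
(a voxel map; a sparse SNP weight vector) and columns of $A$ are subject
loadings. Three couplings distinguish this from two separate ICAs: the
optimizer (i) enhances the squared correlation of the currently
best-correlated loading-column pair across blocks, (ii) pushes each SNP
component whose Hoyer sparseness falls below a threshold (default 0.4)
toward it, and (iii) leaves the GMV components unconstrained. A
multi-run ICASSO step then picks the most representative run, and every
pairwise loading association is tested with ancestry covariates under
Bonferroni correction over all $k_g \times k_s$ pairs.

Because the motivating cohorts (adults with ADHD, their unaffected
siblings, and controls; an adolescent family-based replication sample)
are private, the package ships a synthetic-data generator that emulates
the study design with a known planted truth. Every guarantee the test
suite makes is a statement about recovery of planted structure, not about
any private dataset.

## The optimizer

**Whitening.** Each block is reduced to its top-$k$ principal subspace
after removing each subject's mean over features (the ICA channel-mean
convention; feature-wise centering would make a two-subject
source-recovery problem rank-deficient). The reduced data $Z$ ($k \times$
features) satisfies $ZZ^\top/p = I$ exactly; the stored dewhitening
matrix back-projects components to feature space.

**Infomax.** The per-block update is natural-gradient extended Infomax
(kurtosis-adaptive score): $\Delta W \propto (I - K\tanh(U)U^\top/p -
UU^\top/p)\,W$ with $U = WZ$ and $K$ the diagonal of source kurtosis
signs re-estimated each iteration. A pure logistic score was rejected
because it cannot separate sub-Gaussian sources (uniform sources are the
canonical recovery test), while sparse SNP weight vectors and blob-like
voxel maps are super-Gaussian and work under either score. Defaults:
learning rate 0.2, annealed by 0.9 whenever successive updates oppose
each other, halved with a fresh random start (up to 3 restarts) on
divergence; convergence when the update Frobenius norm falls below 1e-6;
at most 1000 iterations. The same stepper drives both the
single-modality `fit_ica()` and the joint loop, so a joint fit with
coupling and sparsity disabled reproduces `fit_ica()` bit for bit — a
property the suite tests.

**Coupling.** With $M = W^{-1}$ (so loadings are $A = D M$ for the
dewhitening matrix $D$), the best-correlated loading pair $(i, j)$
receives a relative gradient-ascent step on $r^2$ in the columns $M_g[,i]$
and $M_s[,j]$. The step weight starts at 0.005 of the column norm and
adapts: up 1.1-fold when the tracked correlation slips, halved whenever
the pair reaches the ceiling (default $|r| = 0.8$) or the updated
unmixing matrix becomes ill-conditioned (reciprocal condition number
below 1e-6, or entries above 1e3 — such steps are reverted). The ceiling
is the overfitting guard: on planted data the recovered pair correlation
should approach the within-sample planted value, not the ceiling, and the
acceptance checks assert exactly that.

**Sparsity.** Hoyer sparseness $h(v) = (\sqrt{n} - \|v\|_1/\|v\|_2)/
(\sqrt{n}-1)$ is made differentiable by $|x| \approx \sqrt{x^2 +
10^{-8}}$. Each SNP component with $h$ below the threshold takes a
gradient step in its $W$ row; each component carries a multiplicative
step weight initialized at 1 (the "regularizer initialized as one"
convention), grown 1.1-fold while under the threshold and shrunk
0.9-fold above it, capped at 5. Steps that break invertibility are
reverted and the weights halved.

**Run selection.** Ten runs (master seed $m$; run $r$ seeds its two
blocks with $m + r$ and $m + r + 50021$) are clustered per modality by
average-linkage agglomeration on $1 - |r|$ between pooled component
rows; cluster quality is $I_q$ = mean within-cluster $|r|$ minus mean
between-cluster $|r|$; the representative run maximizes the summed
similarity of its components to their clusters' centrotypes. Degenerate
clusterings fall back to a greedy assignment seeded by run 1.

**Order estimation.** For each candidate $k$ the decomposition is
repeated on fresh 90% subject subsamples, components are greedily
matched across run pairs by $|r|$ of feature weights, and the
consistency statistic is the mean over run pairs of the *weakest*
matched $|r|$. Restart-only consistency was rejected: on fixed data even
spurious components re-lock onto stable noise principal directions and
stay near-perfectly reproducible far beyond the true order, so
subsampling is what makes over-specification visible, and the weakest
component is the right summary because one unstable component already
falsifies an order. The selected order is the largest candidate above
the floor (default 0.8), else the argmax.

## Preparation rules

- Voxel mask: strictly greater than 0.2 mean GMV (configurable).
- Subject QC: Pearson $r > 0.8$ against the mean GMV map, computed once
  on all input subjects (no iteration after exclusions).
- Voxel-wise residualization of age, sex, site with an intercept always
  included; the operation is an orthogonal projection and therefore
  idempotent.
- ROI reconstruction: $X_{roi} = X S^\top (S S^\top)^{-1} S$ for prior
  maps $S$ — the orthogonal projection of each subject's voxel vector
  onto the priors' row space.
- SNP preselection at external GWAS $p < 10^{-3}$, then greedy
  p-value-informed clumping at $r^2 \ge 0.9$ (squared Pearson
  correlation of dosage columns, within chromosome only; ties on $p$
  broken by chromosome, position, ID so the result is order-invariant).
- Dosage columns are z-scored before decomposition (`standardize_snp`):
  dosage variance is $2f(1-f)$, so the unstandardized principal subspace
  tracks allele frequency rather than latent structure.

## Association battery

Models 1-4 and 8 are OLS with an intercept; 5-7 add a family random
intercept. Model numbering: (1) GMV loading ~ SNP loading + 5 ancestry
components; (2) behavior ~ age + sex + GMV loading; (3) behavior ~ age +
sex + SNP loading + ancestry; (4) SNP loading ~ diagnosis + ancestry,
cases and controls only; (5) model 1 + medication with the family
intercept; (6) GMV ~ diagnosis + medication, family intercept; (7) SNP ~
diagnosis + ancestry, family intercept; (8) model 1 + family label +
family label $\times$ SNP loading, the interaction being the reported
term. Effect sizes are partial $\eta^2 = t^2/(t^2 + \mathrm{df})$ for
single-df terms. GMV case-control contrasts use a pooled-variance
two-sample t-test (Welch as a logged fallback for a zero-variance group
of two). All p-values are two-sided.

The mixed model is fitted by profiled REML: for a single random
intercept the covariance is block-diagonal, so for any variance ratio
$\theta = \sigma^2_u/\sigma^2_e$ the GLS transform subtracts
$(1 - 1/\sqrt{1 + n_f\theta})$ times the family mean from each member,
and the restricted likelihood is optimized in one dimension
(log-scale golden search over $[10^{-8}, 10^4]$, with an explicit check
of the $\theta = 0$ boundary, which reduces the fit to OLS and is
flagged, not an error). Wald tests use residual degrees of freedom
$n - p$. The suite cross-checks estimates against lme4 and a planted
intraclass correlation of 0.5.

## Stability and replication

- **Subsampling**: stratified 90% draws per diagnostic group; each refit
  is matched to the reference by greedy $|r|$ of feature weights with
  sign alignment; a pair is "reproduced" when the matched loadings
  associate at the full-sample Bonferroni threshold with the reference's
  sign. The same-sign-significance rule is a configurable default.
- **Permutation null**: subject order permuted independently in the two
  blocks, refit, all $k_g k_s$ pair statistics pooled. Two summaries are
  reported: the fraction of null pairs significant under Bonferroni at
  $\alpha/(n_{perm} k_g k_s)$ (`sig_fraction`), and a conventional
  max-$|r|$ tail per identified pair. Both are kept because the first
  depends on the Bonferroni denominator in an unusual way.
  Permutations are applied to the prepared (residualized) matrices so the
  covariate structure is preserved.
- **Sweeps** over SNP order, preselection $p$, and pruning $r^2$ refit
  and report the best-match $|r|$ per reference SNP component.
- **Replication**: least-squares projection of fixed components into the
  new cohort ($A = X_c S^\top(SS^\top)^{-1}$, subject means removed),
  model 5 per identified pair with BH-FDR across identified pairs only,
  age-stratified fits in five quantile bins (the original bin edges are
  not public; quantile bins are the package default, configurable), and
  a univariate per-SNP scan with BH-FDR.

## The synthetic cohorts

`generate_cohort()` defaults emulate the adult discovery sample: n = 341,
group counts 167/47/127 (largest-remainder rounding makes stated
proportions exact), ages uniform on 18-63, group-conditional sex, site,
stimulant-medication rates and symptom/digit-span moments patterned on
the published demographics table. Sibling-family mode (for the
adolescent sample: n = 461, 188/129/144, ages 7-17) draws family sizes
from a configurable distribution; family members share site and ancestry
exactly and fall in a 6-year age window.

GMV data are a fixed smooth baseline envelope (peak 0.5 — the "brain",
so mean-GMV masking behaves as on tissue) plus $A_g S_g$ with unit-norm
Gaussian-blob maps and voxel noise of SD 0.01. Genotypes stay valid
dosages: SNP $j$ of subject $i$ is Binomial$(2, f_{ij})$ with
$\mathrm{logit}(f_{ij}) = \mathrm{logit}(f_j) + \beta a_i w_j$, where
$a_i$ is the loading on the component owning the SNP's LD block. $\beta$
is calibrated per run by a small pilot simulation to a target
dosage-loading correlation (default 0.75). LD is block-copy with
per-allele flip probability 0.15. Three of these values were set by
identifiability analysis rather than taken from any published number,
and the reasoning matters for interpreting test results:

- *Coherent within-block weights.* Block members are noisy copies of a
  root, so a weight pattern that flips sign inside a block is not
  expressible in the data at all; one sign and base magnitude per block
  (with 20% per-SNP jitter) makes the planted weights recoverable and
  matches how LD tagging behaves.
- *Flip probability 0.15.* At 0.05 a block is essentially one effective
  measurement of $a_i$ and the planted weights are statistically
  unidentifiable at n = 300; at 0.15 the in-block $r^2$ is about 0.8 for
  signal blocks and 0.5 for null blocks — a panel that plausibly
  survived light (r² < 0.9) pruning, which is exactly what the
  preselection emulates.
- *Dosage-correlation target 0.75.* Binomial sampling caps the
  per-SNP information; below about 0.5 the ten planted components
  interleave with null LD-block directions in the principal subspace and
  no method could separate them at this n.

For each linked pair the two loading columns are drawn from a bivariate
normal whose correlation is the subject's group target, optionally
ramped linearly in age and clipped to $(-0.95, 0.95)$. Group-wise sample
correlations converge to the targets (tested at n = 3000 within 0.05).

What the generator does **not** emulate: scanner artifacts and site
effects beyond a categorical covariate, realistic recombination (LD is
blockwise only), population stratification beyond Gaussian ancestry
scores, and any relationship between the behavioral scores and the
planted components. Passing tests therefore demonstrate that the
algorithms recover the structure they model, under noise levels chosen
for testability — not that the effect sizes of any real cohort are
attainable.

## Problem sizes used by the checks

The recovery checks run at n = 300 subjects, a 20^3 voxel grid
(4000 voxels), 800 SNPs and 10 SNP components (the adult-cohort shape at
reduced feature counts); stability and permutation checks run at n =
150-200 with 200-400 SNPs and 2-5 components, with 2-3 ICASSO runs per
refit and 40-50 permutations; the end-to-end acceptance script uses the
full n = 341 / 461 cohort sizes. These sizes were chosen so the full
battery completes in minutes on one CPU while keeping every recovery
margin comfortable.

## Known limitations

- The coupling enhances one loading pair per iteration (the current
  best); simultaneous enhancement of several pairs is configurable in
  principle but not enabled by default.
- Wald degrees of freedom in the mixed model are the residual $n - p$,
  which is mildly liberal for small family counts (no Satterthwaite
  correction).
- The permutation and subsampling drivers refit with reduced run counts
  by default; fully matching the discovery fit's 10 runs per refit is a
  parameter change, not a code change.
- NIfTI support covers reading and writing volumes on a regular grid;
  no affine resampling or atlas lookup is provided.
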