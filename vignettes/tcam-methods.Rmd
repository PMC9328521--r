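---
title: "Tensor component analysis for longitudinal omics: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor component analysis for longitudinal omics: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcam)
```

## The problem

A longitudinal omics study yields, for each of $m$ subjects, a $p \times n$
matrix of features by timepoints. Two sources of variance compete in such
data. Static inter-individual differences — each person's idiosyncratic
microbiome or proteome baseline — are usually large. Temporal
intra-individual changes — the response to a treatment, the recovery after a
perturbation — are usually smaller, and are usually what the study is about.
When the data are flattened to a (subject, timepoint) $\times$ feature
matrix and ordinated with PCA, the static differences dominate: samples
cluster by subject and the dynamics are invisible. tcam keeps the
subject/feature/time structure intact and reduces trajectories, not
samples.

## The model

Data live in an order-3 tensor $\mathcal{A} \in \mathbb{R}^{m \times p
\times n}$ (subjects $\times$ features $\times$ timepoints). The algebra is
parameterized by an invertible $n \times n$ matrix $M$ applied along time:
the mode-3 product $\hat{\mathcal{A}} = \mathcal{A} \times_3 M$ transforms
every tube fiber $\mathcal{A}_{i,j,:}$, and the $\star_M$ product of two
tensors multiplies their hat-domain frontal faces slice by slice before
mapping back with $M^{-1}$. Under $\star_M$ every tensor admits a tubal SVD
(tsvdm)
$$\mathcal{A} = \mathcal{U} \star_M \mathcal{S} \star_M \mathcal{V}^T$$
with $\star_M$-orthogonal $\mathcal{U}, \mathcal{V}$ and f-diagonal
$\mathcal{S}$; computationally this is one economy matrix SVD per
hat-domain face.

tcam centers $\mathcal{A}$ to mean-deviation form (MDF) by subtracting the
mean sample $\bar{\mathcal{A}}$, decomposes the centered tensor, and sorts
*all* hat-domain singular values $\hat\sigma$ across faces into one global
ranking $r = \{(r_{h,1}, r_{h,2})\}_h$ of (diagonal, face) pairs. Factor
$h$ then has:

* **score** $Z_{\ell,h} = [(\mathcal{A} \star_M \mathcal{V}) \times_3
  M]_{\ell, r_{h,1}, r_{h,2}}$ — for training data this equals
  $\hat{U}_{\ell, r_{h,1}, r_{h,2}} \hat\sigma_h$, which is how the fit
  computes it (the definitional path is what `predict()` uses, and the two
  agree to $10^{-10}$ by test);
* **loading** row $h$ = the $r_{h,1}$-th right singular vector of hat face
  $r_{h,2}$ — a unit-norm $p$-vector of signed feature contributions;
* **explained variance** $\hat\sigma_h^2 / \sum_j \hat\sigma_j^2$.

Keeping the $q$ top-ranked factors is *explicit rank-$q$ truncation*.
Empirically verified guarantees (all in the test suite): the truncation
error satisfies $\|\mathcal{A}-\mathcal{A}_q\|_F^2 = \sum_{h>q}
\hat\sigma_h^2$ for orthonormal $M$ and is minimal among all keep-sets of
$q$ hat diagonals (checked exhaustively on small tensors); among random
pseudo $\star_M$-orthogonal rank-$q$ maps, tcam's scores maximize retained
variance and minimize the nuclear-norm distortion $\|AA^T - ZZ^T\|_*$ of
the mode-1-unfolded Gram configuration; full-rank score distances equal
centered-trajectory Frobenius distances, which is what justifies running
PERMANOVA-style testing on the scores; the factors are nested in $q$; and
at $n = 1$ with $M = [[1]]$ everything collapses to classical PCA.

## Parameters that matter

**The transform $M$** (`m_transform()`): default is the orthonormal DCT-II,
which concentrates smooth temporal variation into low-frequency faces and
makes $\times_3 M$ an exact isometry — so hat-domain and data-domain errors
coincide, and the truncation-error identity holds exactly. A seeded
Haar-random orthogonal matrix is provided as an alternative; results are
reproducible from the stored seed. Only real orthogonal transforms are
supported: they keep scores and loadings real-valued. Searching for a
data-optimal $M$ is out of scope (and not generally feasible).

**The retained dimension $q$** (default: all $k n$ components, $k = \min(m,
p)$): because the factors are nested, $q$ is presentation, not fitting.
`choose_q_by_variance()` implements the usual cumulative-variance rule;
`plot_scree()` supports the visual one.

**Baseline normalization** (`normalize_dfb()`, `normalize_lfb()`): both
re-express each subject relative to their own baseline timepoint(s), which
is what removes the static offsets that mask dynamics. Multiple baseline
timepoints are aggregated by their arithmetic mean — the simplest
subject-level reference. LFB uses a symmetric pseudocount (default 1,
suited to counts) inside the ratio and log base 2 (fold-change convention);
both are explicit arguments, not hidden constants. Baseline slices become
(for a single baseline timepoint, exactly) zero and are retained so $n$
stays the same for every subject; drop them explicitly if you prefer.

**rclr** (`normalize_rclr()`): per (subject, timepoint) sample, nonzero
entries are log-transformed and centered by the mean log over the *nonzero*
support; zeros stay zero. This matched-mask convention avoids the
distortion a pseudocount imposes on sparse compositions; the cost is that a
zero is treated as "no information", not as a small value.

**Feature filtering** (`filter_features()`): prevalence and mean-abundance
thresholds with no defaults beyond "keep everything" — cutoffs are
study-specific and belong in the analysis record, which is why every
preprocessing step is appended to a `normalization_log` that
`replay_normalization()` can re-execute bitwise.

## Numerical choices

* **Economy decomposition.** Only $k = \min(m,p)$ singular triplets per
  face are computed and the ranking spans $k n$ tuples, not $p n$: omics
  data have $p$ in the hundreds-to-thousands and $m$ in the tens, and the
  omitted tuples all have $\hat\sigma = 0$ exactly, carrying no score or
  loading information.
* **Sign convention.** SVD columns are sign-ambiguous; we make the
  largest-magnitude entry of each hat-domain right singular vector positive
  (ties: lowest feature index), flipping the matching left column. Fits are
  therefore bitwise reproducible across runs, which the regression tests
  rely on.
* **Tie-breaks in the ranking.** Equal $\hat\sigma$ are ordered by
  ascending face, then ascending diagonal index — stable and documented.
* **Degenerate input.** A tensor whose horizontal slices are all identical
  has zero total variance; `tcam()` raises an error rather than emitting
  NaN variance fractions. A single subject cannot be centered meaningfully
  and is likewise rejected.
* **Loadings orientation.** A face of $\hat{\mathcal{V}}$ holds orthonormal
  *columns* (right singular vectors); loadings row $h$ is defined as the
  $(r_{h,1})$-th such column of face $r_{h,2}$. This makes loadings rows
  unit-norm, mutually orthogonal within a face, and consistent with the
  tensor $\mathcal{V}$ used by the projection — the orientation under which
  "feature $j$'s contribution to factor $h$" is well defined.
* **Tolerances.** Reconstruction and round-trip identities are asserted at
  $10^{-10}$ relative; orthogonality at $10^{-8}$; Gram/distance identities
  at $10^{-8}$ — comfortably above double-precision noise for the problem
  sizes used, far below any scientifically meaningful difference.

## The synthetic test bench

`generate_longitudinal_tensor()` emulates the structure the method is
designed for, with entry
$$x_{ijt} = \text{baseline}_j + \text{offset}_{ij} +
\text{effect}_{g(i),t}\,\mathbb{1}[j \in \text{signal}] + \varepsilon_{ijt}.$$
Defaults — chosen once as a realistic modest two-arm study — are 2 groups
$\times$ 10 subjects, $p = 50$ features, $n = 8$ timepoints, 3 signal
features, subject offsets of SD 1, noise SD 0.5, and a group effect that
ramps linearly from 0 at baseline to amplitude 3 at the last timepoint (so
the baseline timepoint is group-neutral, as in a treatment study). A
`counts` mode draws from a log-normal–Poisson chain to produce the sparse
non-negative tables rclr expects. All randomness flows from one seed.

What the generator does *not* emulate: compositional closure and
sequencing-depth variation, taxon–taxon ecological interactions, irregular
sampling grids, dropout that correlates with state, batch effects. Passing
the recovery tests therefore shows the machinery is correct on data with
known planted structure — it does not by itself certify performance on any
real cohort.

Two designed scenarios back the main scientific claims. With a single
planted signal feature and zero noise, deviation-from-baseline
normalization removes the (time-constant) subject offsets exactly, so the
signal feature must top the loadings of the group-separating factor — this
is checked across 40 seeds. With offsets made much larger than the effect,
flattened-matrix PCA clusters by subject (higher silhouette by subject than
by group) while tcam after DFB still isolates a group-separating factor —
the masking phenomenon the method exists to overcome, constructed here so
it is provable by design.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use deliberately small tensors:
50 random tensors up to $9 \times 9 \times 8$ for reconstruction;
$4 \times 5 \times 3$ for the exhaustive keep-set enumeration (2509
reconstructions); 10 MDF tensors of $6 \times 8 \times 3$ against 200
random competitor maps each for the optimality properties; cohorts of 10–20
subjects for synthetic recovery. These sizes make every guarantee checkable
exhaustively or near-exhaustively; all of the properties asserted are
dimension-free identities, so nothing about them is specific to the sizes
chosen.

## Known limitations

* Missing data are handled by naive whole-sample imputation (zeros, LOCF,
  linear); tensor-completion approaches are out of scope.
* The choice of $M$ is the user's; there is no data-driven selection.
* Tensors of order $> 3$ (e.g. multi-omics as a fourth mode) are not
  supported.
* Statistical inference on the scores (PERMANOVA, mixed models, FDR) is
  deliberately left to the established downstream tools; tcam produces the
  coordinates those tools consume.
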