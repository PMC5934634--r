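---
title: "Explicit one-dimensional normalization of Hi-C matrices: model and methods"
author: "onedhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explicit one-dimensional normalization of Hi-C matrices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onedhic)
```

## Why a one-dimensional model

A binned Hi-C experiment yields a symmetric matrix $x_{ij}$ of contact counts
between genomic bins. Local genomic features — G+C content, read mappability,
restriction-site density — distort counts multiplicatively, and implicit
balancing methods (vanilla, ICE, Knight–Ruiz) remove the distortion by forcing
every bin to the same total. That regularity assumption breaks on aberrant
karyotypes: a bin present in four copies legitimately carries about twice the
diploid signal, and balancing erases the difference or, worse, redistributes it.

This package instead models the biases *explicitly* on a single variable, the
contact profile
$$t_i = \sum_j x_{ij},$$
the genome-wide per-bin total (cis plus trans, diagonal counted once). Totals
are overdispersed counts, so they are modeled as negative binomial:
$$t_i \sim \mathrm{NB}(\lambda_i, \theta), \qquad
\log \lambda_i = \alpha + \sum_k f_k(z_{k,i}),$$
with one smooth function $f_k$ per covariate $z_k$. Each $f_k$ is a low-rank
thin-plate regression spline (basis dimension 10 by default) with a
second-order wiggliness penalty; smoothing parameters are selected by REML and
the dispersion $\theta$ is estimated jointly, using mgcv as the fitting
engine. The smooths are centered, so the proportionality between
$\log\lambda_i$ and the covariate effects is resolved by a free intercept.

The fitted means are rescaled to mean one over the bins that entered the fit,
$$\lambda_i' = \frac{\lambda_i}{\sum_j \lambda_j / n},$$
and every entry is corrected as
$$\hat x_{ij} = \frac{x_{ij}}{\sqrt{\lambda_i' \lambda_j'}}.$$
Because the rescaling cancels any global factor, the correction is invariant
to sequencing depth, and whether the intercept is included in $\lambda$ is
immaterial. Crucially, the corrected profile $\hat t_i$ remains proportional
to the local copy number: karyotype is treated as signal, not bias.

## Optional copy-number correction

When a euploid-equivalent map is wanted, per-bin copy number is inferred from
the corrected profile with an 8-state hidden Markov model with Student-$t$
emissions. States $k = 1..7$ represent $k$ copies and share a tied location
$k\beta$; state 8 ("8 or more") has its own location $\mu_8$; all states share
one scale $\sigma$ and one degrees-of-freedom $\nu$ — four emission parameters
in total, plus 56 free transition parameters; the initial distribution is
fixed uniform. Fitting is by Baum–Welch; the Viterbi path gives the copy
number $c_i$ and the matrix is corrected as
$$\hat x^*_{ij} = \frac{\hat x_{ij}}{\sqrt{c_i c_j}},$$
with $c = 8$ standing in for the open-ended top state.

Implementation choices, where the procedure is genuinely open:

* **Chains.** One chain per run of consecutive unmasked bins within a
  chromosome; masked bins and chromosome boundaries break chains, since copy
  number has no continuity across either.
* **Initialization.** $\beta = \mathrm{median}(\hat t)/\mathrm{modal\_cn}$
  (modal copy number 2 by default — the most common state is assumed diploid
  and is user-configurable), $\mu_8 = 8\beta$, $\sigma = \mathrm{MAD}$,
  $\nu = 10$, transition matrix 0.99 on the diagonal.
* **M-step.** The $t$ distribution is handled as a scale mixture of normals:
  posterior-weighted least squares for the tied $\beta$, a weighted mean for
  $\mu_8$, the standard weighted second moment for $\sigma$. The degrees of
  freedom are updated by direct one-dimensional maximization of the
  observed-data log-likelihood over $\log\nu \in [\log 1, \log 100]$ (an ECME
  step). This keeps every iteration provably non-decreasing in the actual
  likelihood and avoids the digamma fixed-point equation; the update is
  validated in the tests against a numerically optimized M-step.
* **Numerics.** Scaled forward–backward recursions with a per-bin shift of
  the log emissions, so finite input can never underflow; $\sigma$ is floored
  at $10^{-6}\beta$; Viterbi ties break toward the lower copy number;
  convergence at relative log-likelihood change $< 10^{-6}$ or 500 iterations.

## Masking and capture designs

Bins with zero total (threshold configurable), missing covariates or zero
mappability are masked: they contribute nothing to the profile or the fit,
receive no correction and are dropped from corrected output. This is what
makes the method applicable to capture designs, where most of the genome is
formally present in "zero copies": the empty bins are excluded and the model
fits only where there is signal. Below 50 usable bins the fit refuses rather
than extrapolate.

## Baselines and metrics

The balancing baselines are provided for comparison: `vanilla()` (one
iterative-correction pass), `ice()` (iterated until the coefficient of
variation of per-bin totals drops below $10^{-5}$; the published tolerance is
not stated, so the textbook variant is used), and `kr()` (Knight–Ruiz Newton
balancing, inner–outer conjugate-gradient form). All express their output as
per-bin biases feeding the same entry-wise correction primitive.

Four comparison metrics operate on pairs of matrices over a shared bin table,
restricted to bins unmasked in both and — except for the spectral score — to
cis cells within 5 Mb by default. Zero cells inside the band are always
included, so values do not depend on sparsity patterns:

* banded Spearman correlation;
* Pearson correlation of observed/expected ratios, where the expected count
  is the per-(chromosome, distance) mean over all valid pairs;
* the stratum-adjusted correlation coefficient: per-distance Pearson
  correlations combined with weights $N_k \,\mathrm{sd}_1(k)\,\mathrm{sd}_2(k)$,
  after an optional 2D mean filter (half-window 2 at 100 kb by default, with
  truncated windows at the borders); zero-variance strata are skipped;
* a spectral score: per chromosome, the leading 20 non-trivial eigenvectors of
  the symmetric normalized Laplacian are compared by Euclidean distance after
  per-vector sign alignment, and the summed distance is rescaled linearly to
  $[0, 1]$ as $1 - d/(k\sqrt{2})$ ($\sqrt{2}$ being the largest possible
  distance between sign-aligned unit vectors), clamped at 0 and averaged over
  chromosomes. Eigenvectors are paired in eigenvalue order; repeated
  eigenvalues make the pairing unstable, a known limitation. When a
  chromosome has fewer usable bins than requested eigenvectors, the number is
  reduced and recorded.

`roc_evaluate()` turns similarity scores plus same/different labels into a
ROC curve by threshold sweeping (tied scores enter simultaneously) and a
trapezoidal AUC, which equals the normalized Mann–Whitney statistic.

## What the simulator emulates

`simulate_base_matrix()` builds an expected matrix
$\mu_{ij} = s\,(1 + |i-j|)^{-\alpha}\, b_i b_j$ on the cis blocks, a constant
trans floor calibrated so trans contacts make up a configurable fraction
(default 0.3) of a typical bin's total, optional domain (TAD-like) block
enrichment, and draws negative-binomial counts (dispersion 20 by default)
around it. The defaults describe a 500-bin genome (4 chromosomes of 125 bins)
at 100 kb, decay exponent 1 and $10^6$ expected contacts.

The covariate tracks mimic two scales of real genomic features: an
isochore-like backbone with a period of a few bins plus bin-to-bin jitter
(plain Poisson counts for restriction sites). The fast component matters: real
G+C and mappability vary much faster than copy-number segments, and that
separation of scales is what prevents the profile smooths from absorbing
genuine copy-number structure. The default bias functions (near-linear in
G+C, logarithmic in mappability, saturating in restriction-site count) are
scaled so the raw contact profile fluctuates with a coefficient of variation
of roughly 0.35 inside constant-copy-number regions, the magnitude seen in
raw profiles of published experiments.

Copy-number aberrations follow the published injection protocol: 3–10
breakpoints placed uniformly at random on the target chromosomes, each
segment assigned 2, 3, 4 or 10 copies with equal probability, and the matrix
multiplied element-wise by the outer product of $c_i/2$ (diploid baseline, so
copy number 2 is neutral), with deterministic half-up rounding to keep counts
integral. `simulate_benchmark()` reproduces the benchmark design: per
simulation, two "cell types" with distinct domain structure, replicates with
their own random smooth biases (standing in for batch and protocol effects),
and **one** copy-number profile shared by all samples of the simulation, as
in the original protocol.

What the simulator does *not* emulate: translocations and inversions,
fragment-level resolution, realistic TAD hierarchies, subclonal (fractional)
copy numbers, and ligation artifacts. Passing tests therefore demonstrate the
mechanics of the method under its stated model, not performance on any real
library.

## Desk-scale effects worth knowing about

The test genome is roughly 60-fold smaller than a mammalian genome, and one
consequence is quantitatively important. Under the outer-product injection, a
segment with copy number $c$ in a diploid background raises the totals of its
bins by a factor $(c/2)\,(1 + (c/2 - 1)\, s)$, where $s$ is the share of a
segment bin's contacts that land inside the segment. The often-quoted
first-order rule — a duplicated region gains 50% — is the limit $s \to 0$,
appropriate when the segment is a vanishing fraction of a $3\times10^4$-bin
genome. With decay exponent 1 the contact mass is close to uniform per decade
of distance, so at 125–250-bin chromosomes $s$ is 0.15–0.45 for any contiguous
segment and a CN-3 segment gains roughly 80%, not 50%; injected segments also
sit *between* HMM states (a CN-3 segment near $3.5\beta$). The acceptance
suite reports the honestly measured value; the copy-number recovery tests
assert binarized aberrant-versus-diploid calls and breakpoint positions, and
validate exact state recovery on profiles generated at the HMM's own scale.
For the same reason the matrix-level flatness checks use a fixture whose
contact pattern is short-range relative to the bias wavelength — the regime
the square-root correction assumes — while bias removal in general is asserted
at the profile level ($t_i / \lambda_i'$), where it is exact.

## Problem sizes and numerical tolerances used in validation

The shipped validation uses 500-bin genomes for pipeline checks, 2,000 bins
for dispersion and bias recovery, 20 simulations of 2×250-bin genomes for the
reproducibility benchmark, and exhaustive enumeration over all $8^6$ state
paths for the HMM oracles. Identities derived from the equations (mean-one
rescaling, correction round-trips, uniform copy-number division) are asserted
to $10^{-10}$ or tighter; stochastic recovery checks use the thresholds stated
in their tests. The penalized-likelihood optimum is verified at fixed
smoothing parameters against an independent multi-start BFGS optimizer, since
the REML-selected smoothing parameter is not itself a penalized-deviance
minimizer.

## Known limitations

* The square-root entry correction fully flattens the profile only when
  biases vary slowly relative to the contact-decay window; high-frequency
  bias components are corrected at half strength in log scale (visible as
  residual profile fluctuation), though the rescaled correction vector itself
  is unbiased.
* Copy-number inference assumes the most common state is the modal copy
  number supplied by the user, and cannot distinguish globally rescaled
  karyotypes (a triploid genome with `modal_cn = 2` will be mis-anchored).
* Artifacts that are not copy-number changes (inversions, translocations)
  pass through unchanged.
* The spectral score's eigenvector pairing is unstable under (near-)repeated
  Laplacian eigenvalues.
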