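---
title: "Group-level PCA solvers: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level PCA solvers: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grouppca)
```

## The model

Group ICA of temporally concatenated fMRI works on a two-stage reduction.
Stage one takes each subject's column-centered voxels-by-time matrix
$Z_i \in \mathbb{R}^{v \times t}$ and keeps its top $p$ principal
components, $Y_i \in \mathbb{R}^{v \times p}$, via EVD of the small
$t \times t$ time covariance (whitening the scores is optional at this
stage — `reduce_subject(whiten =)`). Stage two, the subject of this
package, needs the top $k$ eigenpairs of the group covariance of the
stacked data $Y = [Y_1 \cdots Y_M]$,

$$C = \frac{Y^\top Y}{v - 1} \in \mathbb{R}^{Mp \times Mp},
\qquad
C^v = \frac{Y Y^\top}{v - 1} = \sum_{i=1}^M \frac{Y_i Y_i^\top}{v-1}
 \in \mathbb{R}^{v \times v},$$

which share their nonzero eigenvalues. Every solver returns the same
contract (`pca_result`): an orthonormal spatial basis $X \in
\mathbb{R}^{v\times k}$, the eigenvalues $\Lambda$ of $C$, a whitened
basis, and the eigenvector matrix $F = Y^\top X$ with unit-norm columns,
which downstream back-reconstruction consumes.

Three cost axes matter, and they trade off: floating-point work, resident
memory, and *dataloads* — reads of one subject's matrix from storage,
the unit of I/O cost when $Y$ cannot be held in memory. Every solver here
can run "un-stacked", touching one subject at a time per pass, and the
provider counts dataloads so the accounting is testable: exact EVD via
$C$ costs $M(M-1)/2$ pairwise loads; via $C^v$, $M$ loads; MPOWIT costs
$M$ per iteration; EM PCA $2M$ per iteration; STP exactly $M$ total.

## Whitening convention

Published formulations of the final scaling differ between
$X = Y F \Lambda^{-1/2}$ (which gives unit *sample variance*,
$X^\top X/(v-1) = I$) and $X_j W_j \Lambda_j^{-1/2}$ applied to an
orthonormal block (which gives column norms $\lambda^{-1/2}$). The package
standardizes on **unit sample variance** for every `whitened` output,
always exposes the orthonormal `basis` separately, and keeps the verbatim
eigenvalue scaling available in `mpowit(scaling = "eigs")` for
compatibility. Eigenvector signs are fixed by making the
largest-magnitude entry of each basis column positive; when eigenvalues
tie, only subspaces (principal angles), never individual vectors, are
meaningful, and the tests respect that.

## The solvers and their tunable parameters

**Exact EVD** (`evd_group_pca`) forms the covariance in the smaller
dimension (time path if $Mp < v$, else voxel path) and eigendecomposes it.
Dimension caps (`cap = 20000` per side, configurable) stand in for
hardware-specific memory guidance: beyond them the function refuses and
names the iterative alternatives. Top-$k$ extraction uses the full LAPACK
symmetric EVD with truncation, which at these capped sizes is exact and
cheap; the iterative solvers carry the published tolerance
$\delta = 10^{-6}$ and 1000-iteration limit.

**SVP** (`svp`) exploits spatial smoothness: smoothed volumes are
oversampled, so a depth-2 lattice subsampling (all-odd and all-even
coordinates, $v' \approx v/8$ each) retains most information. Each parity
set gets its own EVD in the reduced voxel space with intermediate order
$k'$ (default $\min(500, v', Mp)$; 500 matches $k \approx 100$ at
production scale, keeping the ratio $k' \approx 5k$), both bases are
projected back through the data, and a joint $2k' \times 2k'$ Gram EVD
merges them. Two dataloads per subject build the subspace; one further
documented pass reads out Rayleigh–Ritz eigenvalues and $F$ on the merged
subspace, because the merge-Gram spectrum lives on a squared data scale
(its projection matrices are not column-orthonormal) and would not be
comparable to the exact spectrum.

**STP** (`stp`) consumes subjects in groups of $g$ (default 20; desk-scale
analyses here use $g = 5$, i.e. $M/2$, so at least one merge is
exercised), eigendecomposes each group's $gp \times gp$ covariance, keeps
the *variance-weighted* group subspace $X_g = Y_g F_g$ — deliberately not
whitened, so principal-component weights stay correct across merges — and
folds it into the running estimate via a $2k' \times 2k'$ Gram EVD,
truncating back to $k'$ columns after each merge so memory stays bounded.
Because every projection applied to the data is orthonormal, the
merge-Gram eigenvalues *are* Rayleigh–Ritz values of $C$ on the data
scale, so STP needs no read-out pass and its single-pass ($M$ dataloads)
contract holds exactly; `backproj` is therefore `NULL` unless requested.
Normalization happens once at the end ($X = X_g\Lambda^{-1/2}$), not per
merge. With $g = 1$ this is MELODIC's incremental group PCA; with
$g \ge M$ it reduces to exact EVD truncated to $k$.

**Large PCA** (`large_pca`) grows a block Krylov basis
$Kr = [X_0, \ldots, X_j]$, $X_j = (YY^\top) X_{j-1}$, from a Gaussian
block $X_0 = Y G$ of width $b$. Defaults $b = 170$ and $j_0 = 6$ blocks
before the first check follow the published compromise between memory and
dataloads; with a warm start $j_0 = 1$. After each additional block the
top-$k$ singular values of the orthonormalized $Kr$ projected through the
data are re-estimated, and the run stops when their successive L2
difference drops below `tol` (absolute by default, mirroring the L2
eigenvalue-error accuracy metric; a relative option exists). The check
covers only the $k$ values of interest, not all $(j+1)b$. `tol = Inf`
reproduces the fixed-$j$ variant. Re-orthogonalization is a full economy
QR of the whole $Kr$ at every check — at desk scale, robustness beats the
incremental-QR savings. Rank-deficient $Kr$ (common once $(j+1)b$ exceeds
the data rank) drops dependent columns with a warning.

**MPOWIT** (`mpowit`) iterates an enlarged $lk$-dimensional block:
orthonormalize $\chi_{j-1}$, apply the covariance in one pass
($\chi_j = \sum_i Y_i (X_j^\top Y_i)^\top$), eigendecompose the small
$lk \times lk$ projection $X_j^\top \chi_j/(v-1)$, keep the top $k$
eigenvalues, and stop when $\lVert\Lambda_j - \Lambda_{j-1}\rVert_2 <$
`tol`. $\Lambda_0 = 0$ under random initialization, so the test cannot
pass before the second iteration; a warm start supplies both $X_0$ (top
$lk$ components) and $\Lambda_0$. The default $l = 5$ follows the
published selection; $lk \le 500$ keeps the small EVD negligible. The
orthonormalization is the EVD-based `orth_evd` ($m F L^{-1}$ from the
Gram EVD), which is faster than QR for tall thin blocks; an `orth = "qr"`
backend exists and reaches the same fixed point, which the tests verify.
The small-matrix top-$k$ extraction uses a full symmetric EVD with
truncation rather than a restricted solver — at $lk \le 500$ the full
decomposition is exact and cheaper. The final pass's per-subject products
are reused for $F$, so the total dataload count is exactly $(j+1)M$.

**EM PCA** (`em_pca`) alternates
$F_j^\top = (X^\top X)^{-1} X^\top Y$ and
$X_j = Y F_j (F_j^\top F_j)^{-1}$; each iteration needs two passes. The
published stopping rule $\lVert X_j - X_{j-1}\rVert < \delta$ is
sensitive to column sign and rotation, so the default criterion here is
the largest principal angle between successive subspaces, with the
sign-aligned Frobenius norm behind `criterion = "frobenius"`. The
published finalization (small EVD of $X^\top Y Y^\top X/(v-1)$) assumes an
orthonormal $X$, which the converged EM iterate is not; the package
orthonormalizes first and then applies the small Rayleigh–Ritz EVD — the
same span, with oracle-consistent eigenvalues. `subspace_equivalence()`
executes the equivalence argument numerically: EM and subspace iteration
from a shared Gaussian start span identical subspaces at every iteration
(both equal $\mathrm{span}((YY^\top)^j X_0)$), which is why an
"accelerated EM PCA" is simply `mpowit` and no separate code path exists.

## Method selection

`select_method()` encodes the decision rule: exact EVD whenever
$v \le 10000$ or $Mp \le 10000$; a stacked iterative solver when $Y$ fits
in RAM (`stacked_fits()` does the byte arithmetic,
$8\,v\,M\,p \times$ a working-set factor, as a portable approximation to
machine-specific guidance); otherwise un-stacked MPOWIT warm-started from
STP, which keeps memory flat in $M$ and iterations at 2–3.

## The synthetic generator

`generate_group()` plants a shared orthonormal spatial basis $U$ ($v
\times r$, zero-mean columns so column centering cannot disturb it) with a
positive descending spectrum, gives every subject its own random
orthonormal time-mixing $A_i$, and adds i.i.d. Gaussian noise:
$Z_i = U\,\mathrm{diag}(\sqrt{\lambda (v-1)})\,A_i^\top + \varepsilon$.
With zero noise each subject's time covariance has eigenvalues exactly
$\lambda$ and the group covariance is $M\,U\,\mathrm{diag}(\lambda)\,
U^\top$, so the planted group spectrum is $M\lambda$ — the ground truth
for exact-recovery tests. `smoothness > 0` lays the basis out on a
synthetic 3D grid and applies a separable moving-average kernel before
re-orthonormalization, giving the spatial regularity that voxel
subsampling needs to be meaningful.

Fixture profiles (`default_fixture`) fix the desk-scale study conditions
once: tiny ($v{=}500, t{=}30, M{=}4, p{=}10, r{=}6$), small ($v{=}3000,
t{=}50, M{=}10, p{=}20, r{=}15$; the standard validation size), medium
($v{=}8000, t{=}60, M{=}40, p{=}30, r{=}20$), all with spectrum
$10 \cdot 0.85^{\,i-1}$, `noise_sd = 0.1` (signal-to-noise comfortably
above the detection floor, as in well-behaved resting-state data),
smoothness 2 voxels (production pipelines smooth with a ~10 mm kernel;
without smoothness, depth-2 subsampling at desk scale retains full rank
and SVP becomes trivially lossless, a regime in which subsampling error
cannot be studied at all), and seed 0. Profiles run the full two-stage
pipeline — subject PCA included — and keep the subject scores
*unwhitened* by default: whitening flattens every subject spectrum to
unity, which at these small $r$ would leave the group spectrum nearly
degenerate and its eigenvector ordering ill-conditioned; the unwhitened
default preserves the planted eigengaps that convergence and
principal-angle checks require (figure-style captions of the two-stage
framework mark whitening as optional). `whiten = TRUE` is available.

What the fixtures deliberately do **not** emulate: temporal
autocorrelation, hemodynamics, scanner drift, subject-specific spatial
variability beyond the random mixings, or non-Gaussian noise. The solvers
are data-agnostic linear algebra, so passing tests demonstrate numerical
correctness of the decompositions, not robustness to fMRI artifacts.

## Numerical choices and degenerate inputs

* Tolerances: solver convergence $10^{-6}$ (absolute L2 on top-$k$
  eigen/singular values); rank thresholds $10^{-12}$ relative to the
  largest Gram eigenvalue; tiny negative eigenvalues clipped at
  $-10^{-10}$.
* Principal angles use the cosine SVD refined by the sine-residual
  formula for small angles; plain `acos` bottoms out near
  $\sqrt{\varepsilon} \approx 10^{-8}$ and would mask genuine agreement.
* Ties and signs: equal eigenvalues leave the within-block basis
  backend-defined; comparisons are always subspace-based.
* Degenerate inputs error early and descriptively: NaN/Inf anywhere, all
  zero volumes, empty masks or empty common masks, non-centered matrices
  (providers never re-center — centering is an explicit, flagged step, so
  nothing is silently centered twice), $k$ beyond the numerical rank,
  singular Gram matrices in EM, and non-convergence (the error object
  carries the trace).
* Masked voxels are linearized in fixed column-major grid order on every
  I/O path, so voxel identity is stable across masks, subsampling
  schemes, and file round-trips.
* Reduced subjects and results are stored via R's native serialization,
  one self-describing file per subject; missing values are not supported.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the tiny and small profiles
(plus a $v{=}500, M{=}4$ noiseless exact-recovery case), with $k = 10$,
$k' = 50$, $g = 5$ as the scaled-down analysis parameters chosen by the
published ratios ($k' = 5k$; at least two STP groups). A single solver
run on the small profile completes in seconds on one CPU; the medium
profile stays under ten minutes for any solver and is available for
heavier local experimentation.

## Known limitations

Exact EVD paths materialize a covariance and are capped, not chunked;
voxel tiling below per-subject granularity is out of scope. The
memory-fit heuristic is byte arithmetic, not a measured footprint.
Infomax ICA, stability analysis, and subject-map back-reconstruction are
downstream consumers, not part of this package — it stops at the $X$,
$\Lambda$, $F$ contract.
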