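---
title: "Methods: sparse estimation of conformational variability in density space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse estimation of conformational variability in density space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A crystallographic ensemble is a set of alternate atomic models that
collectively explain one diffraction experiment. Some members differ from the
deposited single-conformer model only by coordinate noise — the uncertainty
that isotropic B-factors are meant to absorb — while others represent genuine
alternative conformations. Telling the two apart from coordinates alone is
hard: per-atom tests ignore correlated motion, and RMSD or B-factor profiles
mix noise and signal into one number.

`edmlasso` performs the test in electron-density space. Let
$\rho_{\mathrm{base}}(g)$ be the density of the base conformer at grid point
$g$ and $\rho_i(g)$ the density of ensemble member $i$. The base map is
modeled as a linear combination of member maps over a grid region $G$,

$$
\min_{\omega} \;\sum_{g \in G}\Big(\rho_{\mathrm{base}}(g)
  - \sum_{i=1}^{K}\omega_i\,\rho_i(g)\Big)^2
  \;+\; \lambda \sum_{i=1}^{K} |\omega_i|,
$$

an L1-penalized (Lasso) regression. Members that are noise variants of the
base are highly predictive of its density and receive significant weights
$\omega_i > 0$; members representing a genuinely different conformation are
redundant given the noise variants, and the L1 penalty drives their weights
to zero. The per-member label is therefore:

* `noise_variant` — $\omega_i \neq 0$, statistically significant, and not
  negligibly small;
* `truly_variable` — everything else ($\omega_i$ "approaches zero").

Because the comparison happens in map space, B-factors enter the test
automatically (they set the width of each atom's density), and correlated
displacements of neighboring atoms are pooled into one whole-model statistic
instead of being tested atom by atom.

## The density engine

* **Cell and symmetry.** Everything is computed in P1 on a rectangular
  (orthorhombic) cell, by default the base conformer's bounding box plus
  10 Å of padding. Crystallographic symmetry contributes nothing to the
  statistics of the test and would complicate the FFTs; non-90° cells are
  rejected rather than silently mishandled.
* **Atomic model.** Each atom is a single isotropic Gaussian carrying
  `occupancy × Z` electrons with per-axis variance
  $\sigma^2 = B/(8\pi^2)$ (the crystallographic convention
  $B = 8\pi^2\langle u^2\rangle$). Multi-Gaussian Cromer–Mann form factors
  would change absolute peak shapes but none of the properties the test
  relies on (linearity in occupancy, positivity, B-dependence); the single
  Gaussian keeps the forward model and the structure-factor expression
  analytically consistent: $F(hkl) = \sum_j \mathrm{occ}_j Z_j
  e^{-B_j s^2/4} e^{2\pi i\, h\cdot x_j}$, $s = 1/d$.
* **Sampling.** Default grid spacing is $d_{\min}/3$, the standard
  crystallographic sampling rule. Gaussian tails are evaluated to
  $4\sigma$ and wrap periodically, so translation by a whole grid vector is
  an exact circular shift.
* **R factors.** $R = \sum_{\mathrm{work}} \big||F_o| - k|F_c|\big| /
  \sum_{\mathrm{work}} |F_o|$ with a single least-squares amplitude scale
  $k$ fitted on the work set; $R_{\mathrm{free}}$ uses the same $k$ on the
  held-out set. $F(000)$ is excluded. No per-shell scaling, no bulk
  solvent: the synthetic data contain neither.

## The synthetic world

The simulator reproduces the conditions of a two-conformer crystal
experiment:

* a poly-alanine toy chain (N, CA, C, O, CB; ideal geometry) with uniform
  $B = 30\,\text{Å}^2$ and unit occupancies;
* an alternate conformer drawn from the 0.8–1.2 Å backbone-RMSD
  neighborhood of the base. The inverse-kinematics samplers and
  refinement programs used for real ensembles are deliberately **not**
  re-implemented — the classifier is agnostic to how the ensemble was
  produced — and are replaced by seeded Cartesian perturbation followed by
  bond-length regularization (a SHAKE-style projection onto the base bond
  lengths) and displacement rescaling into the target RMSD range;
* simulated diffraction to $d_{\min} = 2.0$ Å obtained by **complex
  averaging of the two conformers' structure factors** at equal weights,
  with 10% of reflections flagged free;
* a four-member labeled ensemble: two members are Gaussian coordinate
  perturbations ($\sigma = 0.1$ Å per coordinate) of the base
  (truth: noise), two of the alternate conformer (truth: variable).

The standard fixture uses a 12-residue chain — large enough for windowed
statistics, small enough that the full pipeline runs in seconds. A helix is
used where geometry is incidental; the localization test uses a strand
because its extended shape keeps per-residue windows spatially disjoint.

What the generator does **not** emulate: side chains and rotamer
heterogeneity, experimental amplitude noise and incompleteness, bulk
solvent, lattice disorder, non-P1 symmetry, and refinement-induced
correlation between members and data. A green test therefore establishes
that the statistical machinery separates the two stated populations under
an idealized forward model — not that it would survive every pathology of
real diffraction data.

## Penalty selection and significance: what we measured, what we changed

Three defaults differ from the most naive textbook pipeline. All three were
forced by measurements on the stated synthetic world, and all three have
standard statistical pedigree.

**Cross-validation folds are spatial blocks.** Density maps are
band-limited: at $d_{\min}/3$ sampling, neighboring voxels are strongly
dependent, and a random row-wise fold assignment puts near-copies of each
observation into training and test folds simultaneously. CV error then
keeps decreasing as $\lambda \to 0$ and the "optimal" penalty is the bottom
of the grid. Assigning contiguous slabs of the region to folds (blocked CV,
the standard remedy for spatially autocorrelated data) removes most of the
leakage. `cv_lambda(fold_type = "random")` retains the naive behavior.

**The classifier uses the one-standard-error rule.** Even with blocked
folds, the response map is a deterministic function of the members plus a
*structured* mismatch, not iid noise, so the CV minimum still sits at a
smaller penalty than support recovery needs. The 1-SE rule — take the
largest $\lambda$ whose CV error is within one standard error of the
minimum — is the conventional parsimonious choice in Lasso practice and is
what `classify_ensemble` passes to `cv_lambda`; the plain minimum (with
ties broken toward the sparser model) remains `cv_lambda`'s default rule.

**Significance is tested across spatial blocks.** The post-selection OLS
refit is kept, but the iid residual-variance t-test is dishonest here for
the same reason the naive CV is: with $\sim 2.5\times10^4$ correlated
voxels a member with a scaled weight of $10^{-3}$ gets $t \approx 24$.
Instead, the default (`coef_significance(se = "blocks")`) refits the OLS on
five contiguous slabs and tests the mean coefficient against its
between-block standard error ($t$ with 4 degrees of freedom) — a
cluster-style test whose effective sample size is the number of
quasi-independent regions, not the number of voxels. The iid mode is
retained (`se = "iid"`) and is verified against textbook OLS in the tests.

**Reading "$\omega$ approaches zero".** A member can enter the support at a
marginally small penalty with a scaled weight two orders of magnitude below
the leading member's. On the stated world the two populations are cleanly
separated: noise variants carry ≥ 79% of the leading scaled weight,
spurious entrants ≤ 0.8%. A member whose scaled weight is below 5% of the
leading one is therefore classified as approaching zero regardless of its
p-value. The value 5% sits two decades from both observed populations; it
is a numerical tolerance, not a fitted constant.

## Numerical choices

* Solver: cyclic coordinate descent with soft-thresholding on unit-norm
  columns, on precomputed Gram/covariance statistics (each sweep is
  $O(K^2)$, independent of region size). No intercept, no centering:
  densities share physical units and a true zero baseline. Weights are
  reported on the original column scale.
* Convergence: largest coefficient change below
  $10^{-8}(1 + \max_i|\omega_i|)$, at most $10^5$ sweeps; every fit carries
  a KKT stationarity residual, checked at $10^{-6}\lambda_{\max}$.
* $\lambda$ grid: 30 logarithmic points from exactly $\lambda_{\max} =
  \max_i |2x_i^\top y|$ down to $10^{-4}\lambda_{\max}$, warm-started.
* CV ties: broken toward the larger penalty (sparser model).
* Degenerate features: a member with (numerically) zero density over a
  region is excluded from that fit and reported with weight 0.
* Complete-to-Nyquist Fourier analysis of a map (the exact round-trip
  identity) requires odd grid dimensions: on an even grid the Nyquist
  planes are their own Friedel partners and cannot be represented in a
  half-set reflection list. Resolution-truncated extraction works on any
  grid.
* Chain-terminal windows are clipped, not dropped; windowed fits use the
  fixed penalty $\lambda = 10$ by default, which sits mid-gap between the
  penalty where spurious members enter and the penalty where genuine noise
  variants drop (measured range ≈ [6, 55] on the standard fixture).
* The nonnegative variant (`nonneg = TRUE`) clamps the coordinate update at
  zero. Density mixtures are physically nonnegative, but the signed fit is
  the default because the penalized objective is stated without sign
  constraints; on the standard fixture the two give identical labels.

## Known limitations

* The response map defaults to the model-calculated base-conformer density.
  Regressing against a data-derived map (e.g. the mixed-crystal map) is
  supported by passing that map as the response, but the acceptance
  experiments exercise the model-map route.
* The internal ranking of near-tied members (e.g. the two noise variants of
  the standard fixture, whose average weights differ by a few percent) can
  swap between region schemes in unlucky draws; the noise-vs-variable
  separation itself is stable.
* Blockwise standard errors assume the region is large enough to carve into
  ≥ 3 full-rank slabs; tiny regions fall back with an error rather than a
  silent approximation.
* Single-Gaussian scattering underestimates density sharpness for heavy
  elements; electron counts, not form-factor detail, carry the statistics
  here.
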