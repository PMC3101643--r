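# edmlasso

Sparse estimation of conformational variability in electron-density space.

## The problem

X-ray crystallography increasingly describes a protein not by one model but
by an *ensemble* of alternate conformers that collectively explain the
diffraction data. The hard question is interpretive: which ensemble members
represent **genuine conformational variability** (hinge and loop motions,
alternate states — the biologically interesting signal), and which are merely
**noise variants** of the deposited structure, i.e. the coordinate scatter
that B-factors are supposed to absorb? Coordinate-space comparators — RMSD
profiles, B-factors, torsion differences — fold both effects into one number
and are unreliable exactly where ensembles matter most, at medium-to-low
resolution.

`edmlasso` is for structural bioinformaticians and methods developers who
want a whole-model statistical answer. It is a self-contained R
re-implementation of an EDM-space sparse-estimation approach, complete with
a synthetic two-conformer crystal simulator, so the entire method can be
exercised and tested without any external data.

## The statistic

Work in electron-density-map (EDM) space. With $\rho_{\mathrm{base}}(g)$ the
base conformer's density on a grid region $G$ and $\rho_i(g)$ the densities
of the $K$ ensemble members, solve the Lasso problem

$$
\hat\omega \;=\; \arg\min_{\omega}\;
\sum_{g\in G}\Big(\rho_{\mathrm{base}}(g)-\sum_{i=1}^{K}\omega_i\rho_i(g)\Big)^2
\;+\;\lambda\sum_{i=1}^{K}|\omega_i| .
$$

Members sampled from the noise distribution around the base are predictive of
its density and keep significant weights $\omega_i$; members representing a
different conformation are redundant and their weights are driven to exactly
zero — they are labeled *truly variable*. The penalty $\lambda$ is chosen by
spatially blocked cross-validation; significance of the selected weights is
assessed by an OLS refit with between-block standard errors (density voxels
are strongly spatially correlated, so naive iid tests are invalid — see the
methods vignette `vignettes/edmlasso-methods.Rmd`).

The package also provides the supporting machinery: PDB I/O, Kabsch
superposition, Gaussian-atom density and structure-factor synthesis in P1,
FFT map synthesis, R/R-free, R-free-based ensemble filtering, deduplication,
regularization paths, per-residue sliding-window profiles, and baseline
RMSD/B-factor comparators.

## Worked example

Simulate a crystal containing two conformations — a 12-residue toy protein
and an alternate conformer at ~1 Å backbone RMSD, uniform B = 30 Å², equal
complex averaging of structure factors at d_min = 2 Å — then classify a
four-member ensemble in which two members are noise perturbations
(σ = 0.1 Å) of each underlying conformer:

```r
library(edmlasso)

base <- make_toy_protein(12, "helix")                             # conformer 1
alt  <- sample_neighborhood(base, c(0.8, 1.2), 1, seed = 2)[[1]]  # conformer 2
round(rmsd(base, alt), 3)
#> [1] 1.15

fx  <- make_two_conformer_crystal(base, alt, d_min = 2.0)
fx$mixed_map
#> <density_grid 54x49x54 on 34.8 x 32.1 x 33.9 A cell, sum 396.0 e>

ens  <- make_labeled_ensemble(fx, n_noise = 2, n_variable = 2,
                              noise_model(0.1, 3))
maps <- lapply(ens$members, density_map, cell = fx$cell,
               shape = fx$mixed_map$dim)
base_map <- density_map(fx$base, fx$cell, shape = fx$mixed_map$dim)
region   <- fragment_box(fx$base, 1:12, margin = 2, base_map)

report <- classify_ensemble(base_map, maps, region, lam = "cv", seed = 1)
report
#> <variability_report: lam = 3.209, R^2 = 0.9874, 24986 points>
#>     member weight     t         p          label
#> 1 member_1 0.5298 12.24 0.0002561  noise_variant
#> 2 member_2 0.4242 10.92 0.0003989  noise_variant
#> 3 member_3 0.0000  0.00 1.0000000 truly_variable
#> 4 member_4 0.0000  0.00 1.0000000 truly_variable

ens$truth_labels
#> [1] "noise"    "noise"    "variable" "variable"
```

Reading the output: the two base-derived members reconstruct the base
density almost completely (weights 0.53 + 0.42, refit R² = 0.987) and test
significant; the two members derived from the alternate conformation receive
weights of exactly zero at the cross-validated penalty λ ≈ 3.2 — the
method recovers the planted heterogeneity perfectly.

Command-line equivalents (`simulate`, `classify`, `path`, `profile`) live in
`inst/cli/edmlasso.R`:

```sh
Rscript inst/cli/edmlasso.R simulate --out runs/fixture --seed 7
Rscript inst/cli/edmlasso.R classify --base runs/fixture/base.pdb \
    --members runs/fixture/members --out runs/report \
    --reflections runs/fixture/reflections.csv
```

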