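# Synthetic fixtures: ideal-geometry poly-alanine chains, Gaussian coordinate
# perturbation, a neighborhood sampler with bond regularization (desk-scale
# stand-in for inverse-kinematics samplers + refinement), and the
# two-conformer simulated crystal with labeled ensembles.

# Ideal backbone geometry (lengths A, angles degrees).
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1, a_n_c_ca_cb_dihedral = 122.5
)

# NeRF: place atom D given reference atoms A-B-C, bond |C-D|, angle B-C-D
# and dihedral A-B-C-D (degrees).
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m, n) %*% d2
}

#' Noise model for coordinate perturbation
#' @param sigma_cart Per-coordinate Gaussian standard deviation, Angstrom.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_cart, seed = 0L) {
  stopifnot(sigma_cart >= 0)
  structure(list(sigma_cart = sigma_cart, seed = as.integer(seed)),
            class = "noise_model")
}

#' Build an ideal-geometry poly-alanine toy protein
#'
#' Backbone N, CA, C, O plus CB per residue with ideal bond lengths and
#' angles; dihedrals set by secondary-structure type (`helix`
#' phi/psi = -57/-47, `strand` -119/113, `coil` seeded draws from the
#' broad allowed region). All occupancies 1; all B-factors `b_iso`
#' (default 30 A^2, the uniform value used for the simulated crystal).
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"`, `"strand"` or `"coil"`.
#' @param seed Integer seed (used by `"coil"` only).
#' @param b_iso Uniform isotropic B-factor, Angstrom^2.
#' @return A `conformer` with `5 * n_residues` atoms.
#' @export
make_toy_protein <- function(n_residues, geometry = c("helix", "strand", "coil"),
                             seed = 0L, b_iso = 30) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("n_residues must be at least 2")
  G <- .GEOM
  phi_psi <- switch(geometry,
    helix  = cbind(rep(-57, n_residues), rep(-47, n_residues)),
    strand = cbind(rep(-119, n_residues), rep(113, n_residues)),
    coil   = withr_seed(seed, cbind(stats::runif(n_residues, -150, -60),
                                    stats::runif(n_residues, -70, 150))))
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(G$b_n_ca, 0, 0)
  th <- G$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + G$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N[i, ]  <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                             G$b_c_n, G$a_ca_c_n, phi_psi[i - 1, 2])   # psi
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             G$b_n_ca, G$a_c_n_ca, 180)                # omega
      C[i, ]  <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                             G$b_ca_c, G$a_n_ca_c, phi_psi[i, 1])      # phi
    }
    CB[i, ] <- .place_atom(N[i, ], C[i, ], CA[i, ],
                           G$b_ca_cb, G$a_c_ca_cb, G$a_n_c_ca_cb_dihedral)
  }
  for (i in seq_len(n_residues)) {
    # carbonyl O: dihedral N-CA-C-O = psi + 180 (trans to the next N)
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          G$b_c_o, G$a_ca_c_o, phi_psi[i, 2] + 180)
  }
  per_res <- function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ])
    data.frame(element = c("N", "C", "C", "O", "C"),
               name = c("N", "CA", "C", "O", "CB"),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, b = b_iso, resi = i, resn = "ALA", chain = "A",
               stringsAsFactors = FALSE)
  }
  conformer(do.call(rbind, lapply(seq_len(n_residues), per_res)),
            label = sprintf("toy_%s_%d", geometry, n_residues))
}

#' Perturb a conformer with independent Gaussian coordinate noise
#'
#' Every coordinate is displaced by N(0, sigma_cart^2); B-factors and
#' occupancies are untouched. Deterministic given the noise model's seed.
#'
#' @param c A `conformer`.
#' @param noise A `noise_model`.
#' @return A perturbed `conformer`.
#' @export
perturb_conformer <- function(c, noise) {
  xyz <- coords(c)
  if (noise$sigma_cart > 0) {
    eps <- withr_seed(noise$seed,
                      matrix(stats::rnorm(length(xyz), 0, noise$sigma_cart),
                             ncol = 3))
    xyz <- xyz + eps
  }
  set_coords(c, xyz, label = paste0(c$label, "_pert", noise$seed))
}

# Backbone/side-chain bond list (index pairs) and base lengths.
.bond_list <- function(c) {
  a <- c$atoms
  find <- function(resi, name) which(a$resi == resi & a$name == name)
  pairs <- list()
  for (r in unique(a$resi)) {
    for (bp in list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))) {
      i <- find(r, bp[1]); j <- find(r, bp[2])
      if (length(i) == 1 && length(j) == 1) pairs[[length(pairs) + 1]] <- c(i, j)
    }
    i <- find(r, "C"); j <- find(r + 1, "N")
    if (length(i) == 1 && length(j) == 1) pairs[[length(pairs) + 1]] <- c(i, j)
  }
  bm <- do.call(rbind, pairs)
  xyz <- coords(c)
  len <- sqrt(rowSums((xyz[bm[, 1], , drop = FALSE] -
                       xyz[bm[, 2], , drop = FALSE])^2))
  list(pairs = bm, lengths = len)
}

# SHAKE-like projection of coordinates onto the base bond lengths.
.regularize_bonds <- function(xyz, bonds, n_iter = 40) {
  for (it in seq_len(n_iter)) {
    for (k in seq_len(nrow(bonds$pairs))) {
      i <- bonds$pairs[k, 1]; j <- bonds$pairs[k, 2]
      v <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(v^2))
      if (d < 1e-9) next
      corr <- 0.5 * (d - bonds$lengths[k]) / d
      xyz[i, ] <- xyz[i, ] + corr * v
      xyz[j, ] <- xyz[j, ] - corr * v
    }
  }
  xyz
}

#' Sample conformers from an RMSD neighborhood of a base structure
#'
#' Seeded Cartesian perturbation followed by iterative bond-length
#' regularization and displacement rescaling until the best-fit backbone
#' RMSD to the base falls in `rmsd_range`. This is a statistical stand-in
#' for inverse-kinematics neighborhood samplers: the variability classifier
#' downstream is agnostic to how the ensemble was produced.
#'
#' @param base A `conformer`.
#' @param rmsd_range `(lo, hi)` in Angstrom, `0 <= lo < hi <= 2`.
#' @param n Number of conformers.
#' @param seed Integer seed.
#' @return List of `n` conformers, each with backbone RMSD to `base` inside
#'   the range and bond lengths within 10% of the base's.
#' @export
sample_neighborhood <- function(base, rmsd_range, n, seed = 0L) {
  stopifnot(length(rmsd_range) == 2, rmsd_range[1] >= 0,
            rmsd_range[1] < rmsd_range[2], rmsd_range[2] <= 2, n >= 0)
  if (n == 0) return(list())
  bonds <- .bond_list(base)
  xyz0 <- coords(base)
  out <- vector("list", n)
  for (m in seq_len(n)) {
    conf <- withr_seed(seed * 1000L + m, {
      target <- stats::runif(1, rmsd_range[1], rmsd_range[2])
      ok <- FALSE
      for (attempt in 1:20) {
        disp <- matrix(stats::rnorm(length(xyz0), 0, target), ncol = 3)
        xyz <- xyz0 + disp
        for (inner in 1:12) {
          xyz <- .regularize_bonds(xyz, bonds)
          cand <- set_coords(base, xyz, label = sprintf("nbr_%d", m))
          r <- rmsd(base, cand, BACKBONE, fit = TRUE)
          if (r >= rmsd_range[1] && r <= rmsd_range[2]) { ok <- TRUE; break }
          xyz <- xyz0 + (xyz - xyz0) * (target / max(r, 1e-6))
        }
        if (ok) break
      }
      if (!ok) stop("could not reach the requested RMSD range")
      cand
    })
    out[[m]] <- conf
  }
  out
}

#' Simulate a two-conformer crystal
#'
#' Structure factors of the base and alternate conformers are computed to
#' `d_min` on a shared auto-sized P1 cell and complex-averaged (equal
#' weights by default); the mixed map is synthesized from the averaged
#' reflections. Ten percent of reflections are flagged free.
#'
#' @param base Conformer 1 (plays the role of the deposited model).
#' @param alternate Conformer 2 (the genuinely different conformation).
#' @param d_min Resolution limit, Angstrom (default 2.0).
#' @param weights Mixing weights for (base, alternate); default (0.5, 0.5).
#' @param cell Optional shared `unit_cell`; default auto-sized around `base`.
#' @param free_seed Seed for the free-flag draw.
#' @return An object of class `crystal_fixture` with fields `base`,
#'   `alternate`, `mixed_reflections`, `mixed_map`, `cell`, `d_min`.
#' @export
make_two_conformer_crystal <- function(base, alternate, d_min = 2.0,
                                       weights = c(0.5, 0.5), cell = NULL,
                                       free_seed = 0L) {
  if (!identical(.atom_key(base), .atom_key(alternate))) {
    stop("base and alternate must share atom ordering")
  }
  if (is.null(cell)) cell <- cell_around(base)
  alternate <- center_conformer(alternate, cell, reference = base)
  base <- center_conformer(base, cell)
  f1 <- structure_factors(base, cell, d_min)
  f2 <- structure_factors(alternate, cell, d_min)
  mixed <- mix_structure_factors(list(f1, f2), weights)
  mixed <- assign_free_flags(mixed, 0.10, free_seed)
  shape <- grid_shape(cell, d_min / 3)
  structure(list(base = base, alternate = alternate,
                 mixed_reflections = mixed,
                 mixed_map = map_from_reflections(mixed, cell, shape),
                 cell = cell, d_min = d_min),
            class = "crystal_fixture")
}

#' Build a truth-labeled ensemble from a two-conformer crystal
#'
#' `n_noise` members are Gaussian perturbations of the base (truth label
#' `"noise"`), `n_variable` are perturbations of the alternate conformer
#' (truth label `"variable"`). Member seeds derive from the noise model's
#' seed.
#'
#' @param fixture A `crystal_fixture`.
#' @param n_noise,n_variable Member counts (not both zero).
#' @param noise A `noise_model`.
#' @return A truth-labeled `ensemble` whose base is the fixture's base.
#' @export
make_labeled_ensemble <- function(fixture, n_noise, n_variable, noise) {
  stopifnot(n_noise >= 0, n_variable >= 0)
  if (n_noise + n_variable == 0) stop("ensemble must have at least one member")
  members <- list(); labels <- character(0)
  for (i in seq_len(n_noise)) {
    members[[length(members) + 1]] <-
      perturb_conformer(fixture$base,
                        noise_model(noise$sigma_cart, noise$seed * 100L + i))
    labels <- c(labels, "noise")
  }
  for (i in seq_len(n_variable)) {
    members[[length(members) + 1]] <-
      perturb_conformer(fixture$alternate,
                        noise_model(noise$sigma_cart, noise$seed * 100L + 50L + i))
    labels <- c(labels, "variable")
  }
  ensemble(members, fixture$base, truth_labels = labels)
}

#' Filter ensemble members by fit to data (R-free)
#'
#' Keeps members whose R-free against `obs` is at most the base conformer's
#' R-free plus `tolerance` — the ensemble must represent the data as well as
#' the base model does.
#'
#' @param e An `ensemble`.
#' @param obs Observed `reflection_set` with free flags and a cell.
#' @param tolerance R-free slack (default 0.02).
#' @return The filtered `ensemble` (possibly empty, with a warning).
#' @export
filter_by_fit <- function(e, obs, tolerance = 0.02) {
  cell <- obs$cell
  if (is.null(cell)) stop("observed reflections carry no unit cell")
  rf <- function(c) r_factors(obs, structure_factors(c, cell, obs$d_min))$r_free
  cutoff <- rf(e$base) + tolerance
  keep <- vapply(e$members, function(m) rf(m) <= cutoff, logical(1))
  if (!any(keep)) warning("no ensemble members pass the R-free filter")
  ensemble(e$members[keep], e$base,
           truth_labels = if (is.null(e$truth_labels)) NULL else e$truth_labels[keep])
}

#' Remove near-duplicate ensemble members
#'
#' Greedy selection in member order: a member is kept iff its best-fit
#' backbone RMSD to every already-kept member exceeds `rmsd_tol`.
#'
#' @param e An `ensemble`.
#' @param rmsd_tol Duplicate threshold, Angstrom (default 0.1).
#' @return The deduplicated `ensemble`, truth labels preserved.
#' @export
deduplicate <- function(e, rmsd_tol = 0.1) {
  stopifnot(rmsd_tol >= 0)
  kept <- integer(0)
  for (i in seq_along(e$members)) {
    dup <- FALSE
    for (j in kept) {
      if (rmsd(e$members[[j]], e$members[[i]], BACKBONE, fit = TRUE) <= rmsd_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  ensemble(e$members[kept], e$base,
           truth_labels = if (is.null(e$truth_labels)) NULL else e$truth_labels[kept])
}

#' Write a crystal fixture and labeled ensemble to disk
#'
#' Emits `base.pdb`, `alternate.pdb`, `members/member_XX.pdb`,
#' `reflections.csv` and `truth_labels.json` — the inputs the classify
#' command consumes.
#'
#' @param fixture A `crystal_fixture`.
#' @param e A labeled `ensemble`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_fixture <- function(fixture, e, out_dir) {
  dir.create(file.path(out_dir, "members"), recursive = TRUE, showWarnings = FALSE)
  write_pdb(fixture$base, file.path(out_dir, "base.pdb"))
  write_pdb(fixture$alternate, file.path(out_dir, "alternate.pdb"))
  for (i in seq_along(e$members)) {
    write_pdb(e$members[[i]],
              file.path(out_dir, "members", sprintf("member_%02d.pdb", i)))
  }
  write_reflections(fixture$mixed_reflections, file.path(out_dir, "reflections.csv"))
  if (!is.null(e$truth_labels)) {
    jsonlite::write_json(
      as.list(stats::setNames(e$truth_labels,
                              sprintf("member_%02d", seq_along(e$members)))),
      file.path(out_dir, "truth_labels.json"), auto_unbox = TRUE)
  }
  invisible(out_dir)
}
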