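# Shared fixtures and independent oracles. Everything is generated in code;
# the standard two-conformer fixture (seed 1) is cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The standard two-conformer crystal fixture: 12-residue helix base, an
# alternate conformer at ~1 A backbone RMSD, uniform B = 30, d_min = 2.0,
# equal-weight structure-factor averaging, 4 labeled members at sigma 0.1.
standard_fixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  base <- make_toy_protein(12, "helix")
  alt <- sample_neighborhood(base, c(0.8, 1.2), 1, seed = seed + 1L)[[1]]
  fx <- make_two_conformer_crystal(base, alt, 2.0)
  ens <- make_labeled_ensemble(fx, 2, 2, noise_model(0.1, seed + 2L))
  cell <- fx$cell
  shape <- fx$mixed_map$dim
  base_map <- density_map(fx$base, cell, shape = shape)
  alt_map <- density_map(fx$alternate, cell, shape = shape)
  member_maps <- lapply(ens$members, density_map, cell = cell, shape = shape)
  region <- fragment_box(fx$base, 1:12, 2, base_map)
  out <- list(fx = fx, ens = ens, cell = cell, shape = shape,
              base_map = base_map, alt_map = alt_map,
              member_maps = member_maps, region = region)
  .fixture_cache[[key]] <- out
  out
}

# Small deterministic regression problem (no density machinery) for solver
# tests: k unit-scale columns, n rows, y built from true sparse weights.
toy_problem <- function(seed, n = 40, k = 3, w_true = NULL, noise = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  if (is.null(w_true)) w_true <- c(1.5, 0, -0.7)[seq_len(k)]
  y <- as.numeric(X %*% w_true + rnorm(n, 0, noise))
  g <- grid_region(seq_len(n), c(n, 1, 1))
  structure(list(y = y, X = X,
                 member_labels = sprintf("m%d", seq_len(k)),
                 region = g, col_norms = sqrt(colSums(X^2)),
                 dropped = character(0)),
            class = "regression_problem")
}

# ---- Independent oracles ---------------------------------------------------

# Exhaustive multi-resolution grid minimization of the Lasso objective
# ||y - Xs w||^2 + lam |w|_1 on unit-norm columns. Coarse-to-fine is safe
# because the objective is convex; zero stays on-grid at every stage so
# sparse optima are representable. Returns scaled weights at resolution
# `final_step`. Default bounds cover the per-coordinate interval that must
# contain the minimizer: |w_i| <= |x_i' y| <= ||y|| on unit-norm columns.
lasso_grid_oracle <- function(y, Xs, lam, lo = NULL, hi = NULL,
                              final_step = 1e-3) {
  k <- ncol(Xs)
  G <- crossprod(Xs)
  b <- as.numeric(crossprod(Xs, y))
  yty <- sum(y^2)
  if (is.null(lo)) lo <- -1.05 * sqrt(yty)
  if (is.null(hi)) hi <- 1.05 * sqrt(yty)
  eval_obj <- function(W) {
    rowSums((W %*% G) * W) - 2 * as.numeric(W %*% b) + yty +
      lam * rowSums(abs(W))
  }
  step <- (hi - lo) / 40
  lo_k <- rep(lo, k); hi_k <- rep(hi, k)
  repeat {
    axes <- lapply(seq_len(k), function(i) {
      g <- seq(floor(lo_k[i] / step) * step, ceiling(hi_k[i] / step) * step,
               by = step)
      sort(unique(c(g, 0)))
    })
    W <- as.matrix(do.call(expand.grid, axes))
    best <- W[which.min(eval_obj(W)), ]
    if (step <= final_step) return(as.numeric(best))
    lo_k <- best - 2 * step
    hi_k <- best + 2 * step
    step <- max(step / 8, final_step)
  }
}

# Brute-force best-fit RMSD: minimize over a multi-resolution Euler-angle
# grid with optimal translation (centroid matching) at each rotation.
rmsd_rotation_oracle <- function(P, Q, final_step = 0.1 * pi / 180) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  score <- function(a, b, c) {
    sqrt(mean(rowSums((P0 %*% t(rot(a, b, c)) - Q0)^2)))
  }
  step <- 6 * pi / 180
  ctr <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- NULL
  repeat {
    aa <- seq(ctr[1] - span[1], ctr[1] + span[1], by = step)
    bb <- seq(max(0, ctr[2] - span[2]), min(pi, ctr[2] + span[2]), by = step)
    cc <- seq(ctr[3] - span[3], ctr[3] + span[3], by = step)
    g <- expand.grid(a = aa, b = bb, c = cc)
    v <- mapply(score, g$a, g$b, g$c)
    i <- which.min(v)
    best <- v[i]
    ctr <- c(g$a[i], g$b[i], g$c[i])
    if (step <= final_step) return(best)
    span <- rep(2 * step, 3)
    step <- step / 6
  }
}

expect_conformers_equal <- function(a, b, tol_xyz = 1e-3, tol_b = 1e-2) {
  expect_equal(a$atoms$name, b$atoms$name)
  expect_equal(a$atoms$resi, b$atoms$resi)
  expect_lt(max(abs(coords(a) - coords(b))), tol_xyz + 1e-12)
  expect_lt(max(abs(a$atoms$b - b$atoms$b)), tol_b + 1e-12)
  expect_equal(a$atoms$occ, b$atoms$occ, tolerance = 1e-6)
}
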