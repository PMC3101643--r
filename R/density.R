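# Electron-density maps and structure factors on a P1 orthorhombic cell:
# Gaussian-atom density synthesis, direct-summation structure factors, FFT
# map synthesis, R/R-free, and grid-region bookkeeping.

#' Construct a P1 unit cell
#'
#' Only orthorhombic (all angles 90 degrees) P1 cells are supported by the
#' map/transform machinery; the statistics of the variability test do not
#' depend on crystal symmetry.
#'
#' @param a,b,c Edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees (must be 90).
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(abs(c(alpha, beta, gamma) - 90) > 1e-9)) {
    stop("only orthorhombic P1 cells (angles 90) are supported")
  }
  structure(list(a = as.numeric(a)[1], b = as.numeric(b)[1],
                 c = as.numeric(c)[1], alpha = unname(alpha),
                 beta = unname(beta), gamma = unname(gamma)),
            class = "unit_cell")
}

#' Cell volume
#' @param cell A `unit_cell`.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) cell$a * cell$b * cell$c

#' Auto-size a cell around a conformer
#'
#' Rectangular P1 cell equal to the conformer's bounding box plus padding on
#' every side. The returned cell is meant to be shared by all members of an
#' ensemble, so pass the base conformer (perturbed members stay inside thanks
#' to the padding and periodic wrapping).
#'
#' @param c A `conformer`.
#' @param padding Padding in Angstrom (default 10).
#' @return A `unit_cell`.
#' @export
cell_around <- function(c, padding = 10) {
  xyz <- coords(c)
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  unit_cell(ext[1] + 2 * padding, ext[2] + 2 * padding, ext[3] + 2 * padding)
}

#' Center a conformer in a cell
#'
#' Translation that moves a reference conformer's bounding-box center to the
#' cell center. Apply the same shift to every member of an ensemble so that
#' relative displacements are preserved and no model straddles a cell face.
#'
#' @param c The `conformer` to shift.
#' @param cell The target `unit_cell`.
#' @param reference The `conformer` whose bounding box defines the shift
#'   (default `c` itself).
#' @return The translated `conformer`.
#' @export
center_conformer <- function(c, cell, reference = c) {
  xyz <- coords(reference)
  ctr <- apply(xyz, 2, function(v) mean(range(v)))
  shift <- c(cell$a, cell$b, cell$c) / 2 - ctr
  set_coords(c, sweep(coords(c), 2, -shift))
}

# FFT-friendly grid dimension: smallest n >= target with factors 2,3,5,7.
.good_fft_size <- function(target) {
  n <- max(2L, as.integer(ceiling(target)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Grid dimensions for a cell at a given spacing
#' @param cell A `unit_cell`.
#' @param spacing Target grid spacing, Angstrom.
#' @return Integer vector (nx, ny, nz), FFT-friendly.
#' @export
grid_shape <- function(cell, spacing) {
  stopifnot(spacing > 0)
  vapply(c(cell$a, cell$b, cell$c),
         function(len) .good_fft_size(len / spacing), integer(1))
}

#' Construct a density grid
#' @param cell A `unit_cell`.
#' @param values 3D numeric array of density values, electrons/Angstrom^3.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(cell, values) {
  stopifnot(inherits(cell, "unit_cell"), is.array(values),
            length(dim(values)) == 3L)
  if (!all(is.finite(values))) stop("non-finite density values")
  structure(list(cell = cell, dim = dim(values), values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid %dx%dx%d on %.1f x %.1f x %.1f A cell, sum %.1f e>\n",
              x$dim[1], x$dim[2], x$dim[3], x$cell$a, x$cell$b, x$cell$c,
              sum(x$values) * cell_volume(x$cell) / prod(x$dim)))
  invisible(x)
}

#' Voxel volume of a density grid
#' @param grid A `density_grid`.
#' @return Volume per voxel, cubic Angstrom.
#' @export
voxel_volume <- function(grid) cell_volume(grid$cell) / prod(grid$dim)

#' Electron-density map of a conformer (Gaussian atoms)
#'
#' Each atom is rendered as an isotropic 3D Gaussian carrying
#' `occupancy x Z` electrons, with per-axis variance
#' `sigma^2 = (B + b_added) / (8 pi^2)` — the crystallographic convention
#' B = 8 pi^2 <u^2>. Tails are evaluated to 4 sigma and wrap periodically
#' across the P1 cell, so rigid translations by whole grid vectors are exact
#' circular shifts.
#'
#' @param c A `conformer`. Atoms are wrapped into the cell periodically.
#' @param cell A `unit_cell`; `NULL` auto-sizes via [cell_around()].
#' @param spacing Grid spacing in Angstrom.
#' @param b_added Extra isotropic B added to every atom (Angstrom^2),
#'   e.g. to emulate resolution-dependent blurring. Default 0.
#' @param shape Optional explicit grid dimensions (overrides `spacing`).
#' @return A `density_grid` with nonnegative values.
#' @export
density_map <- function(c, cell = NULL, spacing = 0.7, b_added = 0,
                        shape = NULL) {
  if (is.null(cell)) cell <- cell_around(c)
  if (is.null(shape)) shape <- grid_shape(cell, spacing)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  n <- shape
  lens <- c(cell$a, cell$b, cell$c)
  step <- lens / n
  a <- c$atoms
  z <- electron_count(a$element)
  btot <- a$b + b_added
  if (any(btot <= 0)) stop("total B-factor must be positive")
  vals <- array(0, dim = n)
  sigma <- sqrt(btot / (8 * pi^2))
  for (j in seq_len(nrow(a))) {
    s <- sigma[j]
    amp <- a$occ[j] * z[j] / ((2 * pi * s^2)^1.5)
    pos <- c(a$x[j], a$y[j], a$z[j]) %% lens  # periodic wrap into the cell
    # local neighborhood out to 4 sigma along each axis, wrapped
    half <- pmin(ceiling(4 * s / step), n %/% 2)
    ctr <- floor(pos / step)
    ax <- vector("list", 3)
    gx <- vector("list", 3)
    for (d in 1:3) {
      offs <- (ctr[d] - half[d]):(ctr[d] + half[d])
      dd <- offs * step[d] - pos[d]
      ax[[d]] <- (offs %% n[d]) + 1L
      gx[[d]] <- exp(-dd^2 / (2 * s^2))
    }
    block <- amp * (gx[[1]] %o% gx[[2]] %o% gx[[3]])
    vals[ax[[1]], ax[[2]], ax[[3]]] <-
      vals[ax[[1]], ax[[2]], ax[[3]]] + block
  }
  density_grid(cell, vals)
}

# ---- Reflections -----------------------------------------------------------

#' Construct a reflection set
#'
#' @param hkl Integer matrix (n x 3) of Miller indices, no duplicates.
#' @param f Complex structure factors, electrons.
#' @param d_min Resolution limit, Angstrom.
#' @param free Logical cross-validation flags (default all `FALSE`).
#' @param cell The `unit_cell` the indices refer to.
#' @return An object of class `reflection_set`.
#' @export
reflection_set <- function(hkl, f, d_min, free = NULL, cell = NULL) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  stopifnot(length(f) == nrow(hkl), d_min > 0)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("duplicate Miller indices")
  if (is.null(free)) free <- rep(FALSE, nrow(hkl))
  stopifnot(length(free) == nrow(hkl))
  structure(list(hkl = hkl, f = as.complex(f), d_min = d_min,
                 free = as.logical(free), cell = cell),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set: %d reflections to %.2f A, %d free>\n",
              nrow(x$hkl), x$d_min, sum(x$free)))
  invisible(x)
}

# 1/d^2 for each hkl row on an orthorhombic cell.
.inv_d2 <- function(hkl, cell) {
  (hkl[, 1] / cell$a)^2 + (hkl[, 2] / cell$b)^2 + (hkl[, 3] / cell$c)^2
}

# Friedel-unique hkl list complete to d_min (hemisphere + F(000)).
.hkl_to_dmin <- function(cell, d_min) {
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax))
  keep <- .inv_d2(g, cell) <= 1 / d_min^2 + 1e-12
  # hemisphere: l > 0, or l == 0 & k > 0, or l == k == 0 & h >= 0
  hemi <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] >= 0)
  g[keep & hemi, , drop = FALSE]
}

#' Structure factors of a conformer by direct summation
#'
#' `F(hkl) = sum_j occ_j Z_j exp(-B_j s^2 / 4) exp(2 pi i (h,k,l).x_frac_j)`
#' with `s = 1/d(hkl)`, on a Friedel-unique index list complete to `d_min`
#' (F(000) included). Gaussian single-atom form factors, consistent with
#' [density_map()].
#'
#' @param c A `conformer`.
#' @param cell A `unit_cell`; `NULL` auto-sizes via [cell_around()].
#' @param d_min Resolution limit, Angstrom.
#' @return A `reflection_set`.
#' @export
structure_factors <- function(c, cell = NULL, d_min = 2.0) {
  if (is.null(cell)) cell <- cell_around(c)
  stopifnot(d_min > 0)
  hkl <- .hkl_to_dmin(cell, d_min)
  if (nrow(hkl) < 2) stop("d_min too coarse for this cell")
  a <- c$atoms
  z <- electron_count(a$element)
  frac <- cbind(a$x / cell$a, a$y / cell$b, a$z / cell$c)
  s2 <- .inv_d2(hkl, cell)
  phase <- hkl %*% t(frac)             # n_refl x n_atom, in cycles
  damp <- exp(outer(s2, a$b, function(ss, bb) -bb * ss / 4))
  w <- damp * matrix(a$occ * z, nrow(hkl), length(z), byrow = TRUE)
  f <- as.complex(rowSums(w * cos(2 * pi * phase))) +
    1i * rowSums(w * sin(2 * pi * phase))
  reflection_set(hkl, f, d_min, cell = cell)
}

#' Flag a random subset of reflections as the free (cross-validation) set
#'
#' F(000) is never flagged free.
#'
#' @param r A `reflection_set`.
#' @param fraction Fraction flagged free (default 0.10).
#' @param seed Integer seed for the draw.
#' @return The `reflection_set` with `free` flags set.
#' @export
assign_free_flags <- function(r, fraction = 0.10, seed = 0L) {
  n <- nrow(r$hkl)
  free <- withr_seed(seed, stats::runif(n) < fraction)
  free[rowSums(abs(r$hkl)) == 0] <- FALSE
  r$free <- free
  r
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Complex-average structure-factor sets
#'
#' `F_mix = sum_k w_k F_k` over identically indexed sets — the simulated
#' diffraction of a crystal containing several conformations.
#'
#' @param sets List of `reflection_set`s sharing hkl lists and `d_min`.
#' @param weights Nonnegative weights summing to 1.
#' @return A `reflection_set`.
#' @export
mix_structure_factors <- function(sets, weights) {
  stopifnot(length(sets) >= 1, length(weights) == length(sets))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1")
  }
  ref <- sets[[1]]
  f <- weights[1] * ref$f
  for (k in seq_along(sets)[-1]) {
    sk <- sets[[k]]
    if (!identical(ref$hkl, sk$hkl) || ref$d_min != sk$d_min) {
      stop("reflection sets must share hkl list and d_min")
    }
    f <- f + weights[k] * sk$f
  }
  reflection_set(ref$hkl, f, ref$d_min, free = ref$free, cell = ref$cell)
}

#' Synthesize a density map from reflections (inverse Fourier transform)
#'
#' `rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)`, with Friedel mates implied
#' by conjugate symmetry, evaluated by FFT on the requested grid.
#'
#' @param r A `reflection_set`.
#' @param cell A `unit_cell` (defaults to the set's own cell).
#' @param shape Grid dimensions; must hold every index below Nyquist.
#' @return A real-valued `density_grid`.
#' @export
map_from_reflections <- function(r, cell = NULL, shape = NULL) {
  if (is.null(cell)) cell <- r$cell
  if (is.null(cell)) stop("no unit cell available")
  if (is.null(shape)) shape <- grid_shape(cell, r$d_min / 3)
  n <- as.integer(shape)
  if (any(apply(abs(r$hkl), 2, max) >= n %/% 2 + (n %% 2))) {
    stop("grid too coarse for these reflections (aliasing); increase shape")
  }
  arr <- array(0 + 0i, dim = n)
  idx <- function(h) cbind((h[, 1] %% n[1]) + 1L, (h[, 2] %% n[2]) + 1L,
                           (h[, 3] %% n[3]) + 1L)
  arr[idx(r$hkl)] <- r$f
  neg <- -r$hkl
  not000 <- rowSums(abs(r$hkl)) > 0
  arr[idx(neg[not000, , drop = FALSE])] <- Conj(r$f[not000])
  rho <- stats::fft(arr) / cell_volume(cell)
  imag_resid <- max(abs(Im(rho))) / max(1e-12, max(abs(Re(rho))))
  if (imag_resid > 1e-6) {
    warning(sprintf("imaginary residual %.2e after Friedel completion", imag_resid))
  }
  density_grid(cell, Re(rho))
}

#' Structure factors of a gridded map (forward Fourier analysis)
#'
#' The analysis direction: `F(h) = (V/N) sum_x rho(x) exp(2 pi i h.x)` by
#' FFT, truncated to `d_min` (or complete to the grid Nyquist when `d_min`
#' is `NULL`, in which case the pair with [map_from_reflections()] is an
#' exact round trip).
#'
#' @param grid A `density_grid`.
#' @param d_min Resolution limit; `NULL` keeps every Friedel-unique grid
#'   frequency.
#' @return A `reflection_set`.
#' @export
map_to_reflections <- function(grid, d_min = NULL) {
  n <- grid$dim
  cell <- grid$cell
  Fall <- stats::fft(grid$values, inverse = TRUE) *
    (cell_volume(cell) / prod(n))
  if (is.null(d_min)) {
    if (any(n %% 2 == 0)) {
      # on an even grid the Nyquist planes are their own Friedel partners
      # and cannot be carried in a half-set reflection list
      stop("complete-to-Nyquist extraction needs odd grid dimensions")
    }
    # every Friedel-unique index representable on the grid
    hseq <- function(nn) {
      up <- (nn - 1L) %/% 2
      (-up):up
    }
    g <- as.matrix(expand.grid(h = hseq(n[1]), k = hseq(n[2]), l = 0:max(hseq(n[3]))))
    hemi <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] >= 0)
    hkl <- g[hemi, , drop = FALSE]
    dmin_eff <- 1 / sqrt(max(.inv_d2(hkl, cell)))
  } else {
    hkl <- .hkl_to_dmin(cell, d_min)
    if (any(apply(abs(hkl), 2, max) >= n %/% 2 + (n %% 2))) {
      stop("grid too coarse for requested d_min")
    }
    dmin_eff <- d_min
  }
  f <- Fall[cbind((hkl[, 1] %% n[1]) + 1L, (hkl[, 2] %% n[2]) + 1L,
                  (hkl[, 3] %% n[3]) + 1L)]
  reflection_set(hkl, f, dmin_eff, cell = cell)
}

#' R and R-free between observed and calculated reflections
#'
#' `R = sum_work | |Fobs| - k |Fcalc| | / sum_work |Fobs|` with `k` the
#' least-squares amplitude scale fitted on the work set; R-free is the same
#' sum over the free set using the work-set `k`. F(000) is excluded.
#'
#' @param obs `reflection_set` carrying the free-flag partition.
#' @param calc `reflection_set` with matching hkl.
#' @return List of class `fit_statistics`: `r`, `r_free`, `scale`.
#' @export
r_factors <- function(obs, calc) {
  if (!identical(obs$hkl, calc$hkl)) stop("hkl lists do not match")
  keep <- rowSums(abs(obs$hkl)) > 0
  fo <- Mod(obs$f)[keep]; fc <- Mod(calc$f)[keep]; fr <- obs$free[keep]
  if (!any(!fr)) stop("empty work set")
  if (!any(fr)) stop("empty free set")
  k <- sum(fo[!fr] * fc[!fr]) / sum(fc[!fr]^2)
  structure(list(
    r = sum(abs(fo[!fr] - k * fc[!fr])) / sum(fo[!fr]),
    r_free = sum(abs(fo[fr] - k * fc[fr])) / sum(fo[fr]),
    scale = k), class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("<fit: R = %.4f, R_free = %.4f, scale = %.4g>\n",
              x$r, x$r_free, x$scale))
  invisible(x)
}

# ---- Grid regions ----------------------------------------------------------

#' Construct a grid region
#' @param idx Integer vector of linear grid indices (1-based).
#' @param dim Grid dimensions the indices refer to.
#' @return An object of class `grid_region`.
#' @export
grid_region <- function(idx, dim) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0) stop("empty grid region")
  if (min(idx) < 1 || max(idx) > prod(dim)) stop("region index out of range")
  structure(list(idx = idx, dim = as.integer(dim)), class = "grid_region")
}

#' Grid region covering the bounding box of selected residues
#'
#' Axis-aligned box around the atoms of a contiguous residue range, expanded
#' by `margin`, mapped to grid points. The box is clipped to the cell (no
#' periodic wrap: regions are for windowed statistics, not for synthesis).
#' At least the nearest grid point along each axis is always included.
#'
#' @param c The `conformer` whose residues define the box. Coordinates are
#'   wrapped into the cell like [density_map()] does.
#' @param residues Integer vector of residue indices (contiguous range).
#' @param margin Box expansion in Angstrom.
#' @param grid The `density_grid` providing cell and dimensions.
#' @return A `grid_region`.
#' @export
fragment_box <- function(c, residues, margin, grid) {
  stopifnot(margin >= 0)
  sel <- c$atoms$resi %in% residues
  if (!any(sel)) stop("no atoms in the requested residue range")
  cell <- grid$cell
  n <- grid$dim
  lens <- c(cell$a, cell$b, cell$c)
  step <- lens / n
  xyz <- coords(c)[sel, , drop = FALSE] %% matrix(lens, sum(sel), 3, byrow = TRUE)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  ax <- vector("list", 3)
  for (d in 1:3) {
    i0 <- max(0L, floor(lo[d] / step[d]))
    i1 <- min(n[d] - 1L, ceiling(hi[d] / step[d]))
    if (i1 < i0) i0 <- i1 <- max(0L, min(n[d] - 1L, round(lo[d] / step[d])))
    ax[[d]] <- i0:i1
  }
  g <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
  idx <- 1L + g$i + n[1] * (g$j + n[2] * g$k)
  grid_region(idx, n)
}

#' Full-grid region
#' @param grid A `density_grid`.
#' @return A `grid_region` covering every point.
#' @export
full_region <- function(grid) grid_region(seq_len(prod(grid$dim)), grid$dim)

#' Extract density values over a region as an ordered vector
#'
#' Ordering is lexicographic in (x, y, z) grid indices — i.e. increasing
#' linear index — so vectors extracted from same-shape grids align
#' point-for-point.
#'
#' @param grid A `density_grid`.
#' @param region A `grid_region` for the same dimensions.
#' @return Numeric vector of length `length(region$idx)`.
#' @export
extract_density <- function(grid, region) {
  if (!identical(as.integer(grid$dim), region$dim)) {
    stop("region dimensions do not match the grid")
  }
  as.numeric(grid$values[region$idx])
}

# ---- Reflection CSV I/O and CCP4 map export --------------------------------

#' Write a reflection set as CSV
#'
#' Columns `h,k,l,F_real,F_imag,free`; the cell and resolution limit travel
#' in `#`-prefixed header comments so the file round-trips.
#'
#' @param r A `reflection_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reflections <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(r$cell)) {
    writeLines(sprintf("# cell %.6f %.6f %.6f", r$cell$a, r$cell$b, r$cell$c), con)
  }
  writeLines(sprintf("# d_min %.6f", r$d_min), con)
  df <- data.frame(h = r$hkl[, 1], k = r$hkl[, 2], l = r$hkl[, 3],
                   F_real = Re(r$f), F_imag = Im(r$f),
                   free = as.integer(r$free))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#' @param path CSV path.
#' @return A `reflection_set`.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  cell <- NULL
  d_min <- NA_real_
  for (h in hdr) {
    tok <- strsplit(trimws(sub("^#", "", h)), "\\s+")[[1]]
    if (tok[1] == "cell") cell <- unit_cell(as.numeric(tok[2]), as.numeric(tok[3]),
                                            as.numeric(tok[4]))
    if (tok[1] == "d_min") d_min <- as.numeric(tok[2])
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  need <- c("h", "k", "l", "F_real", "F_imag", "free")
  if (!all(need %in% names(df))) stop("missing reflection CSV columns")
  if (is.na(d_min)) d_min <- 1 / sqrt(max(.inv_d2(as.matrix(df[, 1:3]), cell)))
  reflection_set(as.matrix(df[, c("h", "k", "l")]),
                 complex(real = df$F_real, imaginary = df$F_imag),
                 d_min, free = df$free != 0, cell = cell)
}

#' Export a density grid as a CCP4/MRC map (mode 2, P1)
#'
#' Minimal but standard-compliant header; axis order X, Y, Z.
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ccp4 <- function(grid, path) {
  n <- grid$dim
  cell <- grid$cell
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                              # NC NR NS
  wi(2L)                             # MODE 2 = float32
  wi(c(0L, 0L, 0L))                  # start
  wi(n)                              # intervals
  wf(c(cell$a, cell$b, cell$c, 90, 90, 90))
  wi(c(1L, 2L, 3L))                  # axis order
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))
  wi(1L)                             # ISPG = P1
  wi(0L)                             # NSYMBT
  wi(rep(0L, 25))                    # extra
  wf(c(0, 0, 0))                     # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))
  wi(0L)                             # NLABL
  writeBin(raw(800), con)            # labels
  wf(as.numeric(v))
  invisible(path)
}
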