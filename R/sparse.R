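# The variability test: Lasso regression of the base conformer's density on
# ensemble-member densities, regularization paths, cross-validated penalty
# selection, post-selection significance, classification, and windowed /
# fragment region schemes.
#
# The penalized objective is
#     L(w) = sum_g (y_g - sum_i w_i x_gi)^2 + lambda * sum_i |w_i|
# fitted on columns scaled to unit Euclidean norm (no intercept, no
# centering: densities share physical units and a zero baseline, and norm
# scaling makes lambda comparable across grid regions). Reported weights are
# rescaled to the original columns.

#' Assemble a density regression problem
#'
#' Extracts the response `y` (base density over the region) and the feature
#' matrix `X` (one column per member density) with identical point ordering.
#' Members whose density is essentially zero over the region are dropped and
#' recorded in `dropped` — they cannot enter the fit but are reported with
#' weight 0 downstream.
#'
#' @param base_map `density_grid` of the base conformer (the response).
#' @param member_maps List of `density_grid`s, one per ensemble member.
#' @param region A `grid_region`; `NULL` means the full grid.
#' @param member_labels Optional identifiers (default `member_1`, ...).
#' @return An object of class `regression_problem` with fields `y`, `X`,
#'   `member_labels`, `region`, `col_norms`, `dropped`.
#' @export
build_problem <- function(base_map, member_maps, region = NULL,
                          member_labels = NULL) {
  stopifnot(length(member_maps) >= 1)
  if (is.null(region)) region <- full_region(base_map)
  for (m in member_maps) {
    if (!identical(m$dim, base_map$dim) ||
        !isTRUE(all.equal(unclass(m$cell), unclass(base_map$cell)))) {
      stop("all maps must share the same cell and grid shape")
    }
  }
  if (is.null(member_labels)) {
    member_labels <- sprintf("member_%d", seq_along(member_maps))
  }
  stopifnot(length(member_labels) == length(member_maps))
  y <- extract_density(base_map, region)
  X <- vapply(member_maps, extract_density, numeric(length(y)), region = region)
  X <- matrix(X, nrow = length(y))
  norms <- sqrt(colSums(X^2))
  live <- norms > 1e-12 * max(norms, 1e-300)
  if (!any(live)) stop("no member has density over this region")
  structure(list(y = y, X = X[, live, drop = FALSE],
                 member_labels = member_labels[live],
                 region = region, col_norms = norms[live],
                 dropped = member_labels[!live]),
            class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf("<regression_problem: %d grid points x %d members%s>\n",
              length(x$y), ncol(x$X),
              if (length(x$dropped)) paste0(", ", length(x$dropped), " dropped") else ""))
  invisible(x)
}

#' Largest useful penalty
#'
#' The smallest lambda for which the all-zero solution is optimal:
#' `lambda_max = max_i |2 x_i' y|` on unit-norm columns.
#'
#' @param p A `regression_problem`.
#' @return `lambda_max`.
#' @export
lambda_max <- function(p) {
  Xs <- sweep(p$X, 2, p$col_norms, "/")
  max(abs(2 * crossprod(Xs, p$y)))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Lasso fit by cyclic coordinate descent
#'
#' Minimizes `||y - Xw||^2 + lambda |w|_1` (optionally under `w >= 0`) by
#' soft-thresholding coordinate updates on unit-norm columns. Convergence is
#' declared when the largest coefficient change in a sweep falls below
#' `tol * (1 + max|w|)`; every converged fit carries its KKT stationarity
#' residual as a certificate.
#'
#' @param p A `regression_problem`.
#' @param lam Penalty `lambda >= 0`.
#' @param nonneg If `TRUE`, constrain weights to be nonnegative.
#' @param tol Convergence tolerance on the coefficient change (default 1e-8).
#' @param max_iter Maximum coordinate-descent sweeps (default 1e5).
#' @param warm Optional warm-start weights on the scaled coordinates.
#' @return An object of class `lasso_fit`: `weights` (original scale),
#'   `weights_scaled`, `lam`, `objective`, `n_iter`, `converged`,
#'   `kkt_ok`, `kkt_residual`, `member_labels`.
#' @export
lasso_fit <- function(p, lam, nonneg = FALSE, tol = 1e-8, max_iter = 1e5,
                      warm = NULL) {
  stopifnot(lam >= 0)
  suff <- .suff_stats(p)
  .lasso_cd(suff, lam, nonneg = nonneg, tol = tol, max_iter = max_iter,
            warm = warm, col_norms = p$col_norms,
            member_labels = p$member_labels)
}

# Sufficient statistics of the scaled problem: Gram matrix G = Xs' Xs,
# b = Xs' y and y' y. Coordinate descent only ever needs these, so sweeps
# cost O(k^2) regardless of the number of grid points.
.suff_stats <- function(p) {
  Xs <- sweep(p$X, 2, p$col_norms, "/")
  list(G = crossprod(Xs), b = as.numeric(crossprod(Xs, p$y)),
       yty = sum(p$y^2))
}

# Coordinate-descent core on sufficient statistics (unit-norm columns, so
# diag(G) = 1 and the per-coordinate update is a plain soft-threshold).
.lasso_cd <- function(suff, lam, nonneg, tol, max_iter, warm, col_norms,
                      member_labels) {
  G <- suff$G; b <- suff$b
  k <- length(b)
  w <- if (is.null(warm)) numeric(k) else as.numeric(warm)
  stopifnot(length(w) == k)
  thr <- lam / 2
  Gw <- as.numeric(G %*% w)
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    delta <- 0
    for (i in seq_len(k)) {
      ci <- b[i] - Gw[i] + w[i]
      wi <- if (nonneg) max(ci - thr, 0) else soft_threshold(ci, thr)
      if (wi != w[i]) {
        Gw <- Gw + G[, i] * (wi - w[i])
        delta <- max(delta, abs(wi - w[i]))
        w[i] <- wi
      }
    }
    if (delta < tol * (1 + max(abs(w)))) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("lasso_fit did not converge in %d sweeps (lam = %.3g)",
                    as.integer(max_iter), lam))
  }
  g <- 2 * (b - Gw)                    # negated RSS gradient at the solution
  ktol <- 1e-6 * max(2 * max(abs(b)), .Machine$double.eps)
  viol <- vapply(seq_len(k), function(i) {
    if (w[i] > 0) abs(g[i] - lam)
    else if (w[i] < 0) abs(g[i] + lam)
    else if (nonneg) max(g[i] - lam, 0)
    else max(abs(g[i]) - lam, 0)
  }, numeric(1))
  rss <- max(suff$yty - 2 * sum(w * b) + sum(w * Gw), 0)
  structure(list(weights = w / col_norms, weights_scaled = w, lam = lam,
                 objective = rss + lam * sum(abs(w)), n_iter = n_iter,
                 converged = converged,
                 kkt_residual = max(viol), kkt_ok = max(viol) <= ktol,
                 member_labels = member_labels),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit: lam = %.4g, %d/%d nonzero, obj = %.6g, %s>\n",
              x$lam, sum(x$weights != 0), length(x$weights), x$objective,
              if (x$converged) sprintf("converged in %d sweeps", x$n_iter)
              else "NOT CONVERGED"))
  invisible(x)
}

#' Default logarithmic penalty grid
#' @param p A `regression_problem`.
#' @param n_lam Number of grid points (default 30).
#' @param lam_min_ratio Smallest lambda as a fraction of `lambda_max`
#'   (default 1e-4).
#' @return Decreasing numeric vector from `lambda_max` down.
#' @export
default_lambda_grid <- function(p, n_lam = 30, lam_min_ratio = 1e-4) {
  lmax <- lambda_max(p)
  g <- exp(seq(log(lmax), log(lmax * lam_min_ratio), length.out = n_lam))
  g[1] <- lmax  # exact, so the first path point is the empty model
  g
}

#' Regularization path
#'
#' Warm-started fits along a decreasing penalty grid. The L1 ratio
#' `|w|_1 / max |w|_1` is computed against a fit at lambda -> 0+ (1e-8 of
#' `lambda_max`).
#'
#' @param p A `regression_problem`.
#' @param lam_grid Decreasing positive penalties; default
#'   [default_lambda_grid()].
#' @param nonneg Passed to [lasso_fit()].
#' @return An object of class `regularization_path`: `lam_grid`,
#'   `weight_matrix` (rows = grid points, columns = members, original scale),
#'   `l1_ratio`, `fits`.
#' @export
regularization_path <- function(p, lam_grid = NULL, nonneg = FALSE) {
  if (is.null(lam_grid)) lam_grid <- default_lambda_grid(p)
  stopifnot(all(lam_grid > 0), all(diff(lam_grid) < 0))
  suff <- .suff_stats(p)
  cd <- function(lam, warm) .lasso_cd(suff, lam, nonneg = nonneg, tol = 1e-8,
                                      max_iter = 1e5, warm = warm,
                                      col_norms = p$col_norms,
                                      member_labels = p$member_labels)
  fits <- vector("list", length(lam_grid))
  warm <- NULL
  for (i in seq_along(lam_grid)) {
    fits[[i]] <- cd(lam_grid[i], warm)
    warm <- fits[[i]]$weights_scaled
  }
  ref <- cd(1e-8 * lambda_max(p), warm)
  l1max <- sum(abs(ref$weights_scaled))
  W <- t(vapply(fits, function(f) f$weights, numeric(ncol(p$X))))
  W <- matrix(W, nrow = length(lam_grid),
              dimnames = list(NULL, p$member_labels))
  l1 <- vapply(fits, function(f) sum(abs(f$weights_scaled)), numeric(1))
  structure(list(lam_grid = lam_grid, weight_matrix = W,
                 l1_ratio = if (l1max > 0) pmin(l1 / l1max, 1) else rep(0, length(l1)),
                 fits = fits, member_labels = p$member_labels),
            class = "regularization_path")
}

#' Write a regularization path as CSV (long format)
#' @param path_obj A `regularization_path`.
#' @param path Output CSV path (columns lam, member, weight, l1_ratio).
#' @return Invisibly, `path`.
#' @export
write_path_csv <- function(path_obj, path) {
  W <- path_obj$weight_matrix
  df <- data.frame(
    lam = rep(path_obj$lam_grid, ncol(W)),
    member = rep(colnames(W), each = nrow(W)),
    weight = as.vector(W),
    l1_ratio = rep(path_obj$l1_ratio, ncol(W)))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validated penalty selection
#'
#' Seeded row-wise k-fold cross-validation over a penalty grid; per fold the
#' path is fitted warm-started on the training rows and scored by held-out
#' mean squared error. `rule = "min"` returns the lambda minimizing the mean
#' CV error (ties broken toward larger lambda, i.e. the sparser model);
#' `rule = "1se"` returns the largest lambda whose mean CV error is within
#' one standard error of the minimum — the conventional parsimonious choice
#' in Lasso practice.
#'
#' @param p A `regression_problem`.
#' @param k Number of folds (default 5).
#' @param lam_grid Decreasing penalties; default [default_lambda_grid()].
#' @param seed Integer seed for the fold assignment.
#' @param nonneg Passed to [lasso_fit()].
#' @param rule `"min"` or `"1se"`.
#' @param fold_type `"blocks"` (default) assigns contiguous runs of grid
#'   points — spatial slabs — to folds, which respects the strong spatial
#'   autocorrelation of density maps; `"random"` is plain row-wise
#'   assignment. See the methods vignette.
#' @return List of class `cv_result`: `lam` (the selected penalty), `rule`,
#'   `lam_grid`, `cvm`, `cvse`.
#' @export
cv_lambda <- function(p, k = 5, lam_grid = NULL, seed = 0L, nonneg = FALSE,
                      rule = c("min", "1se"),
                      fold_type = c("blocks", "random")) {
  rule <- match.arg(rule)
  fold_type <- match.arg(fold_type)
  n <- length(p$y)
  stopifnot(k >= 2)
  if (k > n) stop("more folds than rows")
  if (is.null(lam_grid)) lam_grid <- default_lambda_grid(p)
  fold <- switch(fold_type,
    random = withr_seed(seed, sample(rep_len(seq_len(k), n))),
    # contiguous blocks in grid order = spatial slabs; a seeded rotation
    # keeps the assignment seed-dependent without breaking contiguity
    blocks = {
      shift <- withr_seed(seed, sample.int(n, 1)) - 1L
      base_fold <- ceiling(seq_len(n) / (n / k))
      base_fold[((seq_len(n) - 1L + shift) %% n) + 1L]
    })
  G_all <- crossprod(p$X)
  b_all <- as.numeric(crossprod(p$X, p$y))
  err <- matrix(NA_real_, k, length(lam_grid))
  for (f in seq_len(k)) {
    te <- fold == f
    Xte <- p$X[te, , drop = FALSE]
    yte <- p$y[te]
    G_tr <- G_all - crossprod(Xte)
    b_tr <- b_all - as.numeric(crossprod(Xte, yte))
    norms_tr <- sqrt(pmax(diag(G_tr), 1e-300))
    Dinv <- 1 / norms_tr
    suff <- list(G = G_tr * outer(Dinv, Dinv), b = b_tr * Dinv,
                 yty = sum(p$y[!te]^2))
    warm <- NULL
    for (i in seq_along(lam_grid)) {
      fit <- .lasso_cd(suff, lam_grid[i], nonneg = nonneg, tol = 1e-8,
                       max_iter = 1e5, warm = warm, col_norms = norms_tr,
                       member_labels = p$member_labels)
      warm <- fit$weights_scaled
      err[f, i] <- mean((yte - Xte %*% fit$weights)^2)
    }
  }
  cvm <- colMeans(err)
  cvse <- apply(err, 2, stats::sd) / sqrt(k)
  lam <- if (rule == "min") {
    max(lam_grid[cvm <= min(cvm) + 1e-12 * max(cvm, 1e-300)])
  } else {
    i_min <- which.min(cvm)
    max(lam_grid[cvm <= cvm[i_min] + cvse[i_min]])
  }
  structure(list(lam = lam, rule = rule, lam_grid = lam_grid,
                 cvm = cvm, cvse = cvse),
            class = "cv_result")
}

#' Post-selection significance of regression coefficients
#'
#' Ordinary least-squares refit of `y` on the support columns (original
#' scale, no intercept); per-coefficient t statistics and two-sided
#' p-values. Members off the support get `t = 0`, `p = 1`. Collinear
#' support columns are dropped from the refit (recorded; their `p` is set
#' to 1). The refit's uncentered R^2 is reported.
#'
#' Two standard-error modes are provided. `se = "iid"` is the textbook OLS
#' t-test from the refit's residual variance — valid for independent
#' residuals, but grossly anticonservative on density maps, whose residual
#' fields are band-limited and spatially correlated over many voxels.
#' `se = "blocks"` (the classifier's default) refits the OLS separately on
#' `n_blocks` contiguous spatial slabs of the region and tests the mean
#' coefficient against its between-block standard error
#' (`df = n_blocks - 1`) — an honest test under spatial correlation; see
#' the methods vignette.
#'
#' @param p A `regression_problem`.
#' @param support Logical or integer index of the support members.
#' @param se `"iid"` or `"blocks"`.
#' @param n_blocks Number of spatial slabs for `se = "blocks"` (default 5).
#' @return List of class `coef_significance`: data.frame `table` (member,
#'   estimate, t, p), `r_squared`, `dropped_collinear`.
#' @export
coef_significance <- function(p, support, se = c("iid", "blocks"),
                              n_blocks = 5) {
  se <- match.arg(se)
  if (is.logical(support)) support <- which(support)
  tab <- data.frame(member = p$member_labels,
                    estimate = 0, t = 0, p = 1,
                    stringsAsFactors = FALSE)
  dropped <- character(0)
  r2 <- 0
  if (length(support) > 0) {
    Xs <- p$X[, support, drop = FALSE]
    n <- nrow(Xs)
    if (length(support) >= n) stop("support size must be below the row count")
    qrX <- qr(Xs)
    use <- qrX$pivot[seq_len(qrX$rank)]
    if (qrX$rank < ncol(Xs)) {
      dropped <- p$member_labels[support[setdiff(seq_len(ncol(Xs)), use)]]
      Xs <- Xs[, use, drop = FALSE]
      qrX <- qr(Xs)
    }
    beta <- qr.coef(qrX, p$y)
    res <- p$y - Xs %*% beta
    if (se == "iid") {
      df <- n - ncol(Xs)
      s2 <- sum(res^2) / df
      XtXinv <- chol2inv(qr.R(qrX))
      sebeta <- sqrt(s2 * diag(XtXinv))
      tstat <- beta / sebeta
      pval <- 2 * stats::pt(-abs(tstat), df)
    } else {
      fold <- ceiling(seq_len(n) / (n / n_blocks))
      B <- matrix(NA_real_, ncol(Xs), n_blocks)
      for (f in seq_len(n_blocks)) {
        i <- fold == f
        B[, f] <- qr.coef(qr(Xs[i, , drop = FALSE]), p$y[i])
      }
      ok_blocks <- colSums(is.na(B)) == 0
      if (sum(ok_blocks) < 3) stop("too few full-rank blocks for blockwise se")
      B <- B[, ok_blocks, drop = FALSE]
      nb <- ncol(B)
      mb <- rowMeans(B)
      seb <- apply(B, 1, stats::sd) / sqrt(nb)
      tstat <- mb / pmax(seb, .Machine$double.eps)
      pval <- 2 * stats::pt(-abs(tstat), nb - 1)
    }
    rows <- support[use]
    tab$estimate[rows] <- beta
    tab$t[rows] <- tstat
    tab$p[rows] <- pval
    r2 <- 1 - sum(res^2) / sum(p$y^2)
  }
  structure(list(table = tab, r_squared = r2, dropped_collinear = dropped),
            class = "coef_significance")
}

#' Classify ensemble members as noise variants or truly variable
#'
#' The whole-model test: fit the Lasso of the base density on the member
#' densities over a grid region, then refit the selected members by OLS and
#' test their coefficients. A member is a `noise_variant` iff (a) its Lasso
#' weight is nonzero, (b) the refit p-value is at most `alpha`, and (c) its
#' scaled weight is at least `rel_floor` of the largest scaled weight — the
#' numerical reading of "the coefficient does not approach zero"; otherwise
#' it is `truly_variable` (its density does not help represent the base).
#'
#' @param base_map `density_grid` of the base conformer (the response; pass
#'   a data-derived map here to regress against experimental density
#'   instead).
#' @param member_maps List of member `density_grid`s.
#' @param region `grid_region` or `NULL` (full grid).
#' @param lam Penalty: a number, or `"cv"` for cross-validated selection.
#' @param alpha Significance level (default 0.05).
#' @param nonneg Nonnegative weights (default `FALSE`).
#' @param member_labels Optional identifiers.
#' @param cv_rule `"min"` or `"1se"` when `lam = "cv"` (default `"1se"`; see
#'   the methods vignette).
#' @param k Folds for cross-validation.
#' @param seed Seed for the CV fold draw.
#' @param se_method Standard-error mode for [coef_significance()]
#'   (default `"blocks"`).
#' @param rel_floor Relative scaled-weight floor below which a coefficient
#'   counts as "approaching zero" (default 0.05; see the methods vignette).
#' @return An object of class `variability_report`: data.frame `table`
#'   (member, weight, t, p, label), plus `lam`, `r_squared`, `fit`,
#'   `n_points`.
#' @export
classify_ensemble <- function(base_map, member_maps, region = NULL,
                              lam = "cv", alpha = 0.05, nonneg = FALSE,
                              member_labels = NULL, cv_rule = "1se",
                              k = 5, seed = 0L, se_method = "blocks",
                              rel_floor = 0.05) {
  stopifnot(alpha > 0, alpha < 1, rel_floor >= 0, rel_floor < 1)
  if (is.null(member_labels)) {
    member_labels <- sprintf("member_%d", seq_along(member_maps))
  }
  p <- build_problem(base_map, member_maps, region, member_labels)
  cv <- NULL
  if (identical(lam, "cv")) {
    cv <- cv_lambda(p, k = k, seed = seed, nonneg = nonneg, rule = cv_rule)
    lam_use <- cv$lam
  } else {
    lam_use <- as.numeric(lam)
  }
  fit <- lasso_fit(p, lam_use, nonneg = nonneg)
  support <- which(fit$weights != 0)
  sig <- coef_significance(p, support, se = se_method)
  tab <- data.frame(member = p$member_labels,
                    weight = fit$weights,
                    t = sig$table$t, p = sig$table$p,
                    stringsAsFactors = FALSE)
  wrel <- abs(fit$weights_scaled) / max(abs(fit$weights_scaled), 1e-300)
  tab$label <- ifelse(tab$weight != 0 & tab$p <= alpha & wrel >= rel_floor,
                      "noise_variant", "truly_variable")
  # members dropped for zero density over the region: weight 0, variable
  if (length(p$dropped) > 0) {
    tab <- rbind(tab, data.frame(member = p$dropped, weight = 0, t = 0, p = 1,
                                 label = "truly_variable",
                                 stringsAsFactors = FALSE))
    tab <- tab[match(member_labels, tab$member), ]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, lam = lam_use, alpha = alpha,
                 r_squared = sig$r_squared, fit = fit, cv = cv,
                 n_points = length(p$y)),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report: lam = %.4g, R^2 = %.4f, %d points>\n",
              x$lam, x$r_squared, x$n_points))
  print(x$table, digits = 4)
  invisible(x)
}

#' Per-residue sliding-window Lasso profile
#'
#' For each residue of the base conformer, the Lasso is fitted over the
#' bounding box (plus margin) of the residues in a window of odd size
#' centered on it (clipped at chain ends), at a fixed penalty. Members with
#' no density over a window are recorded with weight 0 there.
#'
#' @param base The base `conformer` (defines residues and boxes).
#' @param base_map `density_grid` of the base.
#' @param member_maps List of member `density_grid`s.
#' @param window Odd window size in residues (default 3).
#' @param margin Box margin in Angstrom (default 2).
#' @param lam Fixed penalty (default 10).
#' @param nonneg Passed to [lasso_fit()].
#' @param member_labels Optional identifiers.
#' @return Object of class `window_profile`: matrix `weights` (rows =
#'   residues, columns = members), `residues`, `window`, `lam`.
#' @export
windowed_profile <- function(base, base_map, member_maps, window = 3,
                             margin = 2, lam = 10, nonneg = FALSE,
                             member_labels = NULL) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (is.null(member_labels)) {
    member_labels <- sprintf("member_%d", seq_along(member_maps))
  }
  res <- sort(unique(base$atoms$resi))
  half <- window %/% 2
  W <- matrix(0, length(res), length(member_maps),
              dimnames = list(res, member_labels))
  for (ri in seq_along(res)) {
    lo <- max(min(res), res[ri] - half)
    hi <- min(max(res), res[ri] + half)
    region <- fragment_box(base, res[res >= lo & res <= hi], margin, base_map)
    p <- build_problem(base_map, member_maps, region, member_labels)
    fit <- lasso_fit(p, lam, nonneg = nonneg)
    W[ri, p$member_labels] <- fit$weights
  }
  structure(list(weights = W, residues = res, window = window, lam = lam,
                 member_labels = member_labels),
            class = "window_profile")
}

#' Per-fragment Lasso profile
#'
#' The chain is split into consecutive fragments of `frag_size` residues
#' (last fragment possibly shorter) and the Lasso fitted over each
#' fragment's bounding box. At `frag_size = 1` this coincides with
#' [windowed_profile()] at window 1.
#'
#' @inheritParams windowed_profile
#' @param frag_size Fragment length in residues.
#' @return Object of class `window_profile` with one row per fragment.
#' @export
fragment_profile <- function(base, base_map, member_maps, frag_size = 4,
                             margin = 2, lam = 10, nonneg = FALSE,
                             member_labels = NULL) {
  stopifnot(frag_size >= 1)
  if (is.null(member_labels)) {
    member_labels <- sprintf("member_%d", seq_along(member_maps))
  }
  res <- sort(unique(base$atoms$resi))
  starts <- seq(1, length(res), by = frag_size)
  W <- matrix(0, length(starts), length(member_maps),
              dimnames = list(res[starts], member_labels))
  for (fi in seq_along(starts)) {
    sel <- res[starts[fi]:min(starts[fi] + frag_size - 1, length(res))]
    region <- fragment_box(base, sel, margin, base_map)
    p <- build_problem(base_map, member_maps, region, member_labels)
    fit <- lasso_fit(p, lam, nonneg = nonneg)
    W[fi, p$member_labels] <- fit$weights
  }
  structure(list(weights = W, residues = res[starts], window = frag_size,
                 lam = lam, member_labels = member_labels),
            class = "window_profile")
}

#' Average member weight over a profile
#'
#' Arithmetic mean of each member's weight over all windows/fragments — a
#' region-scheme-robust summary of how much each member contributes to
#' representing the base density.
#'
#' @param profile A `window_profile`.
#' @return Named numeric vector, one mean weight per member.
#' @export
average_weight <- function(profile) {
  stopifnot(nrow(profile$weights) > 0)
  colMeans(profile$weights)
}

#' Write a variability report as CSV and JSON
#' @param report A `variability_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(lam = report$lam, alpha = report$alpha,
           r_squared = report$r_squared, n_points = report$n_points,
           members = report$table),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}
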