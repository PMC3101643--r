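# The Lasso solver, paths, CV, significance, classification and the
# windowed/fragment region schemes.

test_that("build_problem aligns y and X and drops empty columns", {
  sf <- standard_fixture()
  p <- build_problem(sf$base_map, list(sf$base_map), sf$region)
  expect_identical(p$X[, 1], p$y)  # identity feature
  pf <- build_problem(sf$base_map, sf$member_maps, NULL)
  expect_equal(nrow(pf$X), prod(sf$base_map$dim))
  # permuting member order permutes columns and labels consistently
  perm <- c(3, 1, 4, 2)
  p1 <- build_problem(sf$base_map, sf$member_maps, sf$region)
  p2 <- build_problem(sf$base_map, sf$member_maps[perm], sf$region,
                      member_labels = p1$member_labels[perm])
  expect_identical(p2$X, p1$X[, perm])
  expect_identical(p2$member_labels, p1$member_labels[perm])
  # an all-zero member column is dropped with a record
  zero_map <- density_grid(sf$base_map$cell, array(0, sf$base_map$dim))
  expect_error(build_problem(zero_map, list(zero_map)), "no member")
  p3 <- build_problem(sf$base_map, c(sf$member_maps[1], list(zero_map)),
                      sf$region, member_labels = c("live", "empty"))
  expect_identical(p3$member_labels, "live")
  expect_identical(p3$dropped, "empty")
})

test_that("lambda extremes: saturation at lambda_max, least squares at 0", {
  for (seed in 1:5) {
    p <- toy_problem(seed)
    lmax <- lambda_max(p)
    f_hi <- lasso_fit(p, lmax * (1 + 1e-12))
    expect_identical(f_hi$weights, rep(0, 3))
    f0 <- lasso_fit(p, 0)
    ls <- qr.coef(qr(p$X), p$y)
    expect_lt(max(abs(f0$weights - ls)), 1e-8)
  }
  # orthogonal columns at lam = 0: per-column least squares
  X <- diag(4)[, 1:2] * c(2, 3)[col(diag(4)[, 1:2])]
  X <- cbind(c(2, 0, 0, 0), c(0, 3, 0, 0))
  y <- c(4, 9, 1, 1)
  p <- structure(list(y = y, X = X, member_labels = c("a", "b"),
                      region = grid_region(1:4, c(4, 1, 1)),
                      col_norms = sqrt(colSums(X^2)), dropped = character(0)),
                 class = "regression_problem")
  f <- lasso_fit(p, 0)
  expect_equal(f$weights, colSums(X * y) / colSums(X^2), tolerance = 1e-10)
})

test_that("solver matches the exhaustive grid oracle on small problems", {
  # 10 seeded instances here; the full 50-instance sweep runs in
  # test-acceptance.R (criterion 2)
  for (seed in 1:10) {
    k <- 2 + seed %% 2
    p <- toy_problem(seed, n = 30, k = k,
                     w_true = c(1.2, -0.5, 0.8)[seq_len(k)], noise = 0.1)
    lam <- 0.25 * lambda_max(p)
    fit <- lasso_fit(p, lam)
    Xs <- sweep(p$X, 2, p$col_norms, "/")
    oracle <- lasso_grid_oracle(p$y, Xs, lam)
    expect_lt(max(abs(fit$weights_scaled - oracle)), 2e-3)
    expect_true(fit$kkt_ok)
  }
})

test_that("KKT stationarity certifies every fit, including nonnegative ones", {
  for (seed in 1:8) {
    p <- toy_problem(seed, n = 25, k = 3)
    for (lam in c(0.01, 0.5, 2) * lambda_max(p)) {
      for (nn in c(FALSE, TRUE)) {
        f <- lasso_fit(p, lam, nonneg = nn)
        expect_true(f$converged)
        expect_true(f$kkt_ok)
        if (nn) expect_true(all(f$weights >= 0))
      }
    }
  }
  sf <- standard_fixture()
  p <- build_problem(sf$base_map, sf$member_maps, sf$region)
  f <- lasso_fit(p, 10)
  expect_true(f$kkt_ok)
})

test_that("objective at the solution beats nearby and naive candidates", {
  p <- toy_problem(3, n = 30, k = 3)
  lam <- 0.3 * lambda_max(p)
  f <- lasso_fit(p, lam)
  obj <- function(w) {
    Xs <- sweep(p$X, 2, p$col_norms, "/")
    sum((p$y - Xs %*% w)^2) + lam * sum(abs(w))
  }
  expect_equal(f$objective, obj(f$weights_scaled), tolerance = 1e-8)
  expect_lte(f$objective, obj(rep(0, 3)))
  set.seed(1)
  for (i in 1:20) {
    expect_lte(f$objective, obj(f$weights_scaled + rnorm(3, 0, 0.01)) + 1e-12)
  }
})

test_that("regularization path is warm-start consistent and monotone", {
  sf <- standard_fixture()
  p <- build_problem(sf$base_map, sf$member_maps, sf$region)
  grid <- default_lambda_grid(p, n_lam = 10)
  rp <- regularization_path(p, grid)
  expect_true(all(rp$l1_ratio >= 0 & rp$l1_ratio <= 1))
  expect_true(all(diff(rp$l1_ratio) >= -1e-8))  # nondecreasing as lam drops
  # first grid point is lambda_max -> empty model
  expect_equal(rp$l1_ratio[1], 0)
  expect_true(all(rp$weight_matrix[1, ] == 0))
  # ten cold-started fits agree with the warm-started path
  for (i in seq_along(grid)) {
    cold <- lasso_fit(p, grid[i])
    expect_lt(max(abs(cold$weights - rp$weight_matrix[i, ])), 1e-6)
  }
})

test_that("path CSV serialization round-trips", {
  p <- toy_problem(2)
  rp <- regularization_path(p, default_lambda_grid(p, n_lam = 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_path_csv(rp, f)
  df <- read.csv(f)
  expect_identical(names(df), c("lam", "member", "weight", "l1_ratio"))
  W <- matrix(df$weight, nrow = 8)
  expect_lt(max(abs(W - rp$weight_matrix)), 1e-9)
  expect_true(all(df$l1_ratio >= 0 & df$l1_ratio <= 1))
})

test_that("cv_lambda behaves at the informative and null extremes", {
  # pure-noise response: nothing predicts, so the min rule sits at or near
  # the top of the grid
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3)
  y <- rnorm(100)
  p <- structure(list(y = y, X = X, member_labels = c("a", "b", "c"),
                      region = grid_region(1:100, c(100, 1, 1)),
                      col_norms = sqrt(colSums(X^2)), dropped = character(0)),
                 class = "regression_problem")
  cv <- cv_lambda(p, seed = 1, rule = "min")
  expect_gte(cv$lam, cv$lam_grid[5])
  # exact single-member response: selected lambda retains it within 10%
  p2 <- toy_problem(5, n = 60, k = 3, w_true = c(0, 2.5, 0), noise = 0)
  cv2 <- cv_lambda(p2, seed = 1, rule = "min")
  fit <- lasso_fit(p2, cv2$lam)
  expect_equal(fit$weights[2], 2.5, tolerance = 0.1)
  expect_true(all(abs(fit$weights[c(1, 3)]) < 0.1))
  # determinism under a fixed seed, for both fold types
  for (ft in c("blocks", "random")) {
    expect_identical(cv_lambda(p2, seed = 7, fold_type = ft)$lam,
                     cv_lambda(p2, seed = 7, fold_type = ft)$lam)
  }
  expect_error(cv_lambda(toy_problem(1, n = 4), k = 5), "folds")
})

test_that("coef_significance matches textbook OLS on a small example", {
  set.seed(8)
  X <- cbind(c(1.0, 2.0, 0.5, -1.0, 0.3), c(0.2, -0.7, 1.1, 0.4, -0.9))
  y <- c(2.1, 3.9, 1.8, -1.7, 0.4)
  p <- structure(list(y = y, X = X, member_labels = c("a", "b"),
                      region = grid_region(1:5, c(5, 1, 1)),
                      col_norms = sqrt(colSums(X^2)), dropped = character(0)),
                 class = "regression_problem")
  sig <- coef_significance(p, c(1, 2), se = "iid")
  ref <- summary(lm(y ~ 0 + X))
  expect_equal(sig$table$estimate, unname(coef(ref)[, 1]), tolerance = 1e-8)
  expect_equal(sig$table$t, unname(coef(ref)[, 3]), tolerance = 1e-8)
  expect_equal(sig$table$p, unname(coef(ref)[, 4]), tolerance = 1e-8)
  expect_equal(sig$r_squared, 1 - sum(ref$residuals^2) / sum(y^2),
               tolerance = 1e-10)
  # overwhelming signal
  X1 <- matrix(seq(-1, 1, length.out = 50))
  y1 <- 3 * X1[, 1] + rnorm(50, 0, 1e-4)
  p1 <- structure(list(y = y1, X = X1, member_labels = "a",
                       region = grid_region(1:50, c(50, 1, 1)),
                       col_norms = sqrt(colSums(X1^2)), dropped = character(0)),
                  class = "regression_problem")
  expect_lt(coef_significance(p1, 1, se = "iid")$table$p, 1e-6)
  # empty support
  s0 <- coef_significance(p1, integer(0))
  expect_identical(s0$table$p, 1)
  expect_identical(s0$r_squared, 0)
  # collinear support columns are dropped and recorded
  Xc <- cbind(X1, 2 * X1)
  pc <- structure(list(y = y1, X = Xc, member_labels = c("a", "b"),
                       region = grid_region(1:50, c(50, 1, 1)),
                       col_norms = sqrt(colSums(Xc^2)), dropped = character(0)),
                  class = "regression_problem")
  sc <- coef_significance(pc, 1:2, se = "iid")
  expect_length(sc$dropped_collinear, 1)
})

test_that("blockwise standard errors are honest under spatial correlation", {
  # strongly autocorrelated residual field: iid test is anticonservative,
  # blockwise test is not
  set.seed(21)
  n <- 2000
  x1 <- stats::filter(rnorm(n), rep(1, 50), circular = TRUE) / sqrt(50)
  x2 <- stats::filter(rnorm(n), rep(1, 50), circular = TRUE) / sqrt(50)
  eps <- stats::filter(rnorm(n), rep(1, 50), circular = TRUE) / sqrt(50)
  y <- as.numeric(x1) + 0.5 * as.numeric(eps)  # x2 is irrelevant
  X <- cbind(as.numeric(x1), as.numeric(x2))
  p <- structure(list(y = y, X = X, member_labels = c("sig", "null"),
                      region = grid_region(1:n, c(n, 1, 1)),
                      col_norms = sqrt(colSums(X^2)), dropped = character(0)),
                 class = "regression_problem")
  blocks <- coef_significance(p, 1:2, se = "blocks")
  expect_lt(blocks$table$p[1], 0.01)   # real signal stays significant
  expect_gt(blocks$table$p[2], 0.05)   # null member is not declared real
})

test_that("classify_ensemble handles the self-representation edge case", {
  sf <- standard_fixture()
  rep1 <- classify_ensemble(sf$base_map, list(sf$base_map), sf$region,
                            lam = "cv", member_labels = "self")
  expect_identical(rep1$table$label, "noise_variant")
  expect_equal(rep1$table$weight, 1, tolerance = 0.05)
  expect_gt(rep1$r_squared, 0.99)
})

test_that("windowed profile saturates to the global fit and localizes signal", {
  sf <- standard_fixture()
  base <- sf$fx$base
  # window spanning the whole chain reproduces the global fit in every row
  full_w <- 2 * length(unique(base$atoms$resi)) + 1
  prof <- windowed_profile(base, sf$base_map, sf$member_maps,
                           window = full_w, margin = 2, lam = 10)
  pglob <- build_problem(sf$base_map, sf$member_maps,
                         fragment_box(base, 1:12, 2, sf$base_map))
  wglob <- lasso_fit(pglob, 10)$weights
  for (r in seq_len(nrow(prof$weights))) {
    expect_equal(unname(prof$weights[r, ]), unname(wglob), tolerance = 1e-6)
  }
  # window = 1 coincides with fragment size 1
  p1 <- windowed_profile(base, sf$base_map, sf$member_maps, window = 1,
                         margin = 2, lam = 10)
  f1 <- fragment_profile(base, sf$base_map, sf$member_maps, frag_size = 1,
                         margin = 2, lam = 10)
  expect_equal(p1$weights, f1$weights, tolerance = 1e-9)
})

test_that("windowed profile separates a locally perturbed region", {
  base <- make_toy_protein(12, "strand")  # extended chain: windows separate
  cell <- cell_around(base)
  base_c <- center_conformer(base, cell)
  shape <- grid_shape(cell, 2 / 3)
  # members 1-2: plain global noise; member 3: very clean globally (so it
  # dominates windows where it matches the base) but with residues 5-8
  # displaced 5 A perpendicular to the chain, leaving those window boxes
  m1 <- perturb_conformer(base_c, noise_model(0.15, 1))
  m2 <- perturb_conformer(base_c, noise_model(0.15, 2))
  m3 <- perturb_conformer(base_c, noise_model(0.03, 3))
  sel <- base_c$atoms$resi %in% 5:8
  xyz <- coords(m3)
  xyz[sel, ] <- xyz[sel, ] + matrix(c(0, 4, 3), sum(sel), 3, byrow = TRUE)
  m3 <- set_coords(m3, xyz)
  bm <- density_map(base_c, cell, shape = shape)
  maps <- lapply(list(m1, m2, m3), density_map, cell = cell, shape = shape)
  prof <- windowed_profile(base_c, bm, maps, window = 3, margin = 2, lam = 10)
  w3 <- prof$weights[, 3]
  inside <- prof$residues %in% 6:7    # windows fully inside the moved block
  outside <- prof$residues %in% c(1, 2, 12)
  # the locally displaced member dominates where it matches the base and
  # collapses where it deviates
  expect_gt(mean(w3[outside]) / max(mean(w3[inside]), 1e-6), 2)
  expect_true(all(w3[outside] > 0.3))
})

test_that("average_weight is a plain mean with permutation invariance", {
  W <- matrix(c(1, 1, 1, 0.5, 0.7, 0.9), 3, 2,
              dimnames = list(1:3, c("a", "b")))
  prof <- structure(list(weights = W, residues = 1:3, window = 3, lam = 10,
                         member_labels = c("a", "b")),
                    class = "window_profile")
  expect_equal(average_weight(prof), c(a = 1, b = 0.7))
  prof2 <- prof
  prof2$weights <- W[c(3, 1, 2), ]
  expect_equal(average_weight(prof2), average_weight(prof))
})
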