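# Baseline comparators: per-residue RMSD profiles, normalized RMSD against a
# reference alternate conformation, and B-factor profiles.

#' Construct a residue profile
#' @param residues Integer residue indices.
#' @param value Nonnegative per-residue values.
#' @param kind Tag: e.g. `"rmsd"`, `"bfactor"`, `"normalized_rmsd"`.
#' @return An object of class `residue_profile` (a data.frame).
#' @export
residue_profile <- function(residues, value, kind) {
  stopifnot(length(residues) == length(value), all(value >= -1e-12))
  structure(data.frame(residue = as.integer(residues),
                       value = pmax(value, 0), kind = kind,
                       stringsAsFactors = FALSE),
            class = c("residue_profile", "data.frame"))
}

#' Per-residue backbone RMSD profile
#'
#' Backbone (N, CA, C, O) RMSD per residue between a member and the base,
#' after one optional global best-fit superposition of the member onto the
#' base (no per-residue refitting).
#'
#' @param base,member Matched `conformer`s.
#' @param fit Superpose globally first (default `TRUE`).
#' @return A `residue_profile` in Angstrom.
#' @export
residue_rmsd_profile <- function(base, member, fit = TRUE) {
  if (!identical(.atom_key(base), .atom_key(member))) {
    stop("conformers do not match atom-for-atom")
  }
  m <- member
  if (fit) {
    s <- superpose(base, member, BACKBONE)
    m <- transform_conformer(member, s$rotation, s$translation)
  }
  sel <- base$atoms$name %in% BACKBONE
  d2 <- rowSums((coords(base) - coords(m))^2)
  res <- sort(unique(base$atoms$resi))
  val <- vapply(res, function(r) {
    i <- sel & base$atoms$resi == r
    sqrt(mean(d2[i]))
  }, numeric(1))
  residue_profile(res, val, "rmsd")
}

#' Normalized RMSD of a member relative to a reference alternate conformer
#'
#' `rmsd(member, base) / rmsd(reference_alt, base)` on backbone atoms with
#' best-fit superposition. Values near 1 mean the member sits as far from
#' the base as the reference alternate conformation does; values near 0 mean
#' it is essentially the base.
#'
#' @param member,base,reference_alt Matched `conformer`s.
#' @return Dimensionless scalar.
#' @export
normalized_rmsd <- function(member, base, reference_alt) {
  den <- rmsd(base, reference_alt, BACKBONE, fit = TRUE)
  if (den <= 1e-12) stop("reference alternate coincides with the base")
  rmsd(base, member, BACKBONE, fit = TRUE) / den
}

#' Per-residue mean B-factor profile
#' @param c A `conformer`.
#' @return A `residue_profile` in Angstrom^2.
#' @export
bfactor_profile <- function(c) {
  res <- sort(unique(c$atoms$resi))
  val <- vapply(res, function(r) mean(c$atoms$b[c$atoms$resi == r]), numeric(1))
  residue_profile(res, val, "bfactor")
}

#' Write a residue profile as CSV (6 significant digits)
#' @param profile A `residue_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(residue = profile$residue,
                   value = signif(profile$value, 6),
                   kind = profile$kind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a residue profile CSV
#' @param path CSV path written by [write_profile_csv()].
#' @return A `residue_profile`.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  residue_profile(df$residue, df$value, df$kind[1])
}

#' Plot a regularization path
#' @param path_obj A `regularization_path`.
#' @param file Output PNG path; `NULL` plots to the active device.
#' @return Invisibly, `NULL`.
#' @export
plot_path <- function(path_obj, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  W <- path_obj$weight_matrix
  graphics::matplot(path_obj$lam_grid, W, type = "l", lty = 1, log = "x",
                    xlab = expression(lambda), ylab = "weight",
                    main = "Regularization path")
  graphics::legend("topright", colnames(W), col = seq_len(ncol(W)), lty = 1,
                   cex = 0.8)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

#' Plot a window-weight heatmap
#' @param profile A `window_profile`.
#' @param file Output PNG path; `NULL` plots to the active device.
#' @return Invisibly, `NULL`.
#' @export
plot_window_profile <- function(profile, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  W <- profile$weights
  graphics::image(x = as.integer(rownames(W)), y = seq_len(ncol(W)), z = W,
                  xlab = "residue", ylab = "member", axes = FALSE,
                  main = sprintf("Window weights (size %d, lambda %.3g)",
                                 profile$window, profile$lam))
  graphics::axis(1)
  graphics::axis(2, at = seq_len(ncol(W)), labels = colnames(W), las = 2,
                 cex.axis = 0.7)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
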