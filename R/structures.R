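# Atomic models: conformers, ensembles, PDB fixed-column I/O, Kabsch
# superposition and RMSD.

# Electron counts for the elements that occur in protein models (plus a few
# common hetero elements). Extend here if new scatterers are needed.
.ELECTRONS <- c(
  H = 1L, C = 6L, N = 7L, O = 8L, P = 15L, S = 16L,
  MG = 12L, NA_ = 11L, K = 19L, CA_ION = 20L, FE = 26L, ZN = 30L, CL = 17L
)

#' Electron count of a chemical element
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Integer vector of electron counts.
#' @export
electron_count <- function(element) {
  el <- toupper(trimws(element))
  el[el == "NA"] <- "NA_"
  z <- .ELECTRONS[el]
  if (anyNA(z)) {
    stop("no electron count defined for element(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Construct a conformer
#'
#' A conformer is one complete atomic model: an ordered table of atoms with
#' coordinates (Angstrom), occupancies, isotropic B-factors (Angstrom^2) and
#' residue bookkeeping. It is the unit of ensemble membership.
#'
#' @param atoms A data.frame with columns `element`, `name`, `x`, `y`, `z`,
#'   `occ`, `b`, `resi` (integer residue index), `resn` (3-letter residue
#'   name), `chain` (single character).
#' @param label Identifier string.
#' @return An object of class `conformer`.
#' @export
conformer <- function(atoms, label = "conformer") {
  req <- c("element", "name", "x", "y", "z", "occ", "b", "resi", "resn", "chain")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("atoms must be a data.frame with columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("a conformer needs at least one atom")
  atoms <- atoms[, req]
  atoms$resi <- as.integer(atoms$resi)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy must lie in [0, 1]")
  if (any(atoms$b <= 0)) stop("B-factors must be positive")
  electron_count(atoms$element)  # errors on unknown elements
  for (ch in unique(atoms$chain)) {
    ri <- atoms$resi[atoms$chain == ch]
    if (is.unsorted(ri)) stop("residue indices must be nondecreasing within a chain")
  }
  structure(list(atoms = atoms, label = label), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer '%s': %d atoms, %d residues, chain(s) %s>\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resi))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a conformer
#' @param c A `conformer`.
#' @return Integer atom count.
#' @export
n_atoms <- function(c) nrow(c$atoms)

#' Coordinates of a conformer as a matrix
#' @param c A `conformer`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(c) as.matrix(c$atoms[, c("x", "y", "z")])

#' Replace the coordinates of a conformer
#' @param c A `conformer`.
#' @param xyz n x 3 numeric matrix.
#' @param label Optional new label.
#' @return A new `conformer` with identical atom metadata.
#' @export
set_coords <- function(c, xyz, label = c$label) {
  stopifnot(is.matrix(xyz), nrow(xyz) == n_atoms(c), ncol(xyz) == 3L)
  a <- c$atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  conformer(a, label = label)
}

# Key identifying each atom for cross-member matching.
.atom_key <- function(c) paste(c$atoms$chain, c$atoms$resi, c$atoms$name, sep = "|")

#' Construct an ensemble
#'
#' An ensemble bundles member conformers with the base conformer they are
#' compared against. Every member must match the base atom-for-atom by
#' (chain, residue index, atom name), in the same order; mismatching members
#' are rejected so that density regressions line up column-for-column.
#'
#' @param members List of `conformer` objects.
#' @param base The base `conformer` (typically the deposited single-conformer
#'   model).
#' @param truth_labels Optional character vector (`"noise"` / `"variable"`),
#'   one per member; carried by synthetic fixtures only.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(members, base, truth_labels = NULL) {
  stopifnot(inherits(base, "conformer"), is.list(members))
  if (length(members) > 0) {
    key0 <- .atom_key(base)
    for (i in seq_along(members)) {
      m <- members[[i]]
      if (!inherits(m, "conformer")) stop("member ", i, " is not a conformer")
      if (n_atoms(m) != n_atoms(base) || !identical(.atom_key(m), key0)) {
        stop(sprintf("member %d ('%s') does not match the base atom ordering",
                     i, m$label))
      }
    }
  }
  if (!is.null(truth_labels)) {
    stopifnot(length(truth_labels) == length(members),
              all(truth_labels %in% c("noise", "variable")))
  }
  structure(list(members = members, base = base, truth_labels = truth_labels),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d members over base '%s' (%d atoms)%s>\n",
              length(x$members), x$base$label, n_atoms(x$base),
              if (is.null(x$truth_labels)) "" else ", labeled"))
  invisible(x)
}

# ---- PDB fixed-column I/O (wwPDB v3.3 ATOM/HETATM records) -----------------

.guess_element <- function(name) {
  # Columns 77-78 absent: take the first alphabetic character of the atom
  # name; two-letter elements are not guessed.
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
}

#' Read a single-model PDB file
#'
#' Parses ATOM/HETATM records per the wwPDB fixed-column standard.
#' Multi-model files are rejected unless `first_model = TRUE`. Alternate
#' location indicators with partial occupancy are rejected: this package's
#' multi-conformer representation is the ensemble itself, so each input file
#' must be a single-conformation model.
#'
#' @param path File path.
#' @param first_model If `TRUE`, silently keep the first MODEL of a
#'   multi-model file instead of erroring.
#' @return A `conformer`.
#' @export
read_pdb <- function(path, first_model = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) {
    if (length(grep("^MODEL", lines)) > 1 && !first_model) {
      stop("multi-model PDB file; pass first_model = TRUE to keep model 1")
    }
    lines <- lines[seq_len(endmdl[1] - 1L)]
  }
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  fx <- function(a, b) substr(rec, a, b)
  name   <- trimws(fx(13, 16))
  altloc <- trimws(fx(17, 17))
  resn   <- trimws(fx(18, 20))
  chain  <- fx(22, 22)
  resi   <- suppressWarnings(as.integer(fx(23, 26)))
  x <- suppressWarnings(as.numeric(fx(31, 38)))
  y <- suppressWarnings(as.numeric(fx(39, 46)))
  z <- suppressWarnings(as.numeric(fx(47, 54)))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  b   <- suppressWarnings(as.numeric(fx(61, 66)))
  el  <- trimws(fx(77, 78))
  if (anyNA(resi) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("unparseable mandatory columns in ", path)
  }
  occ[is.na(occ)] <- 1
  b[is.na(b)] <- 30
  miss <- el == ""
  el[miss] <- .guess_element(name[miss])
  if (any(altloc != "" & occ < 1)) {
    stop("partial-occupancy altloc records found in ", path,
         "; supply single-conformation models")
  }
  conformer(data.frame(element = el, name = name, x = x, y = y, z = z,
                       occ = occ, b = b, resi = resi, resn = resn,
                       chain = chain, stringsAsFactors = FALSE),
            label = sub("\\.pdb$", "", basename(path)))
}

.pdb_atom_name_field <- function(name, element) {
  # Standard alignment: 1-letter elements start in column 14 unless the name
  # has 4 characters.
  if (nchar(name) > 4) stop("atom name longer than 4 characters: ", name)
  if (nchar(name) == 4 || nchar(element) == 2) {
    formatC(name, width = -4)
  } else {
    paste0(" ", formatC(name, width = -3))
  }
}

#' Write a conformer as a PDB file
#'
#' Fixed-column ATOM records: coordinates to 3 decimals, occupancy and
#' B-factor to 2 decimals.
#'
#' @param c A `conformer`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(c, path) {
  a <- c$atoms
  name_f <- vapply(seq_len(nrow(a)),
                   function(i) .pdb_atom_name_field(a$name[i], a$element[i]),
                   character(1))
  rec <- sprintf(
    "ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_f, " ", a$resn, a$chain, a$resi,
    a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rec, "END"), con)
  invisible(path)
}

# ---- Superposition and RMSD ------------------------------------------------

.select_idx <- function(c, selection) {
  if (is.null(selection)) seq_len(n_atoms(c))
  else which(c$atoms$name %in% selection)
}

#' Backbone atom names used by default in superposition/RMSD
#' @export
BACKBONE <- c("N", "CA", "C", "O")

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of `b` onto those of `a`.
#'
#' @param a,b Matched `conformer`s (same atom names/order on the selection).
#' @param selection Atom names to fit on; `NULL` for all atoms. Default
#'   backbone N, CA, C, O.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `b` maps onto `a` via `x %*% t(R) + t`, and `rmsd` (Angstrom).
#' @export
superpose <- function(a, b, selection = BACKBONE) {
  ia <- .select_idx(a, selection); ib <- .select_idx(b, selection)
  if (length(ia) != length(ib) ||
      !identical(a$atoms$name[ia], b$atoms$name[ib])) {
    stop("selections do not match between the two conformers")
  }
  P <- coords(b)[ib, , drop = FALSE]  # moving
  Q <- coords(a)[ia, , drop = FALSE]  # target
  if (nrow(P) < 3) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (qr(P0)$rank < 2) stop("selection is collinear; superposition ill-posed")
  s <- svd(crossprod(P0, Q0))        # H = P0' Q0 ; R = V D U' with det fix
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  Pfit <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((Pfit - Q)^2))))
}

#' Apply a rigid transform to a conformer
#' @param c A `conformer`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector.
#' @return Transformed `conformer`.
#' @export
transform_conformer <- function(c, rotation, translation = c(0, 0, 0)) {
  xyz <- coords(c) %*% t(rotation) +
    matrix(translation, n_atoms(c), 3, byrow = TRUE)
  set_coords(c, xyz)
}

#' Root-mean-square deviation between two conformers
#'
#' @param a,b Matched `conformer`s.
#' @param selection Atom names entering the calculation (default backbone).
#' @param fit If `TRUE` (default), best-fit RMSD after Kabsch superposition;
#'   otherwise direct coordinate RMSD in the given frames.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = BACKBONE, fit = TRUE) {
  if (fit) return(superpose(a, b, selection)$rmsd)
  ia <- .select_idx(a, selection); ib <- .select_idx(b, selection)
  if (length(ia) != length(ib) ||
      !identical(a$atoms$name[ia], b$atoms$name[ib])) {
    stop("selections do not match between the two conformers")
  }
  sqrt(mean(rowSums((coords(a)[ia, , drop = FALSE] -
                     coords(b)[ib, , drop = FALSE])^2)))
}
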