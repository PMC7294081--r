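#' Structure model from a PDB file
#'
#' Reads a PDB-format coordinate file (via `bio3d::read.pdb`) into a flat
#' atom table that preserves chymotrypsin-numbering insertion codes (e.g.
#' residue 60D). Alternate locations are reduced to the highest-occupancy
#' conformer per atom; duplicate atom keys after that reduction are an
#' error.
#'
#' @param path Path to a PDB file.
#' @param id Optional model identifier; defaults to the file name.
#' @return An object of class `"structure_model"`: a list with `atoms` (data
#'   frame with columns `type`, `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `x`, `y`, `z`, `o`, `b`, `elesy`) and `id`.
#' @export
read_structure <- function(path, id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- ""
  structure_model(a, id = if (is.null(id)) basename(path) else id)
}

#' @rdname read_structure
#' @param atoms Atom data frame as produced by `bio3d::read.pdb()$atom`
#'   (columns `type`, `chain`, `resno`, `insert`, `resid`, `elety`, `x`,
#'   `y`, `z`, `o`, `b` and optionally `elesy`).
#' @export
structure_model <- function(atoms, id = "model") {
  need <- c("type", "chain", "resno", "insert", "resid", "elety",
            "x", "y", "z", "o", "b")
  stopifnot(all(need %in% names(atoms)))
  if (!"elesy" %in% names(atoms)) atoms$elesy <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$elesy[is.na(atoms$elesy)] <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in model")
  # highest-occupancy conformer per (chain, resno, insert, elety)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  o <- atoms$o
  o[is.na(o)] <- 1
  ord <- order(key, -o)
  atoms <- atoms[ord, , drop = FALSE]
  dup <- duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                          atoms$elety, sep = "|"))
  atoms <- atoms[!dup, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d atoms, %d chains\n", x$id,
              nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

.water_names <- c("HOH", "WAT", "DOD")

# CA atoms of polymer residues (modified residues often come as HETATM,
# so selection is by atom name, excluding solvent)
.select_atoms <- function(m, selection) {
  a <- m$atoms
  a <- a[!(a$resid %in% .water_names), , drop = FALSE]
  if (selection == "calpha") {
    a <- a[a$elety == "CA" & a$elesy != "CA", , drop = FALSE]  # exclude calcium ions
  } else if (selection == "backbone") {
    a <- a[a$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  } else if (selection == "all") {
    a <- a[a$type == "ATOM" | a$resid %in% .trp_like_resids, , drop = FALSE]
  } else stop("unknown selection: ", selection)
  a
}

#' Optimal rigid-body superposition (Kabsch) of two models
#'
#' Pairs atoms between two models on the key (chain, residue number +
#' insertion code, atom name) restricted to an atom selection, computes the
#' least-squares optimal proper rotation and translation of `b` onto `a`
#' (SVD of the cross-covariance with reflection correction), and reports the
#' RMSD over the paired set.
#'
#' @param a,b [structure_model()] objects.
#' @param selection `"calpha"` (default; the conventional choice for
#'   whole-model comparisons), `"backbone"` (N, CA, C, O) or `"all"`
#'   (all polymer atoms). Waters and hetero ligands are always excluded.
#' @return A list of class `"superposition"`: `rmsd` (Angstrom),
#'   `n_atoms_used`, `rotation` (3x3, det = +1), `translation`,
#'   `selection`, and `unmatched` (residue keys present in only one model).
#' @examples
#' \dontrun{
#' s1 <- read_structure("6v5t.pdb")
#' s2 <- read_structure("3sqh.pdb")
#' kabsch_rmsd(s1, s2)$rmsd
#' }
#' @export
kabsch_rmsd <- function(a, b, selection = "calpha") {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  aa <- .select_atoms(a, selection)
  bb <- .select_atoms(b, selection)
  ka <- paste(aa$chain, aa$resno, aa$insert, aa$elety, sep = "|")
  kb <- paste(bb$chain, bb$resno, bb$insert, bb$elety, sep = "|")
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stop("fewer than 3 paired atoms; cannot superpose")
  P <- as.matrix(aa[match(common, ka), c("x", "y", "z")])
  Q <- as.matrix(bb[match(common, kb), c("x", "y", "z")])
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(Q0, P0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P0 - Qr)^2)))
  structure(list(rmsd = rmsd, n_atoms_used = length(common),
                 rotation = R, translation = cp - as.vector(R %*% cq),
                 selection = selection,
                 unmatched = list(only_a = setdiff(ka, kb),
                                  only_b = setdiff(kb, ka))),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition (%s): RMSD = %.3f Angstrom over %d atoms\n",
              x$selection, x$rmsd, x$n_atoms_used))
  nu <- length(x$unmatched$only_a) + length(x$unmatched$only_b)
  if (nu) cat(sprintf("  %d unmatched atoms\n", nu))
  invisible(x)
}

#' Active-site aperture distance
#'
#' The Calpha-Calpha distance between residues 193 and 216 (chymotrypsin
#' numbering), the aperture leading to the primary specificity pocket of
#' trypsin-fold proteases. Reference values for the two active-site
#' conformations are about 12 Angstrom in the open (E) form and 8.1 Angstrom
#' in the collapsed (E*) form; the model is tagged `"E-like"` at or above
#' the 10-Angstrom midpoint and `"E*-like"` below it.
#'
#' @param m A [structure_model()].
#' @param residues Length-2 integer vector of residue numbers (default
#'   `c(193, 216)`).
#' @param chain Optional chain id; by default the first chain containing
#'   both residues.
#' @return A list of class `"aperture"`: `distance` (Angstrom), `class`
#'   (`"E-like"` or `"E*-like"`), `chain`.
#' @export
aperture_distance <- function(m, residues = c(193, 216), chain = NULL) {
  stopifnot(inherits(m, "structure_model"), length(residues) == 2L)
  a <- m$atoms
  ca <- a[a$elety == "CA" & a$insert == "", , drop = FALSE]
  chains <- if (is.null(chain)) unique(ca$chain) else chain
  for (ch in chains) {
    i1 <- which(ca$chain == ch & ca$resno == residues[1])
    i2 <- which(ca$chain == ch & ca$resno == residues[2])
    if (length(i1) >= 1L && length(i2) >= 1L) {
      p1 <- as.numeric(ca[i1[1], c("x", "y", "z")])
      p2 <- as.numeric(ca[i2[1], c("x", "y", "z")])
      d <- sqrt(sum((p1 - p2)^2))
      return(structure(list(distance = d,
                            class = if (d >= 10) "E-like" else "E*-like",
                            chain = ch),
                       class = "aperture"))
    }
  }
  stop(sprintf("Calpha atoms of residues %d and %d not found%s",
               residues[1], residues[2],
               if (is.null(chain)) "" else paste0(" in chain ", chain)))
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf("Active-site aperture: %.2f Angstrom (%s, chain %s)\n",
              x$distance, x$class, x$chain))
  invisible(x)
}

# residue names commonly used for 5-fluoro-Trp in depositions
.trp_like_resids <- c("TRP", "FTR", "FT6", "4FW", "TRF", "F7W")

# canonical nine Trp positions of the thrombin fold (chymotrypsin numbering)
.trp_positions <- data.frame(
  resno = c(29L, 51L, 60L, 96L, 141L, 148L, 207L, 215L, 237L),
  insert = c("", "", "D", "", "", "", "", "", ""),
  stringsAsFactors = FALSE)

#' Trp positions probed by 5-fluoro labeling
#'
#' @return Data frame of the nine Trp positions (chymotrypsin numbering,
#'   insertion code for 60d) carrying the 19F reporters.
#' @export
trp_positions <- function() .trp_positions

#' Verify 5-fluoro-Trp labeling in a structure
#'
#' Checks each of the nine canonical Trp positions for (i) a Trp-derived
#' residue (any of TRP, FTR, FT6, 4FW, TRF, F7W — deposition naming for
#' 5-fluoro-Trp varies) and (ii) a fluorine atom on the indole: element
#' symbol `F`, or an atom name beginning with `F` that is not a standard
#' indole carbon/nitrogen name.
#'
#' @param m A [structure_model()].
#' @param chain Optional chain id restriction.
#' @return A data frame with one row per Trp position found: `residue`
#'   (e.g. `"Trp60d"`), `chain`, `resid`, `labeled` (logical), `f_atom`
#'   (atom name or `NA`). Attribute `n_labeled` gives the summary count.
#'   A model with no Trp-like residues yields zero rows.
#' @export
verify_fluoro_labels <- function(m, chain = NULL) {
  stopifnot(inherits(m, "structure_model"))
  a <- m$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(.trp_positions))) {
    rn <- .trp_positions$resno[k]
    ic <- .trp_positions$insert[k]
    res <- a[a$resno == rn & a$insert == ic &
               a$resid %in% .trp_like_resids, , drop = FALSE]
    if (nrow(res) == 0L) next
    for (ch in unique(res$chain)) {
      rr <- res[res$chain == ch, , drop = FALSE]
      is_f <- toupper(rr$elesy) == "F" |
        (grepl("^F", rr$elety) & !rr$elety %in% c("FE"))
      f_atom <- if (any(is_f)) rr$elety[which(is_f)[1]] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        residue = paste0("Trp", rn, tolower(ic)),
        chain = ch, resid = rr$resid[1],
        labeled = any(is_f), f_atom = f_atom)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(0), chain = character(0),
               resid = character(0), labeled = logical(0),
               f_atom = character(0))
  attr(out, "n_labeled") <- sum(out$labeled)
  out
}
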