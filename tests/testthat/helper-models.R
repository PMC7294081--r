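# Builders for small structure models and PDB-format fixture files.
# Everything here is synthetic and generated in code at test time.

# flat CA-only model from a coordinate matrix
make_ca_model <- function(xyz, resno = seq_len(nrow(xyz)), insert = "",
                          resid = "GLY", chain = "A", id = "toy") {
  structure_model(data.frame(
    type = "ATOM", chain = chain, resno = resno,
    insert = rep_len(insert, nrow(xyz)), resid = rep_len(resid, nrow(xyz)),
    elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, elesy = "C"), id = id)
}

# apply a rigid transform (rotation about z by theta, then translation)
rigid_transform <- function(m, theta = 0.7, shift = c(3, -2, 1)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  a <- m$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  structure_model(a, id = paste0(m$id, "-moved"))
}

# PDB-format line (fixed columns incl. altloc, insertion code, element)
pdb_line <- function(serial, name, alt, resn, chain, resno, icode,
                     x, y, z, occ = 1, b = 0, elem = "C",
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, icode,
          x, y, z, occ, b, elem)
}

# synthetic 5-F-Trp residue: minimal indole-like atom set with a fluorine
trp_res_lines <- function(serial0, resno, icode, origin, with_f = TRUE,
                          resn = "FTR", chain = "A") {
  at <- list(c("N", "N"), c("CA", "C"), c("CB", "C"), c("CD1", "C"),
             c("CE3", "C"), c("CZ3", "C"))
  if (with_f) at <- c(at, list(c("F5", "F")))
  lines <- character(0)
  for (i in seq_along(at)) {
    lines <- c(lines, pdb_line(serial0 + i - 1L, at[[i]][1], "", resn,
                               chain, resno, icode,
                               origin[1] + i, origin[2], origin[3],
                               elem = at[[i]][2], record = "HETATM"))
  }
  lines
}

# write a synthetic labeled-protein PDB file; returns its path.
# Contains: Gly backbone incl. residues 193/216 CA, nine 5-F-Trp residues
# (with 60D insertion code), one altloc pair, and a water.
write_toy_pdb <- function(path = tempfile(fileext = ".pdb"),
                          drop_f_at = NULL, aperture = 10,
                          n_trp = 9L) {
  trp <- trp_positions()[seq_len(n_trp), , drop = FALSE]
  lines <- character(0)
  serial <- 1L
  # scaffold Gly CA trace, incl. the two aperture residues
  gly <- c(10L, 100L, 193L, 216L, 230L)
  for (i in seq_along(gly)) {
    ap <- gly[i] %in% c(193L, 216L)
    lines <- c(lines, pdb_line(serial, "CA", "", "GLY", "A", gly[i], "",
                               if (ap) 50 else i * 7,
                               if (ap) 0 else i * 3,
                               if (gly[i] == 216L) aperture else 0))
    serial <- serial + 1L
  }
  # altloc pair on residue 10 CB: B conformer has higher occupancy
  lines <- c(lines,
             pdb_line(serial, "CB", "A", "GLY", "A", 10L, "", 1, 1, 1, occ = 0.4),
             pdb_line(serial + 1L, "CB", "B", "GLY", "A", 10L, "", 2, 2, 2, occ = 0.6))
  serial <- serial + 2L
  # the nine Trp reporters
  for (k in seq_len(nrow(trp))) {
    rn <- trp$resno[k]; ic <- trp$insert[k]
    tag <- paste0("Trp", rn, tolower(ic))
    with_f <- !(tag %in% drop_f_at)
    lines <- c(lines, trp_res_lines(serial, rn, ic, c(k * 10, -20, 5),
                                    with_f = with_f))
    serial <- serial + if (with_f) 7L else 6L
  }
  lines <- c(lines, pdb_line(serial, "O", "", "HOH", "A", 900L, "",
                             99, 99, 99, elem = "O", record = "HETATM"),
             "END")
  writeLines(lines, path)
  path
}

# brute-force rigid superposition oracle, independent of the SVD route
# under test: optimal translation is centroid matching (provable by setting
# the gradient in the translation to zero), so center both sets and minimize
# over Euler angles from many wide starts
brute_force_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Qm <- Q0 %*% t(Rx %*% Ry %*% Rz)
    sqrt(mean(rowSums((P0 - Qm)^2)))
  }
  best <- Inf
  set.seed(101)
  starts <- rbind(matrix(stats::runif(3 * 30, -pi, pi), ncol = 3), 0)
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(starts[s, ], obj, method = "BFGS",
                      control = list(maxit = 1000))
    best <- min(best, r$value)
  }
  best
}
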