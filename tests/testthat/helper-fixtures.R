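# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no binary data.

# -- minimal PDB texts ------------------------------------------------------

ala_pdb_text <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       3.216   1.620   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
  "TER", "END")

two_model_pdb_text <- function() c(
  "MODEL        1",
  "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ENDMDL",
  "MODEL        2",
  "ATOM      1  CA  GLY A   1       5.000   5.000   5.000  1.00  0.00           C",
  "ENDMDL",
  "END")

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# -- programmatic structures ------------------------------------------------

# structure from compact atom spec: list(chain, resno, resname, atom, x, y, z)
make_structure <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), resname = r[[3]],
               atom = r[[4]], element = substr(gsub("^[0-9]*", "", r[[4]]), 1, 1),
               x = r[[5]], y = r[[6]], z = r[[7]], stringsAsFactors = FALSE)))
  Structure(df)
}

# two-chain Lys/Glu pair with NZ-OE1 at the requested distance
salt_pair_structure <- function(nz_oe1_dist) {
  make_structure(
    list("A", 1, "LYS", "N",  -8, 0, 0), list("A", 1, "LYS", "CA", -7, 0, 0),
    list("A", 1, "LYS", "C",  -7, 1.4, 0), list("A", 1, "LYS", "O", -7, 2.6, 0),
    list("A", 1, "LYS", "CB", -5.6, 0, 0), list("A", 1, "LYS", "NZ", -nz_oe1_dist / 2, 0, 0),
    list("B", 2, "GLU", "N",   8, 0, 0), list("B", 2, "GLU", "CA",  7, 0, 0),
    list("B", 2, "GLU", "C",   7, 1.4, 0), list("B", 2, "GLU", "O",  7, 2.6, 0),
    list("B", 2, "GLU", "CB",  5.6, 0, 0), list("B", 2, "GLU", "OE1", nz_oe1_dist / 2, 0, 0))
}

# backbone N(A)...O=C(B) hydrogen-bond geometry: distance d, donor angle ang
hbond_pair_structure <- function(d, ang_deg) {
  # donor N at origin, antecedent CA placed so that the CA-N...O angle = ang
  a <- ang_deg * pi / 180
  make_structure(
    list("A", 1, "GLY", "CA", cos(a) * 1.46, sin(a) * 1.46, 0),
    list("A", 1, "GLY", "N", 0, 0, 0),
    list("B", 2, "GLY", "C", d + 1.23, 0, 0),
    list("B", 2, "GLY", "O", d, 0, 0),
    list("B", 2, "GLY", "CA", d + 2.2, 1.1, 0))
}

# -- independent oracles ----------------------------------------------------

# direct spatial correlation C(t) = sum_x R(x) L(x - t) over all offsets
brute_correlation <- function(R, L) {
  dR <- dim(R); dL <- dim(L)
  offs <- lapply(1:3, function(ax) (-(dL[ax] - 1)):(dR[ax] - 1))
  out <- array(0, lengths(offs))
  for (i1 in seq_along(offs[[1]])) for (i2 in seq_along(offs[[2]]))
    for (i3 in seq_along(offs[[3]])) {
      t <- c(offs[[1]][i1], offs[[2]][i2], offs[[3]][i3])
      lo <- pmax(1, 1 + t); hi <- pmin(dR, dL + t)
      s <- 0
      if (all(lo <= hi)) {
        xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
        s <- sum(R[xr, yr, zr] * L[xr - t[1], yr - t[2], zr - t[3]])
      }
      out[i1, i2, i3] <- s
    }
  list(values = out, offsets = offs)
}

# O(n^2) residue-contact scan under the heavy-atom-min or CB-CB rule
brute_contacts <- function(structure, side1, side2, metric, cutoff) {
  a <- atomTable(structure)
  if (metric == "CB-CB") {
    keep <- a$atom == "CB" | (a$atom == "CA" &
      !(paste(a$chain, a$resno) %in% paste(a$chain, a$resno)[a$atom == "CB"]))
    a <- a[keep, , drop = FALSE]
  }
  a1 <- a[a$chain %in% side1, , drop = FALSE]
  a2 <- a[a$chain %in% side2, , drop = FALSE]
  k1 <- unique(paste(a1$chain, a1$resno)); k2 <- unique(paste(a2$chain, a2$resno))
  n <- 0
  for (r1 in k1) for (r2 in k2) {
    x1 <- as.matrix(a1[paste(a1$chain, a1$resno) == r1, c("x", "y", "z")])
    x2 <- as.matrix(a2[paste(a2$chain, a2$resno) == r2, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)))
    if (dmin <= cutoff) n <- n + 1
  }
  n
}

# O(n^2) salt-bridge scan: opposite formal charges across chains within cutoff
brute_salt_bridges <- function(structure, side1, side2, cutoff = 4.0) {
  a <- atomTable(structure)
  chg <- coilDock:::.atom_charge_signs(a)
  res <- character()
  for (i in which(chg != "0" & a$chain %in% side1))
    for (j in which(chg != "0" & a$chain %in% side2)) {
      if (chg[i] == chg[j]) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
      if (d <= cutoff)
        res <- c(res, paste(a$chain[i], a$resno[i], a$chain[j], a$resno[j]))
    }
  unique(res)
}

# O(n^2) hydrogen-bond count with independently coded typing and geometry
brute_hbonds <- function(structure, side1, side2, max_dist = 3.9,
                         min_angle = 90) {
  a <- atomTable(structure)
  is_donor <- function(i) {
    rn <- a$resname[i]; at <- a$atom[i]
    at == "N" ||
      (rn == "ARG" && at %in% c("NE", "NH1", "NH2")) ||
      (rn == "LYS" && at == "NZ") || (rn == "ASN" && at == "ND2") ||
      (rn == "GLN" && at == "NE2") || (rn == "HIS" && at %in% c("ND1", "NE2")) ||
      (rn == "TRP" && at == "NE1") || (rn == "SER" && at == "OG") ||
      (rn == "THR" && at == "OG1") || (rn == "TYR" && at == "OH")
  }
  is_acceptor <- function(i)
    a$element[i] == "O" || (a$resname[i] == "HIS" && a$atom[i] %in% c("ND1", "NE2"))
  xyz <- coords(structure)
  n_bonds <- 0
  for (i in seq_len(nrow(a))) {
    if (!is_donor(i)) next
    # antecedent: closest heavy atom of the same residue within 2 A
    same <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                    seq_len(nrow(a)) != i)
    if (!length(same)) next
    dsame <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2))
    if (min(dsame) >= 2.0) next
    ante <- xyz[same[which.min(dsame)], ]
    other <- if (a$chain[i] %in% side1) side2 else if (a$chain[i] %in% side2)
      side1 else next
    for (j in which(a$chain %in% other)) {
      if (!is_acceptor(j)) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > max_dist || d < 1e-6) next
      v1 <- ante - xyz[i, ]; v2 <- xyz[j, ] - xyz[i, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= min_angle) n_bonds <- n_bonds + 1
    }
  }
  n_bonds
}

# random two-chain complexes with charged/polar residues for oracle equality
random_charged_complex <- function(seed, n_per_chain = 6) {
  withr::with_seed(seed, {
    resn <- sample(c("LYS", "ARG", "GLU", "ASP", "HIS", "SER", "ALA"),
                   2 * n_per_chain, replace = TRUE)
    rows <- list()
    for (i in seq_len(2 * n_per_chain)) {
      ch <- if (i <= n_per_chain) "A" else "B"
      base <- c(stats::runif(1, -8, 8), stats::runif(1, -8, 8),
                stats::runif(1, -8, 8))
      if (ch == "B") base[1] <- base[1] + 6
      rn <- resn[i]
      rows[[length(rows) + 1]] <- list(ch, i, rn, "CA", base[1], base[2], base[3])
      extra <- switch(rn,
        LYS = "NZ", ARG = "NH1", GLU = "OE1", ASP = "OD2", HIS = "ND1", NULL)
      if (!is.null(extra))
        rows[[length(rows) + 1]] <- list(ch, i, rn, extra,
                                         base[1] + stats::runif(1, -3, 3),
                                         base[2] + stats::runif(1, -3, 3),
                                         base[3] + stats::runif(1, -3, 3))
    }
    do.call(make_structure, rows)
  })
}

# in-groove predicate for docking fixtures (slab top at z = 14, floor z = 6)
pose_in_groove <- function(rod, pose, center, groove_width) {
  ctr <- colMeans(coords(poseTransform(rod, pose, center)))
  abs(ctr[2]) < groove_width / 2 && ctr[3] > 6 && ctr[3] < 15
}

rod_axis_angle <- function(pose) {
  Rm <- coilDock:::.matrix_from_quat(c(pose$qw, pose$qx, pose$qy, pose$qz))
  acos(min(abs((Rm %*% c(1, 0, 0))[1]), 1)) * 180 / pi
}
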