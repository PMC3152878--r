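## Grid-based rigid-body docking by FFT shape complementarity
## (surface/interior encoding), with deterministic rotation sampling and
## declarative biological restraints.

#' Discretize a structure onto a cubic grid
#'
#' Cells within any atom's van der Waals radius become molecule cells; those
#' within `surface_thickness` of open space form the surface layer (value 1)
#' and the remaining interior cells get `interior_value` (receptor convention
#' -15; call with `interior_value = 1` for the ligand).
#'
#' @param structure A [Structure-class].
#' @param spacing Cell edge in A (> 0; default 1.5).
#' @param surface_thickness Surface layer thickness in A (default 1.5).
#' @param interior_value Value assigned to interior cells (default -15).
#' @param padding Extra empty border in A (default `2 * spacing`).
#' @return A [DockGrid-class].
#' @export
discretizeStructure <- function(structure, spacing = 1.5,
                                surface_thickness = 1.5,
                                interior_value = -15, padding = NULL) {
  if (spacing <= 0) stop("parameter error: spacing must be > 0")
  if (nAtoms(structure) == 0) stop("all-zero grid: empty structure selection")
  if (is.null(padding)) padding <- 2 * spacing
  xyz <- coords(structure)
  rad <- vdwRadius(atomTable(structure)$element)
  lo <- apply(xyz, 2, min) - max(rad) - padding
  hi <- apply(xyz, 2, max) + max(rad) + padding
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  occ <- array(FALSE, dims)
  for (k in seq_len(nrow(xyz))) {
    ctr <- (xyz[k, ] - lo) / spacing + 1
    r_c <- rad[k] / spacing
    i1 <- pmax(ceiling(ctr - r_c), 1); i2 <- pmin(floor(ctr + r_c), dims)
    if (any(i1 > i2)) next
    ix <- i1[1]:i2[1]; iy <- i1[2]:i2[2]; iz <- i1[3]:i2[3]
    dx2 <- (ix - ctr[1])^2; dy2 <- (iy - ctr[2])^2; dz2 <- (iz - ctr[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r_c^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | as.vector(inside)
  }
  ## surface: molecule cells with open space within surface_thickness
  t_c <- ceiling(surface_thickness / spacing)
  open_near <- array(FALSE, dims)
  shift <- function(m, off) {
    d <- dim(m); out <- array(FALSE, d)
    src <- lapply(1:3, function(ax) {
      idx <- seq_len(d[ax]) - off[ax]
      idx
    })
    valid <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
    out[valid[[1]], valid[[2]], valid[[3]]] <-
      m[src[[1]][valid[[1]]], src[[2]][valid[[2]]], src[[3]][valid[[3]]]]
    out
  }
  open <- !occ
  for (ox in -t_c:t_c) for (oy in -t_c:t_c) for (oz in -t_c:t_c) {
    if (sqrt(ox^2 + oy^2 + oz^2) * spacing > surface_thickness + 1e-9) next
    open_near <- open_near | shift(open, c(ox, oy, oz))
  }
  vals <- array(0, dims)
  vals[occ & open_near] <- 1
  vals[occ & !open_near] <- interior_value
  methods::new("DockGrid", spacing = spacing, origin = lo, values = vals)
}

#' FFT translation scan of two docking grids
#'
#' Computes the correlation `C(t) = sum_x R(x) L(x - t)` over all lattice
#' offsets `t` by zero-padded forward/inverse FFT; identical (to numerical
#' precision) to direct spatial correlation.
#'
#' @param receptor_grid,ligand_grid [DockGrid-class] objects with equal
#'   spacing.
#' @param pad_dims Optional fixed padded lattice dimensions (each must be at
#'   least `dim(R) + dim(L) - 1`); useful to reuse sizes across rotations.
#' @return List with `values` (3-D array of scores indexed by offset),
#'   `offsets` (per-axis integer offset vectors, ligand-grid cells relative to
#'   receptor-grid cells) and `spacing`.
#' @export
fftTranslationScan <- function(receptor_grid, ligand_grid, pad_dims = NULL) {
  if (abs(receptor_grid@spacing - ligand_grid@spacing) > 1e-9)
    stop("grid error: mismatched spacing")
  R <- receptor_grid@values; L <- ligand_grid@values
  dR <- dim(R); dL <- dim(L)
  need <- dR + dL - 1L
  if (is.null(pad_dims))
    pad_dims <- vapply(need, function(n) stats::nextn(n, c(2, 3, 5)), 0L)
  if (any(pad_dims < need)) stop("pad_dims too small for linear correlation")
  Rp <- array(0, pad_dims); Rp[seq_len(dR[1]), seq_len(dR[2]), seq_len(dR[3])] <- R
  Lp <- array(0, pad_dims); Lp[seq_len(dL[1]), seq_len(dL[2]), seq_len(dL[3])] <- L
  cc <- Re(stats::fft(stats::fft(Rp) * Conj(stats::fft(Lp)), inverse = TRUE)) /
    prod(pad_dims)
  ## circular index -> signed offset, reordered ascending
  offs <- lapply(1:3, function(ax) (-(dL[ax] - 1)):(dR[ax] - 1))
  idx <- lapply(1:3, function(ax) (offs[[ax]] %% pad_dims[ax]) + 1L)
  list(values = cc[idx[[1]], idx[[2]], idx[[3]]], offsets = offs,
       spacing = receptor_grid@spacing)
}

## deterministic ZYZ Euler lattice on SO(3). Near-duplicate orientations are
## pruned: at the gimbal poles (beta = 0/180) only alpha + gamma matters, and
## near the poles the alpha count is scaled by sin(beta) (neighbouring alpha
## values there differ by much less than the nominal step).
.rotation_grid <- function(angular_step) {
  stopifnot(angular_step > 0)
  n_full <- max(1L, ceiling(360 / angular_step))
  betas <- seq(0, 180, by = angular_step)
  rot_list <- list(); ang <- NULL
  rz <- function(a) { a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) }
  ry <- function(b) { b <- b * pi / 180
    matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3) }
  for (b in betas) {
    if (b %in% c(0, 180)) {
      alphas <- seq(0, 360, length.out = n_full + 1L)[seq_len(n_full)]
      gammas <- 0
    } else {
      n_a <- max(1L, ceiling(n_full * sin(b * pi / 180)))
      alphas <- seq(0, 360, length.out = n_a + 1L)[seq_len(n_a)]
      gammas <- seq(0, 360, length.out = n_full + 1L)[seq_len(n_full)]
    }
    for (al in alphas) for (g in gammas) {
      rot_list[[length(rot_list) + 1L]] <- rz(al) %*% ry(b) %*% rz(g)
      ang <- rbind(ang, c(al, b, g))
    }
  }
  list(matrices = rot_list,
       angles = data.frame(alpha = ang[, 1], beta = ang[, 2], gamma = ang[, 3]))
}

.quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

.matrix_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Generate rigid-body docking poses
#'
#' Scans a deterministic Euler-angle lattice on SO(3) (no randomness
#' anywhere); for each rotation of the ligand about its centroid the best
#' `per_rotation_keep` translations by FFT shape complementarity are retained,
#' and the global top `keep_top` poses are returned sorted by complementarity
#' score, ties broken by rotation index.
#'
#' @param receptor,ligand [Structure-class] objects.
#' @param angular_step Euler-angle step in degrees (default 15).
#' @param spacing Grid spacing in A (default 1.5).
#' @param keep_top Number of poses to return (default 10000).
#' @param per_rotation_keep Best translations kept per rotation (default 3).
#' @param surface_thickness Surface layer thickness in A (default `spacing`).
#' @param interior_value Receptor interior penalty (default -15).
#' @return Data frame of poses (`rotation` index, Euler angles, quaternion,
#'   translation `tx/ty/tz` in A, `score`), with attributes `ligand_center`
#'   (rotation center) and `spacing`. Apply a pose with [poseTransform()].
#' @export
generatePoses <- function(receptor, ligand, angular_step = 15, spacing = 1.5,
                          keep_top = 10000L, per_rotation_keep = 3L,
                          surface_thickness = NULL, interior_value = -15) {
  stopifnot(keep_top >= 1)
  if (is.null(surface_thickness)) surface_thickness <- spacing
  rg <- discretizeStructure(receptor, spacing, surface_thickness,
                            interior_value = interior_value)
  rot <- .rotation_grid(angular_step)
  n_rot <- length(rot$matrices)
  ctr <- colMeans(coords(ligand))
  ## fixed padded dims: receptor grid + worst-case rotated ligand extent
  lig_reach <- max(sqrt(rowSums(sweep(coords(ligand), 2, ctr)^2))) +
    max(vdwRadius(atomTable(ligand)$element))
  lig_cells <- ceiling(2 * lig_reach / spacing) + 3L
  pad_dims <- vapply(dim(rg@values) + lig_cells,
                     function(n) stats::nextn(n, c(2, 3, 5)), 0L)
  fR <- stats::fft(.embed_grid(rg@values, pad_dims))
  res <- vector("list", n_rot)
  for (r in seq_len(n_rot)) {
    Rm <- rot$matrices[[r]]
    lig_r <- transformStructure(ligand, rotation = Rm,
                                translation = ctr - as.vector(Rm %*% ctr))
    lg <- discretizeStructure(lig_r, spacing, surface_thickness,
                              interior_value = 1, padding = 0)
    dL <- dim(lg@values)
    if (any(dL + dim(rg@values) - 1L > pad_dims)) {
      ## enlarge once and redo the receptor transform (defensive; the reach
      ## bound normally prevents this)
      pad_dims <- vapply(dim(rg@values) + dL + 2L,
                         function(n) stats::nextn(n, c(2, 3, 5)), 0L)
      fR <- stats::fft(.embed_grid(rg@values, pad_dims))
    }
    fL <- stats::fft(.embed_grid(lg@values, pad_dims))
    cc <- Re(stats::fft(fR * Conj(fL), inverse = TRUE)) / prod(pad_dims)
    k <- min(per_rotation_keep, length(cc))
    top <- integer(k); top_score <- numeric(k)
    for (m in seq_len(k)) {               # iterated argmax beats a full sort
      top[m] <- which.max(cc)
      top_score[m] <- cc[top[m]]
      cc[top[m]] <- -Inf
    }
    t3 <- arrayInd(top, pad_dims) - 1L
    ## circular index -> signed offset (valid range -(dL-1) .. dR-1)
    for (ax in 1:3) {
      wrap <- t3[, ax] > dim(rg@values)[ax] - 1L
      t3[wrap, ax] <- t3[wrap, ax] - pad_dims[ax]
    }
    tvec <- sweep(t3 * spacing, 2, rg@origin - lg@origin, "+")
    q <- .quat_from_matrix(Rm)
    res[[r]] <- data.frame(rotation = r, alpha = rot$angles$alpha[r],
                           beta = rot$angles$beta[r], gamma = rot$angles$gamma[r],
                           qw = q[1], qx = q[2], qy = q[3], qz = q[4],
                           tx = tvec[, 1], ty = tvec[, 2], tz = tvec[, 3],
                           score = top_score)
  }
  poses <- do.call(rbind, res)
  ord <- order(-poses$score, poses$rotation)
  poses <- poses[ord[seq_len(min(keep_top, nrow(poses)))], , drop = FALSE]
  if (nrow(poses) < keep_top)
    warning("angular step too coarse: only ", nrow(poses), " poses generated")
  rownames(poses) <- NULL
  attr(poses, "ligand_center") <- ctr
  attr(poses, "spacing") <- spacing
  poses
}

.embed_grid <- function(vals, pad_dims) {
  out <- array(0, pad_dims)
  d <- dim(vals)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vals
  out
}

#' Apply a docking pose to the ligand
#'
#' @param ligand The ligand [Structure-class] given to [generatePoses()].
#' @param pose One row of the pose data frame.
#' @param ligand_center Rotation center (defaults to the `ligand_center`
#'   attribute if `pose` retains it, else the ligand centroid).
#' @return The transformed [Structure-class].
#' @export
poseTransform <- function(ligand, pose, ligand_center = NULL) {
  if (is.null(ligand_center)) {
    ligand_center <- attr(pose, "ligand_center")
    if (is.null(ligand_center)) ligand_center <- colMeans(coords(ligand))
  }
  Rm <- .matrix_from_quat(c(pose$qw, pose$qx, pose$qy, pose$qz))
  shift <- ligand_center - as.vector(Rm %*% ligand_center) +
    c(pose$tx, pose$ty, pose$tz)
  transformStructure(ligand, rotation = Rm, translation = shift)
}

## resolve "chain + residue numbers" selector to atom indices
.resolve_selector <- function(structure, chain, resno) {
  a <- atomTable(structure)
  sel <- a$chain %in% .split_csv(chain)
  if (!is.na(resno) && nzchar(as.character(resno)))
    sel <- sel & a$resno %in% as.integer(.split_csv(as.character(resno)))
  which(sel)
}

.split_csv <- function(x) trimws(strsplit(as.character(x), ",")[[1]])

#' Filter docking poses by biological restraints
#'
#' A pose passes a distance restraint iff the minimum heavy-atom distance
#' between the receptor and (transformed) ligand residue selections is at
#' most `max_dist`; it passes the coplanarity (membrane-orientation)
#' restraint iff the N-terminal main-chain atoms of all chains lie within one
#' slab of the declared thickness normal to the bundle axis. Only poses
#' passing all restraints are retained, order preserved.
#'
#' @param poses Pose data frame from [generatePoses()].
#' @param receptor,ligand The [Structure-class] objects that were docked.
#' @param restraints A [restraintSet()].
#' @param return_all Keep failing poses too (with their flags) when `TRUE`.
#' @return The filtered pose data frame with logical flag columns
#'   `pass_distance` and `pass_coplanarity`.
#' @export
applyRestraints <- function(poses, receptor, ligand, restraints,
                            return_all = FALSE) {
  dr <- restraints@distanceRestraints
  rec_sel <- lapply(seq_len(nrow(dr)), function(i)
    .resolve_selector(receptor, dr$receptor_chain[i], dr$receptor_resno[i]))
  lig_sel <- lapply(seq_len(nrow(dr)), function(i)
    .resolve_selector(ligand, dr$ligand_chain[i], dr$ligand_resno[i]))
  for (i in seq_len(nrow(dr)))
    if (!length(rec_sel[[i]]) || !length(lig_sel[[i]]))
      stop("restraint definition error: selector resolves to no atoms (row ", i, ")")
  rec_xyz <- coords(receptor)
  rec_nterm <- .nterm_atoms(receptor)
  lig_nterm <- .nterm_atoms(ligand)
  ctr <- attr(poses, "ligand_center")
  if (is.null(ctr)) ctr <- colMeans(coords(ligand))
  lig_xyz <- coords(ligand)
  axis <- restraints@axis
  pass_d <- rep(TRUE, nrow(poses)); pass_c <- rep(TRUE, nrow(poses))
  for (k in seq_len(nrow(poses))) {
    Rm <- .matrix_from_quat(c(poses$qw[k], poses$qx[k], poses$qy[k], poses$qz[k]))
    shift <- ctr - as.vector(Rm %*% ctr) + c(poses$tx[k], poses$ty[k], poses$tz[k])
    xt <- lig_xyz %*% t(Rm)
    xt <- sweep(xt, 2, -shift)
    for (i in seq_len(nrow(dr))) {
      dmin <- .min_cross_dist(rec_xyz[rec_sel[[i]], , drop = FALSE],
                              xt[lig_sel[[i]], , drop = FALSE])$d
      if (dmin > dr$max_dist[i]) { pass_d[k] <- FALSE; break }
    }
    if (!is.na(restraints@slabThickness)) {
      proj <- c(rec_xyz[rec_nterm, , drop = FALSE] %*% axis,
                xt[lig_nterm, , drop = FALSE] %*% axis)
      if (diff(range(proj)) > restraints@slabThickness) pass_c[k] <- FALSE
    }
  }
  out <- poses
  out$pass_distance <- pass_d
  out$pass_coplanarity <- pass_c
  if (!return_all) out <- out[pass_d & pass_c, , drop = FALSE]
  attr(out, "ligand_center") <- ctr
  attr(out, "spacing") <- attr(poses, "spacing")
  out
}

## index of the N-terminal main-chain atom (N, else first atom) of each chain
.nterm_atoms <- function(structure) {
  a <- atomTable(structure)
  vapply(chainIds(structure), function(ch) {
    idx <- which(a$chain == ch)
    first_res <- idx[a$resno[idx] == min(a$resno[idx])]
    nn <- first_res[a$atom[first_res] == "N"]
    if (length(nn)) nn[1] else first_res[1]
  }, 0L)
}

#' Write a pose manifest as TSV
#'
#' @param poses Pose data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePoseManifest <- function(poses, path) {
  utils::write.table(poses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
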