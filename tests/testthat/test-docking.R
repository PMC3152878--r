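test_that("discretization encodes surface and interior as declared", {
  one <- make_structure(list("A", 1, "GLY", "CA", 0, 0, 0))
  g <- discretizeStructure(one, spacing = 1.0, surface_thickness = 1.0,
                           interior_value = -15)
  occupied <- sum(g@values != 0)
  vol <- 4 / 3 * pi * 1.7^3
  expect_lt(abs(occupied - vol) / vol, 0.3)
  # a lone atom is all surface once the layer spans its radius
  g_thick <- discretizeStructure(one, spacing = 1.0, surface_thickness = 2.0,
                                 interior_value = -15)
  expect_true(all(g_thick@values %in% c(0, 1)))
  expect_error(discretizeStructure(one, spacing = -1), "spacing")
  # two far-apart atoms give two disconnected occupied blocks
  two <- make_structure(list("A", 1, "GLY", "CA", 0, 0, 0),
                        list("A", 2, "GLY", "CA", 20, 0, 0))
  g2 <- discretizeStructure(two, spacing = 1.0)
  occ_x <- which(apply(g2@values != 0, 1, any))
  expect_true(any(diff(occ_x) > 5))  # gap along x between the components
  # a buried interior appears for a dense block
  blk <- do.call(make_structure, lapply(1:27, function(i) {
    xyz <- arrayInd(i, c(3, 3, 3)) * 2.0
    list("A", i, "GLY", "CA", xyz[1], xyz[2], xyz[3])
  }))
  g3 <- discretizeStructure(blk, spacing = 1.0, surface_thickness = 1.0,
                            interior_value = -15)
  expect_true(any(g3@values == -15))
})

test_that("FFT translation scan equals brute-force correlation", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      dR <- if (seed %% 2) c(8, 8, 8) else c(12, 12, 12)
      R <- array(sample(c(-15, 0, 1), prod(dR), TRUE, c(.1, .6, .3)), dR)
      L <- array(sample(c(0, 1), prod(dR), TRUE), dR)
    })
    gR <- methods::new("DockGrid", spacing = 1, origin = c(0, 0, 0), values = R)
    gL <- methods::new("DockGrid", spacing = 1, origin = c(0, 0, 0), values = L)
    got <- fftTranslationScan(gR, gL)
    want <- brute_correlation(R, L)
    expect_equal(got$offsets, want$offsets)
    expect_lt(max(abs(got$values - want$values)) /
                max(1, max(abs(want$values))), 1e-6)
  }
  g1 <- methods::new("DockGrid", spacing = 1, origin = c(0, 0, 0),
                     values = array(1, c(2, 2, 2)))
  g2 <- methods::new("DockGrid", spacing = 2, origin = c(0, 0, 0),
                     values = array(1, c(2, 2, 2)))
  expect_error(fftTranslationScan(g1, g2), "mismatched spacing")
})

test_that("swapping receptor and ligand mirrors the correlation lattice", {
  withr::with_seed(42, {
    R <- array(stats::runif(8^3), c(8, 8, 8))
    L <- array(stats::runif(8^3), c(8, 8, 8))
  })
  gR <- methods::new("DockGrid", spacing = 1, origin = c(0, 0, 0), values = R)
  gL <- methods::new("DockGrid", spacing = 1, origin = c(0, 0, 0), values = L)
  ab <- fftTranslationScan(gR, gL)
  ba <- fftTranslationScan(gL, gR)
  # C_RL(t) = C_LR(-t)
  expect_equal(ab$values, ba$values[rev(seq_len(15)), rev(seq_len(15)),
                                    rev(seq_len(15))], tolerance = 1e-9)
})

test_that("pose generation is deterministic and prefix-stable", {
  rec <- makeGrooveReceptor(12, 8)
  rod <- makeRodLigand(18, 8)
  p1 <- generatePoses(rec, rod, angular_step = 60, spacing = 2, keep_top = 10)
  p2 <- generatePoses(rec, rod, angular_step = 60, spacing = 2, keep_top = 10)
  expect_identical(p1, p2)
  p20 <- generatePoses(rec, rod, angular_step = 60, spacing = 2, keep_top = 20)
  expect_equal(p20[seq_len(10), ], p1, ignore_attr = TRUE)
  expect_equal(nrow(generatePoses(rec, rod, angular_step = 60, spacing = 2,
                                  keep_top = 1)), 1L)
})

test_that("complementarity scores survive a joint rigid transform", {
  rec <- makeGrooveReceptor(12, 8)
  rod <- makeRodLigand(18, 8)
  p1 <- generatePoses(rec, rod, angular_step = 90, spacing = 2, keep_top = 1)
  shift <- c(13, -7, 5)   # pure translation keeps the lattice commensurate
  p2 <- generatePoses(transformStructure(rec, diag(3), shift),
                      transformStructure(rod, diag(3), shift),
                      angular_step = 90, spacing = 2, keep_top = 1)
  expect_equal(p2$score, p1$score, tolerance = 0.15 * abs(p1$score))
})

test_that("distance restraints pass at 5 A and fail at 7 A against a 6 A cutoff", {
  rec <- make_structure(list("R", 1, "GLY", "CA", 0, 0, 0),
                        list("R", 2, "GLY", "CA", 4, 0, 0))
  lig <- make_structure(list("L", 1, "GLY", "CA", 0, 0, 0))
  mk_pose <- function(tx) {
    p <- data.frame(rotation = 1L, alpha = 0, beta = 0, gamma = 0,
                    qw = 1, qx = 0, qy = 0, qz = 0,
                    tx = tx, ty = 0, tz = 0, score = 1)
    attr(p, "ligand_center") <- c(0, 0, 0)
    p
  }
  rs <- restraintSet(data.frame(receptor_chain = "R", receptor_resno = "1",
                                ligand_chain = "L", ligand_resno = "1",
                                max_dist = 6))
  expect_equal(nrow(applyRestraints(mk_pose(5), rec, lig, rs)), 1L)
  expect_equal(nrow(applyRestraints(mk_pose(7), rec, lig, rs)), 0L)
  # selector resolving to nothing is a definition error
  rs_bad <- restraintSet(data.frame(receptor_chain = "R", receptor_resno = "99",
                                    ligand_chain = "L", ligand_resno = "1",
                                    max_dist = 6))
  expect_error(applyRestraints(mk_pose(5), rec, lig, rs_bad),
               "restraint definition error")
})

test_that("coplanarity restraint rejects axial displacement of the N-termini", {
  rec <- make_structure(list("R", 1, "GLY", "N", 0, 0, 0),
                        list("R", 1, "GLY", "CA", 1.4, 0, 0))
  lig <- make_structure(list("L", 1, "GLY", "N", 5, 0, 0),
                        list("L", 1, "GLY", "CA", 6.4, 0, 0))
  mk_pose <- function(tz) {
    p <- data.frame(rotation = 1L, alpha = 0, beta = 0, gamma = 0,
                    qw = 1, qx = 0, qy = 0, qz = 0,
                    tx = 0, ty = 0, tz = tz, score = 1)
    attr(p, "ligand_center") <- c(0, 0, 0)
    p
  }
  rs <- restraintSet(slab_thickness = 8, axis = c(0, 0, 1))
  expect_equal(nrow(applyRestraints(mk_pose(0), rec, lig, rs)), 1L)
  expect_equal(nrow(applyRestraints(mk_pose(20), rec, lig, rs)), 0L)
})

test_that("restraint filtering is idempotent, order-preserving and a subset", {
  rec <- makeGrooveReceptor(12, 8)
  rod <- makeRodLigand(18, 8)
  poses <- generatePoses(rec, rod, angular_step = 60, spacing = 2,
                         keep_top = 30)
  rs <- restraintSet(data.frame(receptor_chain = "R", receptor_resno = "",
                                ligand_chain = "L", ligand_resno = "",
                                max_dist = 10))
  f1 <- applyRestraints(poses, rec, rod, rs)
  f2 <- applyRestraints(f1, rec, rod, rs)
  expect_equal(nrow(f1), nrow(f2))
  expect_lte(nrow(f1), nrow(poses))
  keys <- function(p) paste(p$rotation, p$tx, p$ty, p$tz)
  expect_true(all(keys(f1) %in% keys(poses)))
  # order preserved
  expect_equal(match(keys(f1), keys(poses)), sort(match(keys(f1), keys(poses))))
})

test_that("pose transform round-trips through quaternion encoding", {
  rod <- makeRodLigand(18, 8)
  poses <- generatePoses(makeGrooveReceptor(12, 8), rod, angular_step = 60,
                         spacing = 2, keep_top = 3)
  ctr <- attr(poses, "ligand_center")
  for (k in seq_len(nrow(poses))) {
    Rm <- coilDock:::.matrix_from_quat(unlist(poses[k, c("qw", "qx", "qy", "qz")]))
    expect_equal(det(Rm), 1, tolerance = 1e-9)
    expect_equal(crossprod(Rm), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    placed <- poseTransform(rod, poses[k, ], ctr)
    manual <- sweep(sweep(coords(rod), 2, ctr) %*% t(Rm), 2,
                    -ctr - unlist(poses[k, c("tx", "ty", "tz")]))
    expect_equal(coords(placed), manual, tolerance = 1e-9, ignore_attr = TRUE)
  }
})
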