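test_that("screened-Coulomb potential matches closed forms", {
  neg <- make_structure(list("A", 1, "GLU", "CA", -1.4, 0, 0),
                        list("A", 1, "GLU", "OE1", 0, 0, 0))
  phi <- coulombPotential(neg, matrix(c(5, 0, 0), 1), debye_length = 8)
  expect_equal(phi, -exp(-5 / 8) / 5, tolerance = 1e-4)
  # symmetric +/- pair cancels at the midpoint
  pair <- make_structure(list("A", 1, "GLU", "OE1", -3, 0, 0),
                         list("A", 1, "GLU", "CA", -3, 1.5, 0),
                         list("B", 2, "LYS", "NZ", 3, 0, 0),
                         list("B", 2, "LYS", "CA", 3, 1.5, 0))
  expect_lt(abs(coulombPotential(pair, matrix(0, 1, 3))), 1e-9)
  # neutral structure: identically zero
  neutral <- make_structure(list("A", 1, "ALA", "CA", 0, 0, 0),
                            list("A", 1, "ALA", "CB", 1.5, 0, 0))
  expect_equal(coulombPotential(neutral, matrix(1:6, 2)), c(0, 0))
})

test_that("the potential is linear in the charge set", {
  sA <- make_structure(list("A", 1, "GLU", "OE1", 0, 0, 0),
                       list("A", 1, "GLU", "CA", 0, 1.5, 0))
  sB <- make_structure(list("B", 1, "LYS", "NZ", 4, 2, 0),
                       list("B", 1, "LYS", "CA", 4, 3.5, 0))
  both <- combineStructures(sA, sB)
  pts <- rbind(c(10, 0, 0), c(0, 8, 2))
  expect_equal(coulombPotential(both, pts),
               coulombPotential(sA, pts) + coulombPotential(sB, pts),
               tolerance = 1e-12)
})

test_that("alanine scan reproduces a fresh-rescoring oracle per residue", {
  b <- makeBundle(2, 21, seed = 31)
  ts <- lapply(1:5, function(k) list(structure = makeBundle(2, 21, seed = 60 + k),
                                     partition = list("A", "B")))
  m <- derivePairPotential(ts, contactDefinition("CB-CB"))
  scan <- alanineScan(b, list("A", "B"), m)
  expect_true(all(diff(scan$ddg_proxy) <= 1e-12))  # sorted descending
  base_score <- scoreComplex(b, list("A", "B"), m)
  base_hb <- nrow(detectHBonds(b, list("A", "B")))
  base_sb <- nrow(detectSaltBridges(b, list("A", "B")))
  for (i in which(scan$scannable)[1:min(5, sum(scan$scannable))]) {
    key <- paste(scan$chain[i], scan$resno[i], "", sep = "|")
    mut <- coilDock:::.truncate_to_ala(b, key)
    want <- (base_score - scoreComplex(mut, list("A", "B"), m)) +
      (base_hb - nrow(detectHBonds(mut, list("A", "B")))) +
      (base_sb - nrow(detectSaltBridges(mut, list("A", "B"))))
    expect_equal(scan$ddg_proxy[i], want, tolerance = 1e-9)
  }
  # Gly/Ala are reported but not scanned
  ga <- scan[scan$resname %in% c("GLY", "ALA"), ]
  if (nrow(ga)) {
    expect_true(all(!ga$scannable))
    expect_true(all(ga$ddg_proxy == 0))
  }
})

test_that("residues without interchain contacts have zero ddG proxy", {
  # two chains interacting only through residue 1 of each
  s <- make_structure(
    list("A", 1, "GLU", "CA", 0, 0, 0), list("A", 1, "GLU", "CB", 0, 1.5, 0),
    list("A", 1, "GLU", "OE1", 0, 3.0, 0),
    list("A", 2, "SER", "CA", -30, 0, 0), list("A", 2, "SER", "CB", -30, 1.5, 0),
    list("B", 3, "LYS", "CA", 0, 7, 0), list("B", 3, "LYS", "CB", 0, 5.5, 0),
    list("B", 3, "LYS", "NZ", 0, 4.5, 0),
    list("B", 4, "SER", "CA", 30, 7, 0), list("B", 4, "SER", "CB", 30, 5.5, 0))
  ts <- makeTrainingSet(2, seed = 2, pairs_per_interface = 50)
  m <- derivePairPotential(ts, contactDefinition("CB-CB"))
  scan <- alanineScan(s, list("A", "B"), m)
  expect_false(2 %in% scan$resno)   # distant residue is not interface
  expect_false(4 %in% scan$resno)
  glu <- scan[scan$resno == 1, ]
  expect_equal(glu$lost_saltbridges, 1L)
  expect_equal(glu$primary_type, "SB")   # SB outranks HB and VW
})

test_that("charge patches cluster one helix face and respect sign and size", {
  # a straight helix with Glu at close positions clusters into one patch
  s <- strrep("AEAAEAA", 3)
  b <- buildBundle(bundleSpec(c(X = s, Y = strrep("AAASAAA", 3))))
  patches <- findChargePatches(b, "negative", linkage_distance = 12,
                               min_size = 3)
  expect_gte(length(patches), 1L)
  expect_true(all(sapply(patches, function(p) p$sign == "negative")))
  expect_gte(nrow(patches[[1]]$members), 3L)
  expect_lt(patches[[1]]$mean_potential, 0)
  # an uncharged bundle yields no patches
  s0 <- strrep("LAALASQ", 3)
  b0 <- buildBundle(bundleSpec(c(X = s0, Y = s0),
                               registers = rep(assignRegister(s0, 1), 2)))
  expect_length(findChargePatches(b0, "negative"), 0L)
  # opposite-sign patches never share residues
  bc <- makeChargedBundle(seed = 5)
  pn <- findChargePatches(bc, "negative")
  pp <- findChargePatches(bc, "positive")
  neg_res <- unlist(lapply(pn, function(p) paste(p$members$chain, p$members$resno)))
  pos_res <- unlist(lapply(pp, function(p) paste(p$members$chain, p$members$resno)))
  expect_length(intersect(neg_res, pos_res), 0L)
})

test_that("acidic sequence bands are recovered as the largest negative patch", {
  b <- makeChargedBundle(acidic_bands = list(A = c(50, 70), B = c(85, 95)),
                         seed = 3)
  patches <- findChargePatches(b, "negative", linkage_distance = 10,
                               min_size = 3)
  expect_gte(length(patches), 1L)
  top <- patches[[1]]$members
  in_band <- (top$chain == "A" & top$resno >= 50 & top$resno <= 70) |
    (top$chain == "B" & top$resno >= 85 & top$resno <= 95)
  expect_gt(mean(in_band), 0.8)
  # empty bands leave no large negative patch
  b0 <- makeChargedBundle(acidic_bands = list(), seed = 3)
  p0 <- findChargePatches(b0, "negative", linkage_distance = 10, min_size = 3)
  expect_lte(length(p0), length(patches))
})

test_that("patch detection is invariant under rigid transforms", {
  b <- makeChargedBundle(seed = 9)
  th <- 0.6
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b2 <- transformStructure(b, rot, c(5, 5, 5))
  p1 <- findChargePatches(b, "negative")
  p2 <- findChargePatches(b2, "negative")
  expect_equal(length(p1), length(p2))
  if (length(p1))
    expect_equal(nrow(p1[[1]]$members), nrow(p2[[1]]$members))
})
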