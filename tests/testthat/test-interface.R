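test_that("isolated-atom SASA matches the analytic sphere", {
  s <- make_structure(list("A", 1, "GLY", "N", 0, 0, 0))
  got <- sum(computeSASA(s))
  expect_lt(abs(got - 4 * pi * (1.55 + 1.4)^2) / (4 * pi * 2.95^2), 0.01)
})

test_that("SASA is additive for distant atoms and zero for caged atoms", {
  s2 <- make_structure(list("A", 1, "GLY", "N", 0, 0, 0),
                       list("A", 2, "GLY", "N", 50, 0, 0))
  one <- sum(computeSASA(make_structure(list("A", 1, "GLY", "N", 0, 0, 0))))
  expect_equal(sum(computeSASA(s2)), 2 * one, tolerance = 1e-9)
  # cage a central atom inside a tight shell of 26 carbons
  shell <- expand.grid(x = c(-1.9, 0, 1.9), y = c(-1.9, 0, 1.9),
                       z = c(-1.9, 0, 1.9))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  rows <- c(list(list("A", 1, "GLY", "CA", 0, 0, 0)),
            lapply(seq_len(nrow(shell)), function(i)
              list("A", i + 1, "GLY", "CA", shell$x[i], shell$y[i], shell$z[i])))
  caged <- do.call(make_structure, rows)
  expect_equal(computeSASA(caged)[1], 0)
})

test_that("interface area of separated chains is zero and symmetric otherwise", {
  b <- makeBundle(2, 21, seed = 3)
  far <- combineStructures(selectChains(b, "A"),
                           transformStructure(selectChains(b, "B"), diag(3),
                                              c(50, 0, 0)))
  ia <- interfaceArea(far, list("A", "B"))
  expect_lt(abs(ia$area), 0.5)
  ia2 <- interfaceArea(b, list("A", "B"))
  ia2r <- interfaceArea(b, list("B", "A"))
  expect_gt(ia2$area, 50)
  expect_equal(ia2$area, ia2r$area)
})

test_that("interface area equals the per-atom bookkeeping oracle", {
  b <- makeBundle(2, 21, seed = 6)
  ia <- interfaceArea(b, list("A", "B"))
  # oracle: recompute from per-atom values directly
  sA <- computeSASA(selectChains(b, "A"))
  sB <- computeSASA(selectChains(b, "B"))
  sC <- computeSASA(b)
  expect_equal(ia$area, (sum(sA) + sum(sB) - sum(sC)) / 2, tolerance = 1e-9)
  expect_equal(ia$percent, 100 * ia$area / sum(sC), tolerance = 1e-9)
})

test_that("homodimer sides bury equal area", {
  s <- strrep("LAALAEK", 3)
  b <- buildBundle(bundleSpec(c(X = s, X = s),
                              registers = rep(assignRegister(s, 1), 2)))
  d <- coilDock:::.residue_delta_asa(b, list("A", "B"))
  burA <- sum(d$delta_asa[d$chain == "A"])
  burB <- sum(d$delta_asa[d$chain == "B"])
  expect_lt(abs(burA - burB) / burA, 0.01)
})

test_that("interface residues respect the ASA threshold and include the core", {
  b <- makeBundle(2, 21, seed = 3)
  ir <- interfaceResidues(b, list("A", "B"), threshold = 1.0)
  # all register-a leucines of both chains are buried at the interface
  a <- atomTable(b)
  reg <- strsplit(structureMetadata(b)[["register_A"]], "")[[1]]
  a_pos <- which(reg == "a")
  for (ch in c("A", "B"))
    expect_true(all(a_pos %in% ir$resno[ir$chain == ch]))
  # monotone in threshold; absurd threshold empties the list
  expect_lte(nrow(interfaceResidues(b, list("A", "B"), threshold = 20)),
             nrow(ir))
  expect_equal(nrow(interfaceResidues(b, list("A", "B"), threshold = 1e6)), 0L)
  far <- combineStructures(selectChains(b, "A"),
                           transformStructure(selectChains(b, "B"), diag(3),
                                              c(50, 0, 0)))
  expect_equal(nrow(interfaceResidues(far, list("A", "B"))), 0L)
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  expect_equal(nrow(detectHBonds(hbond_pair_structure(2.9, 160),
                                 list("A", "B"))), 1L)
  expect_equal(nrow(detectHBonds(hbond_pair_structure(4.5, 160),
                                 list("A", "B"))), 0L)
  expect_equal(nrow(detectHBonds(hbond_pair_structure(3.0, 60),
                                 list("A", "B"))), 0L)
  # tightening the cutoff never adds bonds
  b <- makeBundle(2, 28, seed = 13)
  n39 <- nrow(detectHBonds(b, list("A", "B"), max_dist = 3.9))
  n30 <- nrow(detectHBonds(b, list("A", "B"), max_dist = 3.0))
  expect_lte(n30, n39)
})

test_that("salt-bridge detection distinguishes distance and sign", {
  expect_equal(nrow(detectSaltBridges(salt_pair_structure(3.5),
                                      list("A", "B"))), 1L)
  expect_equal(nrow(detectSaltBridges(salt_pair_structure(4.5),
                                      list("A", "B"))), 0L)
  same_sign <- make_structure(
    list("A", 1, "LYS", "CA", -2, 0, 0), list("A", 1, "LYS", "NZ", -1.5, 0, 0),
    list("B", 2, "ARG", "CA", 2.6, 0, 0), list("B", 2, "ARG", "NH1", 1.5, 0, 0))
  expect_equal(nrow(detectSaltBridges(same_sign, list("A", "B"))), 0L)
})

test_that("salt-bridge lists equal the brute-force scan on random complexes", {
  for (seed in 1:30) {
    s <- random_charged_complex(seed)
    got <- detectSaltBridges(s, list("A", "B"))
    want <- brute_salt_bridges(s, "A", "B")
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    canon <- function(c1, r1, c2, r2)
      ifelse(c1 < c2 | (c1 == c2 & r1 <= r2),
             paste(c1, r1, c2, r2), paste(c2, r2, c1, r1))
    if (nrow(got)) {
      wp <- do.call(rbind, strsplit(want, " "))
      expect_setequal(canon(got$pos_chain, got$pos_resno,
                            got$neg_chain, got$neg_resno),
                      canon(wp[, 1], as.integer(wp[, 2]),
                            wp[, 3], as.integer(wp[, 4])))
    }
  }
})

test_that("interface report assembles self-consistent fields", {
  b <- makeBundle(2, 28, seed = 17)
  rep <- interfaceReport(b, list("A", "B"))
  ia <- interfaceArea(b, list("A", "B"))
  expect_equal(rep@interfaceASA, ia$area, tolerance = 1e-9)
  hb <- detectHBonds(b, list("A", "B"))
  sb <- detectSaltBridges(b, list("A", "B"))
  expect_equal(rep@hbondsPer100A2, 100 * nrow(hb) / ia$area, tolerance = 1e-9)
  expect_equal(rep@saltBridgesPer100A2, 100 * nrow(sb) / ia$area,
               tolerance = 1e-9)
  expect_equal(sum(rep@interfaceComposition), 100, tolerance = 0.1)
  expect_equal(sum(rep@surfaceComposition), 100, tolerance = 0.1)
  # z is the long (bundle) axis after alignment
  expect_equal(which.max(rep@dimensions), 3L, ignore_attr = TRUE)
})

test_that("report metrics are invariant under rigid transforms", {
  b <- makeBundle(2, 21, seed = 19)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  b2 <- transformStructure(b, rot, c(7, 8, -9))
  r1 <- interfaceReport(b, list("A", "B"))
  r2 <- interfaceReport(b2, list("A", "B"))
  expect_equal(r2@interfaceASA, r1@interfaceASA,
               tolerance = 0.005)
  expect_identical(r2@counts, r1@counts)
  expect_equal(r2@dimensions, r1@dimensions, tolerance = 0.1)
})

test_that("an all-nonpolar interface reports 100 percent nonpolar", {
  s <- strrep("LALLALA", 3)
  b <- buildBundle(bundleSpec(c(X = s, X = s),
                              registers = rep(assignRegister(s, 1), 2)))
  rep <- interfaceReport(b, list("A", "B"))
  expect_equal(unname(rep@interfaceComposition["nonpolar"]), 100)
})

test_that("stability classification bands work as declared", {
  ref <- meanStableReference()
  mk_report <- function(pct, polar, nonpolar, charged, hb, sb) {
    methods::new("InterfaceReport", interfaceASA = 500,
                 interfaceASAPercent = pct,
                 interfaceComposition = c(polar = polar, nonpolar = nonpolar,
                                          charged = charged),
                 hbondsPer100A2 = hb, saltBridgesPer100A2 = sb,
                 surfaceComposition = c(polar = 30, nonpolar = 40, charged = 30),
                 interfaceResidues = data.frame(), dimensions = c(1, 1, 1),
                 counts = c(hbonds = 1, salt_bridges = 1), flags = character())
  }
  # equal to the reference -> consistent, zero deviations
  r_eq <- mk_report(11.2, 32.2, 39.5, 28.2, 1, 4)
  out <- classifyStability(r_eq, ref)
  expect_equal(out$verdict, "consistent")
  expect_true(all(out$fields$deviation == 0))
  # interface share far below the band flags that field
  r_low <- mk_report(6.1, 32.2, 39.5, 28.2, 1, 4)
  out2 <- classifyStability(r_low, ref)
  expect_false(out2$fields$within[out2$fields$field == "interface_asa_percent"])
  # empty interface is always inconsistent
  r_empty <- mk_report(0, 0, 0, 0, 0, 0)
  r_empty@interfaceASA <- 0
  r_empty@interfaceComposition <- c(polar = 0, nonpolar = 0, charged = 0)
  expect_equal(classifyStability(r_empty, ref)$verdict, "inconsistent")
})

test_that("removing a chain outside the partition leaves the report unchanged", {
  b <- makeBundle(3, 21, seed = 23)
  far <- transformStructure(selectChains(b, "C"), diag(3), c(80, 0, 0))
  with_extra <- combineStructures(selectChains(b, c("A", "B")), far)
  r_ab <- interfaceReport(selectChains(b, c("A", "B")), list("A", "B"))
  r_sub <- interfaceReport(with_extra, list("A", "B"))
  expect_equal(r_sub@interfaceASA, r_ab@interfaceASA)
  expect_identical(r_sub@counts, r_ab@counts)
})
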