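test_that("anchored register assignment fills cyclically and checks spacing", {
  expect_equal(assignRegister("LAAAAAALAAAAAAL", anchor_positions = 1),
               "abcdefgabcdefga")
  expect_error(assignRegister("LAAAAAALAAAAAAL", anchor_positions = c(1, 9)),
               "register conflict")
})

test_that("unanchored assignment picks the frame maximizing core hydrophobics", {
  seq1 <- "LAAAAAALAAAAAAL"
  # independent frame enumeration oracle
  aa <- strsplit(seq1, "")[[1]]
  counts <- sapply(0:6, function(k) {
    idx <- (seq_along(aa) - 1 + k) %% 7
    sum(aa %in% c("L", "I", "V", "M") & idx %in% c(0, 3))
  })
  best <- which.max(counts) - 1
  idx <- (seq_along(aa) - 1 + best) %% 7
  expect_equal(assignRegister(seq1), paste(letters[idx + 1], collapse = ""))
  expect_equal(assignRegister(seq1), assignRegister(seq1, anchor_positions = 1))
})

test_that("dimer geometry: axis separation 2*R0, axial length, CA-CA spacing", {
  n <- 28
  spec <- bundleSpec(c(X = strrep("LAALAEK", 4), Y = strrep("LAALAEK", 4)))
  b <- buildBundle(spec, CrickParams(superhelixRadius = 4.9,
                                     risePerResidue = 1.51))
  a <- atomTable(b)
  ca <- function(ch) as.matrix(a[a$atom == "CA" & a$chain == ch,
                                 c("x", "y", "z")])
  # chain-axis samples: running means over one full minor-helix period
  axis_pts <- function(m) t(sapply(1:(nrow(m) - 6), function(i)
    colMeans(m[i:(i + 6), ])))
  axA <- axis_pts(ca("A")); axB <- axis_pts(ca("B"))
  sep <- mean(sqrt(rowSums((axA - axB)[, 1:2]^2)))
  expect_lt(abs(sep - 2 * 4.9), 0.2)
  len <- diff(range(ca("A")[, 3]))
  expect_lt(abs(len - (n - 1) * 1.51), 1.5)
  dd <- sqrt(rowSums(diff(ca("A"))^2))
  expect_true(all(abs(dd - 3.8) < 0.1))
})

test_that("interchain CB contacts concentrate at register positions a and d", {
  b <- makeBundle(2, 28, seed = 11)
  a <- atomTable(b)
  cb <- function(ch) as.matrix(a[a$atom == "CB" & a$chain == ch,
                                 c("x", "y", "z")])
  cb1 <- cb("A"); cb2 <- cb("B")
  D <- sqrt(outer(rowSums(cb1^2), rowSums(cb2^2), "+") - 2 * cb1 %*% t(cb2))
  mind <- apply(D, 1, min)
  reg <- strsplit(structureMetadata(b)[["register_A"]], "")[[1]][
    seq_len(nrow(cb1))]
  mean_core <- mean(mind[reg %in% c("a", "d")])
  mean_rest <- mean(mind[!reg %in% c("a", "d")])
  expect_lt(mean_core, mean_rest)
  # the closest contacts should all be core positions
  expect_true(all(reg[order(mind)[1:4]] %in% c("a", "d")))
})

test_that("register periodicity: anchors a full heptad apart are equivalent", {
  s <- strrep("LAALAEK", 4)
  reg1 <- assignRegister(s, anchor_positions = 1)
  reg2 <- assignRegister(s, anchor_positions = 8)   # rotated by 7
  expect_identical(reg1, reg2)
  b1 <- buildBundle(bundleSpec(c(X = s, Y = s), registers = c(reg1, reg1)))
  b2 <- buildBundle(bundleSpec(c(X = s, Y = s), registers = c(reg2, reg2)))
  expect_equal(coords(b1), coords(b2), tolerance = 1e-9)
  # contrast: a one-position frame shift genuinely moves the atoms
  reg3 <- assignRegister(s, anchor_positions = 2)
  b3 <- buildBundle(bundleSpec(c(X = s, Y = s), registers = c(reg3, reg3)),
                    check_clash = FALSE)
  expect_gt(max(abs(coords(b3) - coords(b1))), 0.5)
})

test_that("bundles of identical chains are cyclically symmetric", {
  s <- strrep("LAALAEK", 4)
  reg <- assignRegister(s, anchor_positions = 1)
  b <- buildBundle(bundleSpec(c(X = s, X = s, X = s), registers = rep(reg, 3)))
  a <- atomTable(b)
  xyz <- function(ch) as.matrix(a[a$chain == ch, c("x", "y", "z")])
  # rotating chain A by 120 degrees about z must superpose onto chain B
  th <- 2 * pi / 3
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(max(abs(xyz("A") %*% t(rot) - xyz("B"))), 1e-6)
})

test_that("the supercoil is left-handed for negative pitch", {
  b <- makeBundle(2, 35, seed = 2)
  a <- atomTable(b)
  ca <- as.matrix(a[a$atom == "CA" & a$chain == "A", c("x", "y", "z")])
  # chain-axis samples: running means of 7 consecutive CA
  ax <- t(sapply(1:(nrow(ca) - 6), function(i) colMeans(ca[i:(i + 6), ])))
  phi <- atan2(ax[, 2], ax[, 1])
  dphi <- diff(phi)
  dphi[dphi > pi] <- dphi[dphi > pi] - 2 * pi
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  # left-handed: azimuth decreases as z increases
  expect_true(mean(dphi) < 0)
  expect_true(all(diff(ax[, 3]) > 0))
})

test_that("stoichiometry enumeration yields the four specs with pairing rules", {
  seqs <- syntheticPeriplasmicSequences()
  specs <- enumerateStoichiometries(c(FtsB = unname(seqs[1])),
                                    c(FtsL = unname(seqs[2])),
                                    start_A = 25, start_B = 61)
  expect_named(specs, c("1:1", "2:1", "1:2", "2:2"))
  expect_equal(unname(sapply(specs, function(s) length(s@chains))),
               c(2L, 3L, 3L, 4L))
  prots <- sapply(specs[["2:2"]]@chains, function(ch) ch$protein)
  expect_equal(prots, c("FtsB", "FtsL", "FtsB", "FtsL"))  # alternating
  expect_length(specs[["2:2"]]@pairing, 2L)
  # the GDHS motif of the FtsL-like chain becomes a break in the 2:2 spec only
  expect_equal(nrow(specs[["1:1"]]@breaks), 0L)
  expect_equal(nrow(specs[["2:2"]]@breaks), 2L)
  expect_true(all(specs[["2:2"]]@breaks$type == "turn"))
})

test_that("identical proteins collapse the enumeration to homomers", {
  s <- strrep("LAALAEK", 4)
  expect_warning(specs <- enumerateStoichiometries(c(X = s), c(X = s)),
                 "identical")
  expect_equal(unname(sapply(specs, function(sp) length(sp@chains))),
               c(2L, 3L, 4L))
})

test_that("all four enumerated stoichiometries build without clashes", {
  seqs <- syntheticPeriplasmicSequences()
  specs <- enumerateStoichiometries(c(FtsB = unname(seqs[1])),
                                    c(FtsL = unname(seqs[2])),
                                    start_A = 25, start_B = 61)
  for (st in names(specs)) {
    b <- buildBundle(specs[[st]])
    expect_s4_class(b, "Structure")
    expect_equal(length(chainIds(b)), length(specs[[st]]@chains))
  }
})

test_that("pentamer admissibility requires core Trp/Tyr in half the chains", {
  seqs <- syntheticPeriplasmicSequences()
  regs <- vapply(seqs, assignRegister, "")
  out <- pentamerAdmissible(unname(seqs), unname(regs))
  expect_false(out$admissible)
  expect_match(out$reason, "lack")
  w <- strrep("WAALAAA", 3)
  regw <- assignRegister(w, anchor_positions = 1)
  expect_true(pentamerAdmissible(rep(w, 5), rep(regw, 5))$admissible)
  expect_false(pentamerAdmissible(character(), character())$admissible)
})

test_that("antiparallel orientation and oversized bundles are rejected", {
  s <- strrep("LAALAEK", 4)
  spec <- bundleSpec(c(X = s, Y = s))
  spec@orientation <- "antiparallel"
  expect_error(methods::validObject(spec), "parallel")
  expect_error(bundleSpec(stats::setNames(rep(s, 5), letters[1:5])), "2-4")
})
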