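## Synthetic inputs: ideal bundles, decoy sets, toy groove/rod docking
## fixtures, charged-patch bundles, and interface training sets with
## controlled contact statistics. All generators are pure functions of their
## parameters and seed.

## default training-set background: uniform over a small alphabet so every
## pair cell accumulates enough counts for stable log-odds at ~10^4 contacts
.default_background <- function()
  stats::setNames(rep(0.25, 4), c("L", "E", "K", "S"))

#' Background composition for enrichment-recovery experiments
#'
#' Uniform backgrounds cap the realizable enrichment of a diagonal pair (the
#' observed/expected ratio saturates as the enriched type floods the
#' marginals), so controlled-enrichment training sets keep the enriched type
#' rare. This composition holds the declared type at frequency `f_enriched`
#' and spreads the remainder over the default alphabet.
#'
#' @param type One-letter code of the type to be enriched (default `"L"`).
#' @param f_enriched Its background frequency (default 0.05).
#' @return Named numeric frequency vector.
#' @export
enrichmentBackground <- function(type = "L", f_enriched = 0.05) {
  others <- setdiff(names(.default_background()), type)
  out <- stats::setNames(c(f_enriched, rep((1 - f_enriched) / length(others),
                                           length(others))),
                         c(type, others))
  out / sum(out)
}

#' Synthetic coiled-coil bundle
#'
#' A 2-4 chain parallel bundle with `core_residue` at every *a*/*d* position
#' and seeded random surface residues; chain identities alternate between two
#' labels. The register of each chain is recorded in the structure metadata.
#'
#' @param n_chains 2, 3 or 4.
#' @param length Residues per chain (>= 14).
#' @param core_residue One-letter code placed at core positions (default L).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @param surface_alphabet Residues drawn at non-core positions.
#' @return A [Structure-class].
#' @export
makeBundle <- function(n_chains = 2L, length = 28L, core_residue = "L",
                       seed = 1L,
                       surface_alphabet = c("A", "E", "K", "Q", "S", "N", "T",
                                            "R", "D", "G")) {
  stopifnot(n_chains %in% 2:4, length >= 14)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_chains), function(j) {
      aa <- sample(surface_alphabet, length, replace = TRUE)
      idx <- (seq_len(length) - 1L) %% 7L
      aa[idx %in% c(0L, 3L)] <- core_residue
      paste(aa, collapse = "")
    }, "")
  })
  names(seqs) <- rep(c("P1", "P2"), length.out = n_chains)
  spec <- bundleSpec(seqs, registers = rep(strrep("abcdefg", ceiling(length / 7)),
                                           n_chains) |>
                       substr(1, length))
  buildBundle(spec)
}

#' Register-shuffled decoys of a bundle
#'
#' Decoys rebuilt from seeded random permutations of each chain's sequence on
#' the same geometry, so core positions lose their designed residues while
#' composition is preserved.
#'
#' @param n_chains,length,core_residue,seed As [makeBundle()].
#' @param n_decoys Number of decoys.
#' @return List of [Structure-class] decoys.
#' @export
makeDecoySet <- function(n_decoys = 20L, n_chains = 2L, length = 28L,
                         core_residue = "L", seed = 1L) {
  native <- makeBundle(n_chains, length, core_residue, seed)
  md <- structureMetadata(native)
  regs <- md[grep("^register_", names(md))]
  seqs0 <- vapply(chainIds(native), function(ch) {
    a <- atomTable(native)
    first <- !duplicated(a$resno[a$chain == ch])
    paste(residueOneLetter()[a$resname[a$chain == ch][first]], collapse = "")
  }, "")
  withr::with_seed(seed + 1000L, {
    lapply(seq_len(n_decoys), function(k) {
      seqs <- vapply(seqs0, function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, "")
      names(seqs) <- rep(c("P1", "P2"), length.out = n_chains)
      buildBundle(bundleSpec(seqs, registers = unname(regs)),
                  check_clash = FALSE)
    })
  })
}

## --- training sets with controlled contact statistics --------------------

## calibrate sampling weights so the realized observed/expected ratio
## (expectation from realized marginals, as the derivation computes it)
## equals the declared enrichment for every declared cell
.calibrate_joint <- function(background, enrichment, max_iter = 200,
                             tol = 1e-6) {
  types <- names(background)
  k <- length(types)
  f <- background / sum(background)
  q0 <- outer(f, f) * (2 - diag(k))           # unordered base weights
  w <- matrix(1, k, k, dimnames = list(types, types))
  cells <- list()
  if (length(enrichment)) {
    for (nm in names(enrichment)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(pr) != 2 || !all(pr %in% types))
        stop("generation error: enrichment pair '", nm,
             "' not covered by the background composition")
      cells[[length(cells) + 1L]] <- c(pr, enrichment[[nm]])
      w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- enrichment[[nm]]
    }
  }
  for (it in seq_len(max_iter)) {
    q <- q0 * w
    ## keep only upper triangle+diag mass once for normalization
    tot <- sum(q[upper.tri(q, diag = TRUE)])
    q <- q / tot
    m <- (rowSums(q) + diag(q)) / 2           # q holds both triangles
    err <- 0
    for (cl in cells) {
      i <- cl[1]; j <- cl[2]; e <- as.numeric(cl[3])
      r <- q[i, j] / ((2 - (i == j)) * m[i] * m[j])
      err <- max(err, abs(log(r) - log(e)))
      adj <- e / r
      w[i, j] <- w[i, j] * adj
      if (i != j) w[j, i] <- w[i, j]
      if (!is.finite(w[i, j]) || w[i, j] > 1e8)
        stop("generation error: infeasible enrichment for pair ", i, ":", j,
             " at this background composition")
    }
    if (err < tol) break
    if (it == max_iter)
      stop("generation error: enrichment calibration did not converge ",
           "(factor unrealizable at this background composition)")
  }
  q <- q0 * w
  q / sum(q[upper.tri(q, diag = TRUE)])
}

## vectorized atom table: one minimal 5-atom residue per (chain, resno, type),
## facing the partner chain across the interface
.pair_residues <- function(chain, resno, resname3, x, ysign) {
  n <- length(resno)
  y0 <- 4.8 * ysign
  data.frame(chain = rep(chain, each = 5),
             resno = rep(unname(resno), each = 5), insert = "",
             resname = rep(unname(resname3), each = 5),
             atom = rep(c("N", "CA", "C", "O", "CB"), n),
             element = rep(c("N", "C", "C", "O", "C"), n),
             x = rep(x, each = 5) + rep(c(-1.2, 0, 1.2, 1.9, 0), n),
             y = rep(y0, each = 5) + rep(c(0.4, 0, 0.4, 1.2, 0), n) +
               rep(c(0, 0, 0, 0, -2.3), n) * rep(ysign, each = 5),
             z = rep(c(0.3, 0, -0.3, 0.6, 0), n),
             stringsAsFactors = FALSE)
}

#' Synthetic interface training set with declared contact enrichments
#'
#' Generates two-chain interfaces whose contact-type frequencies realize the
#' declared enrichment factors over a declared background composition. Each
#' contact is an isolated residue pair placed across the interface at CB-CB
#' distance 5.0 A (pairs are 20 A apart, so the CB-CB 6.5 A rule sees exactly
#' one contact per pair). The sampling distribution is calibrated so that the
#' realized observed/expected ratio -- with the expectation computed from the
#' realized marginals, exactly as [derivePairPotential()] computes it --
#' equals the declared factor; the realized counts are recorded in the
#' `counts` attribute.
#'
#' @param n_interfaces Number of interface structures.
#' @param enrichment Named numeric vector of enrichment factors, names
#'   `"X:Y"` in one-letter codes (e.g. `c("L:L" = 2)`); empty for a null set.
#' @param seed Integer seed.
#' @param background Named numeric vector of residue frequencies (one-letter
#'   codes); default uniform over L, E, K, S.
#' @param pairs_per_interface Contacts per interface (default 100).
#' @return List of `list(structure, partition)` entries with attributes
#'   `counts` (realized pair-count matrix), `background` and `enrichment`.
#' @export
makeTrainingSet <- function(n_interfaces, enrichment = numeric(), seed = 1L,
                            background = .default_background(),
                            pairs_per_interface = 100L) {
  stopifnot(n_interfaces >= 1)
  if (length(enrichment) && any(enrichment <= 0))
    stop("generation error: enrichment factors must be > 0")
  q <- .calibrate_joint(background, as.list(enrichment))
  types <- rownames(q)
  k <- length(types)
  ut <- which(upper.tri(q, diag = TRUE), arr.ind = TRUE)
  probs <- q[ut]
  lv <- .aa_levels()
  counts <- matrix(0, 20, 20, dimnames = list(lv, lv))
  three <- stats::setNames(names(residueOneLetter()), residueOneLetter())
  out <- withr::with_seed(seed, {
    lapply(seq_len(n_interfaces), function(ifc) {
      draw <- sample(nrow(ut), pairs_per_interface, replace = TRUE,
                     prob = probs)
      t1 <- types[ut[draw, 1]]; t2 <- types[ut[draw, 2]]
      ## seeded side assignment so both chains carry both types
      flip <- sample(c(TRUE, FALSE), pairs_per_interface, replace = TRUE)
      a_type <- ifelse(flip, t1, t2); b_type <- ifelse(flip, t2, t1)
      xs <- 20 * (seq_len(pairs_per_interface) - 1)
      atoms <- rbind(
        .pair_residues("A", seq_len(pairs_per_interface), three[a_type], xs,
                       rep(-1, pairs_per_interface)),
        .pair_residues("B", seq_len(pairs_per_interface), three[b_type], xs,
                       rep(+1, pairs_per_interface)))
      structure_ <- Structure(atoms,
                              metadata = c(kind = "synthetic training interface"))
      list(structure = structure_, partition = list("A", "B"),
           pairs = paste0(pmin(t1, t2), pmax(t1, t2)))
    })
  })
  for (e in out) {
    tb <- table(e$pairs)
    for (nm in names(tb)) {
      i <- substr(nm, 1, 1); j <- substr(nm, 2, 2)
      counts[i, j] <- counts[i, j] + tb[[nm]]
      if (i != j) counts[j, i] <- counts[i, j]
    }
  }
  out <- lapply(out, function(e) e[c("structure", "partition")])
  attr(out, "counts") <- counts
  attr(out, "background") <- background
  attr(out, "enrichment") <- enrichment
  out
}

## --- toy docking fixtures -------------------------------------------------

## pseudo-atom helper: one GLY residue with a single CA per point
.pseudo_structure <- function(xyz, chain = "R", metadata = character()) {
  n <- nrow(xyz)
  Structure(data.frame(chain = chain, resno = seq_len(n), insert = "",
                       resname = "GLY", atom = "CA", element = "C",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
            metadata = metadata)
}

#' Toy groove receptor
#'
#' Rectangular pseudo-atomic slab with a groove of declared width and depth
#' carved along x into its top face; a docking fixture with a known best
#' binding mode.
#'
#' @param groove_width,groove_depth Groove dimensions in A.
#' @param seed Integer seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @param slab_dims Slab extents (x, y, z) in A.
#' @param lattice Pseudo-atom lattice spacing in A.
#' @return A [Structure-class] with chain `"R"`.
#' @export
makeGrooveReceptor <- function(groove_width = 12, groove_depth = 8, seed = 1L,
                               slab_dims = c(40, 30, 14), lattice = 2.0) {
  xs <- seq(0, slab_dims[1], by = lattice)
  ys <- seq(-slab_dims[2] / 2, slab_dims[2] / 2, by = lattice)
  zs <- seq(0, slab_dims[3], by = lattice)
  g <- expand.grid(x = xs, y = ys, z = zs)
  ztop <- max(zs)
  in_groove <- abs(g$y) < groove_width / 2 & g$z > ztop - groove_depth
  g <- g[!in_groove, , drop = FALSE]
  .pseudo_structure(as.matrix(g),
                    metadata = c(kind = "synthetic groove receptor",
                                 groove_axis = "x",
                                 groove_width = as.character(groove_width)))
}

#' Toy rod ligand
#'
#' Cylinder of pseudo-atoms along x: an axial line plus rings of six atoms,
#' with overall diameter `diameter` (including the 1.7 A pseudo-atom radius).
#'
#' @param length Rod length in A.
#' @param diameter Rod diameter in A (default 10).
#' @param lattice Axial spacing of rings in A.
#' @return A [Structure-class] with chain `"L"`.
#' @export
makeRodLigand <- function(length = 30, diameter = 10, lattice = 2.0) {
  r <- max(diameter / 2 - 1.7, 0.1)
  xs <- seq(0, length, by = lattice)
  ring <- seq(0, 2 * pi, length.out = 7)[-7]
  pts <- do.call(rbind, lapply(xs, function(x)
    rbind(c(x, 0, 0), cbind(x, r * cos(ring), r * sin(ring)))))
  .pseudo_structure(pts, chain = "L",
                    metadata = c(kind = "synthetic rod ligand",
                                 rod_axis = "x",
                                 diameter = as.character(diameter)))
}

## --- charged bundles ------------------------------------------------------

#' Synthetic bundle with acidic sequence bands
#'
#' Builds a two-chain coiled coil whose non-core positions inside the
#' declared bands are acidic (Glu/Asp) while non-core positions elsewhere
#' carry basic residues at a declared background rate; used to exercise
#' charged-patch detection.
#'
#' @param acidic_bands Named list of `c(from, to)` author-numbering ranges,
#'   one per chain id (`"A"`, `"B"`).
#' @param seed Integer seed.
#' @param chain_starts,chain_lengths Author numbering start and length per
#'   chain (defaults mimic two periplasmic helices, 25-88 and 61-109).
#' @param basic_rate Probability of Lys/Arg at non-core positions outside the
#'   bands (default 0.25).
#' @return A [Structure-class].
#' @export
makeChargedBundle <- function(acidic_bands = list(A = c(50, 70), B = c(85, 95)),
                              seed = 1L, chain_starts = c(A = 25L, B = 61L),
                              chain_lengths = c(A = 64L, B = 49L),
                              basic_rate = 0.25) {
  ids <- names(chain_starts)
  seqs <- withr::with_seed(seed, {
    vapply(ids, function(ch) {
      n <- chain_lengths[[ch]]
      resno <- chain_starts[[ch]] + seq_len(n) - 1L
      idx <- (seq_len(n) - 1L) %% 7L
      aa <- sample(c("A", "Q", "S", "N", "T"), n, replace = TRUE)
      basic <- stats::runif(n) < basic_rate
      aa[basic] <- sample(c("K", "R"), sum(basic), replace = TRUE)
      band <- acidic_bands[[ch]]
      if (!is.null(band)) {
        in_band <- resno >= band[1] & resno <= band[2]
        if (any(band < chain_starts[[ch]]) ||
            any(band > chain_starts[[ch]] + n - 1L))
          stop("acidic band outside chain range for chain ", ch)
        aa[in_band] <- sample(c("E", "D"), sum(in_band), replace = TRUE)
      }
      aa[idx %in% c(0L, 3L)] <- "L"          # core stays hydrophobic
      paste(aa, collapse = "")
    }, "")
  })
  names(seqs) <- ids
  spec <- bundleSpec(seqs,
                     registers = vapply(chain_lengths, function(n)
                       substr(strrep("abcdefg", ceiling(n / 7)), 1, n), ""),
                     start_seq_ids = unname(chain_starts[ids]))
  buildBundle(spec)
}

#' Shipped synthetic periplasmic sequences
#'
#' Constructed stand-ins for the FtsB (25-88) and FtsL (61-109) periplasmic
#' fragments, labelled synthetic: they carry the documented sequence features
#' (leucine heptads, a GDHS turn candidate in the FtsL-like chain, acidic
#' bands at FtsB 50-70 / FtsL 85-95, no core Trp/Tyr) but are not the natural
#' sequences.
#'
#' @return Named character vector of two one-letter sequences.
#' @export
syntheticPeriplasmicSequences <- function() {
  readFastaChains(system.file("extdata", "ftsBL_periplasmic_synthetic.fasta",
                              package = "coilDock"))
}
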