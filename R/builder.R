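## Parametric coiled-coil bundle construction.
##
## Backbone atoms are generated on Crick coil-of-coils geometry: each chain's
## atoms follow minor helices wound on a common superhelical axis (z), chains
## offset by 360/n degrees. The cylindrical offsets of N, C, O relative to the
## CA helix were frozen from an internal-coordinate build of an ideal
## alpha-helix (phi = -57.8, psi = -47, omega = 180 degrees); CB is placed
## tetrahedrally from N/CA/C and side chains extend along the CA->CB vector
## with declared per-residue lengths (no rotamer sampling).

## cylindrical offsets relative to the CA minor helix: radius (A),
## phase (deg), axial (A)
.helix_offsets <- list(
  N  = c(r = 1.570, dphi = -26.66, dz = -0.913),
  CA = c(r = 2.295, dphi = 0.00,   dz = 0.000),
  C  = c(r = 1.689, dphi = 26.72,  dz = 1.064),
  O  = c(r = 1.935, dphi = 21.19,  dz = 2.257))

## side-chain pseudo-atom templates: distance along the CA->CB axis from CA
## (A) and perpendicular offset (A). CB itself is placed tetrahedrally.
.sidechain_templates <- list(
  GLY = NULL, ALA = NULL,
  SER = data.frame(atom = "OG", d = 2.42, p = 0),
  CYS = data.frame(atom = "SG", d = 2.81, p = 0),
  THR = data.frame(atom = c("OG1", "CG2"), d = c(2.42, 2.52), p = c(0.5, -0.9)),
  VAL = data.frame(atom = c("CG1", "CG2"), d = c(2.52, 2.52), p = c(0.9, -0.9)),
  LEU = data.frame(atom = c("CG", "CD1", "CD2"), d = c(2.55, 3.35, 3.35),
                   p = c(0, 1.0, -1.0)),
  ILE = data.frame(atom = c("CG1", "CG2", "CD1"), d = c(2.55, 2.52, 3.80),
                   p = c(0.6, -0.9, 0.6)),
  MET = data.frame(atom = c("CG", "SD", "CE"), d = c(2.55, 3.90, 5.10), p = 0),
  PRO = data.frame(atom = c("CG", "CD"), d = c(2.40, 2.40), p = c(0.7, -0.8)),
  PHE = data.frame(atom = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   d = c(2.55, 3.30, 3.30, 4.60, 4.60, 5.20),
                   p = c(0, 1.1, -1.1, 1.1, -1.1, 0)),
  TYR = data.frame(atom = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
                   d = c(2.55, 3.30, 3.30, 4.60, 4.60, 5.20, 6.55),
                   p = c(0, 1.1, -1.1, 1.1, -1.1, 0, 0)),
  TRP = data.frame(atom = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                            "CZ3", "CH2"),
                   d = c(2.55, 3.30, 3.40, 4.50, 4.70, 3.90, 6.00, 5.20, 6.10),
                   p = c(0, 1.1, -0.9, 1.2, 0.1, -2.1, -0.1, -2.3, -1.3)),
  ASP = data.frame(atom = c("CG", "OD1", "OD2"), d = c(2.55, 3.50, 3.50),
                   p = c(0, 1.0, -1.0)),
  GLU = data.frame(atom = c("CG", "CD", "OE1", "OE2"),
                   d = c(2.55, 3.85, 4.80, 4.80), p = c(0, 0, 1.0, -1.0)),
  ASN = data.frame(atom = c("CG", "OD1", "ND2"), d = c(2.55, 3.50, 3.50),
                   p = c(0, 1.0, -1.0)),
  GLN = data.frame(atom = c("CG", "CD", "OE1", "NE2"),
                   d = c(2.55, 3.85, 4.80, 4.80), p = c(0, 0, 1.0, -1.0)),
  LYS = data.frame(atom = c("CG", "CD", "CE", "NZ"),
                   d = c(2.55, 3.85, 5.15, 6.40), p = 0),
  ARG = data.frame(atom = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
                   d = c(2.55, 3.85, 5.10, 6.20, 7.00, 7.00),
                   p = c(0, 0, 0, 0, 1.0, -1.0)),
  HIS = data.frame(atom = c("CG", "ND1", "CD2", "CE1", "NE2"),
                   d = c(2.55, 3.40, 3.50, 4.70, 4.80),
                   p = c(0, 1.1, -1.0, 0.9, -0.3)))

.element_of <- function(atom) substr(gsub("^[0-9]*", "", atom), 1, 1)

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
.unit <- function(v) v / sqrt(sum(v^2))

#' Default Crick parameters per oligomeric state
#'
#' Canonical GCN4-family values: superhelix radius 4.9 A (dimer), 6.7 A
#' (trimer), 7.6 A (tetramer); pitch -148 A (left-handed); rise 1.51 A per
#' residue.
#'
#' @param n_chains Integer 2, 3 or 4.
#' @return A [CrickParams-class] object.
#' @export
defaultCrickParams <- function(n_chains) {
  stopifnot(n_chains %in% 2:4)
  CrickParams(superhelixRadius = c(4.9, 6.7, 7.6)[n_chains - 1])
}

#' Construct a bundle specification
#'
#' @param sequences Named character vector of one-letter sequences, one per
#'   helix, names giving the protein identity of each chain (may repeat).
#' @param registers Optional character vector of heptad registers (auto
#'   assigned by [assignRegister()] when `NULL`).
#' @param start_seq_ids Integer vector of author numbering starts (default 1).
#' @param breaks Data frame (`chain`, `from`, `to`, `type`) of declared helix
#'   breaks in author numbering, or `NULL`.
#' @param pairing List of chain-id pairs forming heterodimeric faces (4-helix
#'   bundles), or `NULL`.
#' @return A [BundleSpec-class] object; chains get ids A, B, C, D in order.
#' @export
bundleSpec <- function(sequences, registers = NULL, start_seq_ids = 1L,
                       breaks = NULL, pairing = NULL) {
  n <- length(sequences)
  if (is.null(registers))
    registers <- vapply(sequences, assignRegister, "")
  start_seq_ids <- rep_len(as.integer(start_seq_ids), n)
  ids <- LETTERS[seq_len(n)]
  chains <- lapply(seq_len(n), function(i)
    list(sequence = unname(sequences[i]), register = unname(registers[i]),
         startSeqId = start_seq_ids[i],
         protein = if (!is.null(names(sequences))) names(sequences)[i] else ids[i],
         chainId = ids[i]))
  prot <- vapply(chains, function(ch) ch$protein, "")
  comp <- table(prot)
  if (is.null(breaks))
    breaks <- data.frame(chain = character(), from = integer(),
                         to = integer(), type = character())
  methods::new("BundleSpec", chains = chains,
               composition = stats::setNames(as.integer(comp), names(comp)),
               orientation = "parallel", breaks = breaks,
               pairing = if (is.null(pairing)) list() else pairing)
}

## place every atom of one chain on the supercoil
.build_chain <- function(ch, params, phi0, breaks) {
  seq1 <- strsplit(toupper(ch$sequence), "")[[1]]
  resn <- .one_to_three(seq1)
  n <- length(seq1)
  hreg <- .heptad_index(ch$register)
  R0 <- params@superhelixRadius; P <- params@pitch
  h <- params@risePerResidue
  w0 <- 2 * pi * h / P
  w1 <- 2 * pi * (2 / 7)                     # relative minor frequency: 7-residue core period
  alph <- atan2(2 * pi * R0, abs(P)) * sign(P)
  ca <- cos(alph); sa <- sin(alph)
  ## turn mask from breaks (author numbering -> 0-based local index)
  is_turn <- rep(FALSE, n)
  if (nrow(breaks)) {
    b <- breaks[breaks$chain == ch$chainId, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      lo <- b$from[i] - ch$startSeqId; hi <- b$to[i] - ch$startSeqId
      is_turn[(lo:hi) + 1L] <- TRUE
    }
  }
  ## cumulative axial index: turns advance faster (extended, non-helical)
  rise_mult <- ifelse(is_turn, 2.1, 1.0)
  ct <- cumsum(rise_mult) - rise_mult[1]
  rad_mult <- ifelse(is_turn, 0.35, 1.0)
  ## per-residue minor phase: within each helical segment the register string
  ## fixes the phase so heptad position 'a' points at the bundle axis (phase pi)
  seg <- cumsum(c(TRUE, diff(is_turn) != 0))
  phi1 <- numeric(n)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    t0 <- idx[1] - 1L
    phi1[idx] <- pi + w1 * (hreg[idx[1]] - t0) + params@interfacePhase * pi / 180
  }
  place <- function(t, r1, dphi, dz) {
    ## t: 0-based residue index
    teff <- ct[t + 1L] + dz / h
    t1 <- (t + dz / h)
    th0 <- w0 * teff + phi0
    th1 <- w1 * t1 + phi1[t + 1L] + dphi * pi / 180
    r1 <- r1 * rad_mult[t + 1L]
    c(R0 * cos(th0) + r1 * cos(th0) * cos(th1) - r1 * ca * sin(th0) * sin(th1),
      R0 * sin(th0) + r1 * sin(th0) * cos(th1) + r1 * ca * cos(th0) * sin(th1),
      h * teff - r1 * sa * sin(th1))
  }
  rows <- vector("list", n)
  for (t in 0:(n - 1)) {
    rn <- resn[t + 1L]
    Np <- place(t, .helix_offsets$N["r"], .helix_offsets$N["dphi"], .helix_offsets$N["dz"])
    CAp <- place(t, .helix_offsets$CA["r"], 0, 0)
    Cp <- place(t, .helix_offsets$C["r"], .helix_offsets$C["dphi"], .helix_offsets$C["dz"])
    Op <- place(t, .helix_offsets$O["r"], .helix_offsets$O["dphi"], .helix_offsets$O["dz"])
    names(Np) <- names(CAp) <- names(Cp) <- names(Op) <- NULL
    atoms <- list(N = Np, CA = CAp, C = Cp, O = Op)
    if (rn != "GLY") {
      b1 <- .unit(CAp - Np); b2 <- .unit(CAp - Cp)
      bis <- .unit(b1 + b2); pn <- .unit(.cross3(b2, b1))
      CBp <- CAp + 1.53 * (bis * cos(0.9111) + pn * sin(0.9111))
      atoms$CB <- CBp
      tmpl <- .sidechain_templates[[rn]]
      if (!is.null(tmpl)) {
        ## extension direction: CA->CB blended with the outward radial
        ## direction (side chains splay away from the bundle axis)
        rhat <- c(CAp[1], CAp[2], 0)
        rhat <- if (sum(rhat^2) > 1e-9) .unit(rhat) else c(1, 0, 0)
        u <- .unit(.unit(CBp - CAp) + 0.6 * rhat)
        v <- .unit(.cross3(u, CAp - Np))
        for (i in seq_len(nrow(tmpl)))
          atoms[[tmpl$atom[i]]] <- CAp + tmpl$d[i] * u + tmpl$p[i] * v
      }
    }
    xyz <- do.call(rbind, atoms)
    rows[[t + 1L]] <- data.frame(
      chain = ch$chainId, resno = ch$startSeqId + t, insert = "",
      resname = rn, atom = names(atoms), element = .element_of(names(atoms)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build an all-atom-backbone coiled-coil bundle
#'
#' Realizes a [BundleSpec-class] on Crick coil-of-coils geometry: chains are
#' placed at equal angular offsets around the z axis at superhelix radius R0,
#' register positions *a*/*d* face the bundle axis, and declared helix breaks
#' are rendered as extended non-helical turns joining two Crick segments.
#' Full side chains are placed by an idealized extension along the CA-CB
#' vector.
#'
#' @param spec A [BundleSpec-class].
#' @param params A [CrickParams-class]; default chosen by chain count via
#'   [defaultCrickParams()].
#' @param check_clash Raise a geometry error when interchain heavy atoms come
#'   closer than 2.0 A (default `TRUE`; decoy construction disables it and
#'   leaves clashes to be penalized at ranking time).
#' @return A [Structure-class] whose metadata records the register and protein
#'   identity of each chain.
#' @examples
#' spec <- bundleSpec(c(X = strrep("LAALAEK", 4), Y = strrep("LAALAEK", 4)))
#' buildBundle(spec)
#' @export
buildBundle <- function(spec, params = NULL, check_clash = TRUE) {
  methods::validObject(spec)
  n <- length(spec@chains)
  if (is.null(params)) params <- defaultCrickParams(n)
  methods::validObject(params)
  blocks <- lapply(seq_len(n), function(j)
    .build_chain(spec@chains[[j]], params, phi0 = 2 * pi * (j - 1) / n,
                 breaks = spec@breaks))
  atoms <- do.call(rbind, blocks)
  ## interchain clash check
  if (check_clash) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- as.matrix(blocks[[i]][, c("x", "y", "z")])
    xj <- as.matrix(blocks[[j]][, c("x", "y", "z")])
    dmin <- .min_cross_dist(xi, xj)
    if (dmin$d < 2.0)
      stop(sprintf("geometry error: chains %s and %s clash (%s %d/%s - %s %d/%s at %.2f A)",
                   spec@chains[[i]]$chainId, spec@chains[[j]]$chainId,
                   blocks[[i]]$atom[dmin$i], blocks[[i]]$resno[dmin$i],
                   blocks[[i]]$chain[dmin$i],
                   blocks[[j]]$atom[dmin$j], blocks[[j]]$resno[dmin$j],
                   blocks[[j]]$chain[dmin$j], dmin$d))
  }
  md <- c(kind = "coiled-coil bundle",
          stats::setNames(vapply(spec@chains, function(ch) ch$register, ""),
                          paste0("register_", vapply(spec@chains, function(ch) ch$chainId, ""))),
          stats::setNames(vapply(spec@chains, function(ch) ch$protein, ""),
                          paste0("protein_", vapply(spec@chains, function(ch) ch$chainId, ""))))
  Structure(atoms, metadata = md)
}

## minimum cross distance between two coordinate sets, with arg indices
.min_cross_dist <- function(a, b) {
  ## chunked to bound memory on large pairs
  best <- list(d = Inf, i = NA_integer_, j = NA_integer_)
  step <- max(1L, floor(2e6 / nrow(b)))
  for (s in seq(1L, nrow(a), by = step)) {
    idx <- s:min(s + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    m <- which.min(d2)
    dmin <- sqrt(max(d2[m], 0))
    if (dmin < best$d) {
      best$d <- dmin
      best$i <- idx[(m - 1) %% length(idx) + 1]
      best$j <- (m - 1) %/% length(idx) + 1
    }
  }
  best
}

#' Enumerate candidate stoichiometries of a two-protein coiled coil
#'
#' Returns the four oligomeric hypotheses for two distinct proteins: 1A:1B
#' dimer, 2A:1B and 1A:2B trimers, and the 2A:2B tetramer assembled as two
#' heterodimeric faces with A/B alternating around the axis. The pentamer is
#' deliberately not enumerated; see [pentamerAdmissible()]. If the two
#' sequences are identical the specs collapse to homomeric 2-, 3- and 4-helix
#' bundles with a warning.
#'
#' @param protein_A,protein_B Named length-1 character vectors (name = protein
#'   identity, value = one-letter sequence).
#' @param registers_A,registers_B Optional explicit registers.
#' @param start_A,start_B Author numbering of the first residue.
#' @param turn_motif Sequence motif marking a candidate helix break in
#'   protein B (default `"GDHS"`); when present, the break is applied to the
#'   B chains of the 2:2 spec only (straight helices suffice for the dimer
#'   and trimers).
#' @return Named list of [BundleSpec-class] objects
#'   (`"1:1"`, `"2:1"`, `"1:2"`, `"2:2"`).
#' @export
enumerateStoichiometries <- function(protein_A, protein_B,
                                     registers_A = NULL, registers_B = NULL,
                                     start_A = 1L, start_B = 1L,
                                     turn_motif = "GDHS") {
  nmA <- if (!is.null(names(protein_A))) names(protein_A)[1] else "A"
  nmB <- if (!is.null(names(protein_B))) names(protein_B)[1] else "B"
  sA <- unname(protein_A[1]); sB <- unname(protein_B[1])
  rA <- if (is.null(registers_A)) assignRegister(sA) else registers_A
  rB <- if (is.null(registers_B)) assignRegister(sB) else registers_B
  if (identical(sA, sB)) {
    warning("identical sequences: degenerate specs collapse to homomeric bundles")
    mk <- function(k) bundleSpec(stats::setNames(rep(sA, k), rep(nmA, k)),
                                 registers = rep(rA, k),
                                 start_seq_ids = rep(start_A, k))
    return(list("2" = mk(2), "3" = mk(3), "4" = mk(4)))
  }
  chainsOf <- function(order_vec) {
    seqs <- ifelse(order_vec == "A", sA, sB)
    names(seqs) <- ifelse(order_vec == "A", nmA, nmB)
    regs <- ifelse(order_vec == "A", rA, rB)
    starts <- ifelse(order_vec == "A", start_A, start_B)
    list(seqs = seqs, regs = regs, starts = starts)
  }
  mk <- function(order_vec, breaks = NULL, pairing = NULL) {
    cc <- chainsOf(order_vec)
    bundleSpec(cc$seqs, registers = cc$regs, start_seq_ids = cc$starts,
               breaks = breaks, pairing = pairing)
  }
  ## GDHS-style turn in the B protein, applied to the 2:2 bundle only
  brk22 <- NULL
  if (nzchar(turn_motif)) {
    pos <- regexpr(turn_motif, sB, fixed = TRUE)
    if (pos > 0) {
      from <- start_B + as.integer(pos) - 1L
      to <- from + nchar(turn_motif) - 1L
      brk22 <- data.frame(chain = c("B", "D"), from = from, to = to,
                          type = "turn", stringsAsFactors = FALSE)
    }
  }
  list("1:1" = mk(c("A", "B")),
       "2:1" = mk(c("A", "B", "A")),
       "1:2" = mk(c("B", "A", "B")),
       "2:2" = mk(c("A", "B", "A", "B"), breaks = brk22,
                  pairing = list(c("A", "B"), c("C", "D"))))
}

#' Test pentamer admissibility
#'
#' Five-helix coiled coils require bulky aromatic hydrophobics (Trp/Tyr) in
#' the packing core. A chain set is admissible iff at least one Trp or Tyr
#' occupies a core position (*a* or *d*) in at least half of the chains.
#'
#' @param sequences Character vector of one-letter sequences.
#' @param registers Character vector of matching heptad registers.
#' @return List with elements `admissible` (logical) and `reason` (character).
#' @export
pentamerAdmissible <- function(sequences, registers) {
  stopifnot(length(sequences) == length(registers))
  if (!length(sequences))
    return(list(admissible = FALSE, reason = "no chains given"))
  hits <- mapply(function(s, r) {
    aa <- strsplit(toupper(s), "")[[1]]
    hi <- .heptad_index(r)
    any(aa %in% c("W", "Y") & hi %in% c(0L, 3L))
  }, sequences, registers)
  ok <- sum(hits) >= length(sequences) / 2 && length(sequences) > 0
  list(admissible = ok,
       reason = if (ok) "bulky aromatic residues (Trp/Tyr) present at core a/d positions"
                else "lack of bulky hydrophobic residues (Trp/Tyr) at core a/d positions")
}
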