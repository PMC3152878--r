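## Quantitative interface and surface descriptors for a partitioned complex:
## buried area, interface residues, hydrogen bonds, salt bridges, composition
## percentages, interaction densities, and the stability classification
## against a mean-stable-complex reference.

#' Buried interface area of a partitioned complex
#'
#' `([SASA(side1 alone) + SASA(side2 alone)] - SASA(complex)) / 2`. The
#' percentage uses the complex ASA as denominator (declared convention,
#' configurable via `percent_of`).
#'
#' @param complex A [Structure-class] whose chains are covered by `partition`.
#' @param partition List of two disjoint chain-id vectors covering all chains.
#' @param probe Probe radius in A (default 1.4).
#' @param n_points Sphere points per atom for SASA (default 960).
#' @param percent_of Denominator of the percentage: `"complex"` (default) or
#'   `"monomers"`.
#' @return List with `area` (A^2), `percent`, and the three total SASA values.
#' @export
interfaceArea <- function(complex, partition, probe = 1.4, n_points = 960L,
                          percent_of = c("complex", "monomers")) {
  percent_of <- match.arg(percent_of)
  p <- .check_partition(complex, partition)
  complex <- selectChains(complex, c(p$s1, p$s2))  # ignore bystander chains
  s_cplx <- sum(computeSASA(complex, probe, n_points))
  s1 <- sum(computeSASA(selectChains(complex, p$s1), probe, n_points))
  s2 <- sum(computeSASA(selectChains(complex, p$s2), probe, n_points))
  area <- (s1 + s2 - s_cplx) / 2
  denom <- if (percent_of == "complex") s_cplx else s1 + s2
  list(area = area, percent = 100 * area / denom,
       sasa_complex = s_cplx, sasa_side1 = s1, sasa_side2 = s2)
}

## per-residue ASA loss on complexation, both sides
.residue_delta_asa <- function(complex, partition, probe = 1.4, n_points = 960L) {
  p <- .check_partition(complex, partition)
  a <- atomTable(complex)
  asa_cplx <- computeSASA(complex, probe, n_points)
  out <- NULL
  for (side in list(p$s1, p$s2)) {
    sub <- selectChains(complex, side)
    asa_iso <- computeSASA(sub, probe, n_points)
    sa <- atomTable(sub)
    idx <- match(paste(.res_key(sa), sa$atom), paste(.res_key(a), a$atom))
    delta <- asa_iso - asa_cplx[idx]
    key <- .res_key(sa)
    dres <- tapply(delta, key, sum)
    first <- !duplicated(key)
    blk <- data.frame(chain = sa$chain[first], resno = sa$resno[first],
                      insert = sa$insert[first], resname = sa$resname[first],
                      key = key[first], stringsAsFactors = FALSE)
    blk$delta_asa <- as.numeric(dres[blk$key])
    out <- rbind(out, blk)
  }
  out
}

#' Interface residues of a partitioned complex
#'
#' Residues whose summed per-atom accessible area drops by more than
#' `threshold` between the isolated partition side and the complex.
#'
#' @inheritParams interfaceArea
#' @param threshold ASA-change threshold in \eqn{\mathrm{\AA}^2} (> 0; default 1.0).
#' @return Data frame of interface residues with their `delta_asa`.
#' @export
interfaceResidues <- function(complex, partition, threshold = 1.0,
                              probe = 1.4, n_points = 960L) {
  stopifnot(threshold > 0)
  d <- .residue_delta_asa(complex, partition, probe, n_points)
  out <- d[d$delta_asa > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## donor antecedent: nearest bonded heavy atom in the same residue
.antecedent_coords <- function(atoms, xyz, donor_idx) {
  out <- matrix(NA_real_, length(donor_idx), 3)
  key <- .res_key(atoms)
  for (k in seq_along(donor_idx)) {
    i <- donor_idx[k]
    same <- which(key == key[i]); same <- same[same != i]
    if (!length(same)) next
    d2 <- colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2)
    j <- same[which.min(d2)]
    if (min(d2) < 2.0^2) out[k, ] <- xyz[j, ]
  }
  out
}

#' Detect interchain hydrogen bonds
#'
#' Heavy-atom geometric criteria (hydrogens are not modelled): donor-acceptor
#' distance at most `max_dist` and angle at the donor (antecedent-donor-
#' acceptor) at least `min_angle`. Donors are backbone/side-chain N and
#' hydroxyl O; acceptors are all oxygens plus His ring nitrogens. Only bonds
#' across the partition are reported, each donor-acceptor pair once.
#'
#' @param complex A [Structure-class].
#' @param partition List of two disjoint chain-id vectors.
#' @param max_dist Donor-acceptor cutoff in A (default 3.9).
#' @param min_angle Minimum angle at the donor in degrees (default 90).
#' @return Data frame of bonds: donor and acceptor identifiers, distance and
#'   donor angle.
#' @export
detectHBonds <- function(complex, partition, max_dist = 3.9, min_angle = 90) {
  p <- .check_partition(complex, partition)
  a <- atomTable(complex)
  xyz <- coords(complex)
  don <- which(.hbond_donor_atoms(a))
  acc <- which(.hbond_acceptor_atoms(a))
  side <- ifelse(a$chain %in% p$s1, 1L, 2L)
  bonds <- NULL
  for (dir in 1:2) {
    di <- don[side[don] == dir]; ai <- acc[side[acc] == (3L - dir)]
    if (!length(di) || !length(ai)) next
    hits <- .pairs_within(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE],
                          max_dist)
    if (!nrow(hits)) next
    didx <- di[hits$i]; aidx <- ai[hits$j]
    ante <- .antecedent_coords(a, xyz, didx)
    v1 <- ante - xyz[didx, , drop = FALSE]
    v2 <- xyz[aidx, , drop = FALSE] - xyz[didx, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok <- !is.na(ang) & ang >= min_angle & hits$d > 1e-6
    if (!any(ok)) next
    bonds <- rbind(bonds, data.frame(
      donor_chain = a$chain[didx[ok]], donor_resno = a$resno[didx[ok]],
      donor_resname = a$resname[didx[ok]], donor_atom = a$atom[didx[ok]],
      acceptor_chain = a$chain[aidx[ok]], acceptor_resno = a$resno[aidx[ok]],
      acceptor_resname = a$resname[aidx[ok]], acceptor_atom = a$atom[aidx[ok]],
      dist = hits$d[ok], donor_angle = ang[ok], stringsAsFactors = FALSE))
  }
  if (is.null(bonds))
    bonds <- data.frame(donor_chain = character(), donor_resno = integer(),
                        donor_resname = character(), donor_atom = character(),
                        acceptor_chain = character(), acceptor_resno = integer(),
                        acceptor_resname = character(), acceptor_atom = character(),
                        dist = numeric(), donor_angle = numeric())
  ## one report per donor-acceptor atom pair
  bonds[!duplicated(paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom,
                          bonds$acceptor_chain, bonds$acceptor_resno,
                          bonds$acceptor_atom)), , drop = FALSE]
}

#' Detect interchain salt bridges
#'
#' Oppositely charged side-chain atoms (per [chargedAtoms()]) across the
#' partition within the cutoff; one bridge is reported per residue pair (the
#' minimum-distance atom pair). The cutoff convention is *within* 4 A.
#'
#' @inheritParams detectHBonds
#' @param cutoff Distance cutoff in A (> 0; default 4.0).
#' @return Data frame of bridges with the positive and negative atom
#'   identifiers and their distance.
#' @export
detectSaltBridges <- function(complex, partition, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  p <- .check_partition(complex, partition)
  a <- atomTable(complex)
  xyz <- coords(complex)
  sign <- .atom_charge_signs(a)
  side <- ifelse(a$chain %in% p$s1, 1L, 2L)
  empty <- data.frame(pos_chain = character(), pos_resno = integer(),
                      pos_resname = character(), pos_atom = character(),
                      neg_chain = character(), neg_resno = integer(),
                      neg_resname = character(), neg_atom = character(),
                      dist = numeric())
  bridges <- empty
  for (dir in 1:2) {
    pi_ <- which(sign == "+" & side == dir)
    ni <- which(sign == "-" & side == (3L - dir))
    if (!length(pi_) || !length(ni)) next
    hits <- .pairs_within(xyz[pi_, , drop = FALSE], xyz[ni, , drop = FALSE],
                          cutoff)
    if (!nrow(hits)) next
    pidx <- pi_[hits$i]; nidx <- ni[hits$j]
    bridges <- rbind(bridges, data.frame(
      pos_chain = a$chain[pidx], pos_resno = a$resno[pidx],
      pos_resname = a$resname[pidx], pos_atom = a$atom[pidx],
      neg_chain = a$chain[nidx], neg_resno = a$resno[nidx],
      neg_resname = a$resname[nidx], neg_atom = a$atom[nidx],
      dist = hits$d, stringsAsFactors = FALSE))
  }
  if (!nrow(bridges)) return(empty)
  rp <- paste(bridges$pos_chain, bridges$pos_resno, "|",
              bridges$neg_chain, bridges$neg_resno)
  bridges <- bridges[order(rp, bridges$dist), , drop = FALSE]
  out <- bridges[!duplicated(paste(bridges$pos_chain, bridges$pos_resno, "|",
                                   bridges$neg_chain, bridges$neg_resno)), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

## composition percentages over a residue table
.composition_pct <- function(restab) {
  out <- c(polar = 0, nonpolar = 0, charged = 0)
  if (!nrow(restab)) return(out)
  tab <- table(factor(suppressWarnings(classifyResidue(restab$resname)),
                      c("polar", "nonpolar", "charged")))
  100 * as.numeric(tab) / nrow(restab) -> pct
  stats::setNames(pct, c("polar", "nonpolar", "charged"))
}

## principal-axis alignment: longest axis -> z, second -> x
.axis_aligned_extents <- function(structure) {
  xyz <- coords(structure)
  ctr <- colMeans(xyz)
  v <- svd(sweep(xyz, 2, ctr))$v
  rot <- cbind(v[, 2], v[, 3], v[, 1])      # x = 2nd, y = 3rd, z = principal
  proj <- sweep(xyz, 2, ctr) %*% rot
  apply(proj, 2, function(u) diff(range(u)))
}

#' Full interface report for a partitioned complex
#'
#' Assembles buried area, interface share of the complex surface, interface
#' composition percentages (over interface residues), hydrogen-bond and
#' salt-bridge densities per 100 A^2, surface composition over
#' solvent-exposed residues (relative side-chain exposure above
#' `exposure_cutoff`), the interface residue list, and the bounding-box
#' dimensions with the principal (bundle) axis aligned to z.
#'
#' @inheritParams interfaceArea
#' @param threshold Interface-residue ASA-change threshold (A^2, default 1.0).
#' @param exposure_cutoff Relative SASA (fraction of the residue-type
#'   maximum) above which a residue counts as surface (default 0.05).
#'   Chains in neither partition side are ignored.
#' @return An [InterfaceReport-class] object.
#' @export
interfaceReport <- function(complex, partition, probe = 1.4, n_points = 960L,
                            threshold = 1.0, exposure_cutoff = 0.05) {
  p <- .check_partition(complex, partition)
  complex <- selectChains(complex, c(p$s1, p$s2))  # ignore bystander chains
  ## one SASA evaluation per entity; everything below reuses them
  asa <- computeSASA(complex, probe, n_points)
  a <- atomTable(complex)
  key_atom <- paste(.res_key(a), a$atom)
  dres <- NULL; iso_sum <- 0
  for (side in list(p$s1, p$s2)) {
    sub <- selectChains(complex, side)
    asa_iso <- computeSASA(sub, probe, n_points)
    iso_sum <- iso_sum + sum(asa_iso)
    sa <- atomTable(sub)
    idx <- match(paste(.res_key(sa), sa$atom), key_atom)
    delta <- asa_iso - asa[idx]
    key <- .res_key(sa)
    first <- !duplicated(key)
    blk <- data.frame(chain = sa$chain[first], resno = sa$resno[first],
                      insert = sa$insert[first], resname = sa$resname[first],
                      key = key[first], stringsAsFactors = FALSE)
    blk$delta_asa <- as.numeric(tapply(delta, key, sum)[blk$key])
    dres <- rbind(dres, blk)
  }
  ia <- list(area = (iso_sum - sum(asa)) / 2)
  ia$percent <- 100 * ia$area / sum(asa)
  ires <- dres[dres$delta_asa > threshold, , drop = FALSE]
  rownames(ires) <- NULL
  hb <- detectHBonds(complex, partition)
  sb <- detectSaltBridges(complex, partition)
  flags <- character()
  if (ia$area <= 0) {
    dens_hb <- 0; dens_sb <- 0
    flags <- c(flags, "empty interface: densities reported as 0")
  } else {
    dens_hb <- 100 * nrow(hb) / ia$area
    dens_sb <- 100 * nrow(sb) / ia$area
  }
  ## exposed residues of the complex
  res_asa <- tapply(asa, .res_key(a), sum)
  rt <- residueTable(complex)
  rel <- as.numeric(res_asa[rt$key]) /
    maxResidueSASA()[ifelse(rt$resname %in% standardResidues(), rt$resname, "ALA")]
  surf <- rt[!is.na(rel) & rel > exposure_cutoff, , drop = FALSE]
  methods::new("InterfaceReport",
               interfaceASA = max(ia$area, 0),
               interfaceASAPercent = max(ia$percent, 0),
               interfaceComposition = .composition_pct(ires),
               hbondsPer100A2 = dens_hb, saltBridgesPer100A2 = dens_sb,
               surfaceComposition = .composition_pct(surf),
               interfaceResidues = ires,
               dimensions = .axis_aligned_extents(complex),
               counts = c(hbonds = nrow(hb), salt_bridges = nrow(sb)),
               flags = flags)
}

#' Reference interface parameters of a mean stable complex
#'
#' @return Data frame (shipped as editable plain text) with one row per
#'   reference field; range-valued fields carry distinct `value_lo`/`value_hi`.
#' @export
meanStableReference <- function() {
  path <- system.file("extdata", "mean_stable_complex_v1.tsv",
                      package = "coilDock")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Classify interface stability against the reference complex
#'
#' Each of the six reference fields (interface ASA percent, the three
#' interface composition percentages, and the two interaction densities) is
#' compared with a tolerance band around the reference: a field is within the
#' band when it lies within a factor (1 + `band`) of the reference (bands of
#' range-valued references extend from `lo / 1.5` to `hi * 1.5` at the default
#' `band = 0.5`). Verdict: `consistent` when at least 5 of 6 fields lie
#' inside their bands, `borderline` at 4, otherwise `inconsistent`; an empty
#' interface is always `inconsistent`.
#'
#' @param report An [InterfaceReport-class].
#' @param reference Reference data frame as in [meanStableReference()].
#' @param band Half-width of the tolerance band as a fraction (default 0.5).
#' @return List with the per-field table (`value`, `lo`, `hi`, `within`) and
#'   the `verdict`.
#' @export
classifyStability <- function(report, reference = meanStableReference(),
                              band = 0.5) {
  vals <- c(interface_asa_percent = report@interfaceASAPercent,
            pct_polar = unname(report@interfaceComposition["polar"]),
            pct_nonpolar = unname(report@interfaceComposition["nonpolar"]),
            pct_charged = unname(report@interfaceComposition["charged"]),
            hbonds_per_100A2 = report@hbondsPer100A2,
            saltbridges_per_100A2 = report@saltBridgesPer100A2)
  ref <- reference[match(names(vals), reference$field), ]
  ## multiplicative band: within a factor (1 + band) of the reference
  tab <- data.frame(field = names(vals), value = unname(vals),
                    ref_lo = ref$value_lo, ref_hi = ref$value_hi,
                    lo = ref$value_lo / (1 + band),
                    hi = (1 + band) * ref$value_hi)
  tab$deviation <- ifelse(vals < tab$ref_lo, vals - tab$ref_lo,
                          ifelse(vals > tab$ref_hi, vals - tab$ref_hi, 0))
  tab$within <- vals >= tab$lo & vals <= tab$hi
  n_within <- sum(tab$within)
  verdict <- if (report@interfaceASA <= 0) "inconsistent"
             else if (n_within >= 5) "consistent"
             else if (n_within == 4) "borderline"
             else "inconsistent"
  list(fields = tab, n_within = n_within, verdict = verdict)
}
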