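## Hotspot identification by alanine-substitution rescoring and charged
## surface-patch mapping with a screened-Coulomb potential.

## delete side-chain atoms beyond CB of one residue
.truncate_to_ala <- function(structure, key) {
  a <- atomTable(structure)
  keep <- .res_key(a) != key | a$atom %in% c("N", "CA", "C", "O", "CB")
  methods::new("Structure", atoms = {
    b <- a[keep, , drop = FALSE]; rownames(b) <- NULL; b
  }, chainOrder = chainIds(structure), metadata = structureMetadata(structure))
}

#' Computational alanine scan of an interface
#'
#' For every interface residue the side chain is truncated to CB and the
#' pair-potential score, interchain hydrogen bonds and salt bridges are
#' recomputed; the hotspot proxy is
#' `ddG = delta_score + w_hb * delta_nHB + w_sb * delta_nSB`. The proxy is a
#' dimensionless ranking quantity, not a physical free energy in kJ/mol.
#' Interaction types lost are annotated with precedence SB > HB > VW.
#'
#' @param complex A [Structure-class].
#' @param partition List of two disjoint chain-id vectors.
#' @param matrix A [PairPotential-class] used for rescoring.
#' @param w_hb,w_sb Weights of lost hydrogen bonds / salt bridges (default 1).
#' @param threshold Interface-residue ASA threshold passed through to
#'   [interfaceResidues()].
#' @return Data frame sorted by decreasing `ddg_proxy`: residue identifiers,
#'   `ddg_proxy`, `delta_score`, `lost_hbonds`, `lost_saltbridges`,
#'   `interaction_types` (comma-joined subset of SB/HB/VW), `primary_type`,
#'   `partner_chain`, and `scannable` (`FALSE` for Gly/Ala, reported with 0).
#' @export
alanineScan <- function(complex, partition, matrix, w_hb = 1, w_sb = 1,
                        threshold = 1.0) {
  .check_partition(complex, partition)
  ires <- interfaceResidues(complex, partition, threshold)
  base_score <- scoreComplex(complex, partition, matrix)
  base_hb <- detectHBonds(complex, partition)
  base_sb <- detectSaltBridges(complex, partition)
  contacts <- extractContacts(complex, partition, matrix@contactDef)
  rows <- vector("list", nrow(ires))
  for (i in seq_len(nrow(ires))) {
    key <- ires$key[i]
    ## contacts this residue participates in (for partner annotation)
    kc <- paste(contacts$chain_i, contacts$resno_i, "", sep = "|") == key |
      paste(contacts$chain_j, contacts$resno_j, "", sep = "|") == key
    partner <- if (any(kc)) {
      pc <- ifelse(paste(contacts$chain_i[kc], contacts$resno_i[kc], "",
                         sep = "|") == key,
                   contacts$chain_j[kc], contacts$chain_i[kc])
      names(sort(table(pc), decreasing = TRUE))[1]
    } else NA_character_
    if (ires$resname[i] %in% c("GLY", "ALA")) {
      rows[[i]] <- data.frame(chain = ires$chain[i], resno = ires$resno[i],
                              resname = ires$resname[i], ddg_proxy = 0,
                              delta_score = 0, lost_hbonds = 0L,
                              lost_saltbridges = 0L, interaction_types = "",
                              primary_type = "", partner_chain = partner,
                              scannable = FALSE, stringsAsFactors = FALSE)
      next
    }
    mut <- .truncate_to_ala(complex, key)
    d_score <- base_score - scoreComplex(mut, partition, matrix)
    d_hb <- nrow(base_hb) - nrow(detectHBonds(mut, partition))
    d_sb <- nrow(base_sb) - nrow(detectSaltBridges(mut, partition))
    types <- c(if (d_sb > 0) "SB", if (d_hb > 0) "HB",
               if (d_score > 1e-12 || any(kc)) "VW")
    rows[[i]] <- data.frame(chain = ires$chain[i], resno = ires$resno[i],
                            resname = ires$resname[i],
                            ddg_proxy = d_score + w_hb * d_hb + w_sb * d_sb,
                            delta_score = d_score, lost_hbonds = d_hb,
                            lost_saltbridges = d_sb,
                            interaction_types = paste(types, collapse = ","),
                            primary_type = if (length(types)) types[1] else "",
                            partner_chain = partner, scannable = TRUE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), ddg_proxy = numeric(),
                      delta_score = numeric(), lost_hbonds = integer(),
                      lost_saltbridges = integer(),
                      interaction_types = character(),
                      primary_type = character(), partner_chain = character(),
                      scannable = logical()))
  out <- out[order(-out$ddg_proxy, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screened-Coulomb potential at test points
#'
#' `phi(p) = sum_q sign(q) exp(-d/lambda) / d` over formally charged atoms,
#' with the distance floored at 1 A. Units are arbitrary; the sign pattern is
#' the meaningful output. This is a declared screened-Coulomb approximation,
#' not a Poisson-Boltzmann solution.
#'
#' @param structure A [Structure-class].
#' @param test_points Numeric matrix (n x 3) of evaluation points (A).
#' @param debye_length Screening length lambda in A (> 0; default 8,
#'   approximately 150 mM ionic strength).
#' @return Numeric vector of potentials, one per test point.
#' @export
coulombPotential <- function(structure, test_points, debye_length = 8) {
  stopifnot(debye_length > 0)
  test_points <- matrix(test_points, ncol = 3)
  a <- atomTable(structure)
  sgn <- .atom_charge_signs(a)
  ch <- which(sgn != "0")
  if (!length(ch)) return(rep(0, nrow(test_points)))
  q <- ifelse(sgn[ch] == "+", 1, -1)
  xyz <- coords(structure)[ch, , drop = FALSE]
  out <- numeric(nrow(test_points))
  for (i in seq_len(nrow(test_points))) {
    d <- sqrt(colSums((t(xyz) - test_points[i, ])^2))
    d <- pmax(d, 1)
    out[i] <- sum(q * exp(-d / debye_length) / d)
  }
  out
}

#' Find charged surface patches
#'
#' Single-linkage clustering of solvent-exposed charged residues of one sign:
#' two residues are linked when their charged side-chain atoms come within
#' `linkage_distance`; clusters smaller than `min_size` are dropped. Patches
#' are returned sorted by size.
#'
#' @param structure A [Structure-class].
#' @param sign `"positive"` or `"negative"`.
#' @param linkage_distance Linkage cutoff in A (default 10).
#' @param min_size Minimum patch size (>= 2).
#' @param exposure_cutoff Relative residue SASA above which a residue counts
#'   as exposed (default 0.05).
#' @param debye_length Screening length for the reported mean potential.
#' @return List of patches; each has `members` (residue data frame), `sign`,
#'   `centroid` and `mean_potential`.
#' @export
findChargePatches <- function(structure, sign = c("negative", "positive"),
                              linkage_distance = 10, min_size = 2L,
                              exposure_cutoff = 0.05, debye_length = 8) {
  sign <- match.arg(sign)
  stopifnot(min_size >= 2)
  want <- if (sign == "positive") "+" else "-"
  a <- atomTable(structure)
  sgn <- .atom_charge_signs(a)
  key <- .res_key(a)
  ## exposure filter
  asa <- computeSASA(structure)
  res_asa <- tapply(asa, key, sum)
  rt <- residueTable(structure)
  rel <- as.numeric(res_asa[rt$key]) /
    maxResidueSASA()[ifelse(rt$resname %in% standardResidues(), rt$resname, "ALA")]
  exposed_keys <- rt$key[!is.na(rel) & rel > exposure_cutoff]
  cand_keys <- unique(key[sgn == want])
  cand_keys <- cand_keys[cand_keys %in% exposed_keys]
  if (length(cand_keys) < min_size) return(list())
  ## min charged-atom distance between candidate residues
  pts <- lapply(cand_keys, function(k)
    coords(structure)[key == k & sgn == want, , drop = FALSE])
  n <- length(cand_keys)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (.min_cross_dist(pts[[i]], pts[[j]])$d <= linkage_distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  patches <- list()
  for (cid in unique(comp)) {
    members_keys <- cand_keys[comp == cid]
    if (length(members_keys) < min_size) next
    members <- rt[match(members_keys, rt$key), c("chain", "resno", "resname")]
    rownames(members) <- NULL
    xyz <- do.call(rbind, pts[comp == cid])
    patches[[length(patches) + 1L]] <-
      list(members = members, sign = sign, centroid = colMeans(xyz),
           mean_potential = mean(coulombPotential(structure, xyz,
                                                  debye_length)))
  }
  patches[order(-vapply(patches, function(p) nrow(p$members), 0))]
}
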