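## Empirical residue-pair contact potential: derivation from two-chain
## interface training sets and rescoring/ranking of candidate complexes.

.aa_levels <- function() sort(unname(residueOneLetter()))

## resolve a partition argument (list of two chain-id vectors) against a
## structure, with overlap/coverage checks
.check_partition <- function(structure, partition, require_cover = FALSE) {
  stopifnot(is.list(partition), length(partition) == 2)
  s1 <- partition[[1]]; s2 <- partition[[2]]
  if (!length(s1) || !length(s2)) stop("both partition sides must be non-empty")
  if (length(intersect(s1, s2))) stop("partition sides overlap")
  if (!all(c(s1, s2) %in% chainIds(structure)))
    stop("partition references chains absent from the structure")
  if (require_cover && !setequal(c(s1, s2), chainIds(structure)))
    stop("partition must cover all chains")
  list(s1 = s1, s2 = s2)
}

## representative side-chain point for CB-CB metric (CA for glycine)
.cb_points <- function(atoms) {
  key <- .res_key(atoms)
  cb <- atoms[atoms$atom == "CB", , drop = FALSE]
  have <- unique(key) %in% .res_key(cb)
  ca <- atoms[atoms$atom == "CA" & !(key %in% .res_key(cb)), , drop = FALSE]
  out <- rbind(cb, ca)
  out <- out[match(unique(key), .res_key(out)), , drop = FALSE]
  out[!is.na(out$chain), , drop = FALSE]
}

#' Extract interface contacts between two chain sets
#'
#' A contact is an unordered residue pair, one residue from each partition
#' side, whose distance under the declared metric is at most the cutoff; each
#' residue pair is counted once.
#'
#' @param structure A [Structure-class] complex.
#' @param partition List of two disjoint chain-id vectors.
#' @param contact_def A [contactDefinition()].
#' @return Data frame with one row per contact: residue identifiers of both
#'   partners, their one-letter types, the sorted `pair` label and the contact
#'   distance.
#' @export
extractContacts <- function(structure, partition,
                            contact_def = contactDefinition()) {
  p <- .check_partition(structure, partition)
  a <- atomTable(structure)
  a1 <- a[a$chain %in% p$s1, , drop = FALSE]
  a2 <- a[a$chain %in% p$s2, , drop = FALSE]
  if (contact_def$metric == "CB-CB") {
    a1 <- .cb_points(a1); a2 <- .cb_points(a2)
  }
  if (!nrow(a1) || !nrow(a2))
    return(data.frame(chain_i = character(), resno_i = integer(),
                      type_i = character(), chain_j = character(),
                      resno_j = integer(), type_j = character(),
                      pair = character(), dist = numeric()))
  x1 <- as.matrix(a1[, c("x", "y", "z")]); x2 <- as.matrix(a2[, c("x", "y", "z")])
  hits <- .pairs_within(x1, x2, contact_def$cutoff)
  if (!nrow(hits))
    return(data.frame(chain_i = character(), resno_i = integer(),
                      type_i = character(), chain_j = character(),
                      resno_j = integer(), type_j = character(),
                      pair = character(), dist = numeric()))
  k1 <- .res_key(a1)[hits$i]; k2 <- .res_key(a2)[hits$j]
  ord <- order(k1, k2, hits$d)
  first <- !duplicated(paste(k1, k2)[ord])
  sel <- ord[first]
  one <- residueOneLetter()
  t1 <- unname(one[a1$resname[hits$i[sel]]])
  t2 <- unname(one[a2$resname[hits$j[sel]]])
  data.frame(chain_i = a1$chain[hits$i[sel]], resno_i = a1$resno[hits$i[sel]],
             type_i = t1, chain_j = a2$chain[hits$j[sel]],
             resno_j = a2$resno[hits$j[sel]], type_j = t2,
             pair = paste0(pmin(t1, t2), pmax(t1, t2)),
             dist = hits$d[sel], stringsAsFactors = FALSE)
}

## all index pairs (i in a, j in b) with distance <= cutoff, chunked
.pairs_within <- function(a, b, cutoff) {
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  step <- max(1L, floor(4e6 / nrow(b)))
  for (s in seq(1L, nrow(a), by = step)) {
    idx <- s:min(s + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    w <- which(d2 <= cutoff^2 + 1e-12)
    if (length(w)) {
      out_i <- c(out_i, idx[(w - 1) %% length(idx) + 1])
      out_j <- c(out_j, (w - 1) %/% length(idx) + 1)
      out_d <- c(out_d, sqrt(pmax(d2[w], 0)))
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

## 20x20 observed contact count matrix from a contact table
.count_matrix <- function(contacts) {
  lv <- .aa_levels()
  O <- matrix(0, 20, 20, dimnames = list(lv, lv))
  if (nrow(contacts)) {
    tab <- matrix(table(factor(contacts$type_i, lv),
                        factor(contacts$type_j, lv)), 20, 20)
    O <- O + tab + t(tab)
    diag(O) <- diag(O) - diag(tab)  # unordered: diagonal counted once
  }
  O
}

#' Derive a residue-pair potential from interface training data
#'
#' Computes `S(i,j) = ln[(O(i,j) + p) / (E(i,j) + p)]` where `O` is the
#' observed count of unordered type-pair contacts over the training set and
#' `E(i,j) = T f(i) f(j) (2 - delta_ij)` is the count expected from the
#' marginal residue frequencies `f` at the interfaces (`T` = total contacts).
#'
#' @param training List of entries, each a list with elements `structure`
#'   (a [Structure-class]) and `partition` (two chain-id vectors).
#' @param contact_def A [contactDefinition()].
#' @param pseudocount Laplace pseudocount `p` (> 0, default 1).
#' @param provenance Optional character note recorded in the matrix.
#' @return A [PairPotential-class] object.
#' @export
derivePairPotential <- function(training, contact_def = contactDefinition(),
                                pseudocount = 1, provenance = NULL) {
  if (!length(training)) stop("derivation error: empty training set")
  stopifnot(pseudocount > 0)
  O <- matrix(0, 20, 20, dimnames = list(.aa_levels(), .aa_levels()))
  for (tr in training) {
    contacts <- extractContacts(tr$structure, tr$partition, contact_def)
    O <- O + .count_matrix(contacts)
  }
  total <- sum(O[upper.tri(O, diag = FALSE)]) + sum(diag(O))
  if (total < 1) stop("derivation error: no contacts in training set")
  f <- (rowSums(O) + diag(O)) / (2 * total)   # rowSums counts diagonal once
  E <- total * outer(f, f) * (2 - diag(20))
  S <- log((O + pseudocount) / (E + pseudocount))
  S <- (S + t(S)) / 2                          # numeric symmetrization
  methods::new("PairPotential", scores = S, pseudocount = pseudocount,
               contactDef = contact_def,
               provenance = if (is.null(provenance))
                 sprintf("derived from %d interface(s), %d contacts",
                         length(training), as.integer(total))
               else provenance)
}

#' @rdname PairPotential-class
#' @param x A [PairPotential-class] object.
#' @export
pairScores <- function(x) x@scores

#' Observed/expected contact counts behind a derivation
#'
#' Convenience for validating a derived matrix against generator bookkeeping:
#' recomputes the observed count matrix and expected counts on a training set.
#'
#' @inheritParams derivePairPotential
#' @return List with `O`, `E`, `total` and marginals `f`.
#' @export
contactCountSummary <- function(training, contact_def = contactDefinition()) {
  O <- matrix(0, 20, 20, dimnames = list(.aa_levels(), .aa_levels()))
  for (tr in training)
    O <- O + .count_matrix(extractContacts(tr$structure, tr$partition, contact_def))
  total <- sum(O[upper.tri(O)]) + sum(diag(O))
  f <- (rowSums(O) + diag(O)) / (2 * max(total, 1))
  list(O = O, E = total * outer(f, f) * (2 - diag(20)), total = total, f = f)
}

#' Score a complex under a pair potential
#'
#' Sum of `S(type_i, type_j)` over interchain contacts across the partition;
#' higher is better.
#'
#' @param structure A [Structure-class] complex.
#' @param partition List of two disjoint chain-id vectors.
#' @param matrix A [PairPotential-class].
#' @return Numeric score (dimensionless).
#' @export
scoreComplex <- function(structure, partition, matrix) {
  contacts <- extractContacts(structure, partition, matrix@contactDef)
  if (!nrow(contacts)) return(0)
  sum(matrix@scores[cbind(contacts$type_i, contacts$type_j)])
}

## number of interchain heavy-atom clashes below a cutoff
.clash_count <- function(structure, partition, cutoff = 2.5) {
  p <- .check_partition(structure, partition)
  a <- atomTable(structure)
  x1 <- as.matrix(a[a$chain %in% p$s1, c("x", "y", "z")])
  x2 <- as.matrix(a[a$chain %in% p$s2, c("x", "y", "z")])
  nrow(.pairs_within(x1, x2, cutoff))
}

#' Rank candidate complexes by pair-potential score
#'
#' Descending score; ties broken by fewer interchain heavy-atom clashes
#' (< 2.5 A), then by input order.
#'
#' @param models List of entries with elements `structure` and `partition`.
#' @param matrix A [PairPotential-class].
#' @return Data frame with `index` (input position), `score`, `clashes`,
#'   sorted best-first.
#' @export
rankModels <- function(models, matrix) {
  stopifnot(length(models) >= 1)
  score <- vapply(models, function(m)
    scoreComplex(m$structure, m$partition, matrix), 0)
  clashes <- vapply(models, function(m)
    .clash_count(m$structure, m$partition), 0L)
  ord <- order(-score, clashes, seq_along(models))
  data.frame(index = ord, score = score[ord], clashes = clashes[ord])
}

#' Write / read a pair potential as TSV plus JSON sidecar
#'
#' The 20x20 matrix goes to `path` as tab-separated values with one-letter
#' row/column names; contact rule, pseudocount and provenance go to
#' `<path>.json`.
#'
#' @param matrix A [PairPotential-class].
#' @param path Output TSV path.
#' @return Invisibly, `path`. `readPairPotential` returns the
#'   [PairPotential-class].
#' @export
writePairPotential <- function(matrix, path) {
  utils::write.table(round(matrix@scores, 6), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(list(metric = matrix@contactDef$metric,
                            cutoff = matrix@contactDef$cutoff,
                            exclude_intrachain = matrix@contactDef$exclude_intrachain,
                            pseudocount = matrix@pseudocount,
                            provenance = matrix@provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePairPotential
#' @export
readPairPotential <- function(path) {
  s <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cd <- contactDefinition(metric = meta$metric, cutoff = meta$cutoff,
                          exclude_intrachain = meta$exclude_intrachain)
  methods::new("PairPotential", scores = s[.aa_levels(), .aa_levels()],
               pseudocount = meta$pseudocount, contactDef = cd,
               provenance = as.character(meta$provenance))
}
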