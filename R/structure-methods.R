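## Accessors and basic manipulation for Structure objects.

#' @rdname Structure-class
#' @param x,object A [Structure-class] object.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Structure-class
#' @export
setMethod("atomTable", "Structure", function(x) x@atoms)

#' @rdname Structure-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname Structure-class
#' @export
setMethod("chainIds", "Structure", function(x) x@chainOrder)

#' @rdname Structure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Structure-class
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname Structure-class
#' @export
setGeneric("structureMetadata", function(x) standardGeneric("structureMetadata"))

#' @rdname Structure-class
#' @export
setMethod("structureMetadata", "Structure", function(x) x@metadata)

#' Atom coordinates as a matrix
#'
#' @param x A [Structure-class] object.
#' @return Numeric matrix with columns x, y, z (one row per atom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Structure",
          function(x) as.matrix(x@atoms[, c("x", "y", "z")]))

#' Residue-level view of a structure
#'
#' @param x A [Structure-class] object.
#' @return Data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `polarity` and the residue `key` used internally.
#' @export
residueTable <- function(x) {
  a <- atomTable(x)
  key <- .res_key(a)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resname = a$resname[first],
                    key = key[first], stringsAsFactors = FALSE)
  out$polarity <- suppressWarnings(classifyResidue(out$resname))
  out
}

.res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")

#' Number of residues in a structure
#'
#' @param x A [Structure-class] object.
#' @return Integer count over all chains.
#' @export
nResidues <- function(x) length(unique(.res_key(atomTable(x))))

#' Subset a structure by chain
#'
#' @param x A [Structure-class] object.
#' @param chains Character vector of chain identifiers to keep.
#' @return A [Structure-class] with only the selected chains, order preserved.
#' @export
selectChains <- function(x, chains) {
  stopifnot(all(chains %in% chainIds(x)))
  a <- atomTable(x)
  a <- a[a$chain %in% chains, , drop = FALSE]
  keep <- chainIds(x)[chainIds(x) %in% chains]
  rownames(a) <- NULL
  methods::new("Structure", atoms = a, chainOrder = keep,
               metadata = structureMetadata(x))
}

#' Apply a rigid transform to a structure
#'
#' @param x A [Structure-class] object.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric 3-vector (A).
#' @return The transformed [Structure-class].
#' @export
transformStructure <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(x) %*% t(rotation)
  xyz <- sweep(xyz, 2, -translation)
  a <- atomTable(x)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  methods::new("Structure", atoms = a, chainOrder = chainIds(x),
               metadata = structureMetadata(x))
}

#' Merge two structures into one complex
#'
#' Chains of `y` whose identifiers collide with chains of `x` are renamed to
#' the first free letters/digits.
#'
#' @param x,y [Structure-class] objects.
#' @return A combined [Structure-class]; renamed chains are reported in the
#'   `renamed` metadata entry.
#' @export
combineStructures <- function(x, y) {
  ax <- atomTable(x); ay <- atomTable(y)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)),
                  c(chainIds(x), chainIds(y)))
  renamed <- character()
  for (ch in chainIds(y)) {
    if (ch %in% chainIds(x)) {
      new_id <- pool[1]; pool <- pool[-1]
      ay$chain[ay$chain == ch] <- new_id
      renamed <- c(renamed, paste0(ch, "->", new_id))
    }
  }
  a <- rbind(ax, ay)
  rownames(a) <- NULL
  md <- c(structureMetadata(x),
          if (length(renamed)) c(renamed = paste(renamed, collapse = ",")))
  methods::new("Structure", atoms = a, chainOrder = unique(a$chain),
               metadata = md)
}

setMethod("show", "Structure", function(object) {
  a <- atomTable(object)
  cat("Structure:", length(chainIds(object)), "chain(s),",
      nResidues(object), "residue(s),", nrow(a), "atoms\n")
  for (ch in chainIds(object)) {
    sel <- a$chain == ch
    cat("  chain ", ch, ": residues ", min(a$resno[sel]), "-",
        max(a$resno[sel]), "\n", sep = "")
  }
  if (length(structureMetadata(object)))
    cat("  metadata:", paste(names(structureMetadata(object)), collapse = ", "), "\n")
})

setMethod("show", "CrickParams", function(object) {
  cat("CrickParams: R0 =", object@superhelixRadius, "A, pitch =",
      object@pitch, "A, rise =", object@risePerResidue,
      "A/res, res/turn =", object@residuesPerTurn, "\n")
})

setMethod("show", "BundleSpec", function(object) {
  comp <- paste(paste0(names(object@composition), ":", object@composition),
                collapse = " ")
  cat("BundleSpec:", length(object@chains), "parallel helices (", comp, ")\n")
  for (ch in object@chains)
    cat("  ", ch$chainId, " [", ch$protein, "] ", nchar(ch$sequence),
        " res from ", ch$startSeqId, "\n", sep = "")
  if (nrow(object@breaks)) cat("  breaks:", nrow(object@breaks), "\n")
})

setMethod("show", "PairPotential", function(object) {
  cat("PairPotential: 20x20 log-odds matrix,",
      "pseudocount", object@pseudocount, "\n")
  cat("  contact rule:", object@contactDef$metric, "<=",
      object@contactDef$cutoff, "A\n")
  cat("  range:", round(min(object@scores), 3), "..",
      round(max(object@scores), 3), "\n")
  if (length(object@provenance)) cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "DockGrid", function(object) {
  d <- dim(object@values)
  cat("DockGrid:", paste(d, collapse = "x"), "cells @", object@spacing, "A\n")
})

setMethod("show", "InterfaceReport", function(object) {
  cat("InterfaceReport\n")
  cat(sprintf("  interface ASA: %.1f A^2 (%.2f%% of complex ASA)\n",
              object@interfaceASA, object@interfaceASAPercent))
  cat(sprintf("  interface %%polar/nonpolar/charged: %.1f / %.1f / %.1f\n",
              object@interfaceComposition["polar"],
              object@interfaceComposition["nonpolar"],
              object@interfaceComposition["charged"]))
  cat(sprintf("  H-bonds/100A^2: %.2f   salt bridges/100A^2: %.2f\n",
              object@hbondsPer100A2, object@saltBridgesPer100A2))
  cat(sprintf("  dimensions: %.0f x %.0f x %.0f A\n",
              object@dimensions[1], object@dimensions[2], object@dimensions[3]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
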