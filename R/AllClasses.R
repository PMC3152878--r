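## Central S4 containers.

setOldClass("data.frame")

#' Molecular structure container
#'
#' Hierarchical atom/residue/chain coordinate model used throughout the
#' package. Atom records live in a single data frame (`chain`, `resno`,
#' `insert`, `resname`, `atom`, `element`, `x`, `y`, `z`); chains keep their
#' file order in `chainOrder`; `metadata` is a named character vector of
#' free-text provenance.
#'
#' @slot atoms data.frame of atom records.
#' @slot chainOrder character vector of unique chain identifiers in order.
#' @slot metadata named character vector.
#' @aliases Structure-class
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame",
                        chainOrder = "character",
                        metadata = "character"))

.required_atom_cols <- c("chain", "resno", "insert", "resname", "atom",
                         "element", "x", "y", "z")

setValidity("Structure", function(object) {
  a <- object@atoms
  miss <- setdiff(.required_atom_cols, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@chainOrder)) return("chain ids not unique")
  if (nrow(a)) {
    if (!all(a$chain %in% object@chainOrder)) return("atoms reference unknown chains")
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("non-finite coordinates")
    key <- paste(a$chain, a$resno, a$insert,
                 round(a$x, 3), round(a$y, 3), round(a$z, 3))
    if (anyDuplicated(key))
      return("coincident heavy-atom coordinates within a residue")
  }
  TRUE
})

#' Construct a Structure from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `insert`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` (missing `insert`/`element` columns are
#'   filled in; elements are inferred from the first letter of the atom name).
#' @param metadata Named character vector of provenance notes.
#' @return A [Structure-class] object.
#' @export
Structure <- function(atoms, metadata = character()) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("^[0-9]", "", atoms$atom), 1, 1)
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, .required_atom_cols]
  rownames(atoms) <- NULL
  methods::new("Structure", atoms = atoms,
               chainOrder = unique(atoms$chain),
               metadata = metadata)
}

#' Crick superhelix parameters
#'
#' Geometry of a coiled-coil bundle: superhelix radius `R0` (A), local
#' residues per turn relative to the rotating superhelix frame
#' (3.5 gives an exact 7-residue core period), axial rise per residue (A),
#' superhelix pitch (A; negative = left-handed), and the interface phase
#' offset (degrees) that sets which heptad position faces the bundle axis.
#'
#' @slot superhelixRadius numeric, A.
#' @slot residuesPerTurn numeric.
#' @slot risePerResidue numeric, A.
#' @slot pitch numeric, A (sign encodes handedness).
#' @slot interfacePhase numeric, degrees.
#' @aliases CrickParams-class
#' @exportClass CrickParams
setClass("CrickParams",
         representation(superhelixRadius = "numeric",
                        residuesPerTurn = "numeric",
                        risePerResidue = "numeric",
                        pitch = "numeric",
                        interfacePhase = "numeric"))

setValidity("CrickParams", function(object) {
  if (object@superhelixRadius <= 0) return("superhelixRadius must be > 0")
  if (object@risePerResidue <= 1.0 || object@risePerResidue >= 2.0)
    return("risePerResidue must lie in (1.0, 2.0) A")
  if (object@pitch == 0) return("pitch must be nonzero")
  if (object@residuesPerTurn <= 2) return("residuesPerTurn must exceed 2")
  TRUE
})

#' @param superhelixRadius,residuesPerTurn,risePerResidue,pitch,interfacePhase
#'   See slot documentation. Defaults are canonical GCN4-family values for a
#'   left-handed supercoil.
#' @return A [CrickParams-class] object.
#' @rdname CrickParams-class
#' @export
CrickParams <- function(superhelixRadius = 4.9, residuesPerTurn = 3.5,
                        risePerResidue = 1.51, pitch = -148,
                        interfacePhase = 0) {
  methods::new("CrickParams", superhelixRadius = superhelixRadius,
               residuesPerTurn = residuesPerTurn,
               risePerResidue = risePerResidue, pitch = pitch,
               interfacePhase = interfacePhase)
}

#' Declarative description of a coiled-coil bundle
#'
#' @slot chains list; one entry per helix with fields `sequence` (one-letter
#'   string), `register` (heptad letters, same length), `startSeqId` (integer
#'   author numbering of the first residue), `protein` (identity label) and
#'   `chainId` (single character).
#' @slot composition named integer vector of chain counts per protein identity.
#' @slot orientation character; only `"parallel"` is admissible.
#' @slot breaks data.frame with columns `chain`, `from`, `to`, `type`
#'   describing declared helix breaks (author numbering).
#' @slot pairing list of character pairs; for 4-helix bundles, which chains
#'   form heterodimeric faces.
#' @aliases BundleSpec-class
#' @exportClass BundleSpec
setClass("BundleSpec",
         representation(chains = "list", composition = "integer",
                        orientation = "character", breaks = "data.frame",
                        pairing = "list"))

setValidity("BundleSpec", function(object) {
  n <- length(object@chains)
  if (n < 2 || n > 4) return("bundle must have 2-4 chains")
  if (!identical(object@orientation, "parallel"))
    return("only parallel bundles are supported (membrane-anchored N-termini)")
  for (ch in object@chains) {
    if (nchar(ch$sequence) != nchar(ch$register))
      return("register length must match sequence length")
    if (!all(strsplit(ch$register, "")[[1]] %in% letters[1:7]))
      return("register letters must be a-g")
  }
  ids <- vapply(object@chains, function(ch) ch$chainId, "")
  if (anyDuplicated(ids)) return("chain ids not unique")
  if (nrow(object@breaks)) {
    for (i in seq_len(nrow(object@breaks))) {
      b <- object@breaks[i, ]
      ch <- object@chains[[match(b$chain, ids)]]
      if (is.null(ch)) return("break references unknown chain")
      last <- ch$startSeqId + nchar(ch$sequence) - 1L
      if (b$from < ch$startSeqId || b$to > last || b$from > b$to)
        return("break range outside its chain")
    }
  }
  TRUE
})

#' Interface contact definition
#'
#' @param metric `"heavy-atom-min"` (default) or `"CB-CB"` (glycine falls back
#'   to CA).
#' @param cutoff Contact distance cutoff in Angstrom (defaults: 4.5 for
#'   heavy-atom minimum distance, 6.5 for CB-CB).
#' @param exclude_intrachain Logical; score interchain contacts only
#'   (default `TRUE`).
#' @param min_sequence_separation Minimum residue separation for intrachain
#'   contacts (ignored while `exclude_intrachain` is `TRUE`).
#' @return A list with class `ContactDefinition`.
#' @export
contactDefinition <- function(metric = c("heavy-atom-min", "CB-CB"),
                              cutoff = NULL, exclude_intrachain = TRUE,
                              min_sequence_separation = 4L) {
  metric <- match.arg(metric)
  if (is.null(cutoff)) cutoff <- if (metric == "CB-CB") 6.5 else 4.5
  stopifnot(cutoff > 0)
  structure(list(metric = metric, cutoff = cutoff,
                 exclude_intrachain = exclude_intrachain,
                 min_sequence_separation = as.integer(min_sequence_separation)),
            class = "ContactDefinition")
}

#' Residue-pair contact potential
#'
#' 20x20 symmetric log-odds matrix of interface contact preferences,
#' `S(i,j) = ln[(O(i,j)+p) / (E(i,j)+p)]`, with its contact definition and
#' training provenance.
#'
#' @slot scores 20x20 symmetric numeric matrix, rows/columns named by
#'   one-letter residue codes.
#' @slot pseudocount numeric.
#' @slot contactDef the `ContactDefinition` the matrix was derived under.
#' @slot provenance character description of the training set.
#' @aliases PairPotential-class
#' @exportClass PairPotential
setClass("PairPotential",
         representation(scores = "matrix", pseudocount = "numeric",
                        contactDef = "ANY", provenance = "character"))

setValidity("PairPotential", function(object) {
  s <- object@scores
  if (!identical(dim(s), c(20L, 20L))) return("scores must be 20x20")
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-10))) return("scores must be symmetric")
  if (!all(is.finite(s))) return("scores must be finite")
  if (object@pseudocount <= 0) return("pseudocount must be > 0")
  TRUE
})

#' Docking grid
#'
#' Cubic-cell lattice encoding of a structure for shape-complementarity
#' scanning: open space 0, molecular surface layer 1, interior a declared
#' penalty/overlap value.
#'
#' @slot spacing numeric, cell edge in A.
#' @slot origin numeric 3-vector, A (coordinates of the center of cell
#'   `[1,1,1]`).
#' @slot values 3-D numeric array.
#' @aliases DockGrid-class
#' @exportClass DockGrid
setClass("DockGrid",
         representation(spacing = "numeric", origin = "numeric",
                        values = "array"))

setValidity("DockGrid", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@origin) != 3) return("origin must be a 3-vector")
  if (length(dim(object@values)) != 3) return("values must be a 3-D array")
  TRUE
})

#' Docking restraint set
#'
#' @param distance_restraints Data frame with columns `receptor_chain`,
#'   `receptor_resno`, `ligand_chain`, `ligand_resno`, `max_dist` — each row
#'   one restraint; residue selectors may hold comma-separated residue numbers.
#' @param slab_thickness Thickness (A) of the membrane-proximal slab that the
#'   N-terminal main-chain atoms of all chains must share (coplanarity
#'   restraint); `NA` disables it.
#' @param axis Unit 3-vector, the bundle axis normal to the slab
#'   (default z).
#' @return A [RestraintSet-class] object.
#' @aliases RestraintSet-class
#' @exportClass RestraintSet
#' @export restraintSet
setClass("RestraintSet",
         representation(distanceRestraints = "data.frame",
                        slabThickness = "numeric", axis = "numeric"))

setValidity("RestraintSet", function(object) {
  dr <- object@distanceRestraints
  if (nrow(dr) && any(dr$max_dist <= 0)) return("max_dist must be > 0")
  if (!is.na(object@slabThickness) && object@slabThickness <= 0)
    return("slab thickness must be > 0")
  if (length(object@axis) != 3) return("axis must be a 3-vector")
  TRUE
})

restraintSet <- function(distance_restraints = NULL, slab_thickness = NA_real_,
                         axis = c(0, 0, 1)) {
  if (is.null(distance_restraints))
    distance_restraints <- data.frame(receptor_chain = character(),
                                      receptor_resno = character(),
                                      ligand_chain = character(),
                                      ligand_resno = character(),
                                      max_dist = numeric())
  methods::new("RestraintSet", distanceRestraints = distance_restraints,
               slabThickness = slab_thickness, axis = axis / sqrt(sum(axis^2)))
}

#' Interface report
#'
#' One row of interface parameters plus one row of surface composition for a
#' partitioned complex: interface area and its share of the complex surface,
#' composition percentages over interface residues, hydrogen-bond and
#' salt-bridge densities per 100 A^2, surface composition over exposed
#' residues, the interface residue list, and bounding-box dimensions with the
#' bundle axis aligned to z.
#'
#' @slot interfaceASA numeric, A^2.
#' @slot interfaceASAPercent numeric, percent of total complex ASA.
#' @slot interfaceComposition named numeric, percent polar/nonpolar/charged.
#' @slot hbondsPer100A2 numeric.
#' @slot saltBridgesPer100A2 numeric.
#' @slot surfaceComposition named numeric, percent polar/nonpolar/charged.
#' @slot interfaceResidues data.frame (`chain`, `resno`, `insert`, `resname`,
#'   `delta_asa`).
#' @slot dimensions numeric 3-vector, x/y/z extents in A.
#' @slot counts named numeric (`hbonds`, `salt_bridges`).
#' @slot flags character vector of caveats (e.g. empty interface).
#' @aliases InterfaceReport-class
#' @exportClass InterfaceReport
setClass("InterfaceReport",
         representation(interfaceASA = "numeric",
                        interfaceASAPercent = "numeric",
                        interfaceComposition = "numeric",
                        hbondsPer100A2 = "numeric",
                        saltBridgesPer100A2 = "numeric",
                        surfaceComposition = "numeric",
                        interfaceResidues = "data.frame",
                        dimensions = "numeric",
                        counts = "numeric",
                        flags = "character"))

setValidity("InterfaceReport", function(object) {
  if (object@interfaceASA < -1e-6) return("interface ASA must be >= 0")
  for (comp in list(object@interfaceComposition, object@surfaceComposition)) {
    if (length(comp) && sum(comp) > 0 && abs(sum(comp) - 100) > 0.1)
      return("composition percentages must sum to 100 +/- 0.1")
  }
  if (object@hbondsPer100A2 < 0 || object@saltBridgesPer100A2 < 0)
    return("densities must be >= 0")
  TRUE
})
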