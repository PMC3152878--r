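## Residue chemistry tables.
##
## The classification scheme (His charged, Gly polar), side-chain formal
## charges and vdW radii ship as versioned plain-text tables under
## inst/extdata and are parsed once per session.

.chem_cache <- new.env(parent = emptyenv())

.chem_table <- function(name) {
  if (!exists(name, envir = .chem_cache)) {
    path <- system.file("extdata", paste0(name, "_v1.tsv"), package = "coilDock")
    if (path == "") {
      ## during in-source development (pkgload) system.file resolves anyway;
      ## this branch only guards a broken installation
      stop("chemistry table '", name, "' not found in installed package")
    }
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    assign(name, tab, envir = .chem_cache)
  }
  get(name, envir = .chem_cache)
}

#' Standard amino-acid identities
#'
#' @return Character vector of the 20 standard three-letter residue codes.
#' @export
standardResidues <- function() .chem_table("residue_chemistry")$resname

#' One-letter codes for the 20 standard residues
#'
#' @return Named character vector mapping three-letter to one-letter codes.
#' @export
residueOneLetter <- function() {
  tab <- .chem_table("residue_chemistry")
  stats::setNames(tab$one_letter, tab$resname)
}

.one_to_three <- function(x) {
  map <- stats::setNames(names(residueOneLetter()), residueOneLetter())
  out <- map[toupper(x)]
  if (anyNA(out)) stop("unknown one-letter residue code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Classify a residue as polar, nonpolar or charged
#'
#' The scheme is the package's declared convention (the three classes used in
#' interface/surface composition tables): charged = Asp, Glu, Lys, Arg, His;
#' polar = Ser, Thr, Asn, Gln, Tyr, Cys, Trp, Gly; nonpolar = Ala, Val, Leu,
#' Ile, Pro, Phe, Met. Alternative schemes are one edit of the shipped
#' `residue_chemistry` table.
#'
#' @param resname Character vector of three-letter residue codes.
#' @return Character vector in `c("polar", "nonpolar", "charged")`.
#'   Non-standard codes fall back to `"nonpolar"` with a warning.
#' @examples
#' classifyResidue(c("LEU", "ARG", "SER"))
#' @export
classifyResidue <- function(resname) {
  tab <- .chem_table("residue_chemistry")
  cls <- tab$polarity[match(toupper(resname), tab$resname)]
  if (anyNA(cls)) {
    warning("non-standard residue code(s) classified as nonpolar: ",
            paste(unique(resname[is.na(cls)]), collapse = ", "))
    cls[is.na(cls)] <- "nonpolar"
  }
  cls
}

#' Maximum accessible surface area per residue type
#'
#' Theoretical Gly-X-Gly maxima, used as the denominator of relative
#' side-chain exposure.
#'
#' @return Named numeric vector (\eqn{\mathrm{\AA}^2}) keyed by residue code.
#' @export
maxResidueSASA <- function() {
  tab <- .chem_table("residue_chemistry")
  stats::setNames(tab$max_sasa, tab$resname)
}

#' Van der Waals radii by element
#'
#' Single declared table (C 1.70, N 1.55, O 1.52, S 1.80 A) used consistently
#' by the SASA, contact and grid code. Unknown elements default to 1.70 A.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(element) {
  tab <- .chem_table("vdw_radii")
  r <- tab$radius[match(toupper(element), tab$element)]
  r[is.na(r)] <- 1.70
  r
}

#' Formally charged side-chain atoms of a residue
#'
#' Assigns formal charge signs at atom level: Asp OD1/OD2 and Glu OE1/OE2
#' negative; Lys NZ, Arg NE/NH1/NH2 and both His ring nitrogens positive.
#' Chain-terminal N/OXT are neutral unless `include_termini` is set.
#'
#' @param residue Data frame of atom records for a single residue (columns
#'   `resname`, `atom` at minimum), e.g. one block of [atomTable()].
#' @param include_termini Logical; treat backbone N as positive and OXT as
#'   negative (default `FALSE`).
#' @return Data frame with columns `atom` and `sign` (`"+"`/`"-"`); zero rows
#'   when the residue carries no formal charge.
#' @examples
#' glu <- data.frame(resname = "GLU", atom = c("N", "CA", "CB", "OE1", "OE2"))
#' chargedAtoms(glu)
#' @export
chargedAtoms <- function(residue, include_termini = FALSE) {
  stopifnot(is.data.frame(residue), all(c("resname", "atom") %in% names(residue)))
  tab <- .chem_table("charged_atoms")
  key <- paste(toupper(residue$resname), toupper(residue$atom))
  hit <- match(key, paste(tab$resname, tab$atom))
  out <- data.frame(atom = residue$atom[!is.na(hit)],
                    sign = tab$sign[hit[!is.na(hit)]],
                    stringsAsFactors = FALSE)
  if (include_termini) {
    if (any(residue$atom == "OXT"))
      out <- rbind(out, data.frame(atom = "OXT", sign = "-"))
  }
  out
}

## vectorised charge signs for a whole atom table ("+", "-" or "0")
.atom_charge_signs <- function(atoms, include_termini = FALSE) {
  tab <- .chem_table("charged_atoms")
  hit <- match(paste(toupper(atoms$resname), toupper(atoms$atom)),
               paste(tab$resname, tab$atom))
  sign <- ifelse(is.na(hit), "0", tab$sign[hit])
  if (include_termini) sign[atoms$atom == "OXT"] <- "-"
  sign
}

## hydrogen-bond donor / acceptor typing (heavy atoms only).
## donors: backbone N plus side-chain N/O-H groups; acceptors: all oxygens
## plus His ring nitrogens.
.hbond_donor_atoms <- function(atoms) {
  res <- toupper(atoms$resname); at <- toupper(atoms$atom)
  at == "N" |
    (res == "ARG" & at %in% c("NE", "NH1", "NH2")) |
    (res == "LYS" & at == "NZ") |
    (res == "ASN" & at == "ND2") |
    (res == "GLN" & at == "NE2") |
    (res == "HIS" & at %in% c("ND1", "NE2")) |
    (res == "TRP" & at == "NE1") |
    (res == "SER" & at == "OG") |
    (res == "THR" & at == "OG1") |
    (res == "TYR" & at == "OH")
}

.hbond_acceptor_atoms <- function(atoms) {
  res <- toupper(atoms$resname); at <- toupper(atoms$atom)
  atoms$element == "O" |
    (res == "HIS" & at %in% c("ND1", "NE2"))
}
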