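## PDB and FASTA input/output.
##
## Reading wraps bio3d's parser; the writer emits the fixed-column ATOM/TER/END
## subset directly so the layout contract (3-decimal coordinates, one TER per
## chain, END terminator) is guaranteed.

#' Read a PDB file into a Structure
#'
#' HETATM records and waters are excluded; alternate locations are resolved to
#' the highest occupancy (ties to altloc "A"); insertion codes are preserved in
#' residue ordering; hydrogens are dropped (all downstream geometry is
#' heavy-atom based).
#'
#' @param path Path to a PDB file.
#' @param model_index 0-based index of the MODEL to read (default 0, the
#'   first).
#' @return A [Structure-class] object.
#' @examples
#' f <- system.file("extdata", "toy_ala.pdb", package = "coilDock")
#' readPDB(f)
#' @export
readPDB <- function(path, model_index = 0L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  a <- pdb$atom
  keep <- a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) stop("no ATOM records in ", path)
  a <- a[keep, , drop = FALSE]
  n_models <- nrow(pdb$xyz)
  if (model_index < 0 || model_index >= n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  if (n_models > 1) {
    xyz <- matrix(pdb$xyz[model_index + 1L, ], ncol = 3, byrow = TRUE)
    xyz <- xyz[keep, , drop = FALSE]
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  ## altloc: keep highest occupancy, ties to 'A'
  if (any(!is.na(a$alt))) {
    alt <- ifelse(is.na(a$alt), "", a$alt)
    occ <- ifelse(is.na(a$o), 1, a$o)
    key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert), a$elety)
    pref <- order(-occ, alt != "A", alt)        # best candidate first
    keep_idx <- sort(pref[!duplicated(key[pref])])
    a <- a[keep_idx, , drop = FALSE]
  }
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 substr(gsub("^[0-9]*", "", a$elety), 1, 1), a$elesy)
  drop_h <- toupper(elem) == "H" | toupper(elem) == "D"
  a <- a[!drop_h, , drop = FALSE]; elem <- elem[!drop_h]
  unknown <- setdiff(unique(a$resid), standardResidues())
  if (length(unknown))
    warning("non-standard residue name(s) retained with nonpolar fallback: ",
            paste(unknown, collapse = ", "))
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  Structure(data.frame(chain = chain, resno = a$resno,
                       insert = ifelse(is.na(a$insert), "", a$insert),
                       resname = a$resid, atom = a$elety,
                       element = toupper(elem),
                       x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
            metadata = c(source = normalizePath(path),
                         model = as.character(model_index)))
}

#' Write a Structure as a PDB file
#'
#' Emits fixed-column ATOM records with coordinates to three decimals, a TER
#' record after every chain, and a final END.
#'
#' @param structure A [Structure-class] object.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
writePDB <- function(structure, path) {
  a <- atomTable(structure)
  if (!nrow(a)) stop("cannot write an empty structure")
  if (any(a$resno > 9999))
    stop("chain numbering exceeds 9999; PDB fixed columns cannot represent it")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in chainIds(structure)) {
    blk <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(blk))) {
      serial <- serial + 1L
      name <- blk$atom[i]
      ## PDB convention: atom names of <4 chars start in column 14
      name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
      writeLines(sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name_f, "", blk$resname[i], ch, blk$resno[i],
        blk$insert[i], blk$x[i], blk$y[i], blk$z[i], 1, 0,
        blk$element[i]), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %3s %1s%4d%1s", serial %% 100000L,
                       blk$resname[nrow(blk)], ch, blk$resno[nrow(blk)],
                       blk$insert[nrow(blk)]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read chain sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of one-letter sequences.
#' @export
readFastaChains <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
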