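## Heptad register assignment.

#' Assign a heptad register to a sequence
#'
#' Anchors (1-based indices known to occupy position *a*) must be mutually
#' congruent modulo 7; all other positions follow cyclically a-b-...-g-a. With
#' no anchors the frame maximising the count of core hydrophobics (Leu, Ile,
#' Val, Met) at positions *a* and *d* is chosen (ties to the earliest frame).
#'
#' @param sequence One-letter amino-acid string.
#' @param anchor_positions Optional integer vector of 1-based *a* positions.
#' @return Character string of heptad letters, same length as `sequence`.
#' @examples
#' assignRegister("LAAAAAALAAAAAAL", anchor_positions = 1)
#' @export
assignRegister <- function(sequence, anchor_positions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  n <- nchar(sequence)
  if (!is.null(anchor_positions)) {
    anchor_positions <- as.integer(anchor_positions)
    stopifnot(all(anchor_positions >= 1), all(anchor_positions <= n))
    if (length(unique(anchor_positions %% 7L)) > 1)
      stop("register conflict: anchor positions are not congruent modulo 7")
    ## position i gets heptad index (i - a0) mod 7
    a0 <- anchor_positions[1]
    idx <- (seq_len(n) - a0) %% 7L
    return(paste(letters[idx + 1L], collapse = ""))
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  core <- aa %in% c("L", "I", "V", "M")
  best_k <- 0L; best_count <- -1L
  for (k in 0:6) {
    idx <- (seq_len(n) - 1L + k) %% 7L        # 0 = a, 3 = d
    count <- sum(core & idx %in% c(0L, 3L))
    if (count > best_count) { best_count <- count; best_k <- k }
  }
  idx <- (seq_len(n) - 1L + best_k) %% 7L
  paste(letters[idx + 1L], collapse = "")
}

## 0-based heptad indices (a=0 .. g=6) of a register string
.heptad_index <- function(register) {
  match(strsplit(register, "")[[1]], letters[1:7]) - 1L
}
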