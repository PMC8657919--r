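#' Amino-acid alphabet used throughout the package
#'
#' The 21-symbol alphabet: the 20 standard amino acids in alphabetical
#' one-letter order, plus a single shared symbol \code{"-"} for
#' unknown/gap/padding. Non-standard residues (B, Z, U, O, X, J) all map to
#' the 21st symbol.
#'
#' @format Character vector of length 21.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","-")

#' Number of alphabet states (20 amino acids + gap/unknown)
#' @export
N_STATES <- 21L

# fast lookup: char code -> state index 1..21 (gap and anything unknown -> 21)
.aa_index_table <- local({
  tab <- rep(21L, 256L)
  for (i in 1:20) tab[utf8ToInt(AA_ALPHABET[i]) + 1L] <- i
  tab
})

#' Encode a sequence string as integer states
#'
#' @param s character scalar over the alignment alphabet.
#' @return integer vector of states in 1..21 (21 = gap/unknown).
#' @export
encode_sequence <- function(s) {
  .aa_index_table[utf8ToInt(s) + 1L]
}

#' Decode integer states back to a sequence string
#' @param idx integer vector of states in 1..21.
#' @return character scalar.
#' @export
decode_sequence <- function(idx) {
  paste(AA_ALPHABET[idx], collapse = "")
}
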