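#' Amino-acid alphabet used for integer encoding
#'
#' Alignment cells are stored as integers: `0` for a gap (or any ambiguity
#' code) and `1`--`20` for the twenty standard amino acids in alphabetical
#' one-letter order, i.e. `A = 1, C = 2, D = 3, ..., Y = 20`.
#'
#' @return Character vector of length 20 giving the one-letter codes in
#'   encoding order, so `aa_alphabet()[k]` is the residue encoded as `k`.
#' @examples
#' aa_alphabet()
#' match("W", aa_alphabet())  # tryptophan -> 19
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# characters mapped to 0 alongside the plain gap characters '-' and '.':
# ambiguity codes (B, Z, X, J), rare residues (U, O) and alignment
# terminators ('*').
.gap_chars <- c("-", ".", "*", "B", "Z", "X", "J", "U", "O")

#' Encode aligned sequences as an integer matrix
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return integer matrix (sequences x columns) with values in 0..20.
#' @keywords internal
encode_sequences <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to encode", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length", call. = FALSE)
  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  code <- match(chars, aa_alphabet())
  code[is.na(code)] <- 0L
  unknown <- setdiff(unique(as.vector(chars)),
                     c(aa_alphabet(), .gap_chars))
  if (length(unknown) > 0L)
    warning("unrecognised characters encoded as gap: ",
            paste(unknown, collapse = " "), call. = FALSE)
  matrix(as.integer(code), nrow = length(seqs))
}

#' Decode an integer alignment matrix back to character sequences
#'
#' Gaps (and any character originally encoded to 0) decode to `"-"`.
#'
#' @param mat integer matrix with values in 0..20.
#' @return character vector of sequences.
#' @keywords internal
decode_sequences <- function(mat) {
  letters20 <- c("-", aa_alphabet())
  apply(mat, 1L, function(row) paste(letters20[row + 1L], collapse = ""))
}
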