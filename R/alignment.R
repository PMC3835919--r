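#' Construct an integer-encoded multiple sequence alignment
#'
#' The central container of the package: an S x L integer matrix (0 = gap,
#' 1--20 = amino acids, see [aa_alphabet()]) together with sequence
#' identifiers and, optionally, a template row used to label alignment
#' columns with residue numbers of a reference structure.
#'
#' @param mat integer matrix, sequences in rows, alignment columns in
#'   columns; entries must lie in `0:20`.
#' @param seq_ids character vector of sequence identifiers (rownames of
#'   `mat` are used when `NULL`).
#' @param template sequence id or row index of the template sequence, or
#'   `NULL` for no template mapping.
#' @param numbering optional data frame `(column, residue_number,
#'   residue_code)` overriding the default template numbering, e.g. for
#'   chymotrypsin-style numbering (57H, 102D, 195S).
#' @return object of class `"msa"`: list with elements `seq_ids`, `matrix`,
#'   `template_index`, `column_to_residue`.
#' @seealso [read_alignment()] to build one from a FASTA/Clustal file.
#' @export
msa <- function(mat, seq_ids = NULL, template = NULL, numbering = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("alignment needs at least 2 sequences and 2 columns", call. = FALSE)
  if (anyNA(mat) || any(mat < 0L) || any(mat > 20L))
    stop("alignment entries must be integers in 0..20", call. = FALSE)
  if (is.null(seq_ids)) seq_ids <- rownames(mat)
  if (is.null(seq_ids)) seq_ids <- sprintf("seq%04d", seq_len(nrow(mat)))
  if (length(seq_ids) != nrow(mat))
    stop("seq_ids length does not match number of sequences", call. = FALSE)
  dimnames(mat) <- NULL

  template_index <- NULL
  if (!is.null(template)) {
    template_index <- if (is.character(template)) {
      match(template, seq_ids)
    } else {
      as.integer(template)
    }
    if (is.na(template_index) || template_index < 1L ||
        template_index > nrow(mat))
      stop("template sequence not found in alignment", call. = FALSE)
  }

  al <- structure(
    list(seq_ids = as.character(seq_ids), matrix = mat,
         template_index = template_index, column_to_residue = NULL),
    class = "msa")
  if (!is.null(numbering)) {
    al$column_to_residue <- .check_numbering(numbering, ncol(mat))
  } else if (!is.null(template_index)) {
    al$column_to_residue <- .template_numbering(mat, template_index)
  }
  if (any(colSums(mat > 0L) == 0L))
    warning("alignment contains all-gap column(s)", call. = FALSE)
  al
}

# default numbering: walk the template row, count non-gap residues 1-based
.template_numbering <- function(mat, template_index) {
  trow <- mat[template_index, ]
  nongap <- which(trow > 0L)
  data.frame(
    column = nongap,
    residue_number = seq_along(nongap),
    residue_code = aa_alphabet()[trow[nongap]],
    stringsAsFactors = FALSE)
}

.check_numbering <- function(numbering, L) {
  numbering <- as.data.frame(numbering)
  need <- c("column", "residue_number", "residue_code")
  if (!all(need %in% names(numbering)))
    stop("numbering table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  numbering <- numbering[order(numbering$column), need]
  if (any(numbering$column < 1L) || any(numbering$column > L))
    stop("numbering refers to columns outside the alignment", call. = FALSE)
  if (any(diff(numbering$residue_number) <= 0))
    stop("residue numbers must be strictly increasing", call. = FALSE)
  numbering
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$template_index))
    cat(sprintf("  template: %s (%d mapped columns)\n",
                x$seq_ids[x$template_index], nrow(x$column_to_residue)))
  gapfrac <- mean(x$matrix == 0L)
  cat(sprintf("  gap fraction: %.3f\n", gapfrac))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$matrix)

#' Read a multiple sequence alignment from FASTA or Clustal
#'
#' Parses the file with [Biostrings::readAAMultipleAlignment()] and encodes
#' it numerically. Ambiguity codes (B, Z, X, J, U, O) and the gap characters
#' `-`, `.`, `*` all encode to 0; anything else is encoded to 0 with a
#' warning. Sequence order is preserved.
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"clustal"`.
#' @param template,numbering passed to [msa()].
#' @return an [msa()] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "ACDG", ">s3", "AC-G"), fa)
#' al <- read_alignment(fa, template = "s1")
#' al$column_to_residue
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           template = NULL, numbering = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    format <- if (startsWith(first[[1L]], ">")) "fasta" else "clustal"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  seqs <- as.character(Biostrings::unmasked(aln))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(seqs))
  # first token of the FASTA description line, as most tools use
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1L), 1L)
  msa(encode_sequences(unname(seqs)), seq_ids = ids,
      template = template, numbering = numbering)
}

#' Write an alignment to FASTA
#'
#' @param al an [msa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(al, path) {
  stopifnot(inherits(al, "msa"))
  seqs <- decode_sequences(al$matrix)
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", al$seq_ids)
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}
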