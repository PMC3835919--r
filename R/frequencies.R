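#' Single-site, joint and background amino-acid frequencies
#'
#' Counts residue frequencies in an integer-encoded alignment: `f1[i, a]` is
#' the frequency of amino acid `a` at column `i`, `f2[i, j, a, b]` the joint
#' frequency of `a` at `i` and `b` at `j`, and `q[a]` the background
#' frequency of `a` pooled over the whole alignment.
#'
#' Gaps never contribute to an amino-acid count. Under the default
#' `gap_denominator = "full"` convention the denominator is the total number
#' of sequences S, so `sum(f1[i, ])` equals the non-gap fraction of column
#' `i` (and 1 only for gap-free columns). With `"nongap"` the per-column
#' (and, for `f2`, per-column-pair) non-gap counts are used instead.
#'
#' @param al an [msa()] object.
#' @param joint compute the L x L x 20 x 20 joint-frequency array? This is
#'   `400 * L^2` doubles; disable for large alignments when only `f1`/`q`
#'   are needed.
#' @param background optional externally supplied background frequencies
#'   (length-20, positive; normalised internally). Default: pooled residue
#'   counts of `al` divided by its total non-gap residue count.
#' @param gap_denominator `"full"` (denominator S, default) or `"nongap"`.
#' @return object of class `"freq_model"`: list with `f1` (L x 20), `f2`
#'   (L x L x 20 x 20 or `NULL`), `q` (length 20), `n_seq`, and the
#'   convention used.
#' @examples
#' al <- msa(rbind(c(1, 3), c(1, 3), c(1, 4), c(1, 4)))
#' fm <- frequencies(al)
#' fm$f1[1, 1]        # column 1 is all 'A': frequency 1
#' fm$f2[1, 2, 1, 3]  # P(A at 1 and D at 2) = 0.5
#' @export
frequencies <- function(al, joint = TRUE, background = NULL,
                        gap_denominator = c("full", "nongap")) {
  stopifnot(inherits(al, "msa"))
  gap_denominator <- match.arg(gap_denominator)
  mat <- al$matrix
  S <- nrow(mat)
  L <- ncol(mat)

  Z <- .onehot(mat)                       # sparse S x 20L indicator
  counts1 <- matrix(Matrix::colSums(Z), nrow = L, ncol = 20L, byrow = TRUE)
  nongap <- rowSums(counts1)              # per-column non-gap counts

  if (gap_denominator == "full") {
    f1 <- counts1 / S
  } else {
    denom <- ifelse(nongap > 0, nongap, 1)
    f1 <- counts1 / denom
  }

  if (is.null(background)) {
    total <- sum(counts1)
    if (total == 0) stop("alignment has no residues", call. = FALSE)
    q <- colSums(counts1) / total
  } else {
    if (length(background) != 20L || any(background <= 0))
      stop("background must be 20 positive frequencies", call. = FALSE)
    q <- background / sum(background)
  }

  f2 <- NULL
  if (joint) {
    N <- as.matrix(Matrix::crossprod(Z))  # 20L x 20L pair counts
    if (gap_denominator == "full") {
      f2 <- N / S
    } else {
      B <- mat > 0L
      npair <- crossprod(B)               # L x L pairwise non-gap counts
      npair[npair == 0] <- 1
      denom <- npair[rep(seq_len(L), each = 20L), rep(seq_len(L), each = 20L)]
      f2 <- N / denom
    }
    # reorder (a within i, b within j) -> [i, j, a, b]
    f2 <- aperm(array(f2, dim = c(20L, L, 20L, L)), c(2L, 4L, 1L, 3L))
  }

  structure(list(f1 = f1, f2 = f2, q = q, n_seq = S,
                 gap_denominator = gap_denominator),
            class = "freq_model")
}

# sparse one-hot expansion of an integer alignment matrix: S x 20L with a 1
# in column (i-1)*20 + a when sequence s carries amino acid a at column i.
.onehot <- function(mat) {
  S <- nrow(mat)
  L <- ncol(mat)
  idx <- which(mat > 0L)
  s <- ((idx - 1L) %% S) + 1L
  i <- ((idx - 1L) %/% S) + 1L
  a <- mat[idx]
  Matrix::sparseMatrix(i = s, j = (i - 1L) * 20L + a, x = 1,
                       dims = c(S, 20L * L))
}
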