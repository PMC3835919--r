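#' Per-amino-acid covariance tensor between alignment columns
#'
#' `C[i, j, a, b] = f2[i, j, a, b] - f1[i, a] * f1[j, b]`: the covariance of
#' the indicator "amino acid a at column i" with "amino acid b at column j".
#' Diagonal blocks (`i == j`) are computed too but carry no coevolution
#' signal and are excluded downstream.
#'
#' @param fm a [frequencies()] model with the joint array present.
#' @return object of class `"coupling"`: list with the tensor `C`
#'   (L x L x 20 x 20), and `phi`/`W` slots (`NULL` until
#'   [weight_and_reduce()] fills them).
#' @export
covariance_tensor <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  if (is.null(fm$f2))
    stop("frequency model lacks joint frequencies; ",
         "rerun frequencies() with joint = TRUE", call. = FALSE)
  L <- nrow(fm$f1)
  P <- outer(fm$f1, fm$f1)                # [i, a, j, b]
  C <- fm$f2 - aperm(P, c(1L, 3L, 2L, 4L))
  structure(list(C = C, phi = NULL, W = NULL, fm = fm), class = "coupling")
}

#' Conservation weight for one site/amino-acid frequency
#'
#' The log-odds of observing frequency `f` at a site against background `q`:
#' `phi = ln[f (1 - q) / ((1 - f) q)]`. Frequencies are clamped to
#' `[eps, 1 - eps]` so the weight stays finite at fully conserved or absent
#' residues. Isolated so an alternative weighting can be swapped in.
#'
#' @param f frequency (vector or L x 20 matrix).
#' @param q background frequency, recycled along the amino-acid dimension.
#' @param eps clamp; the default used by the pipeline is `1/(2S)`.
#' @return weights, same shape as `f`.
#' @export
conservation_weight <- function(f, q, eps) {
  f <- pmin(pmax(f, eps), 1 - eps)
  if (is.matrix(f)) q <- matrix(q, nrow(f), 20L, byrow = TRUE)
  log(f * (1 - q) / ((1 - f) * q))
}

# Frobenius reduction over the amino-acid dimensions; isolated like the
# weight so alternates (e.g. spectral norm) can be swapped.
.reduce_frobenius <- function(Ct) sqrt(apply(Ct^2, c(1L, 2L), sum))

#' Weight the covariance tensor and reduce it to a site-coupling matrix
#'
#' Applies the conservation weight multiplicatively,
#' `Ct[i,j,a,b] = phi[i,a] * phi[j,b] * C[i,j,a,b]`, then collapses the two
#' amino-acid dimensions by the Frobenius norm:
#' `W[i, j] = sqrt(sum_ab Ct[i,j,a,b]^2)`. The diagonal is set to zero
#' (self-coupling is not a coevolution signal).
#'
#' @param cm a [covariance_tensor()] result.
#' @param fm the matching frequency model (defaults to the one stored in
#'   `cm`).
#' @param eps clamp for the weight; default `1/(2S)`.
#' @return `cm` with `phi` (L x 20) and the symmetric nonnegative `W`
#'   (L x L) filled in.
#' @seealso [weighted_correlation()] for the equivalent single-call fast
#'   path used on large alignments.
#' @export
weight_and_reduce <- function(cm, fm = cm$fm, eps = NULL) {
  stopifnot(inherits(cm, "coupling"), inherits(fm, "freq_model"))
  if (is.null(eps)) eps <- 1 / (2 * fm$n_seq)
  qc <- pmin(pmax(fm$q, .Machine$double.xmin), 1 - .Machine$double.eps)
  phi <- conservation_weight(fm$f1, qc, eps)
  L <- nrow(phi)
  Wphi <- outer(phi, phi)                 # [i, a, j, b]
  Ct <- cm$C * aperm(Wphi, c(1L, 3L, 2L, 4L))
  W <- .reduce_frobenius(Ct)
  diag(W) <- 0
  cm$phi <- phi
  cm$W <- W
  cm
}

#' Weighted site-coupling matrix, computed directly from an alignment
#'
#' Single-call equivalent of
#' `weight_and_reduce(covariance_tensor(frequencies(al)))` that never
#' materialises the L x L x 20 x 20 tensor. Writing `w = phi^2`, the squared
#' coupling expands into three sums over amino acids,
#' `W^2 = T1 - 2 T2 + T3` with
#' `T1 = sum_ab w_ia w_jb f2^2`, `T2 = sum_ab (w f1)_ia f2 (w f1)_jb`,
#' `T3 = (sum_a w_ia f1_ia^2)(sum_b w_jb f1_jb^2)`,
#' each of which reduces to a (sparse) crossproduct. Used by the pipeline
#' and by the shuffle null, where it is evaluated hundreds of times.
#'
#' Only the default `gap_denominator = "full"` counting convention is
#' supported here; use the tensor route for the `"nongap"` convention.
#'
#' @param al an [msa()] object.
#' @param background optional background frequencies `q` to use instead of
#'   the alignment's pooled counts (used by the shuffle null to keep the
#'   weighting identical to the observed matrix).
#' @param eps weight clamp, default `1/(2S)`.
#' @return symmetric L x L matrix `W` with zero diagonal.
#' @export
weighted_correlation <- function(al, background = NULL, eps = NULL) {
  stopifnot(inherits(al, "msa"))
  mat <- al$matrix
  S <- nrow(mat)
  L <- ncol(mat)
  if (is.null(eps)) eps <- 1 / (2 * S)

  Z <- .onehot(mat)
  counts1 <- matrix(Matrix::colSums(Z), nrow = L, ncol = 20L, byrow = TRUE)
  f1 <- counts1 / S
  q <- if (is.null(background)) {
    colSums(counts1) / sum(counts1)
  } else {
    background / sum(background)
  }
  # clamped q for sites where an amino acid is absent everywhere: the weight
  # formula needs q > 0; an absent amino acid gets clamped f anyway.
  qc <- pmin(pmax(q, .Machine$double.xmin), 1 - .Machine$double.eps)
  phi <- conservation_weight(f1, qc, eps)

  w <- phi^2                              # L x 20
  wvec <- as.vector(t(w))                 # ordered a within i, matching Z

  # T1: elementwise-squared joint frequencies, weighted, block-summed
  P <- Matrix::crossprod(Z) / S           # sparse 20L x 20L
  M <- P
  M@x <- M@x^2
  M <- Matrix::Diagonal(x = wvec) %*% M %*% Matrix::Diagonal(x = wvec)
  K <- Matrix::sparseMatrix(i = seq_len(20L * L),
                            j = rep(seq_len(L), each = 20L), x = 1)
  T1 <- as.matrix(Matrix::crossprod(K, M %*% K))

  # T2: A[s, i] = (w * f1)[i, residue of s at i]
  u <- w * f1
  A <- matrix(0, S, L)
  idx <- which(mat > 0L)
  cols <- ((idx - 1L) %/% S) + 1L
  A[idx] <- u[cbind(cols, mat[idx])]
  T2 <- crossprod(A) / S

  # T3: rank-one in the per-site scalar v
  v <- rowSums(w * f1^2)
  T3 <- outer(v, v)

  W <- sqrt(pmax(T1 - 2 * T2 + T3, 0))
  diag(W) <- 0
  W
}

#' Remove noise sites from a coupling matrix
#'
#' A noise site is a column weakly coupled to almost all others. For each
#' site `i`, `Rmax(i)` is the mean of its `ceil(top_fraction * (L - 1))`
#' largest off-diagonal couplings; `plus` is the mean of `Rmax` over all
#' sites. Sites with `Rmax(i) <= factor * plus` are removed (ties at the
#' boundary are removed, as the rule is stated).
#'
#' @param W symmetric coupling matrix with zero diagonal.
#' @param top_fraction fraction of the `L - 1` neighbours averaged into
#'   `Rmax` (default 0.05, i.e. the top 5 percent).
#' @param factor multiplier on `plus` defining the removal threshold
#'   (default 0.8).
#' @return object of class `"noise_reduction"`: list with `rmax`, `plus`,
#'   `kept`, `removed` (both ordered, original column indices) and
#'   `W_reduced`.
#' @examples
#' W <- matrix(0.05, 10, 10); diag(W) <- 0
#' W[1:3, 1:3] <- 0.9; diag(W) <- 0
#' noise_filter(W)$kept
#' @export
noise_filter <- function(W, top_fraction = 0.05, factor = 0.8) {
  W <- as.matrix(W)
  L <- ncol(W)
  if (L < 2L) stop("coupling matrix must have at least 2 sites", call. = FALSE)
  if (!isSymmetric(unname(W), tol = 1e-8))
    stop("coupling matrix must be symmetric", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  n_top <- ceiling(top_fraction * (L - 1L))
  n_top <- max(1L, as.integer(n_top))

  rmax <- vapply(seq_len(L), function(i) {
    nb <- sort(W[i, -i], decreasing = TRUE)
    mean(nb[seq_len(n_top)])
  }, numeric(1L))
  plus <- mean(rmax)
  removed <- which(rmax <= factor * plus)
  kept <- setdiff(seq_len(L), removed)
  if (length(kept) == 0L)
    stop("no signal: every site classified as noise", call. = FALSE)

  structure(list(rmax = rmax, plus = plus, n_top = n_top,
                 kept = kept, removed = removed,
                 factor = factor, top_fraction = top_fraction,
                 W_reduced = W[kept, kept, drop = FALSE]),
            class = "noise_reduction")
}

#' @export
print.noise_reduction <- function(x, ...) {
  cat(sprintf(
    "Noise reduction: %d of %d sites removed (Rmax <= %.3g * plus, plus = %.4f)\n",
    length(x$removed), length(x$kept) + length(x$removed), x$factor, x$plus))
  invisible(x)
}
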