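#' Eigendecompose a symmetric coupling matrix
#'
#' Eigenvalues in descending order with orthonormal eigenvectors; each
#' eigenvector is sign-fixed so its largest-magnitude entry is positive,
#' which makes the downstream bidirectional site selection reproducible.
#'
#' @param W symmetric numeric matrix (typically the noise-reduced coupling
#'   matrix).
#' @return list with `values` (descending) and `vectors` (columns).
#' @export
eigendecompose <- function(W) {
  W <- as.matrix(W)
  if (!isSymmetric(unname(W), tol = 1e-8))
    stop("eigendecompose() requires a symmetric matrix", call. = FALSE)
  if (any(!is.finite(W)))
    stop("coupling matrix contains non-finite entries", call. = FALSE)
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    peak <- which.max(abs(V[, k]))
    if (V[peak, k] < 0) V[, k] <- -V[, k]
  }
  list(values = e$values, vectors = V)
}

#' Null eigenvalue set from column-shuffled alignments
#'
#' Scrambles each column of the original alignment randomly and
#' independently across sequences, recomputes the full covariance ->
#' weight -> reduce pipeline on the shuffled alignment, and collects all
#' its eigenvalues; repeated `n_shuffles` times, giving `n_shuffles * n`
#' null eigenvalues (`n` = number of sites entering the null). Shuffling
#' within columns preserves every single-site frequency (and hence the
#' background `q` and the conservation weights) while destroying
#' between-column correlation.
#'
#' By default the whole alignment is shuffled, so the null spectrum —
#' including the leading "Perron" eigenvalue that any nonnegative coupling
#' matrix carries — comes from all `L` columns, not from the noise-reduced
#' subset. This matters: the noise-reduced observed matrix is built from
#' sites *selected* for strong coupling, and a null restricted to those
#' same sites makes the observed leading eigenvalue exchangeable with the
#' null ones, which would admit one spurious factor on pure-noise data
#' almost surely. See the methods vignette for the argument.
#'
#' @param al the original [msa()] object.
#' @param sites columns of `al` entering the null matrix; `NULL` (default)
#'   uses all of them. Pass the kept-site indices to restrict the null to
#'   the noise-reduced sub-alignment.
#' @param n_shuffles number of shuffled replicates (default 100).
#' @param seed integer seed; the whole null is reproducible from it.
#' @param background optional background frequencies forwarded to
#'   [weighted_correlation()]; `NULL` recomputes `q` from the shuffled
#'   alignment (identical to the original's `q`, since shuffling preserves
#'   column contents).
#' @return numeric vector `E` of length `n_shuffles * n`.
#' @export
null_eigenvalues <- function(al, sites = NULL, n_shuffles = 100L, seed = 1L,
                             background = NULL) {
  stopifnot(inherits(al, "msa"), n_shuffles >= 1L)
  if (is.null(sites)) sites <- seq_len(ncol(al$matrix))
  sub <- al$matrix[, sites, drop = FALSE]
  S <- nrow(sub)
  n <- ncol(sub)
  set.seed(seed)
  E <- numeric(n_shuffles * n)
  shuf <- sub
  for (r in seq_len(n_shuffles)) {
    for (j in seq_len(n)) shuf[, j] <- sub[sample.int(S), j]
    alr <- structure(list(seq_ids = al$seq_ids, matrix = shuf,
                          template_index = NULL, column_to_residue = NULL),
                     class = "msa")
    Wr <- weighted_correlation(alr, background = background)
    E[((r - 1L) * n + 1L):(r * n)] <-
      eigen((Wr + t(Wr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  E
}

#' Number of non-random factors against a null eigenvalue set
#'
#' For each observed eigenvalue `lambda_i` (descending), `N(i)` counts the
#' null eigenvalues strictly greater than it. `N` is non-decreasing in `i`;
#' the retained factor count is the largest `t` with
#' `N(t) < count_threshold`, i.e. the last eigenvalue still exceeded by
#' fewer null eigenvalues than there are shuffled replicates. Returns
#' `t = 0` when even the leading eigenvalue sits inside the null bulk.
#'
#' @param values observed eigenvalues, descending.
#' @param E null eigenvalues from [null_eigenvalues()].
#' @param count_threshold cutoff on `N(i)`; use the number of shuffles
#'   (default 100, matching the default null).
#' @return list with `t`, the counts `N`, and `count_threshold`.
#' @export
select_factors <- function(values, E, count_threshold = 100L) {
  if (length(E) == 0L) stop("empty null eigenvalue set", call. = FALSE)
  if (is.unsorted(rev(values)))
    stop("eigenvalues must be in descending order", call. = FALSE)
  Esort <- sort(E)
  # N(i) = #{e in E : e > lambda_i} via binary search on the sorted null
  N <- length(E) - findInterval(values, Esort)
  t <- if (N[1L] >= count_threshold) 0L else max(which(N < count_threshold))
  list(t = as.integer(t), N = as.integer(N),
       count_threshold = as.integer(count_threshold))
}

# raw varimax criterion: sum over factors of the variance of the squared
# loadings, sum_k [ mean_i b_ik^4 - (mean_i b_ik^2)^2 ]
varimax_criterion <- function(B) {
  sum(apply(B, 2L, function(b) mean(b^4) - mean(b^2)^2))
}

#' Varimax rotation of retained eigenvectors
#'
#' Orthogonally rotates the loading columns to maximise the varimax
#' simplicity criterion (the summed variance of squared loadings), driving
#' each site toward one dominant factor. Classic pairwise (Jacobi) planar
#' rotations, swept until the criterion gain in a full sweep drops below
#' `tol`. Raw varimax by default; `kaiser = TRUE` row-normalises by the
#' communalities before rotating and rescales afterwards.
#'
#' @param V n x t matrix of loading columns (t retained eigenvectors).
#' @param tol convergence tolerance on the criterion gain per sweep.
#' @param max_iter maximum number of sweeps.
#' @param kaiser use Kaiser row normalisation?
#' @return list with `loadings` (`V %*% rotation`), the orthogonal
#'   `rotation` (t x t), the final `criterion`, number of sweeps `iter`,
#'   and `converged`.
#' @export
varimax_rotate <- function(V, tol = 1e-6, max_iter = 1000L, kaiser = FALSE) {
  V <- as.matrix(V)
  n <- nrow(V)
  t <- ncol(V)
  if (t < 1L) stop("need at least one factor to rotate", call. = FALSE)
  if (t == 1L)
    return(list(loadings = V, rotation = diag(1L),
                criterion = varimax_criterion(V), iter = 0L,
                converged = TRUE))

  h <- rep(1, n)
  if (kaiser) {
    h <- sqrt(rowSums(V^2))
    h[h == 0] <- 1
  }
  B <- V / h
  R <- diag(t)
  crit <- varimax_criterion(B)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (k in seq_len(t - 1L)) {
      for (l in (k + 1L):t) {
        x <- B[, k]; y <- B[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        A2 <- sum(u); B2 <- sum(v)
        num <- 2 * sum(u * v) - 2 * A2 * B2 / n
        den <- sum(u^2 - v^2) - (A2^2 - B2^2) / n
        theta <- atan2(num, den) / 4
        if (abs(theta) > 1e-12) {
          G <- matrix(c(cos(theta), -sin(theta),
                        sin(theta),  cos(theta)), 2L, 2L, byrow = TRUE)
          B[, c(k, l)] <- B[, c(k, l)] %*% G
          R[, c(k, l)] <- R[, c(k, l)] %*% G
        }
      }
    }
    newcrit <- varimax_criterion(B)
    if (newcrit - crit < tol) {
      converged <- TRUE
      crit <- newcrit
      break
    }
    crit <- newcrit
  }
  loadings <- (B * h)
  list(loadings = loadings, rotation = R, criterion = varimax_criterion(B),
       iter = iter, converged = converged)
}
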