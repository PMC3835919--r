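# Independent brute-force oracles and small fixtures used across the suite.
# Everything here is written naively (triple loops, explicit enumeration) on
# purpose: it must stay independent of the package's vectorised paths.

# encode a character vector of aligned sequences through the package's
# documented alphabet, but by explicit lookup
toy_msa <- function(seqs, ...) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rows <- lapply(strsplit(seqs, ""), function(ch) {
    v <- match(ch, alpha)
    v[is.na(v)] <- 0L
    as.integer(v)
  })
  msa(do.call(rbind, rows), ...)
}

# naive frequency counts: loops over sequences, full-S denominator
oracle_frequencies <- function(mat) {
  S <- nrow(mat); L <- ncol(mat)
  f1 <- matrix(0, L, 20)
  f2 <- array(0, c(L, L, 20, 20))
  for (i in 1:L) for (a in 1:20) f1[i, a] <- sum(mat[, i] == a) / S
  for (i in 1:L) for (j in 1:L) for (a in 1:20) for (b in 1:20)
    f2[i, j, a, b] <- sum(mat[, i] == a & mat[, j] == b) / S
  q <- rep(0, 20)
  for (a in 1:20) q[a] <- sum(mat == a)
  q <- q / sum(q)
  list(f1 = f1, f2 = f2, q = q)
}

# naive re-implementation of the covariance -> weight -> Frobenius-reduce
# chain: C = f2 - f1 f1, phi = log-odds with clamp eps = 1/(2S), W_ij =
# sqrt(sum_ab (phi_ia phi_jb C_ijab)^2), zero diagonal
oracle_coupling <- function(mat) {
  S <- nrow(mat); L <- ncol(mat)
  fr <- oracle_frequencies(mat)
  eps <- 1 / (2 * S)
  qc <- pmax(fr$q, .Machine$double.xmin)
  phi <- matrix(0, L, 20)
  for (i in 1:L) for (a in 1:20) {
    f <- min(max(fr$f1[i, a], eps), 1 - eps)
    phi[i, a] <- log(f * (1 - qc[a]) / ((1 - f) * qc[a]))
  }
  W <- matrix(0, L, L)
  for (i in 1:L) for (j in 1:L) {
    if (i == j) next
    acc <- 0
    for (a in 1:20) for (b in 1:20) {
      C <- fr$f2[i, j, a, b] - fr$f1[i, a] * fr$f1[j, b]
      acc <- acc + (phi[i, a] * phi[j, b] * C)^2
    }
    W[i, j] <- sqrt(acc)
  }
  W
}

# varimax criterion, written independently
oracle_varimax_criterion <- function(B) {
  tot <- 0
  for (k in seq_len(ncol(B))) {
    b2 <- B[, k]^2
    tot <- tot + mean(b2^2) - mean(b2)^2
  }
  tot
}

# exhaustive planar-rotation search for the 2-factor varimax optimum
oracle_varimax_2d <- function(V, step_deg = 0.1) {
  angles <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  best <- -Inf
  for (th in angles) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    crit <- oracle_varimax_criterion(V %*% R)
    if (crit > best) best <- crit
  }
  best
}

# random small alignment for property tests
random_alignment <- function(S, L, n_states = 20L, gap_rate = 0) {
  mat <- matrix(sample.int(n_states, S * L, replace = TRUE), S, L)
  if (gap_rate > 0) mat[runif(S * L) < gap_rate] <- 0L
  msa(mat)
}
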