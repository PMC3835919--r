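test_that("eigendecomposition satisfies its algebraic contract", {
  expect_equal(eigendecompose(diag(3))$values, rep(1, 3))
  # rank-one: vv' with |v|^2 = 2
  v <- c(1, 1, 0, 0)
  e <- eigendecompose(outer(v, v))
  expect_equal(e$values, c(2, 0, 0, 0))
  # reconstruction of a random symmetric matrix
  set.seed(41)
  M <- crossprod(matrix(rnorm(25), 5))
  e <- eigendecompose(M)
  expect_equal(e$vectors %*% diag(e$values) %*% t(e$vectors), M,
               tolerance = 1e-10)
  expect_true(all(diff(e$values) <= 1e-12))          # descending
  expect_equal(crossprod(e$vectors), diag(5), tolerance = 1e-10)
  # sign convention: largest-magnitude entry positive
  for (k in 1:5) expect_gt(e$vectors[which.max(abs(e$vectors[, k])), k], 0)
  expect_error(eigendecompose(matrix(1:4, 2)), "symmetric")
})

test_that("shuffling an alignment of identical rows changes nothing", {
  al <- toy_msa(rep("ACDEF", 6))
  W <- weighted_correlation(al)
  E <- null_eigenvalues(al, n_shuffles = 1, seed = 3)
  expect_equal(sort(E), sort(eigendecompose(W)$values), tolerance = 1e-10)
})

test_that("null set has n_shuffles * n eigenvalues and is seed-reproducible", {
  set.seed(42)
  al <- random_alignment(20, 8)
  E1 <- null_eigenvalues(al, n_shuffles = 5, seed = 9)
  expect_length(E1, 5L * 8L)
  expect_equal(null_eigenvalues(al, n_shuffles = 5, seed = 9), E1)
  expect_false(isTRUE(all.equal(null_eigenvalues(al, n_shuffles = 5,
                                                 seed = 10), E1)))
  # restricting to a site subset scales |E| accordingly
  expect_length(null_eigenvalues(al, sites = 1:4, n_shuffles = 3, seed = 1),
                12L)
})

test_that("max of the null spectrum is stable across seeds", {
  spec <- synthetic_spec(n_sequences = 200, n_columns = 30,
                         sectors = list(), seed = 8)
  al <- generate_alignment(spec)$alignment
  m1 <- max(null_eigenvalues(al, n_shuffles = 30, seed = 1))
  m2 <- max(null_eigenvalues(al, n_shuffles = 30, seed = 2))
  expect_lt(abs(m1 - m2) / m1, 0.1)
})

test_that("factor count comes from strict null exceedance counts", {
  # lambda_1 above every null value, lambda_2 exceeded by 200 of them
  E <- c(seq(0.5, 1.5, length.out = 200), rep(0.1, 300))
  sel <- select_factors(c(2.0, 0.4, 0.05), E, count_threshold = 100)
  expect_equal(sel$N, c(0L, 200L, 500L))
  expect_equal(sel$t, 1L)
  # all eigenvalues inside the bulk -> t = 0
  expect_equal(select_factors(c(0.05, 0.04), E, 100)$t, 0L)
  # N is non-decreasing for descending eigenvalues
  expect_true(all(diff(sel$N) >= 0L))
  # strict ">": equal values do not count as exceedance
  expect_equal(select_factors(c(0.1), rep(0.1, 150), 100)$t, 1L)
  expect_error(select_factors(c(0.1, 0.2), E), "descending")
})

test_that("varimax leaves a perfectly simple block structure alone", {
  B <- rbind(matrix(c(1, 0), 4, 2, byrow = TRUE),
             matrix(c(0, 1), 4, 2, byrow = TRUE)) / 2
  vr <- varimax_rotate(B)
  expect_equal(abs(vr$rotation), diag(2), tolerance = 1e-6)
  expect_equal(vr$criterion, oracle_varimax_criterion(B), tolerance = 1e-10)
})

test_that("2-factor varimax matches an exhaustive rotation-angle search", {
  set.seed(43)
  for (rep in 1:4) {
    V <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
    vr <- varimax_rotate(V, tol = 1e-10)
    expect_true(vr$converged)
    expect_equal(vr$criterion, oracle_varimax_2d(V), tolerance = 1e-4)
    # orthogonality of the rotation
    expect_equal(crossprod(vr$rotation), diag(2), tolerance = 1e-8)
    # loadings are V R
    expect_equal(vr$loadings, V %*% vr$rotation, tolerance = 1e-12)
  }
})

test_that("rotation preserves communalities and agrees with stats::varimax", {
  set.seed(44)
  V <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  vr <- varimax_rotate(V, tol = 1e-12)
  expect_equal(rowSums(vr$loadings^2), rowSums(V^2), tolerance = 1e-8)
  expect_equal(crossprod(vr$rotation), diag(3), tolerance = 1e-8)
  # independent implementation reaches the same criterion value
  sv <- stats::varimax(V, normalize = FALSE, eps = 1e-10)
  expect_equal(vr$criterion, oracle_varimax_criterion(sv$loadings),
               tolerance = 1e-6)
  # single factor: identity rotation
  v1 <- varimax_rotate(V[, 1, drop = FALSE])
  expect_equal(v1$rotation, diag(1))
})

test_that("bidirectional selection applies the ratio and floor rules", {
  # one factor; two dominant sites
  load1 <- matrix(c(0.9, 0.85, rep(0.05, 18)), ncol = 1)
  ss <- assign_sites(load1, r0 = 0.8, p0 = 0.1, p1 = 0.4)
  expect_length(ss$sectors, 1L)
  expect_equal(ss$sectors[[1]]$sites, c(1L, 2L))
  expect_equal(ss$sectors[[1]]$sign, "+")
  # w = mean of top 50% (ceiling of 20/2 = 10 values)
  w <- mean(sort(load1[, 1], decreasing = TRUE)[1:10])
  r <- load1[, 1] / w
  expect_equal(which((r >= 0.8 & load1[, 1] > 0.1) | load1[, 1] >= 0.4),
               c(1L, 2L))

  # strong negative block is recovered by the negative-sign pass
  load2 <- matrix(c(-0.8, -0.8, -0.75, rep(0.02, 17)), ncol = 1)
  ss2 <- assign_sites(load2)
  signs <- vapply(ss2$sectors, `[[`, character(1), "sign")
  expect_true("-" %in% signs)
  neg <- ss2$sectors[[which(signs == "-")]]
  expect_equal(neg$sites, 1:3)

  # p1 rule admits a site failing the ratio rule
  load3 <- matrix(c(rep(0.9, 10), 0.45, rep(0, 9)), ncol = 1)
  ss3 <- assign_sites(load3, r0 = 0.8, p0 = 0.1, p1 = 0.4)
  expect_true(11L %in% ss3$sectors[[1]]$sites)
})

test_that("degenerate loading patterns are reported, not truncated", {
  # all-equal loadings: r(i) = 1 for every site -> all selected
  ss <- assign_sites(matrix(0.3, 10, 1))
  expect_equal(ss$sectors[[1]]$sites, 1:10)
  # sub-threshold equal loadings: p0 blocks them
  expect_length(assign_sites(matrix(0.05, 10, 1))$sectors, 0L)
  # one-site candidates are discarded by min_size
  load <- matrix(c(0.9, rep(0.01, 19)), ncol = 1)
  expect_length(assign_sites(load)$sectors, 0L)
  expect_length(assign_sites(load, min_size = 1L)$sectors, 1L)
})

test_that("merging follows the hand-traced greedy accretion", {
  # A = {1,2,3}, B = {2,3,4,5}; site 4 couples to {2,3} more than 1 or 5
  W <- matrix(0.01, 6, 6)
  W[4, 2] <- W[2, 4] <- 0.9
  W[4, 3] <- W[3, 4] <- 0.9
  W[1, 2] <- W[2, 1] <- 0.2
  W[5, 2] <- W[2, 5] <- 0.2
  diag(W) <- 0
  ss <- structure(list(sectors = list(
    list(sites = 1:3, source_factor = 1L, sign = "+", merged_from = NULL),
    list(sites = 2:5, source_factor = 2L, sign = "+", merged_from = NULL)),
    thresholds = list()), class = "sector_set")
  merged <- merge_sectors(ss, W)
  expect_length(merged$sectors, 1L)
  # Ssame = {2,3}; greedy adds site 4 (coupling 1.8 beats 0.4 and 0.21);
  # final size = min(3, 4) = 3
  expect_equal(merged$sectors[[1]]$sites, c(2L, 3L, 4L))
  expect_false(is.null(merged$sectors[[1]]$merged_from))
})

test_that("merging edge cases: disjoint, identical, nested, ties", {
  W <- matrix(0.1, 8, 8); diag(W) <- 0
  mk <- function(...) structure(list(sectors = lapply(list(...), function(s)
    list(sites = s, source_factor = 1L, sign = "+", merged_from = NULL)),
    thresholds = list()), class = "sector_set")
  # disjoint: unchanged
  m <- merge_sectors(mk(1:3, 5:7), W)
  expect_equal(sector_sites(m), list(1:3, 5:7))
  # identical: collapses to one copy
  m2 <- merge_sectors(mk(1:3, 1:3), W)
  expect_equal(sector_sites(m2), list(1:3))
  # nested A subset of B: merged = A
  m3 <- merge_sectors(mk(2:4, 1:6), W)
  expect_equal(sector_sites(m3), list(2:4))
  # tie in the coupling sum: lowest column index wins (W constant)
  m4 <- merge_sectors(mk(c(1L, 2L), c(2L, 7L, 8L)), W)
  expect_equal(m4$sectors[[1]]$sites, c(1L, 2L))  # site 1 < 7, 8
  # merged size equals min of the inputs; idempotent
  set.seed(45)
  for (rep in 1:5) {
    a <- sort(sample(8, 4)); b <- sort(sample(8, 5))
    if (length(intersect(a, b)) == 0) next
    Wr <- abs(crossprod(matrix(rnorm(64), 8))); diag(Wr) <- 0
    m5 <- merge_sectors(mk(a, b), Wr)
    expect_equal(length(m5$sectors[[1]]$sites), min(length(a), length(b)))
    expect_equal(merge_sectors(m5, Wr), m5)
  }
})
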