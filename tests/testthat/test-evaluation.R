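test_that("internal correlation: whole-pool sector equals its own baseline", {
  set.seed(51)
  W <- abs(crossprod(matrix(rnorm(100), 10))); diag(W) <- 0
  res <- internal_correlation(W, 1:10, n_random = 50, seed = 2)
  expect_equal(res$observed, res$random_mean)
  expect_equal(res$random_sd, 0)
})

test_that("internal correlation flags planted sectors as significant", {
  sim <- generate_alignment(synthetic_spec(n_sequences = 150,
                                           n_columns = 40,
                                           sectors = list(list(sites = 1:8)),
                                           seed = 21))
  W <- weighted_correlation(sim$alignment)
  res <- internal_correlation(W, 1:8, n_random = 500, seed = 3)
  expect_gt(res$observed, res$random_mean + 4 * res$random_sd)
  expect_lt(res$p_value, 0.01)
})

test_that("internal correlation contract errors", {
  W <- matrix(0.2, 6, 6); diag(W) <- 0
  expect_error(internal_correlation(W, 1L), "at least 2")
  expect_error(internal_correlation(W, 1:4, pool = 1:3), "larger than")
  expect_error(internal_correlation(W, 1:3, n_random = 0), "n_random")
})

test_that("random baseline sd of the mean shrinks roughly as 1/sqrt(n)", {
  set.seed(52)
  W <- abs(crossprod(matrix(rnorm(400), 20))); diag(W) <- 0
  means_small <- vapply(1:30, function(r)
    internal_correlation(W, 1:4, n_random = 20, seed = r)$random_mean,
    numeric(1))
  means_big <- vapply(1:30, function(r)
    internal_correlation(W, 1:4, n_random = 320, seed = 1000 + r)$random_mean,
    numeric(1))
  ratio <- sd(means_small) / sd(means_big)
  expect_gt(ratio, 2)   # expected 4, generous Monte-Carlo band
  expect_lt(ratio, 8)
})

test_that("MDI entropy: single site zero, perfect covariation gives ln 2", {
  al <- toy_msa(rep(c("AD", "CE"), 50))
  expect_equal(as.numeric(mdi_entropy(al, 1L)), 0)
  m <- mdi_entropy(al, c(1L, 2L))
  expect_equal(as.numeric(m), log(2), tolerance = 1e-3)
  expect_true(attr(m, "converged"))
  # GIS contract: fitted marginals matched empirical within tol
  expect_lt(attr(m, "gap"), 1e-6)
})

test_that("independent columns give MDI within the sampling-noise bound", {
  set.seed(53)
  mat <- cbind(sample(1:4, 2000, replace = TRUE),
               sample(5:8, 2000, replace = TRUE))
  m <- mdi_entropy(msa(mat), 1:2)
  # plug-in MI bias ~ (k1-1)(k2-1)/(2S) = 9/4000; generous bound
  expect_lt(as.numeric(m), 0.02)
  expect_gte(as.numeric(m), 0)
})

test_that("GIS route agrees with the closed-form fixed point", {
  set.seed(54)
  al <- random_alignment(60, 3, n_states = 4L)
  gis <- mdi_entropy(al, 1:3)
  cf <- mdi_entropy(al, 1:3, state_cap = 1)   # force the closed form
  expect_equal(attr(gis, "domain"), "product")
  expect_equal(attr(cf, "domain"), "closed_form")
  expect_equal(as.numeric(gis), as.numeric(cf), tolerance = 1e-5)
})

test_that("MDI is invariant to sequence order and nonnegative", {
  set.seed(55)
  al <- random_alignment(40, 4, n_states = 5L, gap_rate = 0.1)
  m1 <- as.numeric(mdi_entropy(al, 1:4))
  alp <- msa(al$matrix[sample(40), ])
  expect_equal(as.numeric(mdi_entropy(alp, 1:4)), m1, tolerance = 1e-9)
  expect_gte(m1, 0)
})

test_that("MDI additivity holds for independent sectors, fails for split ones", {
  spec <- synthetic_spec(n_sequences = 2000, n_columns = 20,
                         sectors = list(list(sites = 1:6, rho = 0.98),
                                        list(sites = 11:16, rho = 0.98)),
                         gap_rate = 0, seed = 23)
  al <- generate_alignment(spec)$alignment
  it <- independence_test(al, 1:6, 11:16, n_random = 0)
  expect_lt(abs(it$additivity_gap), 0.05 * it$mdi_joint)
  # one coupled sector split in two halves: joint exceeds the sum
  it2 <- independence_test(al, 1:3, 4:6, n_random = 0)
  expect_gt(it2$additivity_gap, 4 * abs(it$additivity_gap))
  # empty second sector: joint equals the first exactly
  it3 <- independence_test(al, 1:6, integer(0), n_random = 0)
  expect_equal(it3$mdi_joint, it3$mdi_A)
  expect_error(independence_test(al, 1:6, 6:9), "disjoint")
})

test_that("random re-partitions fall below the joint MDI of coupled sectors", {
  spec <- synthetic_spec(n_sequences = 300, n_columns = 12,
                         sectors = list(list(sites = 1:4, rho = 0.95),
                                        list(sites = 7:10, rho = 0.95)),
                         gap_rate = 0, seed = 24)
  al <- generate_alignment(spec)$alignment
  it <- independence_test(al, 1:4, 7:10, n_random = 30, seed = 6)
  expect_lt(it$random_expectation, it$mdi_joint)
})

test_that("Rate4Site files parse leniently and summarise per sector", {
  r4s <- withr::local_tempfile(fileext = ".res")
  writeLines(c(
    "#Rates were calculated using the expectation of the posterior rate distribution",
    "#POS SEQ  SCORE    QQ-INTERVAL     STD      MSA DATA",
    "1    M    -1.2096  [-1.574,-0.9]   0.29     95/100",
    "2    K     0.8    [0.5,1.1]       0.31     95/100",
    "3    V    -0.4    [-0.6,-0.2]     0.12     94/100",
    "4    L     0.8096  [0.6,1.2]       0.27     93/100",
    "not a rate line"), r4s)
  rates <- read_rate4site(r4s)
  expect_equal(nrow(rates), 4L)
  expect_equal(rates$score, c(-1.2096, 0.8, -0.4, 0.8096))
  expect_error(read_rate4site(r4s, strict = TRUE), "unparseable")

  # normalised file: overall mean 0; per-sector stats by hand
  summ <- rate_summary(rates, list(c(1L, 3L), c(2L, 4L)))
  expect_equal(summ$overall_mean, 0, tolerance = 1e-12)
  expect_equal(summ$per_sector$mean_rate, c(-0.8048, 0.8048))
  expect_equal(summ$per_sector$fraction_negative, c(1, 0))
  # unmatched numbering errors loudly
  expect_error(rate_summary(rates, list(c(1L, 99L))), "99")
})

test_that("rate summary translates alignment columns through a map", {
  rates <- data.frame(pos = c(57L, 102L, 195L), res = c("H", "D", "S"),
                      score = c(-1, -0.5, 1.5))
  map <- data.frame(column = c(3L, 8L, 12L), pos = c(57L, 102L, 195L))
  summ <- rate_summary(rates, list(c(3L, 8L, 12L)), map = map)
  expect_equal(summ$per_sector$mean_rate, 0)
  expect_equal(summ$per_sector$fraction_negative, 2 / 3)
  expect_error(rate_summary(rates, list(5L), map = map), "not in map")
})

test_that("PCA split separates two residue-disjoint sequence clusters", {
  al <- toy_msa(c(rep("AAAA", 5), rep("CCCC", 5)))
  ev <- evolutionary_independence(al, 1:4)
  expect_false(ev$degenerate)
  expect_length(unique(ev$groups[1:5]), 1L)
  expect_length(unique(ev$groups[6:10]), 1L)
  expect_false(ev$groups[1] == ev$groups[10])
})

test_that("PCA split recovers the latent trait behind a planted sector", {
  spec <- synthetic_spec(n_sequences = 200, n_columns = 30,
                         sectors = list(list(sites = 1:10, rho = 0.9)),
                         seed = 25)
  sim <- generate_alignment(spec)
  ev <- evolutionary_independence(sim$alignment, 1:10)
  z <- sim$truth$latent[, 1]
  agree <- max(mean((ev$groups == 1) == (z == 1)),
               mean((ev$groups == 2) == (z == 1)))
  expect_gte(agree, 0.95)
})

test_that("degenerate similarity structures warn and return one group", {
  # all sequences identical on the sector
  al <- toy_msa(c("AAQ", "AAW", "AAY"))
  expect_warning(ev <- evolutionary_independence(al, 1:2), "constant")
  expect_equal(ev$groups, rep(1L, 3))
  expect_true(ev$degenerate)
  # identity-like M: no shared residues anywhere
  al2 <- toy_msa(c("AC", "DE", "FG", "HI"))
  expect_warning(ev2 <- evolutionary_independence(al2, 1:2))
  expect_true(ev2$degenerate)
})

test_that("sensitivity and PPV reproduce hand-computed fixtures", {
  # exact prediction
  r <- sensitivity_ppv(list(1:10), list(1:10))
  expect_equal(r$sensitivity, 100)
  expect_equal(r$ppv, 100)
  # 9 of 10 recovered, one extra site predicted
  r2 <- sensitivity_ppv(list(c(1:9, 11L)), list(1:10))
  expect_equal(r2$sensitivity, 90)
  expect_equal(r2$ppv, 90)
  expect_equal(r2$lost[[1]], 10L)
  # reference split half-half: single-best matching scores 50%
  r3 <- sensitivity_ppv(list(1:5, 6:10), list(1:10))
  expect_equal(r3$sensitivity, 50)
  expect_equal(r3$matched_sector, 1L)    # tie -> earlier sector
  # empty prediction: sensitivity 0, PPV undefined
  r4 <- sensitivity_ppv(list(), list(1:4))
  expect_equal(r4$sensitivity, 0)
  expect_true(is.na(r4$ppv))
  expect_equal(r4$lost[[1]], 1:4)
  # bounds on random cases
  set.seed(56)
  for (rep in 1:5) {
    pred <- list(sort(sample(30, 8)), sort(sample(30, 6)))
    ref <- list(sort(sample(30, 7)))
    r5 <- sensitivity_ppv(pred, ref)
    expect_true(r5$sensitivity >= 0 && r5$sensitivity <= 100)
    expect_true(is.na(r5$ppv) || (r5$ppv >= 0 && r5$ppv <= 100))
  }
})
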