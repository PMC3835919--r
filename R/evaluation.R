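#' Internal correlation of a sector against random site sets
#'
#' Observed statistic: mean off-diagonal coupling over all pairs of sector
#' sites. Baseline: the same statistic over `n_random` random site sets of
#' equal size drawn from `pool` (by default every site of `W`, i.e. the
#' analysed sites). The empirical p-value is the fraction of random draws
#' at least as large as the observed mean.
#'
#' @param W coupling matrix; sector/pool indices index into it.
#' @param sector integer site set, at least 2 sites.
#' @param n_random number of random draws (default 1000).
#' @param seed integer seed for the draws.
#' @param pool candidate sites for the random sets (default: all columns
#'   of `W`).
#' @return list with `observed`, `random_mean`, `random_sd`, `p_value`,
#'   `n_random`.
#' @export
internal_correlation <- function(W, sector, n_random = 1000L, seed = 1L,
                                 pool = seq_len(ncol(W))) {
  W <- as.matrix(W)
  sector <- as.integer(sector)
  if (length(sector) < 2L)
    stop("sector needs at least 2 sites", call. = FALSE)
  if (length(sector) > length(pool))
    stop("sector is larger than the site pool", call. = FALSE)
  if (n_random < 1L)
    stop("n_random must be at least 1", call. = FALSE)
  mean_coupling <- function(sites) {
    sub <- W[sites, sites, drop = FALSE]
    sum(sub) / (length(sites) * (length(sites) - 1L))  # off-diag mean
  }
  observed <- mean_coupling(sector)
  set.seed(seed)
  draws <- vapply(seq_len(n_random), function(r) {
    mean_coupling(sample(pool, length(sector)))
  }, numeric(1L))
  list(observed = observed, random_mean = mean(draws),
       random_sd = stats::sd(draws),
       p_value = mean(draws >= observed), n_random = as.integer(n_random))
}

#' MDI entropy of a group of alignment columns
#'
#' Minimal-discriminant-information entropy: the Kullback--Leibler
#' divergence (in nats) between the empirical joint distribution of the
#' selected columns and the closest maximum-entropy distribution matching
#' the same single-site marginals, fitted by generalized iterative scaling
#' (GIS). Gaps are treated as an ordinary state. A single column gives 0
#' exactly; for two perfectly covarying two-state columns with balanced
#' marginals the value is `ln 2` (the mutual information).
#'
#' With only single-site marginal constraints the maximum-entropy model is
#' the product of the marginals, so GIS has an analytic fixed point. When
#' the product of the per-column observed state sets has at most
#' `state_cap` cells the model is fitted by GIS over that grid (exposing
#' the convergence diagnostics); beyond the cap the fixed point is
#' evaluated in closed form, `MDI = sum_j H(X_j) - H(X_group)` with
#' plug-in entropies, which is exact and needs no enumeration. The two
#' routes agree to within `tol` on enumerable groups.
#'
#' @param al an [msa()] object.
#' @param sites column indices of the group.
#' @param tol convergence tolerance: maximum absolute gap between fitted
#'   and empirical marginals.
#' @param max_iter GIS iteration cap; non-convergence is flagged via the
#'   `converged`/`gap` attributes and a warning, not an error.
#' @param state_cap largest enumerated product state space (default 2e5);
#'   larger groups switch to the closed form.
#' @return nonnegative scalar with attributes `converged`, `gap`, `iter`
#'   and `domain` (`"product"` for the GIS route, `"closed_form"` beyond
#'   the cap).
#' @export
mdi_entropy <- function(al, sites, tol = 1e-6, max_iter = 10000L,
                        state_cap = 2e5) {
  stopifnot(inherits(al, "msa"))
  sites <- as.integer(sites)
  if (length(sites) < 1L) stop("need at least one site", call. = FALSE)
  if (length(sites) == 1L)
    return(structure(0, converged = TRUE, gap = 0, iter = 0L,
                     domain = "product"))
  sub <- al$matrix[, sites, drop = FALSE]
  m <- ncol(sub)
  S <- nrow(sub)

  # per-column observed states, relabelled 1..k_j
  states <- lapply(seq_len(m), function(j) sort(unique(sub[, j])))
  k <- lengths(states)
  X <- vapply(seq_len(m),
              function(j) match(sub[, j], states[[j]]), integer(S))
  X <- matrix(X, nrow = S)

  # empirical joint over observed patterns
  key <- apply(X, 1L, paste, collapse = ",")
  tab <- table(key)
  p_emp <- as.numeric(tab) / S
  emp_pat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))

  if (prod(k) > state_cap) {
    # analytic GIS fixed point: max-ent with matched single-site marginals
    # is the product of marginals, so the KL divergence is the difference
    # between summed marginal entropies and the joint empirical entropy
    entropy <- function(p) -sum(p[p > 0] * log(p[p > 0]))
    h_marg <- vapply(seq_len(m), function(j)
      entropy(tabulate(X[, j], k[j]) / S), numeric(1L))
    mdi <- sum(h_marg) - entropy(p_emp)
    return(structure(max(mdi, 0), converged = TRUE, gap = 0, iter = 0L,
                     domain = "closed_form"))
  }
  D <- as.matrix(expand.grid(lapply(k, seq_len)))
  nD <- nrow(D)
  domain <- "product"

  # empirical marginals (positive by construction of the state sets)
  marg_emp <- lapply(seq_len(m), function(j) tabulate(X[, j], k[j]) / S)

  logm <- rep(-log(nD), nD)
  iter <- 0L
  gap <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    mprob <- exp(logm)
    mprob <- mprob / sum(mprob)
    marg_fit <- lapply(seq_len(m), function(j)
      as.numeric(rowsum(mprob, D[, j], reorder = TRUE)))
    gap <- max(vapply(seq_len(m), function(j)
      max(abs(marg_fit[[j]] - marg_emp[[j]])), numeric(1L)))
    if (gap < tol) break
    for (j in seq_len(m)) {
      adj <- log(marg_emp[[j]] / pmax(marg_fit[[j]], 1e-300)) / m
      logm <- logm + adj[D[, j]]
    }
    logm <- logm - max(logm)
  }
  converged <- gap < tol
  if (!converged)
    warning(sprintf(
      "GIS did not converge in %d iterations (marginal gap %.3g)",
      max_iter, gap), call. = FALSE)

  mprob <- exp(logm)
  mprob <- mprob / sum(mprob)
  dkey <- apply(D, 1L, paste, collapse = ",")
  model_at_emp <- mprob[match(names(tab), dkey)]
  mdi <- sum(p_emp * log(p_emp / pmax(model_at_emp, 1e-300)))
  structure(max(mdi, 0), converged = converged, gap = gap,
            iter = iter, domain = domain)
}

#' Statistical independence of two sectors via MDI additivity
#'
#' If two sectors are statistically independent, the MDI entropy of their
#' union equals the sum of their individual MDI entropies. Reported
#' alongside is a stochastic baseline: the sectors' sites are re-assigned
#' at random into two groups of the original sizes `n_random` times and
#' the mean of `MDI(G1) + MDI(G2)` taken — random splits of genuinely
#' coupled groups leave between-group coupling on the table, so the
#' baseline falls below the joint MDI.
#'
#' @param al an [msa()] object.
#' @param sectorA,sectorB disjoint column sets.
#' @param n_random number of random re-assignments (default 100).
#' @param seed integer seed.
#' @param ... forwarded to [mdi_entropy()] (tolerance, state cap).
#' @return list with `mdi_A`, `mdi_B`, `mdi_joint`, `additivity_gap`
#'   (`mdi_joint - mdi_A - mdi_B`), `random_expectation`, `random_sd`,
#'   `n_random`.
#' @export
independence_test <- function(al, sectorA, sectorB, n_random = 100L,
                              seed = 1L, ...) {
  sectorA <- as.integer(sectorA)
  sectorB <- as.integer(sectorB)
  if (length(intersect(sectorA, sectorB)) > 0L)
    stop("sectors must be disjoint", call. = FALSE)
  mdi_A <- if (length(sectorA)) as.numeric(mdi_entropy(al, sectorA, ...)) else 0
  mdi_B <- if (length(sectorB)) as.numeric(mdi_entropy(al, sectorB, ...)) else 0
  both <- c(sectorA, sectorB)
  mdi_joint <- as.numeric(mdi_entropy(al, both, ...))

  draws <- numeric(0)
  if (n_random > 0L && length(sectorA) > 0L && length(sectorB) > 0L) {
    set.seed(seed)
    draws <- vapply(seq_len(n_random), function(r) {
      g1 <- sample(both, length(sectorA))
      g2 <- setdiff(both, g1)
      as.numeric(mdi_entropy(al, g1, ...)) +
        as.numeric(mdi_entropy(al, g2, ...))
    }, numeric(1L))
  }
  list(mdi_A = mdi_A, mdi_B = mdi_B, mdi_joint = mdi_joint,
       additivity_gap = mdi_joint - mdi_A - mdi_B,
       random_expectation = if (length(draws)) mean(draws) else NA_real_,
       random_sd = if (length(draws)) stats::sd(draws) else NA_real_,
       n_random = as.integer(n_random))
}

#' Read a Rate4Site output file
#'
#' Parses the plain-text per-site rate table produced by Rate4Site
#' (columns `POS SEQ SCORE [QQ-INTERVAL] [STD] [MSA-DATA]`, `#` comments).
#' Lenient by default: lines whose first two tokens are not an integer
#' position and a residue letter are skipped; `strict = TRUE` errors on
#' any non-comment line that fails to parse.
#'
#' @param path path to the Rate4Site output.
#' @param strict error on unparseable lines?
#' @return data frame with columns `pos` (integer), `res` (character),
#'   `score` (numeric normalised rate; negative = slower than average).
#' @export
read_rate4site <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (length(tok) < 3L) return(NULL)
    pos <- suppressWarnings(as.integer(tok[1L]))
    score <- suppressWarnings(as.numeric(tok[3L]))
    if (is.na(pos) || is.na(score) || !grepl("^[A-Za-z-]$", tok[2L]))
      return(NULL)
    data.frame(pos = pos, res = toupper(tok[2L]), score = score,
               stringsAsFactors = FALSE)
  })
  bad <- vapply(rows, is.null, logical(1L))
  if (strict && any(bad))
    stop("unparseable Rate4Site line(s): ",
         paste(utils::head(lines[bad], 3L), collapse = " | "), call. = FALSE)
  out <- do.call(rbind, rows[!bad])
  if (is.null(out) || nrow(out) == 0L)
    stop("no rate rows found in ", path, call. = FALSE)
  out
}

#' Evolutionary-rate summary of sectors from Rate4Site scores
#'
#' Joins per-site normalised evolutionary rates onto sector site lists and
#' summarises them: per-sector mean rate and fraction of sites with
#' negative rate (i.e. evolving slower than the protein average), plus the
#' overall mean (approximately 0 under Rate4Site's normalisation).
#'
#' @param rates data frame from [read_rate4site()].
#' @param sectors a `sector_set` or plain list of site vectors. Sites must
#'   be expressed in the `pos` numbering of `rates`; pass `map` when they
#'   are alignment columns instead.
#' @param map optional named map (or two-column data frame
#'   `(column, pos)`) translating alignment columns to Rate4Site
#'   positions, e.g. built from an alignment's `column_to_residue`.
#' @return list with `overall_mean`, and `per_sector` data frame
#'   (`sector`, `n_sites`, `mean_rate`, `fraction_negative`).
#' @export
rate_summary <- function(rates, sectors, map = NULL) {
  site_lists <- if (inherits(sectors, "sector_set")) sector_sites(sectors)
                else sectors
  lookup <- stats::setNames(rates$score, rates$pos)
  translate <- function(sites) {
    if (!is.null(map)) {
      if (is.data.frame(map)) {
        idx <- match(sites, map$column)
        bad <- sites[is.na(idx)]
        if (length(bad))
          stop("columns not in map: ", paste(bad, collapse = " "),
               call. = FALSE)
        sites <- map$pos[idx]
      } else {
        sites <- map[as.character(sites)]
      }
    }
    sites
  }
  per <- lapply(seq_along(site_lists), function(i) {
    pos <- translate(site_lists[[i]])
    sc <- lookup[as.character(pos)]
    if (anyNA(sc))
      stop("sector ", i, ": sites without a Rate4Site score: ",
           paste(pos[is.na(sc)], collapse = " "), call. = FALSE)
    data.frame(sector = i, n_sites = length(sc), mean_rate = mean(sc),
               fraction_negative = mean(sc < 0))
  })
  list(overall_mean = mean(rates$score),
       per_sector = do.call(rbind, per))
}

#' Evolutionary independence of a sector via PCA of sequence similarity
#'
#' Builds the S x S similarity matrix `M` over the sector's columns
#' (fraction of identical residues; any comparison involving a gap counts
#' as a mismatch), extracts the first principal component of `M`, and
#' splits the sequences into two groups by the sign of their PC1
#' coordinate (threshold 0 after centering). A sector on which all
#' sequences are identical is degenerate: a single group is returned with
#' a warning.
#'
#' @param al an [msa()] object with at least 3 sequences.
#' @param sector column indices, at least 2.
#' @return list with `similarity` (S x S), `pc1` (coordinates), `groups`
#'   (1/2, or all 1 when degenerate), `variance_explained`, `degenerate`.
#' @export
evolutionary_independence <- function(al, sector) {
  stopifnot(inherits(al, "msa"))
  sector <- as.integer(sector)
  if (length(sector) < 2L) stop("sector needs >= 2 sites", call. = FALSE)
  sub <- al$matrix[, sector, drop = FALSE]
  S <- nrow(sub)
  if (S < 3L) stop("need at least 3 sequences", call. = FALSE)
  m <- ncol(sub)
  # match counts via one-hot crossproduct; gaps carry no indicator so any
  # gap comparison is a mismatch
  Z <- .onehot(sub)
  M <- as.matrix(Matrix::tcrossprod(Z)) / m

  if (max(M) - min(M) < 1e-12) {
    warning("similarity matrix is constant; no split possible",
            call. = FALSE)
    return(list(similarity = M, pc1 = rep(0, S), groups = rep(1L, S),
                variance_explained = NA_real_, degenerate = TRUE))
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  # degenerate also when no principal component dominates (e.g. M is
  # identity-like because no two sequences share a residue on the sector)
  tied <- length(pc$sdev) > 1L &&
    (pc$sdev[1L] - pc$sdev[2L]) < 1e-8 * pc$sdev[1L]
  if (pc$sdev[1L] < 1e-12 || tied) {
    warning("degenerate first principal component; no split possible",
            call. = FALSE)
    return(list(similarity = M, pc1 = rep(0, S), groups = rep(1L, S),
                variance_explained = 0, degenerate = TRUE))
  }
  pc1 <- pc$x[, 1L]
  list(similarity = M, pc1 = pc1,
       groups = ifelse(pc1 > 0, 1L, 2L),
       variance_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
       degenerate = FALSE)
}

#' Sensitivity and positive predictive value against reference sectors
#'
#' Each reference sector is matched to the single predicted sector
#' containing the largest number of its sites (ties: the earlier predicted
#' sector). Sensitivity is the percentage of reference sites recovered by
#' that one sector; PPV the percentage of the matched sector's sites that
#' are reference sites. Reference sites outside the matched sector are
#' reported as lost.
#'
#' @param predicted a `sector_set` or list of predicted site vectors.
#' @param reference list of reference site vectors (same numbering as
#'   `predicted`).
#' @return data frame with one row per reference sector: `reference`,
#'   `matched_sector` (NA when nothing is predicted), `n_reference`,
#'   `n_overlap`, `sensitivity`, `ppv` (both in percent; `ppv` is NA for
#'   an empty prediction), and a `lost` list-column of unrecovered sites.
#' @examples
#' sensitivity_ppv(list(c(1:9, 11)), list(1:10))
#' @export
sensitivity_ppv <- function(predicted, reference) {
  pred <- if (inherits(predicted, "sector_set")) sector_sites(predicted)
          else predicted
  rows <- lapply(seq_along(reference), function(i) {
    ref <- as.integer(reference[[i]])
    if (length(pred) == 0L) {
      return(data.frame(reference = i, matched_sector = NA_integer_,
                        n_reference = length(ref), n_overlap = 0L,
                        sensitivity = 0, ppv = NA_real_))
    }
    ov <- vapply(pred, function(p) length(intersect(p, ref)), integer(1L))
    best <- which.max(ov)
    inter <- intersect(pred[[best]], ref)
    data.frame(reference = i, matched_sector = best,
               n_reference = length(ref), n_overlap = length(inter),
               sensitivity = 100 * length(inter) / length(ref),
               ppv = 100 * length(inter) / length(pred[[best]]))
  })
  out <- do.call(rbind, rows)
  out$lost <- lapply(seq_along(reference), function(i) {
    if (is.na(out$matched_sector[i])) as.integer(reference[[i]])
    else setdiff(as.integer(reference[[i]]), pred[[out$matched_sector[i]]])
  })
  out
}
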