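#' Bidirectional assignment of sites to sectors from rotated loadings
#'
#' For each rotated factor and each sign, the factor coefficients
#' `p(i) = sign * b_ik` are ranked, `w` is the mean of the top 50 percent
#' (ceiling for odd counts), and `r(i) = p(i) / w`. Site `i` enters the
#' candidate sector when `r(i) >= r0` and `p(i) > p0`, or outright when
#' `p(i) >= p1`. Both signs are scanned so sectors loading negatively on a
#' factor are not lost. Candidate sectors smaller than `min_size` are
#' discarded (a one-site "sector" carries no coevolution meaning); a sign
#' whose `w` is not positive yields no sector.
#'
#' @param loadings n x t rotated loading matrix ([varimax_rotate()]).
#' @param r0 relative-coefficient threshold (default 0.8).
#' @param p0 absolute floor accompanying the ratio rule (default 0.1).
#' @param p1 outright-inclusion threshold (default 0.4).
#' @param min_size smallest sector reported (default 2).
#' @return object of class `"sector_set"`: list of sectors, each with
#'   `sites` (row indices of `loadings`), `source_factor`, `sign`, and
#'   `merged_from` (`NULL` until merging); thresholds recorded.
#' @export
assign_sites <- function(loadings, r0 = 0.8, p0 = 0.1, p1 = 0.4,
                         min_size = 2L) {
  loadings <- as.matrix(loadings)
  n <- nrow(loadings)
  sectors <- list()
  for (k in seq_len(ncol(loadings))) {
    for (s in c(1, -1)) {
      p <- s * loadings[, k]
      top <- sort(p, decreasing = TRUE)[seq_len(ceiling(n / 2))]
      w <- mean(top)
      if (!is.finite(w) || w <= 0) next
      r <- p / w
      sel <- which((r >= r0 & p > p0) | p >= p1)
      if (length(sel) >= min_size) {
        sectors[[length(sectors) + 1L]] <- list(
          sites = as.integer(sel), source_factor = k,
          sign = if (s > 0) "+" else "-", merged_from = NULL)
      }
    }
  }
  structure(list(sectors = sectors,
                 thresholds = list(r0 = r0, p0 = p0, p1 = p1,
                                   min_size = as.integer(min_size))),
            class = "sector_set")
}

#' Merge overlapping sectors by greedy coupling accretion
#'
#' Bidirectional selection can produce overlapping candidate sectors. For
#' an overlapping pair (A, B) the overlap `Ssame = A` \eqn{\cap} `B` is
#' kept and grown greedily from the symmetric difference: at each step the
#' site with the largest summed coupling to the current `Ssame` joins
#' (ties broken by the lowest column index), until `Ssame` reaches the size
#' of the smaller of the two sectors. The merged sector replaces the pair;
#' the scan repeats until all sectors are pairwise disjoint.
#'
#' @param ss a [assign_sites()] sector set. Site indices must index into
#'   `W`.
#' @param W coupling matrix (the noise-reduced matrix the loadings came
#'   from) supplying the correlation sums.
#' @return a `"sector_set"` with pairwise-disjoint sectors.
#' @export
merge_sectors <- function(ss, W) {
  stopifnot(inherits(ss, "sector_set"))
  W <- as.matrix(W)
  sectors <- ss$sectors
  repeat {
    pair <- .find_overlap(sectors)
    if (is.null(pair)) break
    A <- sectors[[pair[1L]]]
    B <- sectors[[pair[2L]]]
    target <- min(length(A$sites), length(B$sites))
    ssame <- sort(intersect(A$sites, B$sites))
    sdiff <- sort(setdiff(union(A$sites, B$sites), ssame))
    while (length(ssame) < target) {
      score <- vapply(sdiff, function(i) sum(W[i, ssame]), numeric(1L))
      pick <- sdiff[which.max(score)]  # first max = lowest index on ties
      ssame <- sort(c(ssame, pick))
      sdiff <- setdiff(sdiff, pick)
    }
    merged <- list(sites = as.integer(ssame),
                   source_factor = A$source_factor, sign = A$sign,
                   merged_from = list(A = A[c("source_factor", "sign")],
                                      B = B[c("source_factor", "sign")]))
    sectors <- c(sectors[-pair], list(merged))
  }
  ss$sectors <- sectors
  ss
}

.find_overlap <- function(sectors) {
  n <- length(sectors)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(intersect(sectors[[i]]$sites, sectors[[j]]$sites)) > 0L)
        return(c(i, j))
    }
  }
  NULL
}

#' @export
print.sector_set <- function(x, ...) {
  cat(sprintf("Sector set: %d sector(s)\n", length(x$sectors)))
  for (i in seq_along(x$sectors)) {
    s <- x$sectors[[i]]
    tag <- if (!is.null(s$merged_from)) " [merged]" else ""
    cat(sprintf("  sector %d (factor %d%s)%s: %d sites: %s\n",
                i, s$source_factor, s$sign, tag, length(s$sites),
                paste(s$sites, collapse = " ")))
  }
  invisible(x)
}

#' @export
length.sector_set <- function(x) length(x$sectors)

#' Extract sector site lists
#'
#' @param ss a `"sector_set"`.
#' @return list of integer site vectors, one per sector.
#' @export
sector_sites <- function(ss) {
  stopifnot(inherits(ss, "sector_set"))
  lapply(ss$sectors, `[[`, "sites")
}
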