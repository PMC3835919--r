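#' Detect protein sectors in a multiple sequence alignment
#'
#' Runs the full detection pipeline on an alignment:
#' \enumerate{
#'   \item conservation-weighted coupling matrix between all columns
#'     ([weighted_correlation()]);
#'   \item noise-site removal ([noise_filter()]);
#'   \item eigendecomposition of the reduced matrix and retention of
#'     non-random factors against a column-shuffle null
#'     ([null_eigenvalues()], [select_factors()]);
#'   \item varimax rotation of the retained eigenvectors
#'     ([varimax_rotate()]);
#'   \item bidirectional site selection and merging of overlapping
#'     candidates ([assign_sites()], [merge_sectors()]).
#' }
#' When no factor separates from the null (`t = 0`) the fit carries an
#' empty sector set rather than failing.
#'
#' @param al an [msa()] object.
#' @param top_fraction,noise_factor noise-filter parameters
#'   (defaults 0.05 and 0.8).
#' @param n_shuffles shuffled replicates for the eigenvalue null
#'   (default 100); also the cutoff on the null exceedance counts.
#' @param r0,p0,p1,min_sector_size sector-selection thresholds, see
#'   [assign_sites()].
#' @param kaiser Kaiser-normalised varimax? Default raw.
#' @param seed integer seed controlling the shuffle null.
#' @return object of class `"bifanr_fit"`: list with the alignment, `W`
#'   (full coupling matrix), `noise` (noise-reduction result), `eigen`,
#'   `E` (null eigenvalues), `selection` (`t`, `N`), `loadings`,
#'   `rotation`, and `sectors` — a [sector_set][assign_sites()] whose site
#'   indices refer to the **original alignment columns** (element
#'   `sites_kept` keeps the reduced-matrix indexing).
#' @examples
#' spec <- synthetic_spec(n_sequences = 120, n_columns = 40,
#'                        sectors = list(list(sites = 1:8, rho = 0.95),
#'                                       list(sites = 21:28, rho = 0.95)))
#' sim <- generate_alignment(spec)
#' fit <- bifanr(sim$alignment, n_shuffles = 20, seed = 7)
#' fit$sectors
#' @export
bifanr <- function(al, top_fraction = 0.05, noise_factor = 0.8,
                   n_shuffles = 100L, r0 = 0.8, p0 = 0.1, p1 = 0.4,
                   min_sector_size = 2L, kaiser = FALSE, seed = 1L) {
  stopifnot(inherits(al, "msa"))
  fm <- frequencies(al, joint = FALSE)
  W <- weighted_correlation(al)
  noise <- noise_filter(W, top_fraction = top_fraction,
                        factor = noise_factor)
  eig <- eigendecompose(noise$W_reduced)
  E <- null_eigenvalues(al, sites = NULL, n_shuffles = n_shuffles,
                        seed = seed, background = fm$q)
  sel <- select_factors(eig$values, E, count_threshold = n_shuffles)

  fit <- list(alignment = al, frequencies = fm, W = W, noise = noise,
              eigen = eig, E = E, selection = sel,
              loadings = NULL, rotation = NULL,
              sectors = structure(list(sectors = list(),
                                       thresholds = list(r0 = r0, p0 = p0,
                                                         p1 = p1)),
                                  class = "sector_set"),
              params = list(top_fraction = top_fraction,
                            noise_factor = noise_factor,
                            n_shuffles = n_shuffles, r0 = r0, p0 = p0,
                            p1 = p1, min_sector_size = min_sector_size,
                            kaiser = kaiser, seed = seed))
  class(fit) <- "bifanr_fit"
  if (sel$t == 0L) {
    message("no non-random factor found (t = 0); empty sector set")
    return(fit)
  }

  rot <- varimax_rotate(eig$vectors[, seq_len(sel$t), drop = FALSE],
                        kaiser = kaiser)
  ss <- assign_sites(rot$loadings, r0 = r0, p0 = p0, p1 = p1,
                     min_size = min_sector_size)
  ss <- merge_sectors(ss, noise$W_reduced)
  # map reduced-matrix indices back to original alignment columns
  for (i in seq_along(ss$sectors)) {
    ss$sectors[[i]]$sites_kept <- ss$sectors[[i]]$sites
    ss$sectors[[i]]$sites <- noise$kept[ss$sectors[[i]]$sites]
  }
  fit$loadings <- rot$loadings
  fit$rotation <- rot$rotation
  fit$sectors <- ss
  fit
}

#' @export
print.bifanr_fit <- function(x, ...) {
  L <- ncol(x$alignment$matrix)
  cat(sprintf("bifanr fit: %d sequences x %d columns\n",
              nrow(x$alignment$matrix), L))
  cat(sprintf("  noise reduction: %d removed, %d kept\n",
              length(x$noise$removed), length(x$noise$kept)))
  cat(sprintf("  non-random factors: t = %d (null of %d eigenvalues)\n",
              x$selection$t, length(x$E)))
  cat(sprintf("  sectors: %d\n", length(x$sectors$sectors)))
  for (i in seq_along(x$sectors$sectors)) {
    s <- x$sectors$sectors[[i]]
    lab <- .residue_labels(x$alignment, s$sites)
    cat(sprintf("    sector %d (%d sites): %s\n", i, length(s$sites),
                paste(lab, collapse = " ")))
  }
  invisible(x)
}

# label alignment columns by template residue where a mapping exists
.residue_labels <- function(al, cols) {
  map <- al$column_to_residue
  if (is.null(map)) return(as.character(cols))
  idx <- match(cols, map$column)
  ifelse(is.na(idx), paste0("col", cols),
         paste0(map$residue_number[idx], map$residue_code[idx]))
}
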