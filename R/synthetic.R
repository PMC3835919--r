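#' Specification for a synthetic alignment with planted sectors
#'
#' Describes the generative model used throughout testing: groups of
#' columns ("planted sectors") whose residues are correlated across
#' sequences through a shared latent trait, mutually independent between
#' groups, embedded in a background of independently drawn noise columns.
#'
#' Defaults describe the package's reference study conditions: 300
#' sequences, 80 columns, two scattered 12-site sectors driven by binary
#' latent traits at coupling `rho = 0.9`, noise-column conservation 0.3 and
#' a 5 percent gap rate.
#'
#' @param n_sequences,n_columns alignment dimensions.
#' @param sectors list of sector definitions, each a list with `sites`
#'   (column indices, disjoint across sectors), and optionally `n_states`
#'   (latent states, default 2), `rho` (probability a sector column shows
#'   its state's consensus residue, in `[0, 1]`, default 0.9) and `trait`
#'   (`"binary"` or `"continuous"`; a continuous trait is thresholded at
#'   its median into two states).
#' @param conservation background conservation of noise columns: the
#'   probability of the column's consensus residue (default 0.3; the
#'   remainder is spread uniformly over all 20 residues).
#' @param gap_rate independent per-cell gap probability (default 0.05).
#' @param seed integer seed.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_sequences = 300L, n_columns = 80L,
                           sectors = list(
                             list(sites = seq(2L, 68L, by = 6L), rho = 0.9),
                             list(sites = seq(5L, 71L, by = 6L), rho = 0.9)),
                           conservation = 0.3, gap_rate = 0.05, seed = 1L) {
  sectors <- lapply(sectors, function(s) {
    s$sites <- as.integer(s$sites)
    if (is.null(s$n_states)) s$n_states <- 2L
    if (is.null(s$rho)) s$rho <- 0.9
    if (is.null(s$trait)) s$trait <- "binary"
    s
  })
  all_sites <- unlist(lapply(sectors, `[[`, "sites"))
  if (anyDuplicated(all_sites))
    stop("sector site lists must be disjoint", call. = FALSE)
  if (length(all_sites) > 0 &&
      (min(all_sites) < 1L || max(all_sites) > n_columns))
    stop("sector sites must lie within 1..n_columns", call. = FALSE)
  for (s in sectors)
    if (s$rho < 0 || s$rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (gap_rate < 0 || gap_rate >= 1)
    stop("gap_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_sequences = as.integer(n_sequences),
                 n_columns = as.integer(n_columns), sectors = sectors,
                 conservation = conservation, gap_rate = gap_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic alignment with planted sectors
#'
#' Each sequence draws one independent latent state per sector; every
#' column of that sector then shows a state-specific consensus residue
#' with probability `rho`, otherwise a uniformly random residue. Noise
#' columns show their own consensus with probability `conservation`,
#' otherwise a random residue. Gaps are injected independently per cell.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `alignment` (an [msa()]), and `truth`: the planted
#'   sector site lists, the per-sequence latent states (S x n_sectors
#'   matrix) and the consensus residues per sector column and state.
#' @examples
#' sim <- generate_alignment(synthetic_spec(n_sequences = 50,
#'                                          n_columns = 20,
#'                                          sectors = list(list(sites = 1:5))))
#' dim(sim$alignment)
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  S <- spec$n_sequences
  L <- spec$n_columns
  mat <- matrix(0L, S, L)

  sector_sites <- unlist(lapply(spec$sectors, `[[`, "sites"))
  noise_cols <- setdiff(seq_len(L), sector_sites)

  # background: per-column consensus with probability `conservation`
  for (j in noise_cols) {
    cons <- sample.int(20L, 1L)
    hit <- stats::runif(S) < spec$conservation
    mat[, j] <- ifelse(hit, cons, sample.int(20L, S, replace = TRUE))
  }

  latent <- matrix(NA_integer_, S, length(spec$sectors))
  consensus <- vector("list", length(spec$sectors))
  for (g in seq_along(spec$sectors)) {
    sec <- spec$sectors[[g]]
    z <- if (identical(sec$trait, "continuous")) {
      u <- stats::rnorm(S)
      1L + as.integer(u > stats::median(u))
    } else {
      sample.int(sec$n_states, S, replace = TRUE)
    }
    latent[, g] <- z
    # one consensus residue per (column, state), distinct across states
    cons <- vapply(sec$sites,
                   function(j) sample.int(20L, sec$n_states),
                   integer(sec$n_states))
    cons <- matrix(cons, nrow = sec$n_states)   # states x sites
    consensus[[g]] <- cons
    for (ci in seq_along(sec$sites)) {
      j <- sec$sites[ci]
      hit <- stats::runif(S) < sec$rho
      mat[, j] <- ifelse(hit, cons[z, ci],
                         sample.int(20L, S, replace = TRUE))
    }
  }

  if (spec$gap_rate > 0)
    mat[stats::runif(S * L) < spec$gap_rate] <- 0L

  al <- msa(mat, seq_ids = sprintf("synth%04d", seq_len(S)))
  list(alignment = al,
       truth = list(sectors = lapply(spec$sectors, `[[`, "sites"),
                    latent = latent, consensus = consensus, spec = spec))
}
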