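#' Write a coupling matrix to TSV
#'
#' Square matrix with header row and first column holding site labels
#' (template residue labels when the alignment carries a mapping,
#' otherwise column indices).
#'
#' @param W coupling matrix.
#' @param path output path.
#' @param labels optional character labels for the rows/columns.
#' @return `path`, invisibly.
#' @export
write_coupling_tsv <- function(W, path, labels = NULL) {
  W <- as.matrix(W)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(W)))
  df <- data.frame(site = labels, W, check.names = FALSE)
  names(df) <- c("site", labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sectors to TSV or JSON
#'
#' TSV: one row per (sector, site) with the template residue label and,
#' when available, the site's loading on the source factor. JSON: sector
#' site lists plus provenance.
#'
#' @param fit a [bifanr()] fit (or a bare `sector_set` for `format =
#'   "json"`).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_sectors <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(fit, "bifanr_fit")) {
    ss <- fit$sectors
    al <- fit$alignment
  } else {
    ss <- fit
    al <- NULL
  }
  stopifnot(inherits(ss, "sector_set"))
  if (format == "json") {
    payload <- list(
      thresholds = ss$thresholds,
      sectors = lapply(ss$sectors, function(s)
        list(sites = s$sites, source_factor = s$source_factor,
             sign = s$sign,
             merged = !is.null(s$merged_from))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rows <- list()
  for (i in seq_along(ss$sectors)) {
    s <- ss$sectors[[i]]
    lab <- if (is.null(al)) as.character(s$sites)
           else .residue_labels(al, s$sites)
    loading <- rep(NA_real_, length(s$sites))
    if (inherits(fit, "bifanr_fit") && !is.null(fit$loadings) &&
        !is.null(s$sites_kept))
      loading <- fit$loadings[s$sites_kept, s$source_factor]
    rows[[i]] <- data.frame(sector_id = i, column_index = s$sites,
                            template_residue = lab, loading = loading,
                            stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sector_id = integer(), column_index = integer(),
               template_residue = character(), loading = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a configuration and write artifacts
#'
#' Thin orchestration layer over [bifanr()] for scripted use: reads the
#' alignment, runs detection, optionally runs the evaluation suite, and
#' writes all artifacts (coupling matrix, noise-reduction report, factor
#' diagnostics, sectors, evaluation report, manifest) into an output
#' directory.
#'
#' @param config named list (or path to a YAML/JSON file) with elements:
#'   `input` (alignment path) and optionally `format`, `template`,
#'   `n_shuffles` (100), `top_fraction` (0.05), `noise_factor` (0.8),
#'   `r0` (0.8), `p0` (0.1), `p1` (0.4), `min_sector_size` (2),
#'   `n_random_correlation` (1000), `n_random_mdi` (100), `evaluate`
#'   (TRUE), `seed` (1), `output_dir`.
#' @return the [bifanr()] fit, invisibly.
#' @export
run_bifanr <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs", call. = FALSE)
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(format = "auto", template = NULL, n_shuffles = 100L,
                   top_fraction = 0.05, noise_factor = 0.8, r0 = 0.8,
                   p0 = 0.1, p1 = 0.4, min_sector_size = 2L,
                   n_random_correlation = 1000L, n_random_mdi = 100L,
                   evaluate = TRUE, seed = 1L, output_dir = "bifanr_out")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$input)) stop("config needs an 'input' path", call. = FALSE)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  al <- read_alignment(cfg$input, format = cfg$format,
                       template = cfg$template)
  fit <- bifanr(al, top_fraction = cfg$top_fraction,
                noise_factor = cfg$noise_factor,
                n_shuffles = cfg$n_shuffles, r0 = cfg$r0, p0 = cfg$p0,
                p1 = cfg$p1, min_sector_size = cfg$min_sector_size,
                seed = cfg$seed)

  out <- function(f) file.path(cfg$output_dir, f)
  write_coupling_tsv(fit$W, out("coupling_matrix.tsv"),
                     labels = .residue_labels(al, seq_len(ncol(al$matrix))))
  jsonlite::write_json(
    list(kept = fit$noise$kept, removed = fit$noise$removed,
         rmax = fit$noise$rmax, plus = fit$noise$plus,
         factor = fit$noise$factor,
         top_fraction = fit$noise$top_fraction),
    out("noise_reduction.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(index = seq_along(fit$eigen$values),
               eigenvalue = fit$eigen$values,
               null_exceedance = fit$selection$N,
               retained = seq_along(fit$eigen$values) <= fit$selection$t),
    out("factor_diagnostics.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_sectors(fit, out("sectors.tsv"), format = "tsv")
  write_sectors(fit, out("sectors.json"), format = "json")

  if (isTRUE(cfg$evaluate) && length(fit$sectors$sectors) > 0L) {
    report <- evaluate_fit(fit, n_random_correlation = cfg$n_random_correlation,
                           n_random_mdi = cfg$n_random_mdi, seed = cfg$seed)
    jsonlite::write_json(report, out("evaluation.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  manifest <- list(
    package = "bifanr",
    version = as.character(utils::packageVersion("bifanr")),
    input = normalizePath(cfg$input),
    input_md5 = unname(tools::md5sum(cfg$input)),
    seed = cfg$seed,
    parameters = cfg[c("format", "n_shuffles", "top_fraction",
                       "noise_factor", "r0", "p0", "p1",
                       "min_sector_size")],
    n_sequences = nrow(al$matrix), n_columns = ncol(al$matrix),
    n_sectors = length(fit$sectors$sectors),
    t = fit$selection$t)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(fit)
}

#' Evaluation report for a fitted sector model
#'
#' Runs the statistical evaluation suite on a fit: per-sector internal
#' correlation against random site sets and, for every sector pair, the
#' MDI independence test.
#'
#' @param fit a [bifanr()] fit with at least one sector.
#' @param n_random_correlation resamples for the correlation baseline
#'   (default 1000).
#' @param n_random_mdi random re-assignments for the MDI baseline
#'   (default 100).
#' @param seed integer seed.
#' @return list with `internal_correlation` (per sector) and
#'   `independence` (per sector pair).
#' @export
evaluate_fit <- function(fit, n_random_correlation = 1000L,
                         n_random_mdi = 100L, seed = 1L) {
  stopifnot(inherits(fit, "bifanr_fit"))
  ss <- fit$sectors$sectors
  if (length(ss) == 0L) stop("fit has no sectors", call. = FALSE)
  kept <- fit$noise$kept
  Wred <- fit$noise$W_reduced

  ic <- lapply(seq_along(ss), function(i) {
    res <- internal_correlation(Wred, ss[[i]]$sites_kept,
                                n_random = n_random_correlation,
                                seed = seed + i)
    c(list(sector = i, n_sites = length(ss[[i]]$sites)), res)
  })
  pairs <- list()
  if (length(ss) >= 2L) {
    cmb <- utils::combn(length(ss), 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(p) {
      i <- cmb[1L, p]; j <- cmb[2L, p]
      res <- independence_test(fit$alignment, ss[[i]]$sites,
                               ss[[j]]$sites, n_random = n_random_mdi,
                               seed = seed + 100L + p)
      c(list(sector_pair = c(i, j)), res)
    })
  }
  list(internal_correlation = ic, independence = pairs)
}
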