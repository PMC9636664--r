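#' Configuration of a comparison run
#'
#' Bundles everything a full comparison needs: the TAD files, labels, the
#' binning frame, tolerance range, which analyses to run and the embedding
#' seed. `run_compare()` is deterministic given a config.
#'
#' @param tad_paths Character vector of >= 2 TAD file paths.
#' @param labels Unique dataset labels; default: file names.
#' @param chrom Chromosome label.
#' @param resolution Bin width in bp.
#' @param n_bins Number of bins of the region.
#' @param tolerances Integer tolerances in bins for the sharing tables
#'   (default `0:3`).
#' @param profile_tolerance Tolerance for the all-vs-all sharing profiles
#'   (default 1).
#' @param reference Label of the one-vs-all reference dataset; default: the
#'   first.
#' @param moc Compute the MoC matrix? (default `TRUE`).
#' @param embedding_modes Character subset of
#'   `c("PCA", "TSNE")` (default both; TSNE is skipped with a log note when
#'   fewer than 4 datasets are supplied).
#' @param seed Integer seed for the stochastic embedding (default 0).
#' @param units,dialect Passed to [read_tad_set()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(tad_paths, labels = NULL, chrom, resolution, n_bins,
                       tolerances = 0:3, profile_tolerance = 1L,
                       reference = NULL, moc = TRUE,
                       embedding_modes = c("PCA", "TSNE"), seed = 0L,
                       units = "auto", dialect = "auto") {
  if (length(tad_paths) < 2L) {
    stop("comparison needs at least 2 TAD datasets", call. = FALSE)
  }
  if (is.null(labels)) labels <- sub("\\.[^.]*$", "", basename(tad_paths))
  if (length(labels) != length(tad_paths) || anyDuplicated(labels)) {
    stop("`labels` must be unique and match `tad_paths`", call. = FALSE)
  }
  if (is.null(reference)) reference <- labels[1L]
  if (!reference %in% labels) stop("`reference` is not one of the labels", call. = FALSE)
  embedding_modes <- match.arg(embedding_modes, c("PCA", "TSNE"), several.ok = TRUE)
  structure(
    list(tad_paths = tad_paths, labels = labels, chrom = chrom,
         resolution = as.integer(resolution), n_bins = as.integer(n_bins),
         tolerances = as.integer(tolerances),
         profile_tolerance = as.integer(profile_tolerance),
         reference = reference, moc = isTRUE(moc),
         embedding_modes = embedding_modes, seed = as.integer(seed),
         units = units, dialect = dialect),
    class = "run_config"
  )
}

#' Run a full comparison and write the report
#'
#' Executes the whole analysis suite on the configured datasets — counts,
#' size summaries, one-vs-all shared boundaries and domains over the
#' tolerance range, all-vs-all sharing profiles, the MoC matrix with
#' per-dataset averages, and PCA/t-SNE embeddings — and writes each table
#' as CSV plus a provenance block as JSON into `out_dir`. Re-running the
#' same config writes byte-identical files. Any module error aborts the
#' run before files are written.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return The report, invisibly: a list with elements `counts`,
#'   `size_stats`, `one_vs_all_boundaries`, `one_vs_all_domains`,
#'   `sharing_boundaries`, `sharing_domains`, `moc`, `embeddings`,
#'   `provenance`, `log`.
#' @export
run_compare <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config", call. = FALSE)
  binning <- genomic_binning(config$chrom, config$resolution, config$n_bins)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  sets <- vector("list", length(config$tad_paths))
  for (k in seq_along(config$tad_paths)) {
    sets[[k]] <- withCallingHandlers(
      read_tad_set(config$tad_paths[k], binning, label = config$labels[k],
                   dialect = config$dialect, units = config$units),
      message = function(m) {
        note("[read %s] %s", config$labels[k], trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
  }

  counts <- data.frame(
    dataset = config$labels,
    n_tads = vapply(sets, count_tads, integer(1L))
  )
  sizes <- do.call(rbind, lapply(sets, function(s) {
    cbind(dataset = s$label, size_stats(s))
  }))

  ref <- sets[[match(config$reference, config$labels)]]
  others <- sets[config$labels != config$reference]
  ova_b <- one_vs_all(ref, others, config$tolerances, mode = "boundaries")
  ova_d <- one_vs_all(ref, others, config$tolerances, mode = "domains")
  prof_b <- sharing_profile(sets, config$profile_tolerance, mode = "boundaries")
  prof_d <- sharing_profile(sets, config$profile_tolerance, mode = "domains")

  mocm <- NULL
  if (config$moc) mocm <- moc_matrix_and_average(sets)

  embeddings <- list()
  if (length(config$embedding_modes)) {
    feats <- vectorize_tad_sets(sets)
    if ("PCA" %in% config$embedding_modes) {
      embeddings$PCA <- withCallingHandlers(
        pca_embed(feats),
        warning = function(w) {
          note("[pca] %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    }
    if ("TSNE" %in% config$embedding_modes) {
      if (length(sets) >= 4L) {
        embeddings$TSNE <- tsne_embed(feats, seed = config$seed)
      } else {
        note("[tsne] skipped: needs >= 4 datasets, got %d", length(sets))
      }
    }
  }

  provenance <- list(
    package = "tadconcord",
    version = as.character(utils::packageVersion("tadconcord")),
    config = unclass(config)
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(counts, "counts.csv")
  wcsv(sizes, "size_stats.csv")
  wcsv(ova_b, "one_vs_all_boundaries.csv")
  wcsv(ova_d, "one_vs_all_domains.csv")
  wcsv(prof_b, "sharing_profile_boundaries.csv")
  wcsv(prof_d, "sharing_profile_domains.csv")
  if (!is.null(mocm)) {
    utils::write.csv(as.data.frame(mocm$values), file.path(out_dir, "moc_matrix.csv"))
    wcsv(data.frame(dataset = mocm$labels, average_moc = unname(mocm$averages)),
         "moc_averages.csv")
  }
  for (nm in names(embeddings)) {
    wcsv(embeddings[[nm]], sprintf("embedding_%s.csv", tolower(nm)))
  }
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    counts = counts, size_stats = sizes,
    one_vs_all_boundaries = ova_b, one_vs_all_domains = ova_d,
    sharing_boundaries = prof_b, sharing_domains = prof_d,
    moc = mocm, embeddings = embeddings,
    provenance = provenance, log = log_lines
  ))
}

#' Normalize a contact matrix with one or more methods
#'
#' Reads a dense-text or triplet contact matrix, applies each requested
#' balancing method and writes one dense output matrix per method plus a
#' convergence log. A method that fails (e.g. non-convergence) is logged
#' and does not abort the others.
#'
#' @param matrix_path Input matrix file.
#' @param methods Character vector from
#'   `c("vc", "sqrt_vc", "kr", "ice", "scn")`; must be non-empty.
#' @param out_dir Output directory.
#' @param chrom,resolution Binning frame of the matrix.
#' @param format `"dense"` (default) or `"triplet"`; triplet input also
#'   needs `n_bins`.
#' @param n_bins Bin count, required for triplet input.
#' @param tol,max_iter Passed to [normalize_matrix()].
#' @return Invisibly, a data.frame log with columns `method`, `status`,
#'   `iterations`, `residual`, `file`.
#' @export
run_normalize <- function(matrix_path, methods, out_dir, chrom, resolution,
                          format = c("dense", "triplet"), n_bins = NULL,
                          tol = 1e-5, max_iter = NULL) {
  format <- match.arg(format)
  if (!length(methods)) stop("`methods` must be non-empty", call. = FALSE)
  mat <- if (format == "dense") {
    read_dense_matrix(matrix_path, chrom, resolution)
  } else {
    if (is.null(n_bins)) stop("triplet input needs `n_bins`", call. = FALSE)
    read_sparse_triplet(matrix_path, chrom, resolution, n_bins)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(methods, function(m) {
    out_file <- file.path(out_dir, paste0("normalized_", tolower(m), ".txt"))
    res <- tryCatch({
      nm <- normalize_matrix(mat, m, max_iter = max_iter, tol = tol)
      write_contact_matrix(nm, out_file)
      data.frame(method = tolower(m), status = "ok",
                 iterations = attr(nm, "iterations"),
                 residual = attr(nm, "residual"), file = basename(out_file))
    }, error = function(e) {
      data.frame(method = tolower(m), status = conditionMessage(e),
                 iterations = NA_integer_, residual = NA_real_,
                 file = NA_character_)
    })
    res
  })
  log <- do.call(rbind, rows)
  utils::write.csv(log, file.path(out_dir, "normalize_log.csv"), row.names = FALSE)
  invisible(log)
}
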