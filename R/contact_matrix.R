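#' Hi-C contact matrix on a binning frame
#'
#' Wraps a square, symmetric, nonnegative matrix of contact counts (or
#' balanced intensities) together with its [genomic_binning()]. Bins whose
#' marginal sum is zero — unmappable or filtered regions — form the `mask`
#' and are excluded from balancing.
#'
#' @param values Square numeric matrix; symmetric within relative tolerance
#'   1e-9, all entries finite and `>= 0`.
#' @param binning A [genomic_binning()] with `n_bins == nrow(values)`.
#'
#' @return An object of class `contact_matrix` with fields `values`,
#'   `binning` and `mask` (0-based indices of all-zero bins).
#' @export
contact_matrix <- function(values, binning) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square, got ", nrow(values), "x", ncol(values),
         call. = FALSE)
  }
  if (!inherits(binning, "genomic_binning")) {
    stop("`binning` must be a genomic_binning", call. = FALSE)
  }
  if (binning$n_bins != nrow(values)) {
    stop("binning declares ", binning$n_bins, " bins but matrix has ",
         nrow(values), " rows", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite matrix entries", call. = FALSE)
  if (any(values < 0)) stop("negative matrix entries", call. = FALSE)
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1e-300)
  if (asym > 1e-9 * scale) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance (1e-9 relative)", asym),
         call. = FALSE)
  }
  values <- (values + t(values)) / 2  # remove sub-tolerance asymmetry
  marg <- rowSums(values)
  structure(
    list(values = values, binning = binning, mask = which(marg == 0) - 1L),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s @ %d bp: %d x %d, sum %.4g, %d masked bin(s)\n",
    x$binning$chrom, x$binning$resolution, nrow(x$values), ncol(x$values),
    sum(x$values), length(x$mask)
  ))
  invisible(x)
}

#' Read a dense square contact matrix from whitespace-delimited text
#'
#' @param path Path to the matrix text file (one matrix row per line).
#' @param chrom Chromosome label for the binning frame.
#' @param resolution Bin width in bp.
#' @return A [contact_matrix()]; `n_bins` is inferred from the row count.
#'   Ragged rows, non-numeric/negative/NaN entries, non-square shape and
#'   asymmetry beyond tolerance are errors.
#' @export
read_dense_matrix <- function(path, chrom, resolution) {
  if (!file.exists(path)) stop("cannot read matrix file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t,]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in ", path, ": widths ",
         paste(unique(nf), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("non-numeric entries in ", path, call. = FALSE)
  m <- matrix(vals, nrow = length(lines), byrow = TRUE)
  contact_matrix(m, genomic_binning(chrom, resolution, nrow(m)))
}

#' Read a sparse 3-column triplet contact matrix
#'
#' Lines are `i j value`. Coordinates may be bin indices or bp positions;
#' with `coords = "auto"` they are taken as bp when every coordinate is
#' divisible by the resolution and the largest one is at least `n_bins`
#' (bin indices never reach bp scale). The matrix is symmetrized: each
#' triplet is written to both `(i, j)` and `(j, i)`; unspecified cells are 0.
#' Duplicate entries for the same cell (in either orientation) are summed
#' with a warning.
#'
#' @param path Triplet text file.
#' @param chrom Chromosome label.
#' @param resolution Bin width in bp.
#' @param n_bins Number of bins of the full matrix.
#' @param coords `"auto"` (default), `"bins"` or `"bp"`.
#' @return A [contact_matrix()].
#' @export
read_sparse_triplet <- function(path, chrom, resolution, n_bins,
                                coords = c("auto", "bins", "bp")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("cannot read triplet file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("i", "j", "value"))
  binning <- genomic_binning(chrom, resolution, n_bins)
  if (nrow(df) == 0L) {
    return(contact_matrix(matrix(0, n_bins, n_bins), binning))
  }
  if (anyNA(df)) stop("non-numeric triplet entries in ", path, call. = FALSE)
  if (coords == "auto") {
    maxc <- max(df$i, df$j)
    divisible <- all(df$i %% resolution == 0) && all(df$j %% resolution == 0)
    coords <- if (divisible && maxc >= n_bins) "bp" else "bins"
  }
  if (coords == "bp") {
    df$i <- df$i / resolution
    df$j <- df$j / resolution
  }
  if (any(df$i != floor(df$i)) || any(df$j != floor(df$j))) {
    stop("non-integer bin indices in ", path, call. = FALSE)
  }
  if (any(df$i < 0 | df$j < 0 | df$i >= n_bins | df$j >= n_bins)) {
    stop("triplet indices out of range [0, ", n_bins - 1L, "] in ", path,
         call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative triplet values in ", path, call. = FALSE)

  a <- matrix(0, n_bins, n_bins)   # as-given orientation
  hits <- matrix(0L, n_bins, n_bins)
  idx <- cbind(df$i + 1L, df$j + 1L)
  for (k in seq_len(nrow(df))) {
    a[idx[k, 1L], idx[k, 2L]] <- a[idx[k, 1L], idx[k, 2L]] + df$value[k]
    hits[idx[k, 1L], idx[k, 2L]] <- hits[idx[k, 1L], idx[k, 2L]] + 1L
  }
  dup <- (hits + t(hits)) > 1L
  diag(dup) <- diag(hits) > 1L
  if (any(dup)) {
    warning(sum(dup & upper.tri(dup, diag = TRUE)),
            " cell(s) specified more than once; values summed", call. = FALSE)
  }
  m <- a + t(a)
  diag(m) <- diag(a)
  contact_matrix(m, binning)
}

#' Write a contact matrix as dense text or sparse triplet
#'
#' @param mat A [contact_matrix()].
#' @param path Output path.
#' @param format `"dense"` (whitespace-delimited square text) or `"triplet"`
#'   (upper triangle incl. diagonal, non-zero cells, bin indices).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  v <- mat$values
  if (format == "dense") {
    lines <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = "\t"))
    writeLines(lines, path)
  } else {
    keep <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    lines <- sprintf("%d\t%d\t%s", keep[, 1L] - 1L, keep[, 2L] - 1L,
                     format(v[keep], trim = TRUE, digits = 15))
    writeLines(lines, path)
  }
  invisible(path)
}
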