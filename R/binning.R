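#' Genomic binning frame
#'
#' A binning frame fixes the shared coordinate system of every comparison:
#' one chromosome, a bin width (the Hi-C resolution, in bp), and the number
#' of bins. Bin `i` (0-based) spans the half-open bp interval
#' `[i * resolution, (i + 1) * resolution)`.
#'
#' @param chrom Chromosome label, e.g. `"chr10"`.
#' @param resolution Bin width in bp; positive integer.
#' @param n_bins Number of bins on the chromosome region; positive integer.
#'
#' @return An object of class `genomic_binning` with fields `chrom`,
#'   `resolution`, `n_bins`.
#' @examples
#' genomic_binning("chr10", 40000L, 3393L)
#' @export
genomic_binning <- function(chrom, resolution, n_bins) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom)) {
    stop("`chrom` must be a single non-empty string", call. = FALSE)
  }
  resolution <- as.numeric(resolution)
  n_bins <- as.numeric(n_bins)
  if (length(resolution) != 1L || !is.finite(resolution) ||
      resolution < 1 || resolution != floor(resolution)) {
    stop("`resolution` must be a positive integer (bp per bin)", call. = FALSE)
  }
  if (length(n_bins) != 1L || !is.finite(n_bins) ||
      n_bins < 1 || n_bins != floor(n_bins)) {
    stop("`n_bins` must be a positive integer", call. = FALSE)
  }
  structure(
    list(chrom = chrom, resolution = as.integer(resolution), n_bins = as.integer(n_bins)),
    class = "genomic_binning"
  )
}

#' @export
print.genomic_binning <- function(x, ...) {
  cat(sprintf(
    "<genomic_binning> %s | %d bins @ %d bp (%.1f Mb)\n",
    x$chrom, x$n_bins, x$resolution, x$n_bins * x$resolution / 1e6
  ))
  invisible(x)
}

# TRUE when two binning frames describe the same coordinate system.
same_binning <- function(a, b) {
  identical(a$chrom, b$chrom) &&
    identical(a$resolution, b$resolution) &&
    identical(a$n_bins, b$n_bins)
}

stopifnot_same_binning <- function(sets) {
  b0 <- sets[[1L]]$binning
  for (s in sets[-1L]) {
    if (!same_binning(b0, s$binning)) {
      stop(sprintf(
        "binning mismatch: dataset '%s' is on %s/%d bp/%d bins, dataset '%s' on %s/%d bp/%d bins",
        sets[[1L]]$label, b0$chrom, b0$resolution, b0$n_bins,
        s$label, s$binning$chrom, s$binning$resolution, s$binning$n_bins
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}
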