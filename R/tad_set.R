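#' TAD dataset on a binning frame
#'
#' A `tad_set` is a labelled, ordered collection of non-overlapping
#' topologically associating domains from one caller (or cell, or replicate),
#' expressed as 0-based half-open bin intervals `[start_bin, end_bin)` on a
#' common [genomic_binning()]. Domains must be sorted by start, each at least
#' one bin wide, pairwise non-overlapping (adjacency `end == next start` is
#' allowed) and contained in `[0, n_bins]`. Gaps between domains are
#' permitted: real TAD maps rarely tile a chromosome completely.
#'
#' @param label Dataset name (unique within a comparison).
#' @param binning A [genomic_binning()].
#' @param start_bin,end_bin Integer vectors of equal length; domain `k`
#'   occupies bins `start_bin[k] .. end_bin[k] - 1`.
#'
#' @return An object of class `tad_set` with fields `label`, `binning` and
#'   `domains` (a data.frame with columns `start_bin`, `end_bin`).
#' @examples
#' b <- genomic_binning("chr1", 40000L, 100L)
#' tad_set("toy", b, c(0L, 10L), c(10L, 25L))
#' @export
tad_set <- function(label, binning, start_bin = integer(), end_bin = integer()) {
  if (!inherits(binning, "genomic_binning")) {
    stop("`binning` must be a genomic_binning", call. = FALSE)
  }
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("`label` must be a single string", call. = FALSE)
  }
  start_bin <- as.integer(start_bin)
  end_bin <- as.integer(end_bin)
  if (length(start_bin) != length(end_bin)) {
    stop("`start_bin` and `end_bin` must have equal length", call. = FALSE)
  }
  ord <- order(start_bin, end_bin)
  x <- structure(
    list(
      label = label,
      binning = binning,
      domains = data.frame(start_bin = start_bin[ord], end_bin = end_bin[ord])
    ),
    class = "tad_set"
  )
  validate_tad_set(x)
  x
}

#' Validate a TAD dataset
#'
#' Checks every `tad_set` invariant: integer bin coordinates, every domain at
#' least one bin wide, domains sorted and pairwise non-overlapping, all
#' domains within `[0, n_bins]`. Called by every constructor and generator;
#' exposed so externally assembled objects can be checked too.
#'
#' @param x A `tad_set`.
#' @return `x`, invisibly. Errors (listing offending rows) otherwise.
#' @export
validate_tad_set <- function(x) {
  if (!inherits(x, "tad_set")) stop("not a tad_set", call. = FALSE)
  d <- x$domains
  if (anyNA(d$start_bin) || anyNA(d$end_bin)) {
    stop("NA bin coordinates in tad_set '", x$label, "'", call. = FALSE)
  }
  bad <- which(d$end_bin <= d$start_bin)
  if (length(bad)) {
    stop(sprintf(
      "tad_set '%s': zero- or negative-size domains at rows %s (end_bin must exceed start_bin)",
      x$label, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  n <- nrow(d)
  if (n > 1L) {
    ov <- which(d$end_bin[-n] > d$start_bin[-1L])
    if (length(ov)) {
      stop(sprintf(
        "tad_set '%s': overlapping domains at rows %s (e.g. [%d,%d) overlaps [%d,%d))",
        x$label, paste(ov, collapse = ", "),
        d$start_bin[ov[1L]], d$end_bin[ov[1L]],
        d$start_bin[ov[1L] + 1L], d$end_bin[ov[1L] + 1L]
      ), call. = FALSE)
    }
  }
  if (n > 0L && (min(d$start_bin) < 0L || max(d$end_bin) > x$binning$n_bins)) {
    stop(sprintf(
      "tad_set '%s': domains outside [0, %d]",
      x$label, x$binning$n_bins
    ), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.tad_set <- function(x, ...) {
  n <- nrow(x$domains)
  cat(sprintf(
    "<tad_set> '%s' on %s @ %d bp: %d domains", x$label,
    x$binning$chrom, x$binning$resolution, n
  ))
  if (n > 0L) {
    sz <- x$domains$end_bin - x$domains$start_bin
    cat(sprintf(", sizes %d-%d bins (median %.1f)", min(sz), max(sz), stats::median(sz)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.tad_set <- function(x, ...) {
  cbind(label = rep(x$label, nrow(x$domains)), x$domains)
}

# Domain sizes in bins.
tad_sizes <- function(x) x$domains$end_bin - x$domains$start_bin

#' Boundary set of a TAD dataset
#'
#' Collects the rising (start) and falling (end) boundaries of every domain
#' into a sorted set of unique bin indices. The shared corner of two adjacent
#' domains appears once: boundaries are compared with set semantics.
#'
#' @param tads A [tad_set()].
#' @return Sorted integer vector of unique boundary bin indices (possibly
#'   empty).
#' @examples
#' b <- genomic_binning("chr1", 1L, 30L)
#' boundaries_of(tad_set("x", b, c(0L, 10L), c(10L, 20L)))  # 0 10 20
#' @export
boundaries_of <- function(tads) {
  if (!inherits(tads, "tad_set")) stop("`tads` must be a tad_set", call. = FALSE)
  sort(unique(c(tads$domains$start_bin, tads$domains$end_bin)))
}
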