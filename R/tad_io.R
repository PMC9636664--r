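#' Read a TAD dataset from a text file
#'
#' Parses caller output in either BED3 dialect (`chrom start end`) or a
#' headerless two-column `start end` dialect, converts coordinates onto the
#' binning frame and returns a validated [tad_set()]. Comment lines starting
#' with `#`, `track` or `browser` are skipped. In BED3 mode, rows whose
#' chromosome differs from `binning$chrom` are dropped with a message.
#'
#' Base-pair coordinates are converted to bins by
#' `start_bin = floor(start / resolution)`, `end_bin = ceiling(end / resolution)`,
#' which preserves full coverage of intervals that are not bin-aligned.
#' With `units = "auto"` coordinates are treated as bin indices when the
#' largest coordinate is below `2 * n_bins`, and as bp otherwise; the choice
#' is reported with a message and can be forced with `units = "bp"` or
#' `"bins"`.
#'
#' @param path Path to the TAD file.
#' @param binning A [genomic_binning()] giving chromosome, resolution, extent.
#' @param label Dataset label; defaults to the file name without extension.
#' @param dialect `"auto"` (default), `"bed3"` or `"two_column"`. Auto picks
#'   bed3 for rows with three or more fields, two_column for two numeric
#'   fields.
#' @param units `"auto"` (default), `"bp"` or `"bins"`.
#'
#' @return A validated [tad_set()].
#' @seealso [write_tad_set()] for the inverse operation.
#' @export
read_tad_set <- function(path, binning, label = NULL,
                         dialect = c("auto", "bed3", "two_column"),
                         units = c("auto", "bp", "bins")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!inherits(binning, "genomic_binning")) {
    stop("`binning` must be a genomic_binning", call. = FALSE)
  }
  if (!file.exists(path)) stop("cannot read TAD file: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines)) return(tad_set(label, binning))

  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)

  if (dialect == "auto") {
    dialect <- if (nf[1L] >= 3L) "bed3" else "two_column"
  }

  if (dialect == "bed3") {
    if (any(nf < 3L)) {
      stop("bed3 dialect requires >= 3 columns; offending lines: ",
           paste(which(nf < 3L), collapse = ", "), call. = FALSE)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    keep <- chrom == binning$chrom
    if (any(!keep)) {
      message(sum(!keep), " row(s) on other chromosomes dropped (kept ",
              binning$chrom, ")")
    }
    start <- start[keep]
    end <- end[keep]
  } else {
    if (any(nf < 2L)) {
      stop("two_column dialect requires 2 columns; offending lines: ",
           paste(which(nf < 2L), collapse = ", "), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  }

  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinates in ", path, " (lines ",
         paste(which(is.na(start) | is.na(end)), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("non-integer coordinates in ", path, call. = FALSE)
  }

  if (!length(start)) return(tad_set(label, binning))

  if (units == "auto") {
    units <- if (max(end) < 2 * binning$n_bins) "bins" else "bp"
    message("units=auto: interpreting coordinates of '", label, "' as ", units)
  }
  if (units == "bp") {
    start_bin <- floor(start / binning$resolution)
    end_bin <- ceiling(end / binning$resolution)
  } else {
    start_bin <- start
    end_bin <- end
  }

  bad <- which(end_bin <= start_bin)
  if (length(bad)) {
    stop("domains with end <= start after conversion at rows ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  tad_set(label, binning, start_bin, end_bin)
}

#' Write a TAD dataset as BED3 text
#'
#' Emits tab-delimited `chrom start end` rows, preceded by one comment line
#' recording the binning frame and units. With `units = "bp"` bin indices are
#' multiplied by the resolution; with `units = "bins"` they are written as-is.
#' `read_tad_set(write_tad_set(x))` is the identity in both modes.
#'
#' @param tads A [tad_set()].
#' @param path Output path.
#' @param units `"bp"` (default, standard BED) or `"bins"`.
#' @return `path`, invisibly.
#' @export
write_tad_set <- function(tads, path, units = c("bp", "bins")) {
  units <- match.arg(units)
  validate_tad_set(tads)
  b <- tads$binning
  mult <- if (units == "bp") as.numeric(b$resolution) else 1
  header <- sprintf(
    "# tad_set label=%s chrom=%s resolution=%d n_bins=%d units=%s",
    tads$label, b$chrom, b$resolution, b$n_bins, units
  )
  rows <- sprintf(
    "%s\t%.0f\t%.0f", b$chrom,
    tads$domains$start_bin * mult, tads$domains$end_bin * mult
  )
  writeLines(c(header, rows), path)
  invisible(path)
}
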