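#' Extract one chromosome from a cooler container
#'
#' Reads the cooler HDF5 schema (`/chroms`, `/bins`, `/pixels`) and returns
#' the dense intra-chromosomal contact matrix for one chromosome. Both the
#' single-resolution layout (groups at the file root, `.cool`) and the
#' multi-resolution layout (`/resolutions/<res>/...`, `.mcool`) are
#' supported. The resolution is read from the container's bin table; on a
#' multi-resolution container it must be selected explicitly.
#'
#' Any reader satisfying this contract — request a chromosome, get back a
#' dense symmetric [contact_matrix()] on that chromosome's binning at the
#' container's resolution — can stand in for this adapter; other container
#' formats plug in the same way.
#'
#' @param path Path to a `.cool`/`.mcool` HDF5 file.
#' @param chrom Chromosome label to extract. An absent chromosome is an
#'   error naming the available ones.
#' @param resolution Optional resolution in bp; required when the container
#'   stores several.
#' @return A [contact_matrix()] for the requested chromosome.
#' @seealso [write_cool()] to create single-resolution containers.
#' @export
extract_chromosome <- function(path, chrom, resolution = NULL) {
  if (!file.exists(path)) stop("cannot read container: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path, recursive = 2L)
  root <- ""
  if ("resolutions" %in% contents$name[contents$group == "/"]) {
    res_avail <- contents$name[contents$group == "/resolutions"]
    if (is.null(resolution)) {
      if (length(res_avail) > 1L) {
        stop("container stores multiple resolutions (",
             paste(res_avail, collapse = ", "),
             "); select one with `resolution`", call. = FALSE)
      }
      resolution <- as.integer(res_avail)
    } else if (!as.character(resolution) %in% res_avail) {
      stop("resolution ", resolution, " not in container (available: ",
           paste(res_avail, collapse = ", "), ")", call. = FALSE)
    }
    root <- paste0("/resolutions/", as.integer(resolution))
  }

  chrom_names <- as.character(rhdf5::h5read(path, paste0(root, "/chroms/name")))
  ci <- match(chrom, chrom_names)
  if (is.na(ci)) {
    stop("chromosome '", chrom, "' not in container (available: ",
         paste(chrom_names, collapse = ", "), ")", call. = FALSE)
  }

  bin_chrom_raw <- rhdf5::h5read(path, paste0(root, "/bins/chrom"))
  # cooler stores bins/chrom either as an HDF5 enum (decoded to factor/character
  # levels = chrom names) or as integer codes into /chroms/name
  bin_chrom <- if (is.numeric(bin_chrom_raw)) {
    chrom_names[as.integer(bin_chrom_raw) + 1L]
  } else {
    as.character(bin_chrom_raw)
  }
  bin_start <- as.numeric(rhdf5::h5read(path, paste0(root, "/bins/start")))
  bin_end <- as.numeric(rhdf5::h5read(path, paste0(root, "/bins/end")))
  res <- stats::median(bin_end - bin_start)
  if (!is.null(resolution) && res != resolution) {
    stop("container bin width ", res, " does not match requested resolution ",
         resolution, call. = FALSE)
  }

  sel <- which(bin_chrom == chrom)           # 1-based global bin ids
  n <- length(sel)
  offset <- sel[1L] - 1L                     # bins of one chrom are contiguous
  if (any(diff(sel) != 1L)) {
    stop("bins of chromosome '", chrom, "' are not contiguous in container",
         call. = FALSE)
  }

  b1 <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/bin1_id")))
  b2 <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/bin2_id")))
  cnt <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/count")))
  keep <- b1 >= offset & b1 < offset + n & b2 >= offset & b2 < offset + n
  m <- matrix(0, n, n)
  if (any(keep)) {
    ii <- b1[keep] - offset + 1L
    jj <- b2[keep] - offset + 1L
    m[cbind(ii, jj)] <- cnt[keep]
    m[cbind(jj, ii)] <- cnt[keep]
  }
  contact_matrix(m, genomic_binning(chrom, res, n))
}

#' Write a minimal single-resolution cooler container
#'
#' Serializes one or more intra-chromosomal [contact_matrix()] objects into
#' the single-resolution cooler HDF5 layout (`/chroms`, `/bins`, `/pixels`
#' with upper-triangle pixels). Intended for fixtures and interchange with
#' cooler-based tooling; all matrices must share one resolution.
#'
#' @param mats A [contact_matrix()] or list of them (distinct chromosomes).
#' @param path Output `.cool` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_cool <- function(mats, path) {
  if (inherits(mats, "contact_matrix")) mats <- list(mats)
  res <- unique(vapply(mats, function(m) m$binning$resolution, integer(1L)))
  if (length(res) != 1L) stop("all matrices must share one resolution", call. = FALSE)
  chroms <- vapply(mats, function(m) m$binning$chrom, character(1L))
  if (anyDuplicated(chroms)) stop("duplicate chromosome labels", call. = FALSE)

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5createGroup(path, "chroms")
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5createGroup(path, "pixels")

  n_per <- vapply(mats, function(m) m$binning$n_bins, integer(1L))
  rhdf5::h5write(chroms, path, "chroms/name")
  rhdf5::h5write(as.integer(n_per * res), path, "chroms/length")

  bin_chrom <- rep(seq_along(mats) - 1L, n_per)     # integer codes
  bin_start <- unlist(lapply(n_per, function(n) (seq_len(n) - 1L) * res))
  rhdf5::h5write(bin_chrom, path, "bins/chrom")
  rhdf5::h5write(as.integer(bin_start), path, "bins/start")
  rhdf5::h5write(as.integer(bin_start + res), path, "bins/end")

  offs <- c(0L, cumsum(n_per))
  px <- lapply(seq_along(mats), function(k) {
    v <- mats[[k]]$values
    up <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    data.frame(
      bin1_id = offs[k] + up[, 1L] - 1L,
      bin2_id = offs[k] + up[, 2L] - 1L,
      count = v[up]
    )
  })
  px <- do.call(rbind, px)
  px <- px[order(px$bin1_id, px$bin2_id), , drop = FALSE]
  rhdf5::h5write(as.integer(px$bin1_id), path, "pixels/bin1_id")
  rhdf5::h5write(as.integer(px$bin2_id), path, "pixels/bin2_id")
  rhdf5::h5write(px$count, path, "pixels/count")
  invisible(path)
}
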