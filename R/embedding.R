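#' Per-bin feature matrix of a set of TAD datasets
#'
#' Turns each dataset into a length-`n_bins` indicator vector so that
#' datasets can be compared as points in bin space:
#' \describe{
#'   \item{`boundary`}{1 at every boundary bin.}
#'   \item{`occupancy`}{1 at every bin covered by a domain.}
#'   \item{`boundary_dilated`}{boundary indicator dilated by
#'     `tolerance` bins on each side, so near-miss boundaries still
#'     contribute similarity — the embedding analogue of tolerance
#'     matching. The default feeding the embeddings.}
#' }
#'
#' @param sets List of `K >= 2` [tad_set()] on a common binning, unique
#'   labels.
#' @param mode `"boundary_dilated"` (default), `"boundary"` or
#'   `"occupancy"`.
#' @param tolerance Dilation half-width in bins for `boundary_dilated`
#'   (default 1).
#' @return A `K x n_bins` 0/1 matrix with dataset labels as rownames.
#' @export
vectorize_tad_sets <- function(sets, mode = c("boundary_dilated", "boundary", "occupancy"),
                               tolerance = 1L) {
  mode <- match.arg(mode)
  if (length(sets) < 2L) stop("need at least 2 datasets", call. = FALSE)
  stopifnot_same_binning(sets)
  labels <- vapply(sets, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("dataset labels must be unique", call. = FALSE)
  n_bins <- sets[[1L]]$binning$n_bins
  # a boundary at bin n_bins (falling edge of the last domain) is kept by
  # clamping into the vector
  rows <- lapply(sets, function(s) {
    v <- numeric(n_bins)
    if (mode == "occupancy") {
      d <- s$domains
      for (k in seq_len(nrow(d))) v[(d$start_bin[k] + 1L):d$end_bin[k]] <- 1
    } else {
      b <- boundaries_of(s)
      if (mode == "boundary_dilated" && tolerance > 0) {
        b <- unique(unlist(lapply(b, function(x) (x - tolerance):(x + tolerance))))
      }
      b <- b[b >= 0 & b <= n_bins]
      v[pmin(b + 1L, n_bins)] <- 1
    }
    v
  })
  out <- do.call(rbind, rows)
  rownames(out) <- labels
  out
}

#' PCA embedding of TAD datasets
#'
#' Projects the (row-centred) feature matrix onto its top two principal
#' axes. The sign of each axis is fixed by orienting its loading vector
#' against a fixed reference direction, making coordinates reproducible
#' and independent of the order in which datasets are supplied. With only two
#' datasets the second component is identically zero; if all datasets are
#' identical every point sits at the origin (with a warning).
#'
#' @param features `K x n_bins` matrix from [vectorize_tad_sets()].
#' @return A data.frame of class `embedding2d` with columns `label`, `x`,
#'   `y`, `method`, `seed` (`NA` — PCA is deterministic).
#' @export
pca_embed <- function(features) {
  if (nrow(features) < 2L) stop("need at least 2 datasets", call. = FALSE)
  centered <- scale(features, center = TRUE, scale = FALSE)
  if (max(abs(centered)) == 0) {
    warning("all datasets identical: zero-variance features, all points at origin",
            call. = FALSE)
    coords <- matrix(0, nrow(features), 2L)
  } else {
    p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
    ncomp <- min(2L, ncol(p$rotation))
    coords <- matrix(0, nrow(features), 2L)
    for (j in seq_len(ncomp)) {
      rot <- p$rotation[, j]
      # orient each axis against a fixed reference direction; the
      # largest-loading rule is the fallback when the projection is
      # numerically zero (stable under dataset reordering either way)
      ref <- sum(rot * cos(seq_along(rot)))
      flip <- if (abs(ref) > 1e-9) sign(ref) else {
        if (rot[which.max(abs(rot))] < 0) -1 else 1
      }
      coords[, j] <- flip * p$x[, j]
    }
  }
  structure(
    data.frame(label = rownames(features), x = coords[, 1L], y = coords[, 2L],
               method = "PCA", seed = NA_integer_, row.names = NULL),
    class = c("embedding2d", "data.frame")
  )
}

#' t-SNE embedding of TAD datasets
#'
#' Exact (theta = 0) t-SNE on the feature rows. The run is fully seeded:
#' identical features and seed give bit-identical coordinates. Perplexity
#' must satisfy `perplexity < (K - 1) / 3`; larger requests are clamped
#' with a warning. The default is `min(30, (K - 1) / 3 - eps)`. By default
#' the map is initialized from the two leading principal components
#' (shrunk to the conventional 1e-4 scale), which preserves the global
#' arrangement of the datasets far better than a random start at the small
#' `K` typical of TAD comparisons; `init = "random"` gives the classic
#' Gaussian initialization.
#'
#' @param features `K x n_bins` matrix, `K >= 4`.
#' @param seed Integer RNG seed (default 0).
#' @param perplexity Target perplexity; `NULL` for the default.
#' @param max_iter Gradient-descent iterations (default 500).
#' @param init `"pca"` (default) or `"random"`.
#' @return A data.frame of class `embedding2d` with columns `label`, `x`,
#'   `y`, `method`, `seed`.
#' @export
tsne_embed <- function(features, seed = 0L, perplexity = NULL, max_iter = 500L,
                       init = c("pca", "random")) {
  init <- match.arg(init)
  K <- nrow(features)
  if (K < 4L) stop("t-SNE needs at least 4 datasets, got ", K, call. = FALSE)
  if (any(!is.finite(features))) stop("non-finite features", call. = FALSE)
  pmax_allowed <- (K - 1) / 3
  if (is.null(perplexity)) {
    perplexity <- min(30, pmax_allowed - 1e-9)
  } else if (perplexity >= pmax_allowed) {
    warning(sprintf("perplexity %.3g too large for K = %d; clamped below %.3g",
                    perplexity, K, pmax_allowed), call. = FALSE)
    perplexity <- pmax_allowed - 1e-9
  }
  y_init <- NULL
  if (init == "pca") {
    pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)$x
    if (ncol(pc) < 2L) pc <- cbind(pc, 0)
    pc <- pc[, 1:2, drop = FALSE]
    sc <- max(abs(pc))
    if (sc > 0) y_init <- pc * (1e-4 / sc)
    # all-identical datasets: fall through to random initialization
  }
  coords <- withr::with_seed(as.integer(seed), {
    Rtsne::Rtsne(features, dims = 2L, perplexity = perplexity, theta = 0,
                 max_iter = as.integer(max_iter), pca = FALSE,
                 Y_init = y_init,
                 check_duplicates = FALSE, verbose = FALSE)$Y
  })
  structure(
    data.frame(label = rownames(features), x = coords[, 1L], y = coords[, 2L],
               method = "TSNE", seed = as.integer(seed), row.names = NULL),
    class = c("embedding2d", "data.frame")
  )
}
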