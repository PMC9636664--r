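#' Specification for a synthetic TAD partition
#'
#' Describes the left-to-right generative model used to build test
#' partitions: domain sizes drawn uniformly from `min_size..max_size` bins,
#' with an optional gap (probability `gap_prob`, size uniform on
#' `1..gap_max`) before each domain, until the region of `n_bins` bins is
#' exhausted. Defaults emulate a 20 Mb region at 40 kb resolution with
#' TADs of 0.2–1 Mb and occasional unassigned gaps.
#'
#' @param n_bins Region length in bins (default 500).
#' @param min_size,max_size Domain size bounds in bins (defaults 5 and 25).
#' @param gap_prob Probability of inserting a gap before a domain
#'   (default 0.1).
#' @param gap_max Maximum gap size in bins (default 3).
#' @param seed Integer RNG seed (default 0).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 500L, min_size = 5L, max_size = 25L,
                           gap_prob = 0.1, gap_max = 3L, seed = 0L) {
  n_bins <- as.integer(n_bins)
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (min_size < 1L || max_size < min_size) {
    stop("need 1 <= min_size <= max_size", call. = FALSE)
  }
  if (min_size > n_bins) stop("min_size exceeds n_bins", call. = FALSE)
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be in [0, 1]", call. = FALSE)
  if (gap_max < 1L) stop("gap_max must be >= 1", call. = FALSE)
  structure(
    list(n_bins = n_bins, min_size = min_size, max_size = max_size,
         gap_prob = gap_prob, gap_max = as.integer(gap_max),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Uniform integer draw on lo..hi, safe when lo == hi.
.runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a synthetic TAD partition
#'
#' Lays domains left to right according to a [synthetic_spec()]:
#' optionally a gap, then a domain of uniform size, stopping as soon as the
#' next domain would exceed `n_bins`. Deterministic given the spec's seed.
#' With `gap_prob = 0` and `min_size = max_size` dividing `n_bins`, the
#' output tiles the region exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param label Dataset label (default `"synthetic"`).
#' @param chrom,resolution Binning frame labels (defaults `"chrS"`,
#'   40000 bp).
#' @return A validated [tad_set()].
#' @export
generate_partition <- function(spec, label = "synthetic",
                               chrom = "chrS", resolution = 40000L) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be a synthetic_spec", call. = FALSE)
  }
  binning <- genomic_binning(chrom, resolution, spec$n_bins)
  withr::with_seed(spec$seed, {
    starts <- integer()
    ends <- integer()
    pos <- 0L
    repeat {
      gap <- if (spec$gap_prob > 0 && stats::runif(1L) < spec$gap_prob) {
        .runif_int(1L, spec$gap_max)
      } else 0L
      size <- .runif_int(spec$min_size, spec$max_size)
      if (pos + gap + size > spec$n_bins) break
      pos <- pos + gap
      starts <- c(starts, pos)
      ends <- c(ends, pos + size)
      pos <- pos + size
    }
    tad_set(label, binning, starts, ends)
  })
}

#' Jitter the boundaries of a TAD dataset
#'
#' Perturbs each boundary by a uniform integer offset in
#' `-magnitude..magnitude`, emulating the bin-level disagreement between
#' TAD callers. Boundary positions are processed left to right; the shared
#' corner of two adjacent domains moves as one unit, and each move is
#' clamped to stop one bin short of the previously placed boundary and of
#' the next original boundary, so domain order, minimum sizes and the
#' region bounds are always preserved. `magnitude = 0` returns the input
#' unchanged.
#'
#' @param tads A [tad_set()].
#' @param magnitude Nonnegative integer jitter half-width in bins.
#' @param seed Integer RNG seed (default 0).
#' @return A valid [tad_set()] with the same number of domains.
#' @export
jitter_tads <- function(tads, magnitude, seed = 0L) {
  validate_tad_set(tads)
  if (magnitude < 0) stop("`magnitude` must be >= 0", call. = FALSE)
  magnitude <- as.integer(magnitude)
  if (magnitude == 0L || nrow(tads$domains) == 0L) return(tads)

  d <- tads$domains
  n <- nrow(d)
  coords <- c(rbind(d$start_bin, d$end_bin))        # s1 e1 s2 e2 ... nondecreasing
  # a shared corner (end == next start) is one token; drop the duplicate
  # s_{k+1} coordinate and propagate afterwards
  drop <- integer()
  if (n > 1L) drop <- 2L * which(d$end_bin[-n] == d$start_bin[-1L]) + 1L
  tokens <- setdiff(seq_along(coords), drop)

  withr::with_seed(as.integer(seed), {
    new <- coords
    prev_final <- -1L
    for (t in seq_along(tokens)) {
      i <- tokens[t]
      delta <- .runif_int(-magnitude, magnitude)
      lower <- max(0L, prev_final + 1L)
      upper <- if (t < length(tokens)) coords[tokens[t + 1L]] - 1L else tads$binning$n_bins
      new[i] <- min(max(coords[i] + delta, lower), upper)
      prev_final <- new[i]
    }
    for (i in drop) new[i] <- new[i - 1L]
    tad_set(tads$label, tads$binning,
            new[seq(1L, 2L * n, by = 2L)], new[seq(2L, 2L * n, by = 2L)])
  })
}

#' Merge and split domains at random
#'
#' Models the two canonical disagreement modes between TAD callers:
#' merging adjacent domains ("fewer large TADs") and splitting domains in
#' two ("many small TADs"). Adjacent pairs are merged left to right with
#' probability `p_merge` (merges cascade, so `p_merge = 1` collapses a
#' gap-free partition into one domain); each surviving domain of size >= 2
#' is then split at a uniform interior point with probability `p_split`.
#'
#' @param tads A [tad_set()].
#' @param p_merge,p_split Probabilities in `[0, 1]`.
#' @param seed Integer RNG seed (default 0).
#' @return A valid [tad_set()].
#' @export
merge_split <- function(tads, p_merge = 0, p_split = 0, seed = 0L) {
  validate_tad_set(tads)
  if (p_merge < 0 || p_merge > 1 || p_split < 0 || p_split > 1) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  d <- tads$domains
  if (nrow(d) == 0L) return(tads)
  withr::with_seed(as.integer(seed), {
    starts <- d$start_bin[1L]
    ends <- d$end_bin[1L]
    for (k in seq_len(nrow(d))[-1L]) {
      if (p_merge > 0 && stats::runif(1L) < p_merge) {
        ends[length(ends)] <- d$end_bin[k]
      } else {
        starts <- c(starts, d$start_bin[k])
        ends <- c(ends, d$end_bin[k])
      }
    }
    out_s <- integer()
    out_e <- integer()
    for (k in seq_along(starts)) {
      size <- ends[k] - starts[k]
      if (size >= 2L && p_split > 0 && stats::runif(1L) < p_split) {
        cut <- starts[k] + .runif_int(1L, size - 1L)
        out_s <- c(out_s, starts[k], cut)
        out_e <- c(out_e, cut, ends[k])
      } else {
        out_s <- c(out_s, starts[k])
        out_e <- c(out_e, ends[k])
      }
    }
    tad_set(tads$label, tads$binning, out_s, out_e)
  })
}

#' Generate a block-model contact matrix from a TAD partition
#'
#' Builds a symmetric Poisson count matrix whose diagonal blocks follow the
#' domains of `tads`: entries inside a domain block have mean `intra_rate`,
#' all other entries mean `inter_rate`. A crude but sufficient emulation of
#' the elevated intra-TAD contact frequency that callers exploit; it has no
#' genomic distance decay.
#'
#' @param tads A [tad_set()].
#' @param intra_rate,inter_rate Poisson means, `intra_rate > inter_rate >= 0`.
#' @param seed Integer RNG seed (default 0).
#' @return A [contact_matrix()] on the same binning.
#' @export
generate_matrix <- function(tads, intra_rate = 30, inter_rate = 2, seed = 0L) {
  validate_tad_set(tads)
  if (!(intra_rate > inter_rate) || inter_rate < 0) {
    stop("need intra_rate > inter_rate >= 0", call. = FALSE)
  }
  n <- tads$binning$n_bins
  lambda <- matrix(inter_rate, n, n)
  d <- tads$domains
  for (k in seq_len(nrow(d))) {
    idx <- (d$start_bin[k] + 1L):d$end_bin[k]
    lambda[idx, idx] <- intra_rate
  }
  withr::with_seed(as.integer(seed), {
    up <- upper.tri(lambda, diag = TRUE)
    vals <- stats::rpois(sum(up), lambda[up])
    m <- matrix(0, n, n)
    m[up] <- vals
    m <- m + t(m)
    diag(m) <- diag(m) / 2
    contact_matrix(m, tads$binning)
  })
}
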