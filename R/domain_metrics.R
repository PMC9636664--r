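#' Number of domains in a TAD dataset
#'
#' @param tads A [tad_set()].
#' @return Integer domain count.
#' @export
count_tads <- function(tads) {
  validate_tad_set(tads)
  nrow(tads$domains)
}

#' Five-number-plus-mean summary of domain sizes
#'
#' Sizes are reported in genomic bins. Quartiles use linear interpolation
#' between order statistics (R's default quantile type 7), so e.g. sizes
#' `{1,2,3,4}` give `q1 = 1.75`, `median = 2.5`, `q3 = 3.25`.
#'
#' @param tads A non-empty [tad_set()].
#' @return A one-row data.frame with columns `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`.
#' @export
size_stats <- function(tads) {
  validate_tad_set(tads)
  sz <- tad_sizes(tads)
  if (!length(sz)) stop("size_stats of an empty tad_set", call. = FALSE)
  q <- stats::quantile(sz, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  data.frame(
    n = length(sz), min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
    max = q[5L], mean = mean(sz)
  )
}

#' Shared boundaries between two boundary sets at a tolerance
#'
#' A boundary `x` of `a` counts as shared when some boundary of `b` lies
#' within `tolerance` bins of it (`|x - y| <= tolerance`). Matching is
#' existential, not one-to-one: two boundaries of `a` may match the same
#' boundary of `b`, and the count is asymmetric in general. At tolerance 0
#' boundaries must be identical; tolerance `t` corresponds to
#' `t * resolution` bp.
#'
#' @param a,b Sorted integer vectors of boundary bins, as returned by
#'   [boundaries_of()].
#' @param tolerance Nonnegative integer, in bins.
#' @return A list with `count` (number of shared boundaries of `a`) and
#'   `shared` (the matched subset of `a`).
#' @export
shared_boundaries <- function(a, b, tolerance = 0L) {
  if (length(tolerance) != 1L || is.na(tolerance) || tolerance < 0 ||
      tolerance != floor(tolerance)) {
    stop("`tolerance` must be a nonnegative integer", call. = FALSE)
  }
  if (!length(a)) return(list(count = 0L, shared = integer()))
  if (!length(b)) return(list(count = 0L, shared = integer()))
  # nearest element of sorted b for each a
  pos <- findInterval(a, b)
  lo <- b[pmax(pos, 1L)]
  hi <- b[pmin(pos + 1L, length(b))]
  nearest <- pmin(abs(a - lo), abs(a - hi))
  hit <- nearest <= tolerance
  list(count = sum(hit), shared = a[hit])
}

#' Shared domains between two TAD datasets at a tolerance
#'
#' A domain `[s, e)` of `a` is shared when some domain `[s', e')` of `b` has
#' both its rising and falling boundary within tolerance:
#' `|s - s'| <= t` and `|e - e'| <= t`. Matching is existential, as for
#' [shared_boundaries()].
#'
#' @param a,b [tad_set()] objects on the same binning.
#' @param tolerance Nonnegative integer, in bins.
#' @return A list with `count` and `shared` (matched rows of `a$domains`).
#' @export
shared_domains <- function(a, b, tolerance = 0L) {
  stopifnot_same_binning(list(a, b))
  if (length(tolerance) != 1L || is.na(tolerance) || tolerance < 0 ||
      tolerance != floor(tolerance)) {
    stop("`tolerance` must be a nonnegative integer", call. = FALSE)
  }
  da <- a$domains
  db <- b$domains
  if (!nrow(da) || !nrow(db)) {
    return(list(count = 0L, shared = da[integer(), ]))
  }
  hit <- vapply(seq_len(nrow(da)), function(k) {
    any(abs(da$start_bin[k] - db$start_bin) <= tolerance &
          abs(da$end_bin[k] - db$end_bin) <= tolerance)
  }, logical(1L))
  list(count = sum(hit), shared = da[hit, , drop = FALSE])
}

#' One-vs-all shared-boundary (or shared-domain) table
#'
#' Compares a reference dataset against each other dataset across a range of
#' tolerances; entry `(d, t)` is the raw count of reference boundaries
#' (or domains) matched in dataset `d` at tolerance `t`. Counts are
#' non-decreasing along the tolerance axis.
#'
#' @param ref Reference [tad_set()].
#' @param others Non-empty list of [tad_set()] on the same binning.
#' @param tolerances Integer vector of tolerances in bins (default `0:3`).
#' @param mode `"boundaries"` or `"domains"`.
#' @return A data.frame with columns `dataset`, `tolerance`, `shared`,
#'   `total` (the reference's element count).
#' @export
one_vs_all <- function(ref, others, tolerances = 0:3,
                       mode = c("boundaries", "domains")) {
  mode <- match.arg(mode)
  if (!length(others)) stop("`others` must contain at least one dataset", call. = FALSE)
  stopifnot_same_binning(c(list(ref), others))
  bref <- boundaries_of(ref)
  total <- if (mode == "boundaries") length(bref) else nrow(ref$domains)
  rows <- lapply(others, function(d) {
    cnt <- vapply(tolerances, function(t) {
      if (mode == "boundaries") {
        shared_boundaries(bref, boundaries_of(d), t)$count
      } else {
        shared_domains(ref, d, t)$count
      }
    }, numeric(1L))
    data.frame(dataset = d$label, tolerance = tolerances, shared = cnt,
               total = total)
  })
  do.call(rbind, rows)
}

#' All-vs-all sharing profile
#'
#' For every dataset `d` and every one of its elements (boundaries or
#' domains), counts how many of the *other* `K - 1` datasets contain a match
#' within the tolerance, and histograms those counts. This is the
#' machine-readable form of the percentage-based stacked bar chart: a tall
#' bar at `k = K - 1` means consensus, mass at `k = 0` means unique calls.
#'
#' @param sets List of `K >= 2` [tad_set()] on a common binning, with unique
#'   labels.
#' @param tolerance Nonnegative integer, bins.
#' @param mode `"boundaries"` or `"domains"`.
#' @return A data.frame with columns `dataset`, `k` (0..K-1), `count` and
#'   `percent`; per dataset the counts sum to its element total and the
#'   percentages to 100 (or 0 for an empty dataset).
#' @export
sharing_profile <- function(sets, tolerance = 1L,
                            mode = c("boundaries", "domains")) {
  mode <- match.arg(mode)
  K <- length(sets)
  if (K < 2L) stop("sharing_profile needs at least 2 datasets", call. = FALSE)
  stopifnot_same_binning(sets)
  labels <- vapply(sets, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("dataset labels must be unique", call. = FALSE)

  rows <- lapply(seq_len(K), function(d) {
    if (mode == "boundaries") {
      el <- boundaries_of(sets[[d]])
      n_el <- length(el)
      hits <- lapply(setdiff(seq_len(K), d), function(o) {
        bo <- boundaries_of(sets[[o]])
        vapply(el, function(x) length(bo) > 0 && min(abs(x - bo)) <= tolerance,
               logical(1L))
      })
    } else {
      dd <- sets[[d]]$domains
      n_el <- nrow(dd)
      hits <- lapply(setdiff(seq_len(K), d), function(o) {
        do <- sets[[o]]$domains
        vapply(seq_len(n_el), function(i) {
          nrow(do) > 0 && any(abs(dd$start_bin[i] - do$start_bin) <= tolerance &
                                abs(dd$end_bin[i] - do$end_bin) <= tolerance)
        }, logical(1L))
      })
    }
    k_per <- if (n_el) rowSums(matrix(unlist(hits), nrow = n_el)) else integer()
    counts <- tabulate(k_per + 1L, nbins = K)  # k = 0 .. K-1
    data.frame(
      dataset = labels[d], k = 0:(K - 1L), count = counts,
      percent = if (n_el) 100 * counts / n_el else rep(0, K)
    )
  })
  do.call(rbind, rows)
}
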