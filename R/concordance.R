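#' Per-pair overlap term of the Measure of Concordance
#'
#' For two domains the term is `|a intersect b|^2 / (|a| * |b|)` with sizes
#' and overlap measured in bins (the term is scale-invariant, so any common
#' unit gives the same value); 0 when the domains are disjoint, 1 when they
#' are identical.
#'
#' @param a_start,a_end,b_start,b_end Domain coordinates as 0-based
#'   half-open bin intervals; vectors recycle in the usual way.
#' @return Numeric vector of overlap terms in `[0, 1]`.
#' @examples
#' overlap_term(0, 10, 8, 20)  # 2^2 / (10 * 12) = 1/30
#' @export
overlap_term <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ov^2 / ((a_end - a_start) * (b_end - b_start))
}

#' Measure of Concordance between two TAD datasets
#'
#' MoC summarizes how well two domain partitions agree. With
#' `S = sum_{i,j} |A_i intersect B_j|^2 / (|A_i| |B_j|)` over all domain
#' pairs, and `N_A`, `N_B` the domain counts,
#' `MoC = (S - 1) / (sqrt(N_A * N_B) - 1)`, with `MoC = 1` by convention
#' when `N_A = N_B = 1`. Identical datasets score exactly 1; the score is
#' symmetric. For datasets that fully tile the region MoC is nonnegative;
#' gapped datasets can in pathological disjoint cases score below 0, which
#' is reported raw with a warning rather than clamped — a negative value
#' flags a data problem worth seeing.
#'
#' @param a,b Non-empty [tad_set()] objects on the same binning.
#' @return A single numeric MoC value, at most 1.
#' @examples
#' bn <- genomic_binning("chr1", 1L, 20L)
#' x <- tad_set("halves", bn, c(0L, 10L), c(10L, 20L))
#' y <- tad_set("offset", bn, c(0L, 12L), c(12L, 20L))
#' moc(x, x)  # 1
#' moc(x, y)  # 2/3
#' @export
moc <- function(a, b) {
  stopifnot_same_binning(list(a, b))
  na <- nrow(a$domains)
  nb <- nrow(b$domains)
  if (na == 0L || nb == 0L) stop("MoC of an empty tad_set is undefined", call. = FALSE)
  if (na == 1L && nb == 1L) return(1)
  ov <- pmax(0, outer(a$domains$end_bin, b$domains$end_bin, pmin) -
               outer(a$domains$start_bin, b$domains$start_bin, pmax))
  s <- sum(ov^2 / outer(tad_sizes(a), tad_sizes(b)))
  val <- (s - 1) / (sqrt(na * nb) - 1)
  if (val < 0) {
    warning(sprintf("MoC(%s, %s) = %.4g is negative: datasets share almost no coverage",
                    a$label, b$label, val), call. = FALSE)
  }
  val
}

#' One-vs-all MoC vector
#'
#' @param ref Reference [tad_set()].
#' @param others Non-empty list of [tad_set()] on the same binning.
#' @return Named numeric vector `moc(ref, d)` for each other dataset `d`.
#' @export
moc_one_vs_all <- function(ref, others) {
  if (!length(others)) stop("`others` must contain at least one dataset", call. = FALSE)
  out <- vapply(others, function(d) moc(ref, d), numeric(1L))
  names(out) <- vapply(others, `[[`, "", "label")
  out
}

#' All-vs-all MoC matrix with per-dataset averages
#'
#' Computes the full symmetric `K x K` MoC matrix (unit diagonal) and, for
#' each dataset, the mean MoC over the other `K - 1` datasets — the
#' all-vs-all average that summarizes each dataset's overall agreement.
#'
#' @param sets List of `K >= 2` [tad_set()] on a common binning, unique
#'   labels, all non-empty.
#' @return A list of class `moc_matrix` with `labels`, `values`
#'   (the matrix, dimnames = labels) and `averages` (named vector).
#' @export
moc_matrix_and_average <- function(sets) {
  K <- length(sets)
  if (K < 2L) stop("need at least 2 datasets", call. = FALSE)
  stopifnot_same_binning(sets)
  labels <- vapply(sets, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("dataset labels must be unique", call. = FALSE)
  m <- diag(1, K)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      m[i, j] <- m[j, i] <- moc(sets[[i]], sets[[j]])
    }
  }
  dimnames(m) <- list(labels, labels)
  averages <- vapply(seq_len(K), function(i) mean(m[i, -i]), numeric(1L))
  names(averages) <- labels
  structure(list(labels = labels, values = m, averages = averages),
            class = "moc_matrix")
}

#' @export
print.moc_matrix <- function(x, ...) {
  cat("<moc_matrix>", length(x$labels), "datasets\n")
  print(round(x$values, 3))
  cat("averages:\n")
  print(round(x$averages, 3))
  invisible(x)
}
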