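#' Balance a Hi-C contact matrix
#'
#' Applies one of five standard matrix-balancing (bias-correction) methods.
#' Bins with zero marginal sum are masked before balancing and restored as
#' zero rows/columns afterwards; balancing diverges on zero marginals.
#'
#' Methods, writing `M` for the unmasked submatrix and `r` for its row sums:
#' \describe{
#'   \item{`vc`}{Vanilla coverage: `out_ij = m_ij / (r_i r_j)`, rescaled so
#'     the total sum equals the input sum.}
#'   \item{`sqrt_vc`}{As `vc` with `sqrt(r_i r_j)` in the denominator.}
#'   \item{`kr`}{Knight–Ruiz-style diagonal scaling: find `d > 0` such that
#'     `diag(d) M diag(d)` has all unmasked row sums equal to 1 within
#'     `tol`, via the symmetric fixed point `d <- d / sqrt(d * (M d))`.}
#'   \item{`ice`}{Iterative correction: repeatedly divide by the outer
#'     product of mean-centred marginals until unmasked row sums agree
#'     within relative `tol`; result rescaled to unit mean over unmasked
#'     entries.}
#'   \item{`scn`}{Sequential component normalization: alternate row and
#'     column L2 normalization followed by symmetrization, iterated to
#'     `tol`.}
#' }
#'
#' @param mat A [contact_matrix()].
#' @param method One of `"vc"`, `"sqrt_vc"`, `"kr"`, `"ice"`, `"scn"`
#'   (case-insensitive).
#' @param max_iter Iteration cap for the iterative methods; defaults to
#'   3000 for `kr`, 200 for `ice`/`scn`.
#' @param tol Convergence tolerance on the row-sum (or iterate-change)
#'   residual; default `1e-5`.
#' @return A [contact_matrix()] of the same shape, symmetric and
#'   nonnegative, with attributes `method`, `iterations` and `residual`.
#'   Iterative methods stop with an error reporting the final residual if
#'   they fail to converge within `max_iter`.
#' @examples
#' b <- genomic_binning("chrS", 1L, 2L)
#' m <- contact_matrix(matrix(c(0, 2, 2, 0), 2), b)
#' normalize_matrix(m, "kr")$values   # [[0,1],[1,0]]
#' @export
normalize_matrix <- function(mat, method = c("vc", "sqrt_vc", "kr", "ice", "scn"),
                             max_iter = NULL, tol = 1e-5) {
  if (!inherits(mat, "contact_matrix")) {
    stop("`mat` must be a contact_matrix", call. = FALSE)
  }
  method <- match.arg(tolower(method[1L]), c("vc", "sqrt_vc", "kr", "ice", "scn"))
  if (is.null(max_iter)) max_iter <- if (method == "kr") 3000L else 200L

  n <- nrow(mat$values)
  keep <- setdiff(seq_len(n), mat$mask + 1L)
  if (!length(keep)) stop("all-zero matrix cannot be balanced", call. = FALSE)
  m <- mat$values[keep, keep, drop = FALSE]

  res <- switch(method,
    vc = .balance_vc(m, sqrt_denom = FALSE),
    sqrt_vc = .balance_vc(m, sqrt_denom = TRUE),
    kr = .balance_kr(m, max_iter, tol),
    ice = .balance_ice(m, max_iter, tol),
    scn = .balance_scn(m, max_iter, tol)
  )

  out <- matrix(0, n, n)
  out[keep, keep] <- (res$m + t(res$m)) / 2
  out <- contact_matrix(out, mat$binning)
  attr(out, "method") <- method
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  out
}

.balance_vc <- function(m, sqrt_denom) {
  r <- rowSums(m)
  denom <- outer(r, r)
  if (sqrt_denom) denom <- sqrt(denom)
  out <- m / denom
  out <- out * (sum(m) / sum(out))
  list(m = out, iterations = 0L, residual = 0)
}

.balance_kr <- function(m, max_iter, tol) {
  x <- rep(1, nrow(m))
  residual <- Inf
  for (it in seq_len(max_iter)) {
    s <- x * drop(m %*% x)          # row sums of diag(x) M diag(x)
    residual <- max(abs(s - 1))
    if (residual <= tol) {
      return(list(m = m * outer(x, x), iterations = it - 1L, residual = residual))
    }
    x <- x / sqrt(s)
  }
  stop(sprintf("KR balancing failed to converge in %d iterations (residual %.3g)",
               max_iter, residual), call. = FALSE)
}

.balance_ice <- function(m, max_iter, tol) {
  w <- m
  residual <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    s <- s / mean(s)
    residual <- max(abs(s - 1))
    if (residual <= tol) {
      w <- w / mean(w)              # unit mean over unmasked entries
      return(list(m = w, iterations = it - 1L, residual = residual))
    }
    w <- w / outer(s, s)
  }
  stop(sprintf("ICE failed to converge in %d iterations (residual %.3g)",
               max_iter, residual), call. = FALSE)
}

.balance_scn <- function(m, max_iter, tol) {
  w <- m
  residual <- Inf
  for (it in seq_len(max_iter)) {
    w_prev <- w
    rn <- sqrt(rowSums(w^2))
    w <- w / rn
    cn <- sqrt(colSums(w^2))
    w <- sweep(w, 2L, cn, "/")
    w <- (w + t(w)) / 2
    residual <- max(abs(w - w_prev)) / max(abs(w))
    if (residual <= tol) {
      return(list(m = w, iterations = it, residual = residual))
    }
  }
  stop(sprintf("SCN failed to converge in %d iterations (residual %.3g)",
               max_iter, residual), call. = FALSE)
}
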