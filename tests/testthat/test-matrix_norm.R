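bn2 <- genomic_binning("chrS", 1L, 2L)

test_that("dense matrix reading parses, masks zero bins and rejects bad input", {
  f <- withr::local_tempfile(lines = c("4 2", "2 1"))
  m <- read_dense_matrix(f, "chrS", 40000L)
  expect_equal(m$values, matrix(c(4, 2, 2, 1), 2))
  expect_equal(m$binning$n_bins, 2L)
  expect_length(m$mask, 0L)

  f2 <- withr::local_tempfile(lines = c("1 0 0", "0 0 0", "0 0 2"))
  m2 <- read_dense_matrix(f2, "chrS", 40000L)
  expect_equal(m2$mask, 1L)  # 0-based index of the all-zero bin

  f3 <- withr::local_tempfile(lines = c("1 2", "3 4"))
  expect_error(read_dense_matrix(f3, "chrS", 40000L), "asymmetry")

  f4 <- withr::local_tempfile(lines = c("1 2 3", "4 5"))
  expect_error(read_dense_matrix(f4, "chrS", 40000L), "ragged")

  f5 <- withr::local_tempfile(lines = c("1 -2", "-2 1"))
  expect_error(read_dense_matrix(f5, "chrS", 40000L), "negative")
})

test_that("sparse triplets symmetrize, auto-detect bp coordinates and sum duplicates", {
  f <- withr::local_tempfile(lines = "0 1 5")
  m <- read_sparse_triplet(f, "chrS", 40000L, 2L)
  expect_equal(m$values, matrix(c(0, 5, 5, 0), 2))

  f2 <- withr::local_tempfile(lines = c("0 0 2", "40000 80000 3"))
  m2 <- read_sparse_triplet(f2, "chrS", 40000L, 3L)
  expect_equal(m2$values[1, 1], 2)
  expect_equal(m2$values[2, 3], 3)
  expect_equal(m2$values[3, 2], 3)

  f3 <- withr::local_tempfile(lines = c("0 1 2", "1 0 3"))
  expect_warning(m3 <- read_sparse_triplet(f3, "chrS", 40000L, 2L),
                 "more than once")
  expect_equal(m3$values, matrix(c(0, 5, 5, 0), 2))

  f4 <- withr::local_tempfile(lines = "0 5 1")
  expect_error(read_sparse_triplet(f4, "chrS", 40000L, 3L), "out of range")
})

test_that("contact matrix written as dense or triplet reads back identically", {
  x <- generate_matrix(random_tad_set(11, n_bins = 20L), seed = 3L)
  fd <- tempfile()
  write_contact_matrix(x, fd, "dense")
  expect_equal(read_dense_matrix(fd, x$binning$chrom, x$binning$resolution)$values,
               x$values)
  ft <- tempfile()
  write_contact_matrix(x, ft, "triplet")
  expect_equal(read_sparse_triplet(ft, x$binning$chrom, x$binning$resolution,
                                   x$binning$n_bins)$values, x$values)
  unlink(c(fd, ft))
})

test_that("cooler round-trip: a written container extracts to the original matrix", {
  set.seed(5)
  a <- matrix(rpois(100, 6), 10)
  a <- a + t(a)
  m1 <- contact_matrix(a, genomic_binning("chr1", 40000L, 10L))
  b <- matrix(rpois(64, 4), 8)
  b <- b + t(b)
  m2 <- contact_matrix(b, genomic_binning("chr2", 40000L, 8L))

  f <- tempfile(fileext = ".cool")
  write_cool(list(m1, m2), f)
  got1 <- extract_chromosome(f, "chr1")
  got2 <- extract_chromosome(f, "chr2")
  expect_equal(got1$values, m1$values)
  expect_equal(got1$binning$resolution, 40000L)
  expect_equal(got2$values, m2$values)
  expect_error(extract_chromosome(f, "chr3"), "available: chr1, chr2")
  unlink(f)
})

test_that("VC matches its rank-1 closed form and conserves the total sum", {
  # rank-1 matrix r r^T: m_ij / (r_i r_j) is constant, rescaled to sum 9 -> 9/4
  m <- contact_matrix(matrix(c(4, 2, 2, 1), 2), bn2)
  out <- normalize_matrix(m, "vc")
  expect_equal(out$values, matrix(9 / 4, 2, 2), tolerance = 1e-12)
  expect_equal(sum(out$values), sum(m$values), tolerance = 1e-9)

  x <- generate_matrix(random_tad_set(2, n_bins = 30L), seed = 9L)
  outx <- normalize_matrix(x, "vc")
  expect_lt(abs(sum(outx$values) - sum(x$values)), 1e-9 * sum(x$values))
})

test_that("KR reproduces the 2x2 closed form and reaches unit row sums", {
  m <- contact_matrix(matrix(c(0, 2, 2, 0), 2), bn2)
  out <- normalize_matrix(m, "kr")
  expect_equal(out$values, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-9)

  x <- generate_matrix(random_tad_set(3, n_bins = 40L), seed = 1L)
  outx <- normalize_matrix(x, "kr")
  keep <- setdiff(seq_len(40), outx$mask + 1L)
  rs <- rowSums(outx$values)[keep]
  expect_lt(max(abs(rs - 1)), 1e-5)
})

test_that("ICE flattens rank-1 structure and equalizes row sums", {
  r <- c(1, 2, 3, 4)
  m <- contact_matrix(outer(r, r), genomic_binning("chrS", 1L, 4L))
  out <- normalize_matrix(m, "ice")
  # bias ~ 1/r_i makes the result constant
  expect_lt(diff(range(out$values)), 1e-4 * mean(out$values))
  expect_equal(mean(out$values), 1, tolerance = 1e-9)

  const <- contact_matrix(matrix(5, 3, 3), genomic_binning("chrS", 1L, 3L))
  outc <- normalize_matrix(const, "ice")
  expect_equal(outc$values / outc$values[1, 1], matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("all five methods preserve symmetry, nonnegativity, shape and the mask", {
  x <- generate_matrix(random_tad_set(4, n_bins = 30L), seed = 2L)
  # knock out a bin to create a mask
  v <- x$values
  v[7, ] <- 0
  v[, 7] <- 0
  x <- contact_matrix(v, x$binning)
  expect_equal(x$mask, 6L)
  for (meth in c("vc", "sqrt_vc", "kr", "ice", "scn")) {
    out <- normalize_matrix(x, meth)
    expect_equal(dim(out$values), dim(x$values))
    expect_true(all(out$values >= 0), info = meth)
    expect_lt(max(abs(out$values - t(out$values))), 1e-9 * max(out$values))
    expect_true(all(out$values[7, ] == 0), info = meth)  # mask restored as zeros
  }
})

test_that("KR and ICE are idempotent up to tolerance", {
  x <- generate_matrix(random_tad_set(6, n_bins = 30L), seed = 8L)
  for (meth in c("kr", "ice")) {
    once <- normalize_matrix(x, meth)
    twice <- normalize_matrix(once, meth)
    keep <- which(once$values != 0)
    rel <- max(abs(twice$values[keep] - once$values[keep]) / once$values[keep])
    expect_lt(rel, 10 * 1e-5)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  z <- contact_matrix(matrix(0, 3, 3), genomic_binning("chrS", 1L, 3L))
  expect_error(normalize_matrix(z, "kr"), "all-zero")
  m <- contact_matrix(matrix(c(0, 2, 2, 0), 2), bn2)
  expect_error(normalize_matrix(m, "ice", max_iter = 0L), "converge")
})
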