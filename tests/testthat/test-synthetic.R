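test_that("a gap-free equal-size spec tiles the region with a known count", {
  sp <- synthetic_spec(n_bins = 100L, min_size = 10L, max_size = 10L,
                       gap_prob = 0, seed = 1L)
  p <- generate_partition(sp)
  expect_equal(count_tads(p), 10L)
  expect_equal(p$domains$start_bin, seq(0L, 90L, by = 10L))
  expect_equal(p$domains$end_bin, seq(10L, 100L, by = 10L))
})

test_that("generation is seed-deterministic and respects size bounds", {
  sp <- synthetic_spec(n_bins = 300L, min_size = 5L, max_size = 20L,
                       gap_prob = 0.2, gap_max = 4L, seed = 9L)
  p1 <- generate_partition(sp)
  p2 <- generate_partition(sp)
  expect_identical(p1$domains, p2$domains)

  for (seed in 1:50) {
    p <- generate_partition(synthetic_spec(n_bins = 150L, min_size = 5L,
                                           max_size = 20L, gap_prob = 0.3,
                                           seed = seed))
    sz <- p$domains$end_bin - p$domains$start_bin
    expect_true(all(sz >= 5 & sz <= 20))
    expect_silent(validate_tad_set(p))
  }
  expect_error(synthetic_spec(n_bins = 4L, min_size = 10L), "exceeds n_bins")
})

test_that("jitter keeps validity, preserves counts and is the identity at magnitude 0", {
  x <- random_tad_set(1, n_bins = 200L)
  expect_identical(jitter_tads(x, 0L, seed = 5L), x)
  for (seed in 1:50) {
    for (m in c(1L, 3L, 8L)) {
      y <- jitter_tads(x, m, seed = seed)
      expect_silent(validate_tad_set(y))
      expect_equal(count_tads(y), count_tads(x))
      # boundaries move by at most the magnitude
      expect_lte(max(abs(y$domains$start_bin - x$domains$start_bin)), m)
      expect_lte(max(abs(y$domains$end_bin - x$domains$end_bin)), m)
    }
  }
  # shared corners of adjacent domains stay shared
  tight <- generate_partition(synthetic_spec(n_bins = 100L, gap_prob = 0, seed = 2L))
  j <- jitter_tads(tight, 4L, seed = 3L)
  n <- count_tads(j)
  expect_equal(j$domains$end_bin[-n], j$domains$start_bin[-1L])
})

test_that("merge_split reproduces its limit behaviours", {
  x <- generate_partition(synthetic_spec(n_bins = 100L, gap_prob = 0, seed = 4L))
  expect_identical(merge_split(x, 0, 0, seed = 1L)$domains, x$domains)

  merged <- merge_split(x, p_merge = 1, p_split = 0, seed = 1L)
  expect_equal(count_tads(merged), 1L)
  expect_equal(merged$domains$start_bin, min(x$domains$start_bin))
  expect_equal(merged$domains$end_bin, max(x$domains$end_bin))

  split <- merge_split(x, p_merge = 0, p_split = 1, seed = 1L)
  expect_equal(count_tads(split), 2L * count_tads(x))  # all sizes >= 2
  expect_silent(validate_tad_set(split))

  y1 <- merge_split(x, 0.4, 0.4, seed = 7L)
  y2 <- merge_split(x, 0.4, 0.4, seed = 7L)
  expect_identical(y1$domains, y2$domains)
})

test_that("block-model matrices are symmetric, seeded, with rates where expected", {
  x <- random_tad_set(5, n_bins = 60L, gap_prob = 0.3)
  m1 <- generate_matrix(x, intra_rate = 20, inter_rate = 0, seed = 2L)
  m2 <- generate_matrix(x, intra_rate = 20, inter_rate = 0, seed = 2L)
  expect_identical(m1$values, m2$values)
  expect_equal(m1$values, t(m1$values))

  # inter_rate 0 -> strictly block-diagonal support
  inblock <- matrix(FALSE, 60, 60)
  for (k in seq_len(nrow(x$domains))) {
    idx <- (x$domains$start_bin[k] + 1L):x$domains$end_bin[k]
    inblock[idx, idx] <- TRUE
  }
  expect_true(all(m1$values[!inblock] == 0))

  # intra-block mean within 3 standard errors of the rate
  big <- generate_matrix(
    generate_partition(synthetic_spec(n_bins = 200L, gap_prob = 0, seed = 3L)),
    intra_rate = 30, inter_rate = 2, seed = 4L)
  blocks <- matrix(FALSE, 200, 200)
  p <- generate_partition(synthetic_spec(n_bins = 200L, gap_prob = 0, seed = 3L))
  for (k in seq_len(nrow(p$domains))) {
    idx <- (p$domains$start_bin[k] + 1L):p$domains$end_bin[k]
    blocks[idx, idx] <- TRUE
  }
  vals <- big$values[blocks & upper.tri(blocks)]
  se <- sqrt(30 / length(vals))
  expect_lt(abs(mean(vals) - 30), 3 * se)
  expect_error(generate_matrix(x, intra_rate = 1, inter_rate = 2), "intra_rate")
})

test_that("perturbation operators rank identity/small/large correctly on all metrics", {
  n_seeds <- 40
  res <- sapply(1:n_seeds, function(s) {
    x <- random_tad_set(s, n_bins = 300L, min_size = 5L, max_size = 25L,
                        gap_prob = 0)
    j1 <- jitter_tads(x, 1L, seed = s + 1L)
    j8 <- jitter_tads(x, 8L, seed = s + 2L)
    c(
      moc0 = moc(x, x), moc1 = moc(x, j1), moc8 = moc(x, j8),
      sb1 = shared_boundaries(boundaries_of(x), boundaries_of(j1), 1L)$count,
      sb8 = shared_boundaries(boundaries_of(x), boundaries_of(j8), 1L)$count,
      sd1 = shared_domains(x, j1, 1L)$count,
      sd8 = shared_domains(x, j8, 1L)$count
    )
  })
  m <- rowMeans(res)
  expect_gt(m["moc0"], m["moc1"])
  expect_gt(m["moc1"], m["moc8"])
  expect_gt(m["sb1"], m["sb8"])
  expect_gt(m["sd1"], m["sd8"])
})
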