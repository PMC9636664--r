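bn30 <- genomic_binning("chr1", 1L, 30L)

test_that("count and size statistics follow the quantile convention", {
  expect_equal(count_tads(tad_set("e", bn30)), 0L)
  x <- tad_set("x", bn30, c(0L, 5L, 12L), c(5L, 9L, 20L))
  expect_equal(count_tads(x), 3L)

  bn <- genomic_binning("chr1", 1L, 100L)
  s3 <- tad_set("s", bn, c(0L, 20L, 50L), c(10L, 40L, 80L))  # sizes 10,20,30
  st <- size_stats(s3)
  expect_equal(st$min, 10)
  expect_equal(st$median, 20)
  expect_equal(st$max, 30)
  expect_equal(st$mean, 20)

  s4 <- tad_set("c", bn, c(0L, 10L, 20L, 30L), c(4L, 14L, 24L, 34L))
  expect_true(all(unlist(size_stats(s4)[c("min", "q1", "median", "q3", "max", "mean")]) == 4))

  # sizes 1,2,3,4 under linear interpolation
  s5 <- tad_set("q", bn, c(0L, 5L, 10L, 20L), c(1L, 7L, 13L, 24L))
  st5 <- size_stats(s5)
  expect_equal(st5$q1, 1.75)
  expect_equal(st5$median, 2.5)
  expect_equal(st5$q3, 3.25)

  expect_error(size_stats(tad_set("e", bn30)), "empty")
})

test_that("shared boundaries use existential tolerance matching", {
  a <- c(0L, 10L, 20L)
  b <- c(0L, 12L, 20L)
  expect_equal(shared_boundaries(a, b, 0L)$count, 2L)
  expect_equal(shared_boundaries(a, b, 0L)$shared, c(0L, 20L))
  expect_equal(shared_boundaries(a, b, 2L)$count, 3L)
  expect_equal(shared_boundaries(a, a, 0L)$count, length(a))
  expect_error(shared_boundaries(a, b, -1L), "nonnegative")
  expect_equal(shared_boundaries(integer(), b, 1L)$count, 0L)
})

test_that("shared domains require both ends within tolerance", {
  a <- tad_set("a", bn30, c(0L, 10L), c(10L, 20L))
  b <- tad_set("b", bn30, c(0L, 12L), c(12L, 20L))
  expect_equal(shared_domains(a, b, 0L)$count, 0L)
  expect_equal(shared_domains(a, b, 2L)$count, 2L)
  for (t in c(0L, 1L, 5L)) {
    expect_equal(shared_domains(a, a, t)$count, count_tads(a))
  }
  other <- tad_set("c", genomic_binning("chr2", 1L, 30L), 0L, 10L)
  expect_error(shared_domains(a, other), "binning mismatch")
})

test_that("shared counts match exhaustive enumeration on random pairs", {
  for (seed in 1:40) {
    a <- random_tad_set(seed, n_bins = 60L)
    b <- random_tad_set(seed + 500L, n_bins = 60L)
    ba <- boundaries_of(a)
    bb <- boundaries_of(b)
    for (t in 0:3) {
      expect_equal(shared_boundaries(ba, bb, t)$count,
                   oracle_shared_boundaries(ba, bb, t))
      expect_equal(shared_domains(a, b, t)$count,
                   oracle_shared_domains(a, b, t))
    }
  }
})

test_that("shared counts are monotone in tolerance and bounded by |a|", {
  for (seed in 41:70) {
    a <- random_tad_set(seed)
    b <- random_tad_set(seed + 500L)
    ba <- boundaries_of(a)
    bb <- boundaries_of(b)
    cb <- vapply(0:5, function(t) shared_boundaries(ba, bb, t)$count, numeric(1))
    cd <- vapply(0:5, function(t) shared_domains(a, b, t)$count, numeric(1))
    expect_true(all(diff(cb) >= 0))
    expect_true(all(diff(cd) >= 0))
    expect_lte(max(cb), length(ba))
    expect_lte(max(cd), count_tads(a))
  }
})

test_that("one-vs-all table has the reference total on self-comparison and is monotone", {
  ref <- random_tad_set(7)
  others <- list(ref, random_tad_set(8), random_tad_set(9))
  tab <- one_vs_all(ref, others, 0:3, mode = "boundaries")
  self <- tab[tab$dataset == ref$label, ]
  expect_true(all(self$shared == length(boundaries_of(ref))))
  for (d in unique(tab$dataset)) {
    expect_true(all(diff(tab$shared[tab$dataset == d]) >= 0))
  }
  tabd <- one_vs_all(ref, others, 0:3, mode = "domains")
  expect_true(all(tabd$shared[tabd$dataset == ref$label] == count_tads(ref)))
  expect_error(one_vs_all(ref, list()), "at least one")
})

test_that("sharing profiles place identical sets at k=1 and disjoint sets at k=0", {
  a <- tad_set("A", bn30, c(0L, 10L), c(10L, 20L))
  a2 <- a; a2$label <- "A2"
  prof <- sharing_profile(list(a, a2), tolerance = 0L, mode = "boundaries")
  expect_true(all(prof$count[prof$k == 1] == 3))
  expect_true(all(prof$count[prof$k == 0] == 0))

  c1 <- tad_set("C", bn30, c(2L, 14L), c(6L, 25L))  # boundaries 2,6,14,25: disjoint from a
  prof3 <- sharing_profile(list(a, a2, c1), tolerance = 0L, mode = "boundaries")
  pa <- prof3[prof3$dataset == "A", ]
  pc <- prof3[prof3$dataset == "C", ]
  expect_equal(pa$count[pa$k == 1], 3)
  expect_equal(pc$count[pc$k == 0], 4)
  expect_true(all(pc$count[pc$k > 0] == 0))
  expect_error(sharing_profile(list(a), 0L), "at least 2")
})

test_that("sharing profile mass equals element totals and percentages sum to 100", {
  sets <- lapply(1:4, function(s) random_tad_set(s, label = paste0("d", s)))
  for (mode in c("boundaries", "domains")) {
    prof <- sharing_profile(sets, tolerance = 1L, mode = mode)
    for (s in sets) {
      tot <- if (mode == "boundaries") length(boundaries_of(s)) else count_tads(s)
      sub <- prof[prof$dataset == s$label, ]
      expect_equal(sum(sub$count), tot)
      expect_equal(sum(sub$percent), 100, tolerance = 1e-9)
    }
  }
})
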