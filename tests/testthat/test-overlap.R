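test_that("overlap coefficient matches the set definition", {
  x <- make_rep(c(1L, 1L, 1L))               # indices 1..3
  y <- make_rep(c(1L, 1L, 1L, 1L), offset = 1L)  # indices 2..5
  expect_equal(overlap_coefficient(x, y), 2 / 3, tolerance = 1e-12)
  expect_equal(overlap_coefficient(x, x), 1)
  z <- make_rep(c(2L, 2L), offset = 100L)
  expect_equal(overlap_coefficient(x, z), 0)
})

test_that("F2 matches hand computation and bounds", {
  x <- make_rep(c(1L, 1L))                       # f = 0.5, 0.5
  # y2 shares only index 1 with x, at frequency 1/8
  y2 <- repertoire(rbind(x$clonotypes[1, ],
                         make_rep(rep(1L, 7), offset = 50L)$clonotypes))
  expect_equal(f2_metric(x, y2), sqrt(0.5 * 0.125), tolerance = 1e-12)
  expect_equal(f2_metric(x, x), 1, tolerance = 1e-12)
  expect_equal(f2_metric(x, make_rep(3L, offset = 200L)), 0)
})

test_that("R metric: perfect, anti-ordered and degenerate cases", {
  x <- make_rep(c(1L, 2L, 4L))
  expect_equal(r_metric(x, x), 1, tolerance = 1e-12)
  y <- make_rep(c(4L, 2L, 1L))  # same keys, reversed counts
  expect_equal(r_metric(x, y), -1, tolerance = 1e-12)
  one_shared <- repertoire(rbind(x$clonotypes[1, ],
                                 make_rep(5L, offset = 99L)$clonotypes))
  r <- r_metric(x, one_shared)
  expect_true(is.na(r))
  expect_match(attr(r, "undefined"), "shared")
})

test_that("D metric matches the normalized shared count", {
  a <- make_rep(1L)
  expect_equal(d_metric(a, a), 1)
  x <- make_rep(rep(1L, 10))
  y <- make_rep(rep(1L, 20), offset = 8L)  # shares indices 9, 10
  expect_equal(d_metric(x, y), 2 / 200, tolerance = 1e-15)
  expect_equal(d_metric(x, make_rep(1L, offset = 240L)), 0)
})

test_that("all metrics agree with brute-force oracles on 500 random pairs", {
  set.seed(909)
  for (k in 1:500) {
    x <- random_rep(n_max = 15, count_max = 20, sample_id = "x")
    y <- random_rep(n_max = 15, count_max = 20, sample_id = "y")
    # oracle on nt keys
    fx <- tapply(x$clonotypes$count, x$clonotypes$cdr3_nt, sum) /
      x$total_count
    fy <- tapply(y$clonotypes$count, y$clonotypes$cdr3_nt, sum) /
      y$total_count
    shared <- intersect(names(fx), names(fy))
    expect_equal(overlap_coefficient(x, y, "nt"),
                 length(shared) / min(length(fx), length(fy)),
                 tolerance = 1e-12)
    expect_equal(f2_metric(x, y, "nt"),
                 if (length(shared)) sum(sqrt(fx[shared] * fy[shared])) else 0,
                 tolerance = 1e-12)
    expect_equal(d_metric(x, y, "nt"),
                 length(shared) / (length(fx) * length(fy)),
                 tolerance = 1e-12)
    if (length(shared) >= 2 && sd(log10(fx[shared])) > 0 &&
        sd(log10(fy[shared])) > 0) {
      expect_equal(r_metric(x, y, "nt"),
                   cor(log10(fx[shared]), log10(fy[shared])),
                   tolerance = 1e-12)
    }
    # symmetry
    expect_equal(overlap_coefficient(y, x, "nt"),
                 overlap_coefficient(x, y, "nt"), tolerance = 1e-15)
    expect_equal(f2_metric(y, x, "nt"), f2_metric(x, y, "nt"),
                 tolerance = 1e-12)
  }
})

test_that("repertoire_overlap is symmetric in all numeric fields", {
  set.seed(3)
  x <- random_rep(sample_id = "x")
  y <- random_rep(sample_id = "y")
  a <- repertoire_overlap(x, y)
  b <- repertoire_overlap(y, x)
  for (f in c("n_shared", "overlap_coefficient", "F2", "D")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("distance matrix is 1 - coefficient, symmetric, zero diagonal", {
  set.seed(14)
  reps <- list(random_rep(sample_id = "a"), random_rep(sample_id = "b"),
               random_rep(sample_id = "c"))
  m <- distance_matrix(reps)
  expect_equal(diag(m), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"],
               1 - overlap_coefficient(reps[[1]], reps[[2]], "nt"),
               tolerance = 1e-12)
  # identical and disjoint extremes
  same <- list(reps[[1]], reps[[1]])
  same[[2]]$sample_id <- "a2"
  expect_equal(distance_matrix(same)["a", "a2"], 0)
  dis <- list(make_rep(c(1L, 1L), sample_id = "d1"),
              make_rep(c(1L, 1L), offset = 60L, sample_id = "d2"))
  expect_equal(distance_matrix(dis)["d1", "d2"], 1)
})
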