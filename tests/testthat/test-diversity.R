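test_that("closed-form toy values match", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_equal(shannon(10), 0)
  expect_equal(unname(simpson(c(1, 1, 1, 1))), c(0.25, 0.75))
  expect_equal(unname(simpson(c(2, 1, 1))["dominance"]), 0.375)
  expect_equal(unname(simpson(5)), c(1, 0))
  expect_equal(d50(rep(1, 100)), 50)
  expect_equal(d50(c(6, 1, 1, 1, 1)), 20)
  expect_equal(d50(7), 100)
  expect_equal(chao1(c(3, 3, 3, 1, 1, 2)), 6 + 4 / 2)   # S=6, f1=2, f2=1
  expect_equal(chao1(c(5, 1, 1, 1)), 4 + 3 * 2 / 2)     # f2=0 branch
  expect_equal(chao1(c(3, 3, 4)), 3)                    # no singletons
  expect_equal(top100(rep(1, 200)), 50)
  expect_equal(top100(rep(1, 50)), 100)
  expect_equal(top100(c(100, rep(1, 100))), 100 * 199 / 200)
  expect_equal(hill_number(c(2, 1, 1), 2), 1 / 0.375, tolerance = 1e-12)
})

test_that("indices agree with brute-force oracles on random repertoires", {
  set.seed(101)
  for (k in 1:200) {
    counts <- sample.int(60, sample.int(40, 1), replace = TRUE)
    expect_equal(shannon(counts), oracle_shannon(counts), tolerance = 1e-9)
    expect_equal(unname(simpson(counts)["dominance"]),
                 oracle_simpson_D(counts), tolerance = 1e-9)
    expect_equal(d50(counts), oracle_d50(counts), tolerance = 1e-9)
    expect_equal(chao1(counts), oracle_chao1(counts), tolerance = 1e-9)
    expect_equal(top100(counts), oracle_top100(counts), tolerance = 1e-9)
    for (q in c(0, 0.5, 1, 2, 4)) {
      expect_equal(hill_number(counts, q), oracle_hill(counts, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("Shannon and inverse-Simpson agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(55)
  for (k in 1:50) {
    counts <- sample.int(80, sample.int(30, 1), replace = TRUE)
    expect_equal(shannon(counts),
                 unname(vegan::diversity(counts, "shannon")),
                 tolerance = 1e-9)
    expect_equal(hill_number(counts, 2),
                 unname(vegan::diversity(counts, "invsimpson")),
                 tolerance = 1e-9)
  }
})

test_that("Hill identities hold across random repertoires", {
  set.seed(202)
  qs <- seq(0, 8, by = 0.5)
  for (k in 1:300) {
    counts <- sample.int(50, sample.int(25, 1), replace = TRUE)
    qd <- hill_number(counts, qs)
    expect_equal(qd[1], length(counts))
    expect_equal(hill_number(counts, 1), exp(shannon(counts)),
                 tolerance = 1e-9)
    expect_true(all(diff(qd) <= 1e-9))
    # uniform invariance
    u <- rep(counts[1], length(counts))
    expect_equal(hill_number(u, qs), rep(length(u), length(qs)),
                 tolerance = 1e-9)
  }
})

test_that("scale invariance: integer count scaling fixes all but Chao1", {
  set.seed(33)
  for (k in 1:50) {
    counts <- sample.int(40, sample.int(20, 1) + 1, replace = TRUE)
    scaled <- counts * 7L
    expect_equal(shannon(scaled), shannon(counts), tolerance = 1e-12)
    expect_equal(simpson(scaled), simpson(counts), tolerance = 1e-12)
    expect_equal(d50(scaled), d50(counts))
    expect_equal(top100(scaled), top100(counts))
    expect_equal(hill_number(scaled, c(0.5, 2, 3)),
                 hill_number(counts, c(0.5, 2, 3)), tolerance = 1e-12)
  }
})

test_that("merging two clonotypes never increases Shannon or 1-D", {
  set.seed(44)
  for (k in 1:100) {
    counts <- sample.int(30, sample.int(15, 1) + 2, replace = TRUE)
    i <- sample(seq_along(counts), 2)
    merged <- c(counts[-i], sum(counts[i]))
    expect_lte(shannon(merged), shannon(counts) + 1e-12)
    expect_lte(simpson(merged)["diversity"],
               simpson(counts)["diversity"] + 1e-12)
  }
})

test_that("rank abundance and cumulative curves have the stated shape", {
  ra <- rank_abundance(c(3, 1))
  expect_equal(ra$frequency, c(0.75, 0.25))
  expect_equal(ra$rank, 1:2)
  expect_equal(sum(rank_abundance(make_rep(c(9L, 3L, 2L)))$frequency), 1)
  cc <- cumulative_clonotype_curve(c(6, 1, 1, 1, 1))
  expect_equal(cc$cumulative_frequency[cc$fraction_unique == 0.2], 0.6)
  expect_equal(cc$cumulative_frequency[nrow(cc)], 1)
  expect_true(all(diff(cc$cumulative_frequency) >= 0))
  expect_equal(nrow(rank_abundance(rep(2, 17))), 17L)
})

test_that("diversity_profile bundles consistent values", {
  rep <- make_rep(c(8L, 4L, 2L, 1L, 1L))
  prof <- diversity_profile(rep)
  expect_equal(prof$simpson_dominance + prof$simpson_diversity, 1,
               tolerance = 1e-12)
  expect_equal(prof$hill$qD[prof$hill$q == 0], prof$richness)
  expect_equal(prof$hill$qD[prof$hill$q == 1], exp(prof$shannon),
               tolerance = 1e-9)
  expect_gte(prof$chao1, prof$richness)
})

test_that("empty repertoires yield undefined-statistic errors", {
  empty <- repertoire(data.frame(cdr3_nt = character(),
                                 v_gene = character(),
                                 j_gene = character(), count = integer()))
  expect_error(shannon(empty), "undefined")
  expect_error(simpson(empty), "undefined")
  expect_error(d50(empty), "undefined")
  expect_error(hill_number(empty, 1), "undefined")
  expect_error(hill_number(c(1, 2), -1), "nonnegative")
})
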