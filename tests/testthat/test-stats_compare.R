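make_cohort <- function(n = 4, seed = 1, expanded = FALSE) {
  # depths vary across samples, as sequencing yields do
  cfg <- simulation_config(seed = seed, n_clonotypes = 1500L, depth = 3000L,
                           clone_size_law = if (expanded) "powerlaw"
                                            else "geometric")
  lapply(seq_len(n), function(i) {
    cfg$seed <- seed + i
    cfg$depth <- 3000L + 173L * i
    simulate_repertoire(cfg, sample_id = paste0("s", seed, "_", i),
                        group = if (expanded) "KO" else "WT")$repertoire
  })
}

test_that("assemble_features builds a z-scored matrix with group labels", {
  reps <- make_cohort(4, seed = 10)
  fm <- assemble_features(reps)
  expect_equal(dim(fm), c(4L, 4L))
  expect_equal(unname(colMeans(fm)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(fm, 2, var)), rep(1, 4), tolerance = 1e-9)
  expect_equal(attr(fm, "groups"), rep("WT", 4))
  expect_error(assemble_features(reps, features = "no_such_feature"),
               "unknown index")
  expect_error(assemble_features(reps[1:2]), ">= 3")
})

test_that("V-usage feature mode yields one column per observed gene", {
  reps <- make_cohort(4, seed = 20)
  fm <- assemble_features(reps, features = "v_usage", scaling = "none")
  genes <- sort(unique(unlist(lapply(reps, function(r) {
    names(usage(r, "V", "total"))
  }))))
  expect_equal(colnames(fm), genes)
  expect_equal(unname(rowSums(fm)), rep(1, 4), tolerance = 1e-9)
})

test_that("PCA: orientation fixed, variance ordered, reconstruction exact", {
  reps <- c(make_cohort(4, seed = 30), make_cohort(4, seed = 40,
                                                   expanded = TRUE))
  fm <- assemble_features(reps)
  pca <- pca_segregation(fm, n_components = 2L)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  for (k in 1:2) {
    i <- which.max(abs(pca$loadings[, k]))
    expect_gte(pca$loadings[i, k], 0)
  }
  # full-rank reconstruction of the z-scored matrix
  full <- pca_segregation(fm, n_components = min(nrow(fm) - 1, ncol(fm)))
  rec <- full$scores %*% t(full$loadings)
  expect_equal(unname(rec), unname(fm[, , drop = FALSE]), tolerance = 1e-9)
  # duplicated sample gets identical scores
  reps2 <- c(reps, reps[1])
  reps2[[9]]$sample_id <- "dup"
  fm2 <- assemble_features(reps2)
  pca2 <- pca_segregation(fm2, 2L)
  expect_equal(unname(pca2$scores[1, ]), unname(pca2$scores[9, ]),
               tolerance = 1e-9)
})

test_that("separated synthetic groups segregate along PC1", {
  set.seed(88)
  # two groups shifted by 3 SD in two of four features
  m <- rbind(
    cbind(rnorm(8, 0), rnorm(8, 0), rnorm(8, 0), rnorm(8, 0)),
    cbind(rnorm(8, 3), rnorm(8, 3), rnorm(8, 0), rnorm(8, 0)))
  colnames(m) <- paste0("f", 1:4)
  rownames(m) <- paste0("s", 1:16)
  fm <- scale(m)
  attr(fm, "scaled:center") <- NULL
  attr(fm, "scaled:scale") <- NULL
  attr(fm, "groups") <- rep(c("A", "B"), each = 8)
  attr(fm, "scaling") <- "zscore"
  pca <- pca_segregation(fm, 2L)
  pc1 <- pca$scores[, 1]
  gap <- abs(mean(pc1[1:8]) - mean(pc1[9:16]))
  pooled_sd <- sqrt((var(pc1[1:8]) + var(pc1[9:16])) / 2)
  expect_gt(gap, 2 * pooled_sd)
})

test_that("group_test: null, degenerate, order invariance", {
  expect_equal(group_test(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_true(group_test(c(2, 2), c(2, 2))$degenerate)
  set.seed(5)
  a <- rnorm(6)
  b <- rnorm(6, 1)
  r1 <- group_test(a, b)
  r2 <- group_test(sample(a), sample(b))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(group_test(1, c(1, 2)), ">= 2")
})

test_that("t-test machinery is calibrated and powered (simulation)", {
  set.seed(123)
  # type-I error at alpha = 0.05 over 1000 null replicates
  rej_null <- mean(vapply(1:1000, function(i) {
    group_test(rnorm(10), rnorm(10))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej_null - 0.05), 0.02)
  # power for a 2 SD shift, n = 10, 500 replicates
  rej_alt <- mean(vapply(1:500, function(i) {
    group_test(rnorm(10), rnorm(10, 2))$p < 0.05
  }, logical(1)))
  expect_gt(rej_alt, 0.95)
})

test_that("dunnett adjustment is monotone and above raw p", {
  set.seed(9)
  tstat <- c(3.5, 1.0, 0.2, 2.2)
  p_raw <- 2 * pt(abs(tstat), df = 14, lower.tail = FALSE)
  p_adj <- adjust_pvalues(p_raw, "dunnett", statistic = tstat, df = 14,
                          reps = 50000L, seed = 4L)
  expect_true(all(p_adj >= p_raw - 0.02))
  expect_true(all(p_adj <= 1))
  # adjusted order follows |t| order
  expect_equal(order(p_adj), order(-abs(tstat)))
})
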