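test_that("Jaccard coefficient matches hand-counted overlaps", {
  d <- tiny_dataset(list(c(1, 0, 1, 0, 0, 0, 0, 0, 0),
                         c(1, 1, 0, 0, 0, 0, 0, 0, 0)),
                    c("positive", "negative"))
  j <- jaccard_matrix(d)
  expect_equal(j$values[1, 2], 1 / 3)   # M11 = 1, M10 = 1, M01 = 1
  expect_equal(diag(j$values), c(P001 = 1, P002 = 1))
})

test_that("all-zero profiles are identical (J = 1) and flagged", {
  d <- tiny_dataset(list(rep(0, 9), rep(0, 9), c(1, rep(0, 8))),
                    c("positive", "positive", "negative"))
  j <- jaccard_matrix(d)
  expect_equal(j$values[1, 2], 1)
  expect_equal(j$values[1, 1], 1)
  expect_equal(j$values[1, 3], 0)
  expect_identical(j$zero_profile_pairs, 1)
})

test_that("the matrix is symmetric in [0,1] and 1-J obeys the triangle
          inequality", {
  d <- generate_labeled_dataset(dataset_spec(n_positive = 25,
                                             n_negative = 25, seed = 14))
  j <- jaccard_matrix(d)$values
  expect_equal(j, t(j))
  expect_true(all(j >= 0 & j <= 1))
  dist <- 1 - j
  n <- nrow(dist)
  withr::with_seed(8, {
    for (rep in 1:2000) {
      t3 <- sample(n, 3)
      expect_lte(dist[t3[1], t3[3]],
                 dist[t3[1], t3[2]] + dist[t3[2], t3[3]] + 1e-12)
    }
  })
})

test_that("long format covers every unordered pair once", {
  d <- generate_labeled_dataset(dataset_spec(n_positive = 5,
                                             n_negative = 5))
  lg <- jaccard_long(jaccard_matrix(d))
  expect_identical(nrow(lg), 45L)
  expect_equal(lg$distance, 1 - lg$jaccard)
})

test_that("one-way ANOVA matches a sums-of-squares oracle", {
  groups <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8),
                 c(13, 9, 11, 8, 7, 12))
  res <- anova_oneway(groups)
  # brute-force sums of squares
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(f_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_false(res$degenerate)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(44, {
    g1 <- rnorm(12)
    g2 <- rnorm(15, mean = 0.4)
  })
  res <- anova_oneway(list(g1, g2))
  t2 <- unname(t.test(g1, g2, var.equal = TRUE)$statistic)^2
  expect_equal(res$F, t2, tolerance = 1e-10)
})

test_that("degenerate and invalid groupings are flagged or rejected", {
  res <- anova_oneway(list(rep(2, 5), rep(2, 5)))
  expect_true(res$degenerate)
  expect_true(is.na(res$F))
  eq <- anova_oneway(list(c(1, 2, 3, 2), c(2, 1, 3, 2)))
  expect_gt(eq$p, 0.5)   # equal means, ample variance
  expect_error(anova_oneway(list(1:5)), "two groups")
  expect_error(anova_oneway(list(1:5, 3)), "two values")
})

test_that("ANOVA p-values are uniform under exchangeable groups", {
  withr::with_seed(55, {
    p <- replicate(500, {
      anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))$p
    })
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-class feature grouping runs on the replication profile", {
  d <- generate_labeled_dataset(dataset_spec())
  res <- anova_by_feature(d, "positive")
  expect_false(res$degenerate)
  expect_true(res$significant)   # score frequencies differ across features
})
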