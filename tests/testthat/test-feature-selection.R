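informative_dataset <- function(n = 100, flip1 = 0.1, flip3 = 0.3,
                                seed = 19) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    flip <- function(v, p) ifelse(rbinom(n, 1, p) == 1, 1 - v, v)
    rows <- cbind(f1 = flip(y, flip1), f2 = flip(y, flip1),
                  f3 = flip(y, flip3), f4 = rbinom(n, 1, 0.5),
                  f5 = rbinom(n, 1, 0.5))
    tiny_dataset(lapply(seq_len(n), function(i) rows[i, ]),
                 ifelse(y == 1, "positive", "negative"))
  })
}

test_that("CFS selects the label-matching feature and drops duplicates", {
  withr::with_seed(23, {
    y <- rbinom(120, 1, 0.5)
    rows <- cbind(f1 = y, f2 = rbinom(120, 1, 0.5),
                  f3 = rbinom(120, 1, 0.5))
    d <- tiny_dataset(lapply(seq_len(120), function(i) rows[i, ]),
                      ifelse(y == 1, "positive", "negative"))
  })
  sel <- cfs_select(d)
  expect_true(1 %in% sel)

  # exact duplicate of the informative feature: redundancy penalty keeps
  # at most one copy
  d2 <- d
  d2$f2 <- d2$f1
  sel2 <- cfs_select(d2)
  expect_true(1 %in% sel2 || 2 %in% sel2)
  expect_false(all(c(1, 2) %in% sel2))
})

test_that("CFS single-feature input returns that feature", {
  d <- informative_dataset()
  d1 <- d[c("protein_id", "f1", "trs", "label")]
  expect_identical(as.integer(cfs_select(d1)), 1L)
})

test_that("CFS merit matches the brute-force formula on every subset", {
  d <- informative_dataset(n = 60)
  y <- as.integer(d$label == "positive")
  for (k in 1:3) {
    for (s in utils::combn(5, k, simplify = FALSE)) {
      rcf <- mean(vapply(s, function(j)
        abs(cor(d[[paste0("f", j)]], y)), numeric(1)))
      rff <- if (k == 1) 0 else {
        pp <- utils::combn(s, 2)
        mean(vapply(seq_len(ncol(pp)), function(c)
          abs(cor(d[[paste0("f", pp[1, c])]], d[[paste0("f", pp[2, c])]])),
          numeric(1)))
      }
      want <- k * rcf / sqrt(k + k * (k - 1) * rff)
      expect_equal(cfs_merit(d, s), want, tolerance = 1e-12)
    }
  }
})

test_that("CFS warns on constant columns and excludes them", {
  d <- informative_dataset()
  d$f5 <- 1L
  expect_warning(sel <- cfs_select(d), "constant")
  expect_false(5 %in% sel)
})

test_that("PCA ranking reproduces the covariance eigendecomposition", {
  d <- generate_labeled_dataset(dataset_spec(n_positive = 60,
                                             n_negative = 60, seed = 31))
  res <- pca_rank(d)
  expect_setequal(res$ranking, 1:9)
  expect_equal(sum(res$var_fraction), 1, tolerance = 1e-10)
  eg <- eigen(cov(as.matrix(d[paste0("f", 1:9)])))
  expect_equal(res$var_fraction, eg$values / sum(eg$values),
               tolerance = 1e-10)
  for (c in 1:9) {
    expect_equal(unname(abs(res$rotation[, c])), abs(eg$vectors[, c]),
                 tolerance = 1e-8, label = sprintf("component %d", c))
  }
})

test_that("PCA puts a dominant-variance feature first", {
  withr::with_seed(5, {
    rows <- cbind(f1 = rbinom(80, 1, 0.5), f2 = c(rep(0, 79), 1),
                  f3 = c(rep(1, 79), 0))
    d <- tiny_dataset(lapply(seq_len(80), function(i) rows[i, ]),
                      rep(c("positive", "negative"), 40))
  })
  expect_identical(pca_rank(d)$ranking[1], 1L)
  d0 <- d
  d0$f1 <- 0L; d0$f2 <- 1L; d0$f3 <- 0L
  expect_error(pca_rank(d0), "zero-variance")
})

evaluate_plan_oracle <- function(data, subset, plan) {
  sub <- data[c("protein_id", paste0("f", sort(subset)), "label")]
  stratified_kfold_cv(sub, classifier_factory("nb"), plan)$pooled$accuracy
}

test_that("exhaustive search enumerates 2^m - 1 subsets, best >= full set", {
  d <- informative_dataset(n = 60)
  d3 <- d[c("protein_id", "f1", "f2", "f3", "trs", "label")]
  plan <- split_plan(k = 5, seed = 2)
  res <- exhaustive_subset_search(d3, classifier_factory("nb"), plan)
  expect_identical(nrow(res$table), 7L)
  full_acc <- res$table$accuracy[res$table$subset == "1,2,3"]
  expect_gte(res$best$accuracy, full_acc)
  # the winning subset's accuracy is reproducible under the same plan
  redo <- evaluate_plan_oracle(d3, res$best$subset, plan)
  expect_equal(res$best$accuracy, redo)
})

test_that("pairwise correlations match the closed-form r and p", {
  d <- informative_dataset(n = 20)
  rep_ <- pearson_feature_correlations(d)
  expect_identical(nrow(rep_), 10L)
  n <- 20
  for (i in seq_len(nrow(rep_))) {
    x <- d[[paste0("f", rep_$feature_i[i])]]
    y <- d[[paste0("f", rep_$feature_j[i])]]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rep_$pearson_r[i], r, tolerance = 1e-8)
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(rep_$p_two_tailed[i], 2 * pt(-abs(t), n - 2),
                 tolerance = 1e-8)
  }
})

test_that("identical columns correlate at exactly 1", {
  d <- informative_dataset()
  d$f2 <- d$f1
  rep_ <- pearson_feature_correlations(d)
  expect_equal(rep_$pearson_r[rep_$feature_i == 1 & rep_$feature_j == 2], 1)
  expect_error(pearson_feature_correlations(d[1:2, ]), "3 rows")
})

test_that("generator-induced pairs stand out in the correlation report", {
  d <- generate_labeled_dataset(dataset_spec(
    n_positive = 1000, n_negative = 0,
    p_positive = rep(0.5, 9), p_negative = rep(0.5, 9),
    correlated_pairs = list(c(1, 2, 0.5)), seed = 41))
  rep_ <- pearson_feature_correlations(d)
  induced <- rep_$pearson_r[rep_$feature_i == 1 & rep_$feature_j == 2]
  others <- rep_$pearson_r[!(rep_$feature_i == 1 & rep_$feature_j == 2)]
  expect_gt(induced, quantile(others, 0.95))
})

test_that("impact ranking uses competition ranks with shared ties", {
  d <- informative_dataset(n = 80)
  d$f2 <- d$f1   # identical columns must tie
  plan <- split_plan(k = 5, seed = 3)
  imp <- rank_feature_impact(d, classifier_factory("nb"), plan)
  expect_identical(nrow(imp), 5L)
  expect_identical(imp$rank[imp$feature == 1], imp$rank[imp$feature == 2])
  expect_identical(imp$rank[which.max(imp$accuracy)], 1L)
  # a skipped rank follows any tie
  expect_identical(sort(unique(imp$rank)),
                   sort(unique(vapply(imp$accuracy, function(a)
                     1L + sum(imp$accuracy > a), integer(1)))))
})
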