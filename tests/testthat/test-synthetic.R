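test_that("default replication profile has the study's class sizes", {
  d <- generate_labeled_dataset(dataset_spec())
  expect_identical(sum(d$label == "positive"), 106L)
  expect_identical(sum(d$label == "negative"), 194L)
  expect_identical(nrow(d), 300L)
  expect_true(all(as.matrix(d[paste0("f", 1:9)]) %in% 0:1))
  expect_identical(d$trs, as.integer(rowSums(d[paste0("f", 1:9)])))
  expect_true(all(grepl("^SYN[0-9]{6}$", d$protein_id)))
})

test_that("degenerate probabilities give all-or-nothing profiles", {
  spec <- dataset_spec(n_positive = 8, n_negative = 5,
                       p_positive = rep(1, 9), p_negative = rep(0, 9),
                       correlated_pairs = list())
  d <- generate_labeled_dataset(spec)
  expect_true(all(d$trs[d$label == "positive"] == 9L))
  expect_true(all(d$trs[d$label == "negative"] == 0L))
})

test_that("generation is reproducible from the seed and varies across seeds", {
  d1 <- generate_labeled_dataset(dataset_spec(seed = 11))
  d2 <- generate_labeled_dataset(dataset_spec(seed = 11))
  d3 <- generate_labeled_dataset(dataset_spec(seed = 12))
  expect_identical(d1, d2)
  expect_false(identical(d1[paste0("f", 1:9)], d3[paste0("f", 1:9)]))
})

test_that("empirical frequency of an uncorrelated feature matches its p", {
  spec <- dataset_spec(n_positive = 5000, n_negative = 0,
                       p_positive = c(0.7, rep(0.5, 8)),
                       p_negative = rep(0.5, 9),
                       correlated_pairs = list(), seed = 3)
  d <- generate_labeled_dataset(spec)
  ci <- stats::qbinom(c(0.005, 0.995), 5000, 0.7) / 5000
  expect_gte(mean(d$f1), ci[1])
  expect_lte(mean(d$f1), ci[2])
})

test_that("marginals and induced correlations recover the validation profile", {
  spec <- validation_profile(n = 2000, seed = 5)
  d <- generate_labeled_dataset(spec)
  for (cl in c("positive", "negative")) {
    p <- if (cl == "positive") spec$p_positive else spec$p_negative
    freq <- colMeans(d[d$label == cl, paste0("f", 1:9)])
    se <- sqrt(p * (1 - p) / 2000)
    expect_true(all(abs(freq - p) <= 3 * se),
                label = sprintf("class %s frequencies within 3 SE", cl))
  }
  pos <- d[d$label == "positive", paste0("f", 1:9)]
  r <- stats::cor(pos)
  induced <- c(r[1, 2], r[5, 6], r[6, 8])
  non_induced <- r[upper.tri(r)]
  non_induced <- setdiff(non_induced, induced)
  expect_true(all(induced > 0))
  expect_gt(min(induced), max(non_induced))
})

test_that("evidence records round-trip through the scoring rules", {
  cfg <- rule_config()
  d <- generate_labeled_dataset(dataset_spec(n_positive = 50,
                                             n_negative = 50, seed = 9))
  recs <- generate_evidence_records(d, cfg, seed = 10)
  expect_length(recs, 900L)
  m <- build_feature_matrix(recs, cfg)
  expect_identical(m$protein_id, d$protein_id)
  expect_equal(unname(as.matrix(m[paste0("f", 1:9)])),
               unname(as.matrix(d[paste0("f", 1:9)])))
  # forced structure: f8 = 1 rows carry a qualifying PDB template
  by_key <- split(recs, paste(vapply(recs, `[[`, "", "protein_id"),
                              vapply(recs, `[[`, 0L, "feature_id")))
  i <- which(d$f8 == 1)[1]
  rec8 <- by_key[[paste(d$protein_id[i], 8)]][[1]]
  expect_true(any(vapply(rec8$hits, function(h)
    h$is_pdb_template && h$percent_identity > 30, logical(1))))
  # f7 = 0 rows carry no qualifying no-ATG human hit
  j <- which(d$f7 == 0)[1]
  rec7 <- by_key[[paste(d$protein_id[j], 7)]][[1]]
  expect_identical(oracle_pseudogene(rec7$hits), 0L)
})
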