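test_that("pseudogene rule follows the qualifying-hit criteria", {
  cfg <- rule_config()
  qualifying <- evidence_record("P1", 7, list(
    hit_evidence(e_value = 1e-20, has_atg_start_any_frame = FALSE)))
  expect_identical(score_pseudogene(qualifying, cfg), 1L)

  expect_identical(score_pseudogene(evidence_record("P2", 7), cfg), 0L)

  flagged <- evidence_record("P3", 7, list(
    hit_evidence(e_value = 1e-20, has_atg_start_any_frame = FALSE,
                 flags = "end_to_end_alignment")))
  expect_identical(score_pseudogene(flagged, cfg), 0L)

  has_start <- evidence_record("P4", 7, list(
    hit_evidence(e_value = 1e-20, has_atg_start_any_frame = TRUE)))
  expect_identical(score_pseudogene(has_start, cfg), 0L)

  wrong_org <- evidence_record("P5", 7, list(
    hit_evidence(organism = "Mus musculus", e_value = 1e-20,
                 has_atg_start_any_frame = FALSE)))
  expect_identical(score_pseudogene(wrong_org, cfg), 0L)

  # record-level flags disqualify every hit
  rec_flag <- evidence_record("P6", 7, list(
    hit_evidence(e_value = 1e-20, has_atg_start_any_frame = FALSE)),
    flags = "synthetic")
  expect_identical(score_pseudogene(rec_flag, cfg), 0L)

  expect_error(score_pseudogene(evidence_record("P7", 8), cfg),
               "feature_id")
})

test_that("homology rule uses strict >30% identity on PDB templates", {
  cfg <- rule_config()
  for (case in list(c(35, 1), c(30.1, 1), c(30, 0), c(29.9, 0))) {
    rec <- evidence_record("P1", 8, list(
      hit_evidence(percent_identity = case[1], is_pdb_template = TRUE)))
    expect_identical(score_homology_model(rec, cfg), as.integer(case[2]))
  }
  no_template <- evidence_record("P2", 8, list(
    hit_evidence(percent_identity = 80, is_pdb_template = FALSE)))
  expect_identical(score_homology_model(no_template, cfg), 0L)
  expect_identical(score_homology_model(evidence_record("P3", 8), cfg), 0L)
  expect_error(score_homology_model(evidence_record("P4", 7), cfg),
               "feature_id")
})

test_that("new rules equal the truth-table oracle on all <=3-hit sets", {
  cfg <- rule_config()
  for (hits in hit_multisets(pseudogene_hit_types(), 3)) {
    rec <- evidence_record("P", 7, hits)
    expect_identical(score_pseudogene(rec, cfg), oracle_pseudogene(hits))
  }
  for (hits in hit_multisets(homology_hit_types(), 3)) {
    rec <- evidence_record("P", 8, hits)
    expect_identical(score_homology_model(rec, cfg), oracle_homology(hits))
  }
})

test_that("ncRNA rule widens its window only when bit scores are tied", {
  cfg <- rule_config()
  make_rec <- function(bit_scores, ncrna_rank) {
    hits <- lapply(seq_along(bit_scores), function(r) {
      hit_evidence(r, "Homo sapiens", bit_score = bit_scores[r],
                   is_ncrna_annotated = r == ncrna_rank)
    })
    evidence_record("P", 9, hits)
  }
  # hit inside the top-3 window scores regardless of spread
  expect_identical(score_ncrna(make_rec(c(200, 150, 100, 90, 80), 2), cfg), 1L)
  # rank-5 hit: 2% spread widens to top 5, 20% spread does not
  expect_identical(score_ncrna(make_rec(c(100, 99.5, 99, 98.5, 98), 5), cfg),
                   1L)
  expect_identical(score_ncrna(make_rec(c(100, 95, 90, 85, 80), 5), cfg), 0L)
  # non-human hits are invisible to the rule
  rec <- evidence_record("P", 9, list(
    hit_evidence(1, "Mus musculus", is_ncrna_annotated = TRUE)))
  expect_identical(score_ncrna(rec, cfg), 0L)
  expect_identical(score_ncrna(evidence_record("P", 9), cfg), 0L)
})

test_that("legacy rules apply per-feature threshold or presence logic", {
  cfg <- rule_config()
  pfam_hit <- evidence_record("P", 1, list(hit_evidence(e_value = 1e-6)))
  expect_identical(score_legacy_feature(pfam_hit, cfg), 1L)
  pfam_weak <- evidence_record("P", 1, list(hit_evidence(e_value = 0.5)))
  expect_identical(score_legacy_feature(pfam_weak, cfg), 0L)
  expect_identical(score_legacy_feature(evidence_record("P", 4), cfg), 0L)
  ortho <- evidence_record("P", 2, list(hit_evidence()))
  expect_identical(score_legacy_feature(ortho, cfg), 1L)
  # evalue rules judge the best-ranked retained hit
  mixed <- evidence_record("P", 6, list(
    hit_evidence(rank = 2, e_value = 1e-9),
    hit_evidence(rank = 1, e_value = 0.9)))
  expect_identical(score_legacy_feature(mixed, cfg), 0L)
  # missing configuration is an error, not a silent 0
  broken <- rule_config()
  broken$legacy_rules$f3 <- NULL
  expect_error(score_legacy_feature(evidence_record("P", 3,
                                                    list(hit_evidence())),
                                    broken),
               "no legacy rule")
})

test_that("scoring is monotone in qualifying evidence and thresholds", {
  base <- evidence_record("P", 8, list(
    hit_evidence(percent_identity = 20, is_pdb_template = TRUE)))
  more <- evidence_record("P", 8, c(base$hits, list(
    hit_evidence(rank = 2, percent_identity = 50, is_pdb_template = TRUE))))
  expect_gte(score_homology_model(more, rule_config()),
             score_homology_model(base, rule_config()))
  # raising the identity threshold never raises the score
  rec <- evidence_record("P", 8, list(
    hit_evidence(percent_identity = 45, is_pdb_template = TRUE)))
  scores <- vapply(c(10, 30, 44, 46, 80), function(th)
    score_homology_model(rec, rule_config(homology_identity_threshold = th)),
    integer(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("TRS sums the nine binary scores and rejects bad input", {
  expect_identical(compute_trs(rep(1, 9)), 9L)
  expect_identical(compute_trs(rep(0, 9)), 0L)
  expect_identical(compute_trs(c(1, 0, 1, 0, 1, 0, 1, 0, 1)), 5L)
  expect_error(compute_trs(c(rep(1, 8), 2)), "0 or 1")
  expect_error(compute_trs(rep(1, 8)), "nine")
})

test_that("build_feature_matrix dispatches, fills gaps and orders rows", {
  cfg <- rule_config()
  recs <- list(
    evidence_record("B", 8, list(hit_evidence(percent_identity = 45,
                                              is_pdb_template = TRUE))),
    evidence_record("A", 1, list(hit_evidence(e_value = 1e-9))),
    evidence_record("A", 7, list(hit_evidence(e_value = 1e-9,
                                              has_atg_start_any_frame = FALSE)))
  )
  m <- build_feature_matrix(recs, cfg)
  expect_identical(m$protein_id, c("B", "A"))  # first-appearance order
  expect_identical(m$f8, c(1L, 0L))
  expect_identical(m$f1, c(0L, 1L))
  expect_identical(m$f7, c(0L, 1L))
  expect_identical(m$trs, c(1L, 2L))

  empty <- build_feature_matrix(list(), cfg)
  expect_identical(nrow(empty), 0L)
  expect_true(all(paste0("f", 1:9) %in% names(empty)))

  dup <- c(recs, list(evidence_record("A", 1, list())))
  expect_error(build_feature_matrix(dup, cfg), "duplicate")
})

test_that("scoring is a pure function of records and config", {
  d <- generate_labeled_dataset(dataset_spec(n_positive = 10,
                                             n_negative = 10, seed = 7))
  recs <- generate_evidence_records(d, rule_config(), seed = 7)
  m1 <- build_feature_matrix(recs, rule_config())
  m2 <- build_feature_matrix(recs, rule_config())
  expect_identical(m1, m2)
})
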