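#' Scoring-rule configuration
#'
#' Thresholds used by the nine feature rules. The three new rules (pseudogene,
#' homology modelling, non-coding RNA) have explicit parameters; the six
#' legacy features (Pfam, orthology, protein interactions, bidirectional best
#' BLAST hits, subcellular localization, functional linkages) are driven by a
#' generic per-feature rule table with two rule types:
#' \describe{
#'   \item{evalue}{score 1 iff the best retained hit's E-value is at or below
#'     the configured cutoff (Pfam, protein interactions, functional
#'     linkages).}
#'   \item{presence}{score 1 iff any retained hit exists (orthology,
#'     bidirectional best BLAST hits, subcellular localization).}
#' }
#' Hits flagged \code{predicted}, \code{synthetic} or
#' \code{end_to_end_alignment} are discarded before any rule is applied.
#'
#' @param homology_identity_threshold Percent query-template identity a PDB
#'   template hit must strictly exceed to score 1. Default 30.
#' @param pseudogene_evalue_cutoff E-value a Homo sapiens hit must be strictly
#'   below for the pseudogene rule. Default 1.0.
#' @param ncrna_top_k Number of top Homo sapiens hits examined by the ncRNA
#'   rule. Default 3.
#' @param ncrna_extended_k Widened number of hits examined when bit scores are
#'   nearly tied. Default 5.
#' @param ncrna_score_spread_fraction Relative bit-score spread
#'   \eqn{(max - min)/max} among the top \code{ncrna_extended_k} hits below
#'   which the examination window widens. Default 0.05.
#' @param legacy_rules Named list \code{f1}..\code{f6}, each
#'   \code{list(type = "evalue"|"presence", cutoff = <numeric>)}.
#' @return A list of class \code{hp_rule_config}.
#' @export
#' @examples
#' cfg <- rule_config()
#' cfg$homology_identity_threshold
rule_config <- function(homology_identity_threshold = 30,
                        pseudogene_evalue_cutoff = 1.0,
                        ncrna_top_k = 3,
                        ncrna_extended_k = 5,
                        ncrna_score_spread_fraction = 0.05,
                        legacy_rules = default_legacy_rules()) {
  stopifnot(homology_identity_threshold > 0,
            pseudogene_evalue_cutoff > 0,
            ncrna_top_k >= 1,
            ncrna_extended_k >= ncrna_top_k,
            ncrna_score_spread_fraction > 0)
  cfg <- list(
    homology_identity_threshold = homology_identity_threshold,
    pseudogene_evalue_cutoff = pseudogene_evalue_cutoff,
    ncrna_top_k = as.integer(ncrna_top_k),
    ncrna_extended_k = as.integer(ncrna_extended_k),
    ncrna_score_spread_fraction = ncrna_score_spread_fraction,
    legacy_rules = legacy_rules
  )
  class(cfg) <- "hp_rule_config"
  cfg
}

#' @rdname rule_config
#' @export
default_legacy_rules <- function() {
  list(
    f1 = list(type = "evalue",   cutoff = 1e-3),  # Pfam domain match
    f2 = list(type = "presence", cutoff = NA),    # orthology inference
    f3 = list(type = "evalue",   cutoff = 1e-3),  # protein interactions
    f4 = list(type = "presence", cutoff = NA),    # bidirectional best hits
    f5 = list(type = "presence", cutoff = NA),    # subcellular localization
    f6 = list(type = "evalue",   cutoff = 1e-3)   # functional linkages
  )
}

EXCLUSION_FLAGS <- c("predicted", "synthetic", "end_to_end_alignment")

#' Construct a single annotation hit
#'
#' @param rank Hit rank, 1 = best.
#' @param organism Source organism of the hit.
#' @param e_value Non-negative E-value.
#' @param bit_score Alignment bit score.
#' @param percent_identity Percent identity in \[0, 100\].
#' @param has_atg_start_any_frame TRUE if an ATG start codon exists in any of
#'   the six reading frames of the hit.
#' @param is_ncrna_annotated TRUE if the hit is annotated as a non-coding RNA.
#' @param is_pdb_template TRUE if the hit is a PDB structural template.
#' @param flags Character vector of exclusion tags; any of
#'   \code{"predicted"}, \code{"synthetic"}, \code{"end_to_end_alignment"}
#'   disqualifies the hit from all rules.
#' @return A list of class \code{hp_hit}.
#' @export
hit_evidence <- function(rank = 1L, organism = "Homo sapiens",
                         e_value = 1e-10, bit_score = 100,
                         percent_identity = 0,
                         has_atg_start_any_frame = TRUE,
                         is_ncrna_annotated = FALSE,
                         is_pdb_template = FALSE,
                         flags = character()) {
  stopifnot(rank >= 1, e_value >= 0,
            percent_identity >= 0, percent_identity <= 100)
  h <- list(rank = as.integer(rank), organism = organism,
            e_value = e_value, bit_score = bit_score,
            percent_identity = percent_identity,
            has_atg_start_any_frame = isTRUE(has_atg_start_any_frame),
            is_ncrna_annotated = isTRUE(is_ncrna_annotated),
            is_pdb_template = isTRUE(is_pdb_template),
            flags = as.character(flags))
  class(h) <- "hp_hit"
  h
}

#' Construct an evidence record for one (protein, feature) pair
#'
#' @param protein_id Protein identifier.
#' @param feature_id Integer 1--9: 1 Pfam, 2 orthology, 3 protein
#'   interactions, 4 bidirectional best BLAST hits, 5 subcellular
#'   localization, 6 functional linkages, 7 pseudogene, 8 homology
#'   modelling, 9 non-coding RNA.
#' @param hits List of [hit_evidence()] objects; re-sorted by rank.
#' @param flags Record-level exclusion tags applied to every hit.
#' @return A list of class \code{hp_evidence}.
#' @export
evidence_record <- function(protein_id, feature_id, hits = list(),
                            flags = character()) {
  feature_id <- as.integer(feature_id)
  if (length(feature_id) != 1L || is.na(feature_id) ||
      feature_id < 1L || feature_id > 9L) {
    stop("feature_id must be a single integer in 1..9", call. = FALSE)
  }
  if (length(hits) > 0L) {
    hits <- hits[order(vapply(hits, function(h) h$rank, numeric(1)))]
  }
  rec <- list(protein_id = as.character(protein_id),
              feature_id = feature_id, hits = hits,
              flags = as.character(flags))
  class(rec) <- "hp_evidence"
  rec
}

# Hits surviving the predicted/synthetic/end-to-end exclusion filter,
# record-level flags included.
retained_hits <- function(record) {
  keep <- vapply(record$hits, function(h) {
    !any(c(h$flags, record$flags) %in% EXCLUSION_FLAGS)
  }, logical(1))
  record$hits[keep]
}

check_feature_id <- function(record, expected) {
  if (!record$feature_id %in% expected) {
    stop(sprintf("record for protein '%s' has feature_id %d, expected %s",
                 record$protein_id, record$feature_id,
                 paste(expected, collapse = "/")), call. = FALSE)
  }
}

#' Pseudogene feature rule (feature 7)
#'
#' Scores 1 iff, after discarding predicted/synthetic/end-to-end-alignment
#' hits, a Homo sapiens hit below the E-value cutoff lacks an ATG start codon
#' in all six reading frames — the signature of a pseudogene relative.
#'
#' @param record An [evidence_record()] with \code{feature_id = 7}.
#' @param config A [rule_config()].
#' @return 0 or 1.
#' @export
#' @examples
#' rec <- evidence_record("P1", 7, list(
#'   hit_evidence(e_value = 1e-20, has_atg_start_any_frame = FALSE)))
#' score_pseudogene(rec, rule_config())
score_pseudogene <- function(record, config = rule_config()) {
  check_feature_id(record, 7L)
  hits <- retained_hits(record)
  for (h in hits) {
    if (identical(h$organism, "Homo sapiens") &&
        h$e_value < config$pseudogene_evalue_cutoff &&
        !h$has_atg_start_any_frame) {
      return(1L)
    }
  }
  0L
}

#' Homology-modelling feature rule (feature 8)
#'
#' Scores 1 iff a retained PDB-template hit has percent identity strictly
#' greater than the threshold (default 30%) — enough similarity to build a
#' usable structural model.
#'
#' @inheritParams score_pseudogene
#' @return 0 or 1.
#' @export
score_homology_model <- function(record, config = rule_config()) {
  check_feature_id(record, 8L)
  hits <- retained_hits(record)
  for (h in hits) {
    if (h$is_pdb_template &&
        h$percent_identity > config$homology_identity_threshold) {
      return(1L)
    }
  }
  0L
}

#' Non-coding RNA feature rule (feature 9)
#'
#' Examines the top \code{ncrna_top_k} Homo sapiens hits; when the relative
#' bit-score spread among the top \code{ncrna_extended_k} such hits is below
#' \code{ncrna_score_spread_fraction} (no considerable difference between
#' scores) the window widens to \code{ncrna_extended_k}. Scores 1 iff an
#' examined hit is annotated as a non-coding RNA.
#'
#' @inheritParams score_pseudogene
#' @return 0 or 1.
#' @export
score_ncrna <- function(record, config = rule_config()) {
  check_feature_id(record, 9L)
  hits <- retained_hits(record)
  hs <- Filter(function(h) identical(h$organism, "Homo sapiens"), hits)
  if (length(hs) == 0L) return(0L)
  k <- config$ncrna_top_k
  ext <- hs[seq_len(min(config$ncrna_extended_k, length(hs)))]
  if (length(ext) >= 2L) {
    bs <- vapply(ext, function(h) h$bit_score, numeric(1))
    spread <- if (max(bs) > 0) (max(bs) - min(bs)) / max(bs) else Inf
    if (spread < config$ncrna_score_spread_fraction) {
      k <- config$ncrna_extended_k
    }
  }
  examined <- hs[seq_len(min(k, length(hs)))]
  as.integer(any(vapply(examined, function(h) h$is_ncrna_annotated,
                        logical(1))))
}

#' Legacy feature rules (features 1--6)
#'
#' Generic threshold/presence rule for the six features whose detailed
#' criteria live in the earlier six-point schema: an \code{evalue} rule scores
#' 1 iff the best retained hit's E-value is at or below the per-feature
#' cutoff; a \code{presence} rule scores 1 iff any retained hit exists.
#'
#' @inheritParams score_pseudogene
#' @return 0 or 1.
#' @export
score_legacy_feature <- function(record, config = rule_config()) {
  check_feature_id(record, 1:6)
  rule <- config$legacy_rules[[paste0("f", record$feature_id)]]
  if (is.null(rule) || is.null(rule$type)) {
    stop(sprintf("no legacy rule configured for feature %d",
                 record$feature_id), call. = FALSE)
  }
  hits <- retained_hits(record)
  if (length(hits) == 0L) return(0L)
  if (identical(rule$type, "presence")) return(1L)
  if (identical(rule$type, "evalue")) {
    if (is.null(rule$cutoff) || is.na(rule$cutoff)) {
      stop(sprintf("legacy evalue rule for feature %d has no cutoff",
                   record$feature_id), call. = FALSE)
    }
    best <- hits[[which.min(vapply(hits, function(h) h$rank, numeric(1)))]]
    return(as.integer(best$e_value <= rule$cutoff))
  }
  stop(sprintf("unknown legacy rule type '%s'", rule$type), call. = FALSE)
}

#' Score any evidence record with the rule matching its feature id
#'
#' @inheritParams score_pseudogene
#' @return 0 or 1.
#' @export
score_feature <- function(record, config = rule_config()) {
  switch(as.character(record$feature_id),
         "7" = score_pseudogene(record, config),
         "8" = score_homology_model(record, config),
         "9" = score_ncrna(record, config),
         score_legacy_feature(record, config))
}

#' Total Reliability Score
#'
#' Sum of the nine binary feature scores; range 0--9.
#'
#' @param scores Numeric vector of nine values in \{0, 1\}.
#' @return Integer TRS.
#' @export
compute_trs <- function(scores) {
  if (length(scores) != 9L) {
    stop("exactly nine feature scores are required", call. = FALSE)
  }
  if (anyNA(scores) || !all(scores %in% c(0, 1))) {
    stop("feature scores must all be 0 or 1", call. = FALSE)
  }
  as.integer(sum(scores))
}

#' Build a feature matrix from evidence records
#'
#' Dispatches each record to its feature rule and assembles one row of nine
#' binary scores plus the Total Reliability Score per protein. Proteins with
#' no record for a feature score 0 there; row order follows first appearance
#' in the record list.
#'
#' @param records List of [evidence_record()] objects, at most one per
#'   (protein, feature) pair.
#' @param config A [rule_config()].
#' @return data.frame with columns \code{protein_id}, \code{f1}..\code{f9},
#'   \code{trs}.
#' @export
build_feature_matrix <- function(records, config = rule_config()) {
  pid <- vapply(records, function(r) r$protein_id, character(1))
  fid <- vapply(records, function(r) r$feature_id, integer(1))
  key <- paste(pid, fid)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate evidence record for (protein, feature) = (%s)",
                 sub(" ", ", f", dup)), call. = FALSE)
  }
  proteins <- unique(pid)
  scores <- matrix(0L, nrow = length(proteins), ncol = 9L,
                   dimnames = list(proteins, paste0("f", 1:9)))
  for (i in seq_along(records)) {
    scores[pid[i], fid[i]] <- score_feature(records[[i]], config)
  }
  out <- data.frame(protein_id = proteins, scores, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$trs <- as.integer(rowSums(scores))
  out
}
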