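#' Specification of a synthetic labeled dataset
#'
#' Defines a two-class binary feature matrix: class sizes, per-class
#' per-feature Bernoulli probabilities, and induced positive correlations
#' between feature pairs via a value-copying mixture (with probability
#' \code{w} the target feature copies the source feature's realized value,
#' otherwise it is drawn independently).
#'
#' The defaults are the replication profile: 106 positive (hypothetical
#' protein) and 194 negative (functional protein) rows, positive class
#' enriched on the high-impact features (Pfam, orthology, functional
#' linkages, pseudogene, ncRNA), and positively correlated pairs
#' Pfam–orthology (1 & 2), localization–functional linkages (5 & 6) and
#' functional linkages–homology modelling (6 & 8).
#'
#' @param n_positive,n_negative Class sizes. Defaults 106 / 194.
#' @param p_positive,p_negative Length-9 Bernoulli probability vectors.
#' @param correlated_pairs List of \code{c(source, target, w)} triples,
#'   applied in order; \code{w} in \[0, 1\].
#' @param seed Integer RNG seed; the dataset is a pure function of the spec.
#' @return A list of class \code{hp_dataset_spec}.
#' @export
dataset_spec <- function(n_positive = 106L, n_negative = 194L,
                         p_positive = c(0.90, 0.90, 0.35, 0.30, 0.55,
                                        0.90, 0.85, 0.55, 0.95),
                         p_negative = c(0.12, 0.12, 0.30, 0.25, 0.45,
                                        0.10, 0.15, 0.45, 0.05),
                         correlated_pairs = list(c(1, 2, 0.5),
                                                 c(6, 5, 0.5),
                                                 c(6, 8, 0.5)),
                         seed = 1L) {
  stopifnot(n_positive >= 0, n_negative >= 0,
            length(p_positive) == 9L, length(p_negative) == 9L)
  if (any(p_positive < 0 | p_positive > 1) ||
      any(p_negative < 0 | p_negative > 1)) {
    stop("Bernoulli probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (pr in correlated_pairs) {
    stopifnot(length(pr) == 3L, pr[1] %in% 1:9, pr[2] %in% 1:9,
              pr[3] >= 0, pr[3] <= 1)
  }
  spec <- list(n_positive = as.integer(n_positive),
               n_negative = as.integer(n_negative),
               p_positive = p_positive, p_negative = p_negative,
               correlated_pairs = correlated_pairs,
               seed = as.integer(seed))
  class(spec) <- "hp_dataset_spec"
  spec
}

#' Validation profile for parameter-recovery checks
#'
#' A dataset spec whose induced pairs share the same Bernoulli probability
#' within each class, so the value-copying mixture preserves every marginal
#' exactly and empirical frequencies estimate the spec probabilities without
#' bias. Used to validate the generator at large n.
#'
#' @param n Per-class sample size.
#' @param seed Integer RNG seed.
#' @return An [dataset_spec()] object.
#' @export
validation_profile <- function(n = 2000L, seed = 1L) {
  dataset_spec(
    n_positive = n, n_negative = n,
    p_positive = c(0.70, 0.70, 0.30, 0.40, 0.60, 0.60, 0.50, 0.60, 0.80),
    p_negative = c(0.20, 0.20, 0.50, 0.30, 0.45, 0.45, 0.60, 0.45, 0.10),
    correlated_pairs = list(c(1, 2, 0.5), c(6, 5, 0.5), c(6, 8, 0.5)),
    seed = seed
  )
}

draw_class <- function(n, p, pairs, ids, label) {
  x <- matrix(stats::rbinom(n * 9L, 1L, rep(p, each = n)),
              nrow = n, ncol = 9L)
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]; w <- pr[3]
    copy <- stats::rbinom(n, 1L, w) == 1L
    x[copy, j] <- x[copy, i]
  }
  colnames(x) <- paste0("f", 1:9)
  data.frame(protein_id = ids, x, trs = as.integer(rowSums(x)),
             label = rep(label, n), stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic dataset
#'
#' Draws \code{n_positive + n_negative} nine-bit rows per the spec, applies
#' the correlated-pair copying, fills TRS and class labels. Fully
#' reproducible from \code{spec$seed}; the caller's RNG state is untouched.
#'
#' @param spec A [dataset_spec()].
#' @return data.frame with columns \code{protein_id}, \code{f1}..\code{f9},
#'   \code{trs}, \code{label} (\code{"positive"} = hypothetical protein,
#'   \code{"negative"} = functional protein).
#' @export
#' @examples
#' d <- generate_labeled_dataset(dataset_spec())
#' table(d$label)
generate_labeled_dataset <- function(spec) {
  stopifnot(inherits(spec, "hp_dataset_spec"))
  withr::with_seed(spec$seed, {
    ids <- sprintf("SYN%06d", seq_len(spec$n_positive + spec$n_negative))
    pos <- draw_class(spec$n_positive, spec$p_positive,
                      spec$correlated_pairs,
                      ids[seq_len(spec$n_positive)], "positive")
    neg <- draw_class(spec$n_negative, spec$p_negative,
                      spec$correlated_pairs,
                      ids[spec$n_positive + seq_len(spec$n_negative)],
                      "negative")
    rbind(pos, neg)
  })
}

# Random E-value below (qualifying) or above (disqualifying) a cutoff,
# log-uniform within the band.
rand_evalue <- function(n, cutoff, qualify) {
  if (qualify) 10^stats::runif(n, log10(cutoff) - 30, log10(cutoff) - 1)
  else         10^stats::runif(n, log10(cutoff) + 1, log10(cutoff) + 4)
}

# Evidence for one (row, feature) pair reproducing score s under config.
make_record <- function(pid, f, s, config) {
  if (f == 7L) {
    cut <- config$pseudogene_evalue_cutoff
    if (s == 1L) {
      hits <- list(hit_evidence(1, "Homo sapiens",
                                e_value = rand_evalue(1, cut, TRUE),
                                has_atg_start_any_frame = FALSE))
    } else if (stats::runif(1) < 0.5) {
      hits <- list()   # absent evidence
    } else {
      hits <- list(hit_evidence(1, "Homo sapiens",
                                e_value = rand_evalue(1, cut, TRUE),
                                has_atg_start_any_frame = TRUE))
    }
    return(evidence_record(pid, 7, hits))
  }
  if (f == 8L) {
    thr <- config$homology_identity_threshold
    if (s == 1L) {
      hits <- list(hit_evidence(1, percent_identity =
                                  stats::runif(1, thr + 1, 99),
                                is_pdb_template = TRUE))
    } else if (stats::runif(1) < 0.5) {
      hits <- list()
    } else {
      hits <- list(hit_evidence(1, percent_identity =
                                  stats::runif(1, 1, thr - 1),
                                is_pdb_template = TRUE))
    }
    return(evidence_record(pid, 8, hits))
  }
  if (f == 9L) {
    # three human hits with a wide bit-score spread so the top-3 window
    # applies; an ncRNA annotation lands in the window only for score 1
    bs <- sort(stats::runif(3, 50, 200), decreasing = TRUE)
    ncr <- if (s == 1L) sample(3, 1) else 0L
    hits <- lapply(1:3, function(r) {
      hit_evidence(r, "Homo sapiens", bit_score = bs[r],
                   is_ncrna_annotated = r == ncr)
    })
    return(evidence_record(pid, 9, hits))
  }
  rule <- config$legacy_rules[[paste0("f", f)]]
  if (identical(rule$type, "presence")) {
    hits <- if (s == 1L) list(hit_evidence(1)) else list()
  } else {
    hits <- if (s == 1L) {
      list(hit_evidence(1, e_value = rand_evalue(1, rule$cutoff, TRUE)))
    } else if (stats::runif(1) < 0.5) {
      list()
    } else {
      list(hit_evidence(1, e_value = rand_evalue(1, rule$cutoff, FALSE)))
    }
  }
  evidence_record(pid, f, hits)
}

#' Generate evidence records consistent with a feature matrix
#'
#' Inverse of the scoring rules: for every dataset row emits nine evidence
#' records such that rescoring them with the same configuration reproduces
#' the row's binary scores exactly. Score-1 features receive qualifying hits
#' (log-uniform E-values, uniform identities inside the qualifying band);
#' score-0 features receive absent or disqualifying evidence.
#'
#' @param dataset data.frame with \code{protein_id} and \code{f1}..\code{f9}.
#' @param config A [rule_config()].
#' @param seed Integer RNG seed.
#' @return List of [evidence_record()] objects, nine per row.
#' @export
generate_evidence_records <- function(dataset, config = rule_config(),
                                      seed = 1L) {
  withr::with_seed(as.integer(seed), {
    recs <- vector("list", nrow(dataset) * 9L)
    k <- 0L
    for (i in seq_len(nrow(dataset))) {
      for (f in 1:9) {
        k <- k + 1L
        recs[[k]] <- make_record(dataset$protein_id[i], f,
                                 as.integer(dataset[[paste0("f", f)]][i]),
                                 config)
      }
    }
    recs
  })
}
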