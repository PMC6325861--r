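# Independent oracles: straight-line truth tables and closed forms coded
# without reference to the package internals.

ORACLE_BAD_FLAGS <- c("predicted", "synthetic", "end_to_end_alignment")

# pseudogene rule truth table: a retained human hit below the E-value
# cutoff whose six-frame translation lacks an ATG start
oracle_pseudogene <- function(hits, cutoff = 1.0) {
  for (h in hits) {
    if (any(h$flags %in% ORACLE_BAD_FLAGS)) next
    if (h$organism == "Homo sapiens" && h$e_value < cutoff &&
        !h$has_atg_start_any_frame) {
      return(1L)
    }
  }
  0L
}

# homology-modelling rule truth table: retained PDB template strictly above
# the identity threshold
oracle_homology <- function(hits, threshold = 30) {
  for (h in hits) {
    if (any(h$flags %in% ORACLE_BAD_FLAGS)) next
    if (h$is_pdb_template && h$percent_identity > threshold) return(1L)
  }
  0L
}

# recount a confusion table from raw label pairs and apply the printed
# metric formulas directly
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == "positive" & pred == "positive")
  tn <- sum(truth == "negative" & pred == "negative")
  fp <- sum(truth == "negative" & pred == "positive")
  fn <- sum(truth == "positive" & pred == "negative")
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = rec,
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    precision = prec,
    f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
         else 2 * prec * rec / (prec + rec),
    mcc = {
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den)
    }
  )
}

# hit-type grids for exhaustive enumeration of small evidence sets
pseudogene_hit_types <- function() {
  grid <- expand.grid(organism = c("Homo sapiens", "Mus musculus"),
                      e_value = c(1e-20, 5),
                      atg = c(TRUE, FALSE),
                      flag = c("none", ORACLE_BAD_FLAGS),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    hit_evidence(rank = 1, organism = grid$organism[i],
                 e_value = grid$e_value[i],
                 has_atg_start_any_frame = grid$atg[i],
                 flags = if (grid$flag[i] == "none") character()
                         else grid$flag[i])
  })
}

homology_hit_types <- function() {
  grid <- expand.grid(pdb = c(TRUE, FALSE),
                      identity = c(29.9, 30, 30.1, 35),
                      flag = c("none", "end_to_end_alignment"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    hit_evidence(rank = 1, percent_identity = grid$identity[i],
                 is_pdb_template = grid$pdb[i],
                 flags = if (grid$flag[i] == "none") character()
                         else grid$flag[i])
  })
}

# all multisets of up to max_k hit types (rule outputs are order-invariant)
hit_multisets <- function(types, max_k = 3) {
  out <- list(list())   # the empty evidence set
  for (k in seq_len(max_k)) {
    combos <- utils::combn(length(types) + k - 1, k, simplify = FALSE)
    for (cm in combos) {
      idx <- cm - seq_len(k) + 1L   # combinations with repetition
      hits <- lapply(seq_along(idx), function(r) {
        h <- types[[idx[r]]]
        h$rank <- r
        h
      })
      out[[length(out) + 1L]] <- hits
    }
  }
  out
}

# small labeled dataset helper
tiny_dataset <- function(rows, labels) {
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  data.frame(protein_id = sprintf("P%03d", seq_along(labels)), x,
             trs = rowSums(x), label = labels, stringsAsFactors = FALSE)
}

# always-negative baseline classifier: a perceptron with all-zero weights
# (w . x = 0 classifies as the negative class)
majority_negative_model <- function(n_features = 9) {
  m <- list(weights = rep(0, n_features),
            features = paste0("f", seq_len(n_features)),
            include_bias = FALSE, training_accuracy = NA_real_)
  class(m) <- c("hp_perceptron", "hp_model")
  m
}

all_nine_bit_vectors <- function() {
  g <- as.matrix(expand.grid(rep(list(0:1), 9)))
  colnames(g) <- paste0("f", 1:9)
  storage.mode(g) <- "double"
  g
}
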