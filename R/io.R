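# TSV dialect: optional "#"-prefixed provenance lines, then a header
# `protein_id f1 ... f9 trs [label]`, then one row per protein.

provenance_header <- function(seed = NULL, config = NULL) {
  lines <- sprintf("# hpscore %s",
                   as.character(utils::packageVersion("hpscore")))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash=%s", rlang::hash(config)),
               paste0("# config=", jsonlite::toJSON(config, auto_unbox = TRUE,
                                                    digits = NA)))
  }
  lines
}

#' Write a feature matrix to TSV
#'
#' @param data data.frame with \code{protein_id}, \code{f1}..\code{f9},
#'   \code{trs} and optionally \code{label}.
#' @param path Output file.
#' @param seed,config Optional provenance recorded as \code{#} header lines.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(data, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  writeLines(paste(names(data), collapse = "\t"), con)
  if (nrow(data) > 0L) {
    utils::write.table(data, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' Validates the dialect strictly: required columns, binary score cells and
#' TRS consistency; malformed cells are reported with their file line
#' number. A header-only file yields an empty dataset.
#'
#' @param path TSV file written by [write_feature_matrix()] (or compatible).
#' @return data.frame with \code{protein_id}, feature columns, \code{trs}
#'   and, when present in the file, \code{label}.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body_line_no <- which(!is_comment)
  if (length(body_line_no) == 0L) stop("no header line found in ", path,
                                       call. = FALSE)
  header <- strsplit(lines[body_line_no[1]], "\t", fixed = TRUE)[[1]]
  fcols <- grep("^f[0-9]+$", header, value = TRUE)
  required <- c("protein_id", fcols, "trs")
  if (!"protein_id" %in% header || length(fcols) == 0L ||
      !"trs" %in% header) {
    stop(sprintf("line %d: header must contain protein_id, f*, trs",
                 body_line_no[1]), call. = FALSE)
  }
  rows_no <- body_line_no[-1]
  out <- stats::setNames(
    data.frame(matrix(nrow = length(rows_no), ncol = length(header)),
               stringsAsFactors = FALSE), header)
  for (r in seq_along(rows_no)) {
    ln <- rows_no[r]
    cells <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(header)) {
      stop(sprintf("line %d: expected %d columns, found %d",
                   ln, length(header), length(cells)), call. = FALSE)
    }
    out[r, ] <- as.list(cells)
  }
  for (cn in fcols) {
    v <- suppressWarnings(as.integer(out[[cn]]))
    bad <- which(is.na(v) | !v %in% c(0L, 1L))
    if (length(bad)) {
      stop(sprintf("line %d: column %s has non-binary score '%s'",
                   rows_no[bad[1]], cn, out[[cn]][bad[1]]), call. = FALSE)
    }
    out[[cn]] <- v
  }
  out$trs <- suppressWarnings(as.integer(out$trs))
  if (nrow(out) > 0L) {
    calc <- rowSums(out[fcols])
    bad <- which(is.na(out$trs) | out$trs != calc)
    if (length(bad)) {
      stop(sprintf("line %d: trs inconsistent with feature scores",
                   rows_no[bad[1]]), call. = FALSE)
    }
  }
  if ("label" %in% names(out) && nrow(out) > 0L) {
    bad <- which(!out$label %in% c("positive", "negative"))
    if (length(bad)) {
      stop(sprintf("line %d: invalid label '%s'",
                   rows_no[bad[1]], out$label[bad[1]]), call. = FALSE)
    }
  }
  out
}

hit_to_list <- function(h) {
  list(rank = h$rank, organism = h$organism, e_value = h$e_value,
       bit_score = h$bit_score, percent_identity = h$percent_identity,
       has_atg_start_any_frame = h$has_atg_start_any_frame,
       is_ncrna_annotated = h$is_ncrna_annotated,
       is_pdb_template = h$is_pdb_template,
       flags = I(h$flags))
}

#' Write evidence records as JSON Lines
#'
#' One record per line; field names follow the evidence-record and hit
#' definitions.
#'
#' @param records List of [evidence_record()] objects.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_evidence_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(
      list(protein_id = r$protein_id, feature_id = r$feature_id,
           flags = I(r$flags), hits = lapply(r$hits, hit_to_list)),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read evidence records from JSON Lines
#'
#' @param path File written by [write_evidence_records()].
#' @return List of [evidence_record()] objects.
#' @export
read_evidence_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    hits <- lapply(r$hits, function(h) {
      hit_evidence(rank = h$rank, organism = h$organism,
                   e_value = h$e_value, bit_score = h$bit_score,
                   percent_identity = h$percent_identity,
                   has_atg_start_any_frame = h$has_atg_start_any_frame,
                   is_ncrna_annotated = h$is_ncrna_annotated,
                   is_pdb_template = h$is_pdb_template,
                   flags = unlist(h$flags))
    })
    evidence_record(r$protein_id, r$feature_id, hits,
                    flags = unlist(r$flags))
  })
}

#' Read a rule configuration from YAML or JSON
#'
#' Any field omitted from the file keeps its default.
#'
#' @param path YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return A [rule_config()].
#' @export
read_rule_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  defaults <- rule_config()
  for (nm in intersect(names(raw), setdiff(names(defaults), "legacy_rules"))) {
    defaults[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$legacy_rules)) {
    for (nm in names(raw$legacy_rules)) {
      defaults$legacy_rules[[nm]] <- raw$legacy_rules[[nm]]
    }
  }
  do.call(rule_config, unclass(defaults))
}
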