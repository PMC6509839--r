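# Corpus-level accounting.
#
# Mirrors the match-category bookkeeping used to audit a submission corpus:
# gate-name occurrences and distinct gate names, each broken down by match
# provenance (pro_short_label / exact_synonym / manual / not_matched), with
# percentages rounded to whole percent for presentation while raw counts are
# always preserved. Distinct names are counted over case-folded raw token
# text, without stripping intensity suffixes (a name is what was tokenized).

#' Summarize a corpus of validation reports
#'
#' Single pass over all gate assessments. A distinct gate name's provenance
#' is the provenance of its normalized resolution; all occurrences of one
#' (case-folded) name share it by construction.
#'
#' @param reports list of `cellgate_report`.
#' @return object of class `cellgate_corpus_summary` with fields
#'   `rows_processed`, `conflict_rows`, `total_gate_occurrences`,
#'   `occurrences_by_provenance`, `occurrence_pct_by_provenance`,
#'   `distinct_gate_names`, `distinct_by_provenance`,
#'   `distinct_pct_by_provenance`.
#' @export
summarize_corpus <- function(reports) {
  if (inherits(reports, "cellgate_report")) reports <- list(reports)
  occ <- stats::setNames(integer(length(PROVENANCE_LEVELS)), PROVENANCE_LEVELS)
  name_prov <- list()
  conflict_rows <- 0L
  for (rep in reports) {
    statuses <- vapply(rep$assessments, `[[`, character(1), "status")
    if (any(statuses == "conflict")) conflict_rows <- conflict_rows + 1L
    for (a in rep$assessments) {
      g <- a$gate
      occ[[g$provenance]] <- occ[[g$provenance]] + 1L
      key <- fold_label(g$raw)
      if (is.null(name_prov[[key]])) name_prov[[key]] <- g$provenance
    }
  }
  total <- sum(occ)
  stopifnot(total == sum(occ[PROVENANCE_LEVELS]))  # conservation
  dist <- stats::setNames(integer(length(PROVENANCE_LEVELS)), PROVENANCE_LEVELS)
  for (p in unlist(name_prov, use.names = FALSE)) dist[[p]] <- dist[[p]] + 1L
  ndist <- sum(dist)
  pct <- function(x, denom) {
    if (denom == 0L) stats::setNames(rep(0, length(x)), names(x))
    else round(100 * x / denom)
  }
  structure(list(
    rows_processed = length(reports),
    conflict_rows = conflict_rows,
    total_gate_occurrences = as.integer(total),
    occurrences_by_provenance = occ,
    occurrence_pct_by_provenance = pct(occ, total),
    distinct_gate_names = as.integer(ndist),
    distinct_by_provenance = dist,
    distinct_pct_by_provenance = pct(dist, ndist)
  ), class = "cellgate_corpus_summary")
}

summary_to_table <- function(summary) {
  cats <- PROVENANCE_LEVELS
  df <- data.frame(
    category = c(cats, "Total"),
    occurrences = c(unname(summary$occurrences_by_provenance[cats]),
                    summary$total_gate_occurrences),
    occurrence_pct = c(unname(summary$occurrence_pct_by_provenance[cats]),
                       if (summary$total_gate_occurrences > 0L) 100 else 0),
    distinct_names = c(unname(summary$distinct_by_provenance[cats]),
                       summary$distinct_gate_names),
    distinct_pct = c(unname(summary$distinct_pct_by_provenance[cats]),
                     if (summary$distinct_gate_names > 0L) 100 else 0),
    stringsAsFactors = FALSE
  )
  df
}

#' @export
print.cellgate_corpus_summary <- function(x, ...) {
  cat(format_summary_text(x), sep = "\n")
  invisible(x)
}

format_summary_text <- function(summary) {
  tb <- summary_to_table(summary)
  c(sprintf("Rows processed: %d (%d with CONFLICT)",
            summary$rows_processed, summary$conflict_rows),
    "",
    sprintf("%-16s %12s %4s %10s %4s",
            "Category", "Occurrences", "%", "Distinct", "%"),
    sprintf("%-16s %12d %3d%% %10d %3d%%",
            tb$category, tb$occurrences, tb$occurrence_pct,
            tb$distinct_names, tb$distinct_pct))
}

#' Write a corpus summary (and optionally per-gate reports) to disk
#'
#' Output is byte-stable: identical inputs give identical files. The `text`
#' format renders the summary block with conflicts marked by a CONFLICT tag
#' in the per-row section; `tsv` writes the four category rows plus a Total
#' row; `json` writes a machine-readable object that round-trips through
#' [read_summary_json()] and validates against the schema shipped in
#' `inst/schema/corpus_summary.schema.json`.
#'
#' @param summary a `cellgate_corpus_summary`.
#' @param path output file path.
#' @param format one of `tsv`, `json`, `text`.
#' @param reports optional list of `cellgate_report`; when given, the text
#'   format appends per-row verdict lines.
#' @return the path, invisibly.
#' @export
write_summary <- function(summary, path, format = c("tsv", "json", "text"),
                          reports = NULL) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir))
    cg_stop(paste0("output directory does not exist: ", dir),
            "cellgate_io_error")
  if (format == "tsv") {
    write_tsv_strict(summary_to_table(summary), path)
  } else if (format == "json") {
    obj <- list(
      rows_processed = summary$rows_processed,
      conflict_rows = summary$conflict_rows,
      total_gate_occurrences = summary$total_gate_occurrences,
      occurrences_by_provenance = as.list(summary$occurrences_by_provenance),
      occurrence_pct_by_provenance = as.list(summary$occurrence_pct_by_provenance),
      distinct_gate_names = summary$distinct_gate_names,
      distinct_by_provenance = as.list(summary$distinct_by_provenance),
      distinct_pct_by_provenance = as.list(summary$distinct_pct_by_provenance)
    )
    txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(as.character(txt)), con = con, sep = "\n",
               useBytes = TRUE)
  } else {
    lines <- format_summary_text(summary)
    if (!is.null(reports)) {
      lines <- c(lines, "", "Rows:")
      for (rep in reports) {
        tag <- if (rep$verdict == "has_conflicts") "CONFLICT"
          else toupper(rep$verdict)
        lines <- c(lines, sprintf("  [%s] %s -- %s", tag,
                                  as.character(rep$row_id),
                                  rep$population$raw))
      }
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con = con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a corpus summary back from its JSON form
#'
#' @param path path written by [write_summary()] with `format = "json"`.
#' @return a `cellgate_corpus_summary` equal to the one written.
#' @export
read_summary_json <- function(path) {
  obj <- jsonlite::read_json(path)
  as_counts <- function(x) {
    v <- stats::setNames(vapply(PROVENANCE_LEVELS,
                                function(p) as.integer(x[[p]]), integer(1)),
                         PROVENANCE_LEVELS)
    v
  }
  as_pcts <- function(x) {
    stats::setNames(vapply(PROVENANCE_LEVELS,
                           function(p) as.numeric(x[[p]]), numeric(1)),
                    PROVENANCE_LEVELS)
  }
  structure(list(
    rows_processed = as.integer(obj$rows_processed),
    conflict_rows = as.integer(obj$conflict_rows),
    total_gate_occurrences = as.integer(obj$total_gate_occurrences),
    occurrences_by_provenance = as_counts(obj$occurrences_by_provenance),
    occurrence_pct_by_provenance = as_pcts(obj$occurrence_pct_by_provenance),
    distinct_gate_names = as.integer(obj$distinct_gate_names),
    distinct_by_provenance = as_counts(obj$distinct_by_provenance),
    distinct_pct_by_provenance = as_pcts(obj$distinct_pct_by_provenance)
  ), class = "cellgate_corpus_summary")
}

#' Check a summary JSON file against the shipped schema
#'
#' Structural validation (required properties, types, provenance keys)
#' against `inst/schema/corpus_summary.schema.json`. This is a minimal
#' checker, not a general JSON Schema engine.
#'
#' @param path JSON file to check.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_summary_json <- function(path) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "corpus_summary.schema.json",
                                            package = "cellgate"))
  obj <- jsonlite::read_json(path)
  for (req in unlist(schema$required)) {
    if (is.null(obj[[req]]))
      cg_stop(paste0("summary JSON missing required field: ", req),
              "cellgate_schema_error")
  }
  for (fld in c("rows_processed", "conflict_rows", "total_gate_occurrences",
                "distinct_gate_names")) {
    if (!is.numeric(obj[[fld]]))
      cg_stop(paste0("summary JSON field not numeric: ", fld),
              "cellgate_schema_error")
  }
  for (fld in c("occurrences_by_provenance", "distinct_by_provenance",
                "occurrence_pct_by_provenance", "distinct_pct_by_provenance")) {
    miss <- setdiff(PROVENANCE_LEVELS, names(obj[[fld]]))
    if (length(miss) > 0L)
      cg_stop(paste0("summary JSON field ", fld, " missing category: ",
                     paste(miss, collapse = ", ")), "cellgate_schema_error")
  }
  invisible(TRUE)
}

#' Serialize validation reports to JSON
#'
#' Machine-readable per-row report: population resolution, per-gate
#' normalization and assessment, and verdict. [reports_from_json()] rebuilds
#' report objects sufficient for [summarize_corpus()].
#'
#' @param reports list of `cellgate_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reports_json <- function(reports, path) {
  rows <- lapply(reports, function(rep) {
    list(row_id = as.character(rep$row_id),
         population = list(raw = rep$population$raw,
                           base_label = rep$population$base_label,
                           cl_id = rep$population$cl_id,
                           resolved = rep$population$resolved),
         verdict = rep$verdict,
         assessments = lapply(rep$assessments, function(a) {
           g <- a$gate
           list(raw = g$raw, kind = g$kind, marker_id = g$marker_id,
                canonical_label = g$canonical_label,
                intensity_state = if (is.null(g$intensity)) NA_character_
                  else g$intensity$state,
                provenance = g$provenance, status = a$status,
                message = a$message)
         }))
  })
  txt <- jsonlite::toJSON(list(rows = rows), auto_unbox = TRUE, pretty = TRUE,
                          na = "null", digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(txt)), con = con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_reports_json
#' @export
reports_from_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$rows, function(row) {
    assessments <- lapply(row$assessments, function(a) {
      intensity <- if (is.null(a$intensity_state)) NULL
        else new_intensity(a$intensity_state)
      g <- new_gate(a$kind, a$marker_id %||% NA_character_,
                    a$canonical_label, intensity, a$provenance, a$raw)
      new_assessment(g, a$status, message = a$message %||% "")
    })
    structure(list(row_id = row$row_id,
                   population = structure(list(
                     raw = row$population$raw,
                     base_label = row$population$base_label,
                     cl_id = row$population$cl_id %||% NA_character_,
                     resolved = isTRUE(row$population$resolved),
                     extras = list()), class = "cellgate_population"),
                   assessments = assessments,
                   verdict = row$verdict),
              class = "cellgate_report")
  })
}
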