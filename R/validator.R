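# Cross-checking gating definitions against cell-type axioms.
#
# Each parsed gate is compared against the population's marker-constraint
# closure. Identity is by accession (marker_id), never by label text, so a
# protein complex and one of its chains are distinct markers unless the
# catalog maps both names to the same accession. The conflict table:
#
#   gate negative            vs requires_present -> conflict
#   gate detected (+ level)  vs requires_absent  -> conflict
#   gate high (++)           vs requires_low     -> conflict
#   gate low (+-) / negative vs requires_high    -> conflict
#
# Everything else on a constrained marker is consistent; a marker the
# closure does not mention is not_covered (never a guessed conflict); a gate
# with no intensity suffix is read as present-unspecified and never
# conflicts.

PRESENT_STATES <- c("positive", "low", "intermediate", "high")

conflict_reason <- function(state, relation) {
  if (is.na(state)) return(NULL)
  if (state == "negative" && relation == "requires_present")
    return("gated negative but the cell type requires the marker present")
  if (state %in% PRESENT_STATES && relation == "requires_absent")
    return("gated as detected but the cell type lacks the marker")
  if (state == "high" && relation == "requires_low")
    return("gated high but the cell type requires low amounts")
  if (state %in% c("low", "negative") && relation == "requires_high")
    return("gated low/negative but the cell type requires high amounts")
  NULL
}

new_assessment <- function(gate, status, constraint = NULL, message = "") {
  structure(list(gate = gate, status = status, constraint = constraint,
                 message = message),
            class = "cellgate_assessment")
}

#' Assess one gate against a constraint closure
#'
#' @param gate a `cellgate_gate`.
#' @param closure list of `cellgate_constraint` (see [constraint_closure()]).
#' @return a `cellgate_assessment` with `status` one of `consistent`,
#'   `conflict`, `not_covered`, `unresolvable`, the matched `constraint`
#'   (for conflicts), and a human-readable `message`.
#' @export
assess_gate <- function(gate, closure) {
  stopifnot(inherits(gate, "cellgate_gate"))
  if (gate$kind == "unmatched") {
    return(new_assessment(gate, "unresolvable",
                          message = if (nzchar(gate$message)) gate$message
                          else "gate name not matched in any synonym tier"))
  }
  if (gate$kind %in% c("scatter", "dye")) {
    return(new_assessment(gate, "not_covered",
                          message = "non-protein gate; no marker axiom applies"))
  }
  hit <- NULL
  for (co in closure) if (identical(co$key, gate$marker_id)) { hit <- co; break }
  if (is.null(hit)) {
    return(new_assessment(gate, "not_covered",
                          message = "no constraint on this marker in the cell definition"))
  }
  state <- if (is.null(gate$intensity)) NA_character_ else gate$intensity$state
  reason <- conflict_reason(state, hit$relation)
  if (!is.null(reason)) {
    return(new_assessment(gate, "conflict", constraint = hit,
                          message = paste0(gate$canonical_label, ": ", reason)))
  }
  msg <- if (is.na(state))
    "marker named without intensity; read as present-unspecified" else
      paste0("satisfies ", hit$relation)
  new_assessment(gate, "consistent", constraint = hit, message = msg)
}

#' Validate one study row
#'
#' Parses the population name and the gating definition, computes the cell
#' type's constraint closure, and assesses every gate — including population
#' extras that parse as gates, which are checked against the closure exactly
#' like gating-definition gates. An unresolved population yields verdict
#' `unresolvable`, with per-gate assessments still computed (protein and
#' unmatched gates become `unresolvable`, scatter/dye gates `not_covered`).
#'
#' @param population_text raw population name.
#' @param gating_text raw gating definition.
#' @param dialect a `cellgate_dialect`.
#' @param marker_catalog a `cellgate_marker_catalog`.
#' @param cell_catalog a `cellgate_cell_catalog`.
#' @param inherit inherit ancestor constraints (default `TRUE`); `FALSE`
#'   checks only the named class's own axiom.
#' @param row_id identifier carried into the report.
#' @return an object of class `cellgate_report`: fields `row_id`,
#'   `population`, `assessments`, `verdict` (`valid`, `has_conflicts`, or
#'   `unresolvable`).
#' @export
validate_row <- function(population_text, gating_text,
                         dialect = cellgate::dialect("standard"),
                         marker_catalog, cell_catalog,
                         inherit = TRUE, row_id = NA_character_) {
  pop <- parse_population(population_text, cell_catalog, marker_catalog)
  gates <- parse_gating_definition(gating_text, dialect, marker_catalog)
  extra_gates <- Filter(function(e) inherits(e, "cellgate_gate"), pop$extras)
  all_gates <- c(gates, extra_gates)

  if (pop$resolved) {
    closure <- constraint_closure(cell_catalog, pop$cl_id, inherit = inherit)
    assessments <- lapply(all_gates, assess_gate, closure = closure)
    verdict <- if (any(vapply(assessments, `[[`, character(1), "status") ==
                       "conflict")) "has_conflicts" else "valid"
  } else {
    assessments <- lapply(all_gates, function(g) {
      if (g$kind %in% c("scatter", "dye"))
        new_assessment(g, "not_covered",
                       message = "non-protein gate; no marker axiom applies")
      else
        new_assessment(g, "unresolvable",
                       message = "population name not resolved to a cell type")
    })
    verdict <- "unresolvable"
  }

  structure(list(row_id = row_id, population = pop,
                 assessments = assessments, verdict = verdict),
            class = "cellgate_report")
}

#' @export
print.cellgate_report <- function(x, ...) {
  cat("<validation report", if (!is.na(x$row_id)) paste0(" [", x$row_id, "]"),
      ": ", x$verdict, ", ", length(x$assessments), " gates>\n", sep = "")
  invisible(x)
}

#' Validate a study table
#'
#' Applies [validate_row()] to each row of a study table with columns
#' `Population name` and `Gating definition` (an optional `dialect` column
#' overrides the default dialect per row).
#'
#' @param study a data.frame, or path to a TSV/CSV file (extension decides).
#' @param dialect default `cellgate_dialect` for rows without their own.
#' @param marker_catalog,cell_catalog catalogs.
#' @param inherit see [validate_row()].
#' @return list of `cellgate_report`, one per row.
#' @export
validate_study <- function(study, dialect = cellgate::dialect("standard"),
                           marker_catalog, cell_catalog, inherit = TRUE) {
  if (is.character(study)) study <- read_study(study)
  pcol <- intersect(c("Population name", "population_name"), names(study))[1]
  gcol <- intersect(c("Gating definition", "gating_definition"), names(study))[1]
  if (is.na(pcol) || is.na(gcol))
    cg_stop("study table needs 'Population name' and 'Gating definition' columns",
            "cellgate_load_error")
  row_ids <- if ("row_id" %in% names(study)) as.character(study$row_id)
    else as.character(seq_len(nrow(study)))
  lapply(seq_len(nrow(study)), function(i) {
    d <- if ("dialect" %in% names(study) && nzchar(study$dialect[i]))
      cellgate::dialect(study$dialect[i]) else dialect
    validate_row(study[[pcol]][i], study[[gcol]][i], d,
                 marker_catalog, cell_catalog, inherit = inherit,
                 row_id = row_ids[i])
  })
}

#' Read a study table from TSV or CSV
#'
#' @param path file path; `.csv` is read as comma-separated, anything else
#'   as tab-separated.
#' @return data.frame of character columns.
#' @export
read_study <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (!file.exists(path))
      cg_stop(paste0("file not found: ", path), "cellgate_io_error")
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", encoding = "UTF-8")
  } else {
    read_tsv_strict(path)
  }
}

#' Flatten validation reports to a table
#'
#' One row per gate assessment, in the column layout of the CLI report:
#' `row_id`, `population_raw`, `cl_id`, `resolved`, `gate_raw`,
#' `canonical_gate`, `provenance`, `status`, `message`.
#'
#' @param reports list of `cellgate_report` (or a single one).
#' @return data.frame.
#' @export
reports_to_df <- function(reports) {
  if (inherits(reports, "cellgate_report")) reports <- list(reports)
  rows <- lapply(reports, function(rep) {
    if (length(rep$assessments) == 0L) return(NULL)
    do.call(rbind, lapply(rep$assessments, function(a) {
      g <- a$gate
      data.frame(row_id = as.character(rep$row_id),
                 population_raw = rep$population$raw,
                 cl_id = rep$population$cl_id,
                 resolved = as.character(rep$population$resolved),
                 gate_raw = g$raw,
                 canonical_gate = serialize_gating_definition(list(g)),
                 provenance = g$provenance,
                 status = a$status,
                 message = a$message,
                 stringsAsFactors = FALSE)
    }))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(row_id = character(0), population_raw = character(0),
                      cl_id = character(0), resolved = character(0),
                      gate_raw = character(0), canonical_gate = character(0),
                      provenance = character(0), status = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
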