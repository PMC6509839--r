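# Population-name parsing.
#
# The population field names the parent cell type with its Cell Ontology
# label, optionally followed by extra qualifiers after '&' symbols:
# "'plasmacytoid dendritic cell' & BDCA3+". The base label is matched
# exactly (case-insensitively) against catalog labels — no fuzzy matching:
# legacy free-text names are surfaced as unresolved for human triage, not
# guessed at.

#' Resolve a cell-type label
#'
#' Case-insensitive, NFC-normalized exact match against the catalog's cell
#' labels. No partial matching; not-found is a value, not an error.
#'
#' @param label non-empty cell-type label.
#' @param cell_catalog a `cellgate_cell_catalog`.
#' @return a `cellgate_cell`, or `NULL` when the label is not a catalog label.
#' @export
resolve_cell_type <- function(label, cell_catalog) {
  stopifnot(inherits(cell_catalog, "cellgate_cell_catalog"))
  if (!is.character(label) || length(label) != 1L || !nzchar(trim(label)))
    cg_stop("cell label must be a non-empty string", "cellgate_parse_error")
  id <- cell_catalog$label_index[fold_label(trim(label))]
  if (is.na(id)) return(NULL)
  cell_catalog$cells[[unname(id)]]
}

strip_outer_quotes <- function(x) {
  for (q in c("'", '"')) {
    if (nchar(x) >= 2L && startsWith(x, q) && endsWith(x, q))
      return(trim(substr(x, 2L, nchar(x) - 1L)))
  }
  x
}

#' Parse a population name
#'
#' Splits on `&`. The first segment (trimmed, optional surrounding quotes
#' stripped) is resolved against Cell Ontology labels in the cell catalog.
#' Each remaining segment is first attempted as a single gate token through
#' the gate parser and falls back to free text when it does not resolve.
#' An unresolvable base label yields `resolved = FALSE`, not an error.
#'
#' @param text non-empty population name, e.g. `"'B cell' & CD27+"`.
#' @param cell_catalog a `cellgate_cell_catalog`.
#' @param marker_catalog a `cellgate_marker_catalog` (for extras).
#' @return an object of class `cellgate_population`: fields `raw`,
#'   `base_label`, `cl_id` (or `NA`), `resolved`, `extras` (list; each
#'   element either a `cellgate_gate` or a character scalar of free text).
#' @export
parse_population <- function(text, cell_catalog, marker_catalog) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trim(text)))
    cg_stop("population name must be a non-empty string",
            "cellgate_parse_error")
  segs <- trim(strsplit(text, "&", fixed = TRUE)[[1]])
  base <- strip_outer_quotes(segs[1])
  if (!nzchar(base))
    cg_stop("population name has an empty base segment",
            "cellgate_parse_error")
  cell <- resolve_cell_type(base, cell_catalog)

  extras <- list()
  for (seg in segs[-1]) {
    if (!nzchar(seg)) next
    seg <- strip_outer_quotes(seg)
    gate <- tryCatch(normalize_token(seg, NA_integer_, marker_catalog),
                     cellgate_error = function(e) NULL)
    extras[[length(extras) + 1L]] <-
      if (!is.null(gate) && gate$kind != "unmatched") gate else seg
  }

  structure(list(raw = text,
                 base_label = base,
                 cl_id = if (is.null(cell)) NA_character_ else cell$cl_id,
                 resolved = !is.null(cell),
                 extras = extras),
            class = "cellgate_population")
}

#' @export
print.cellgate_population <- function(x, ...) {
  cat("<population '", x$base_label, "' ",
      if (x$resolved) paste0("[", x$cl_id, "]") else "[unresolved]",
      if (length(x$extras) > 0L) paste0(" + ", length(x$extras), " extras"),
      ">\n", sep = "")
  invisible(x)
}
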