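# Gate normalization.
#
# A gate token is normalized in two steps: intensity splitting (see
# split_intensity) and marker resolution. Resolution is a fixed-order,
# case-insensitive cascade over synonym tiers: (1) PRO-style short labels,
# (2) exact synonyms, (3) the manually curated tier, which also covers
# scatter/dye gate spellings. The first hit wins and determines the match
# provenance recorded on the gate — the same four categories used for corpus
# accounting (pro_short_label, exact_synonym, manual, not_matched).

PROVENANCE_LEVELS <- c("pro_short_label", "exact_synonym", "manual", "not_matched")
TIER_PROVENANCE <- c(short_label = "pro_short_label",
                     exact_synonym = "exact_synonym",
                     manual = "manual")

#' Resolve a marker name against the catalog cascade
#'
#' Tiers are tried in fixed order: short label, exact synonym, manual
#' (curated synonyms plus scatter/dye spellings). The first tier containing
#' the case-folded name wins. A name mapping to more than one entry within
#' the winning tier raises an ambiguity error listing the candidates; a hit
#' on a disallowed entry (a lineage cocktail such as LIN) raises an error
#' advising to spell out the cocktail.
#'
#' @param marker_text non-empty marker name.
#' @param catalog a `cellgate_marker_catalog`.
#' @return list with `kind` (`protein_marker`, `scatter`, `dye`, or
#'   `unmatched`), `marker_id` (accession or `NA`), `canonical_label`,
#'   `provenance`.
#' @export
resolve_marker <- function(marker_text, catalog) {
  stopifnot(inherits(catalog, "cellgate_marker_catalog"))
  if (!is.character(marker_text) || length(marker_text) != 1L ||
      !nzchar(trim(marker_text)))
    cg_stop("marker text must be a non-empty string", "cellgate_parse_error")
  f <- fold_label(trim(marker_text))

  for (tr in MARKER_TIERS) {
    ids <- catalog$tier_index[[tr]][[f]]
    if (is.null(ids)) next
    if (length(ids) > 1L)
      cg_stop(paste0("ambiguous marker name '", trim(marker_text),
                     "' in tier ", tr, ": candidates ",
                     paste(ids, collapse = ", ")),
              "cellgate_ambiguous_marker")
    entry <- catalog$entries[[ids]]
    if (entry$marker_class == "disallowed")
      cg_stop(entry$message, "cellgate_disallowed_marker")
    return(list(kind = "protein_marker", marker_id = entry$id,
                canonical_label = entry$preferred_label,
                provenance = unname(TIER_PROVENANCE[tr])))
  }

  if (!is.null(catalog$scatter)) {
    lab <- catalog$scatter$map[[f]]
    if (!is.null(lab)) {
      basis <- catalog$scatter$basis[[lab]]
      return(list(kind = if (basis == "dye") "dye" else "scatter",
                  marker_id = NA_character_, canonical_label = lab,
                  provenance = "manual"))
    }
  }

  list(kind = "unmatched", marker_id = NA_character_,
       canonical_label = trim(marker_text), provenance = "not_matched")
}

new_gate <- function(kind, marker_id, canonical_label, intensity, provenance,
                     raw, position = NA_integer_, message = "") {
  structure(list(kind = kind, marker_id = marker_id,
                 canonical_label = canonical_label, intensity = intensity,
                 provenance = provenance, raw = raw, position = position,
                 message = message),
            class = "cellgate_gate")
}

#' @export
print.cellgate_gate <- function(x, ...) {
  cat("<gate ", x$kind, ": ", x$canonical_label,
      if (!is.null(x$intensity)) x$intensity$symbol else "",
      " [", x$provenance, "]",
      if (nzchar(x$message)) paste0(" -- ", x$message) else "",
      ">\n", sep = "")
  invisible(x)
}

# Normalize one token into a Gate. The raw token is first tried verbatim
# against the catalog (this is what lets curated spellings that end in a
# minus sign, like "Annexin-" or "CFSE-", resolve as dye gates instead of
# being read as negative gates on unknown markers); only then is the
# intensity suffix split off and the remainder resolved. Resolution errors
# (ambiguity, disallowed cocktail) are captured on the gate, not raised.
normalize_token <- function(raw, position, catalog) {
  whole <- tryCatch(resolve_marker(raw, catalog),
                    cellgate_error = function(e) e)
  if (!inherits(whole, "condition") && whole$kind != "unmatched") {
    return(new_gate(whole$kind, whole$marker_id, whole$canonical_label,
                    intensity = NULL, provenance = whole$provenance,
                    raw = raw, position = position))
  }

  sp <- split_intensity(raw)
  intensity <- if (nzchar(sp$intensity_text))
    normalize_intensity(sp$intensity_text) else NULL
  res <- tryCatch(resolve_marker(sp$marker_text, catalog),
                  cellgate_error = function(e) {
                    list(kind = "unmatched", marker_id = NA_character_,
                         canonical_label = trim(sp$marker_text),
                         provenance = "not_matched",
                         message = conditionMessage(e))
                  })
  msg <- res$message %||% ""
  if (res$kind %in% c("scatter", "dye")) {
    # scatter/dye gates carry no meaningful intensity; drop a parsed suffix
    if (!is.null(intensity) && intensity$state != "positive")
      msg <- paste0("ignored intensity '", intensity$symbol,
                    "' on non-protein gate")
    intensity <- NULL
  }
  new_gate(res$kind, res$marker_id, res$canonical_label, intensity,
           res$provenance, raw = raw, position = position, message = msg)
}

#' Parse a gating definition into normalized gates
#'
#' Composes tokenization, intensity splitting, intensity normalization and
#' marker resolution. Tokens that fail to resolve produce `unmatched` gates
#' (provenance `not_matched`) rather than errors; only structural problems
#' (empty definition, unbalanced quote) abort.
#'
#' @param definition non-empty gating definition string.
#' @param dialect a `cellgate_dialect`.
#' @param catalog a `cellgate_marker_catalog`.
#' @return list of `cellgate_gate`, in token order.
#' @export
#' @examples
#' \dontrun{
#' cat <- load_fixture_catalogs()
#' parse_gating_definition("singlet/CD14-/CD3+", dialect("slash"), cat$markers)
#' }
parse_gating_definition <- function(definition,
                                    dialect = cellgate::dialect("standard"),
                                    catalog) {
  tokens <- tokenize(definition, dialect)
  lapply(seq_len(nrow(tokens)), function(i) {
    normalize_token(tokens$raw[i], tokens$position[i], catalog)
  })
}

#' Serialize gates back to the standard comma dialect
#'
#' Emits canonical labels with preferred intensity symbols, comma-joined.
#' A label containing a comma is wrapped in double quotes, with the intensity
#' symbol outside the quotes. Parsing the result under the standard dialect
#' reproduces the same canonical gates.
#'
#' @param gates list of `cellgate_gate`.
#' @return a single string (empty for an empty gate list).
#' @export
serialize_gating_definition <- function(gates) {
  if (length(gates) == 0L) return("")
  parts <- vapply(gates, function(g) {
    lab <- g$canonical_label
    if (grepl(",", lab, fixed = TRUE)) lab <- paste0('"', lab, '"')
    paste0(lab, if (!is.null(g$intensity)) g$intensity$symbol else "")
  }, character(1))
  paste(parts, collapse = ",")
}

#' Tabulate a list of gates
#'
#' @param gates list of `cellgate_gate`.
#' @return data.frame with one row per gate: `position`, `raw`, `kind`,
#'   `marker_id`, `canonical_label`, `intensity` (preferred symbol or empty),
#'   `provenance`, `message`.
#' @export
gates_to_df <- function(gates) {
  data.frame(
    position = vapply(gates, function(g) as.integer(g$position), integer(1)),
    raw = vapply(gates, `[[`, character(1), "raw"),
    kind = vapply(gates, `[[`, character(1), "kind"),
    marker_id = vapply(gates, function(g) g$marker_id %||% NA_character_,
                       character(1)),
    canonical_label = vapply(gates, `[[`, character(1), "canonical_label"),
    intensity = vapply(gates, function(g)
      if (is.null(g$intensity)) "" else g$intensity$symbol, character(1)),
    provenance = vapply(gates, `[[`, character(1), "provenance"),
    message = vapply(gates, `[[`, character(1), "message"),
    stringsAsFactors = FALSE
  )
}

# Canonical-content equality, used by round-trip tests. Provenance is
# deliberately excluded: it describes how the *raw* text matched, and
# serialization rewrites raw text to canonical labels (which then match via
# the short-label tier), so provenance is not preserved by design.
gate_signature <- function(g) {
  paste(g$kind, g$marker_id %||% NA_character_, fold_label(g$canonical_label),
        if (is.null(g$intensity)) "" else g$intensity$state,
        sep = "\r")
}
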