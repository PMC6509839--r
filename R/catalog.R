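# Marker and cell-type catalogs.
#
# The validator does not reason over full OWL releases. It consumes flat TSV
# extracts: protein-marker entries with tiered synonyms (PRO-style short
# labels, exact synonyms, and a manually curated flow-cytometry tier),
# scatter/dye gate spellings, and cell types with parent links plus
# Manchester-style logical definitions ("<parent> and
# lacks_plasma_membrane_part some <marker> and ...").

MARKER_TIERS <- c("short_label", "exact_synonym", "manual")
MARKER_CLASSES <- c("protein", "protein_complex", "phospho_protein", "disallowed")
SCATTER_BASES <- c("size_fsc_ssc", "relative_dimensions", "dye")

# relation names as they appear in logical definitions -> internal relation
RELATION_MAP <- c(
  has_plasma_membrane_part         = "requires_present",
  lacks_plasma_membrane_part       = "requires_absent",
  has_high_plasma_membrane_amount  = "requires_high",
  has_low_plasma_membrane_amount   = "requires_low"
)

#' Load the marker catalog
#'
#' Reads a marker-synonym table and (optionally) a scatter/dye-gate spelling
#' table, and builds an index supporting case-insensitive lookup per synonym
#' tier. A synonym appearing under two different markers within the same tier
#' is recorded as an ambiguity (lookup of that string fails loudly; the load
#' does not).
#'
#' @param markers_path TSV with columns `id`, `preferred_label`, `tier`
#'   (one of `short_label`, `exact_synonym`, `manual`), `synonym`,
#'   `marker_class` (one of `protein`, `protein_complex`, `phospho_protein`,
#'   `disallowed`). One row per synonym.
#' @param scatter_path optional TSV with columns `preferred_label`, `basis`
#'   (`size_fsc_ssc`, `relative_dimensions`, `dye`), `spelling`; one row per
#'   alternative spelling.
#' @return an object of class `cellgate_marker_catalog`.
#' @export
load_marker_catalog <- function(markers_path, scatter_path = NULL) {
  df <- read_tsv_strict(markers_path,
                        required = c("id", "preferred_label", "tier",
                                     "synonym", "marker_class"))
  bad_tier <- setdiff(unique(df$tier), MARKER_TIERS)
  if (length(bad_tier) > 0L)
    cg_stop(paste0("unknown synonym tier: ", paste(bad_tier, collapse = ", ")),
            "cellgate_load_error")
  bad_cls <- setdiff(unique(df$marker_class), MARKER_CLASSES)
  if (length(bad_cls) > 0L)
    cg_stop(paste0("unknown marker class: ", paste(bad_cls, collapse = ", ")),
            "cellgate_load_error")
  if (any(!nzchar(df$id)))
    cg_stop("marker id must be non-empty", "cellgate_load_error")

  entries <- list()
  for (id in unique(df$id)) {
    rows <- df[df$id == id, , drop = FALSE]
    if (length(unique(rows$preferred_label)) != 1L)
      cg_stop(paste0("conflicting preferred labels for ", id),
              "cellgate_load_error")
    if (length(unique(rows$marker_class)) != 1L)
      cg_stop(paste0("conflicting marker classes for ", id),
              "cellgate_load_error")
    tiers <- lapply(MARKER_TIERS, function(tr) {
      syn <- rows$synonym[rows$tier == tr]
      unique(syn[nzchar(syn)])
    })
    names(tiers) <- MARKER_TIERS
    folded <- lapply(tiers, fold_label)
    for (i in seq_along(MARKER_TIERS)) {
      for (j in seq_len(i - 1L)) {
        overlap <- intersect(folded[[i]], folded[[j]])
        if (length(overlap) > 0L)
          cg_stop(paste0("synonym tiers overlap for ", id, ": '",
                         overlap[1], "' in both ", MARKER_TIERS[j], " and ",
                         MARKER_TIERS[i]), "cellgate_load_error")
      }
    }
    entries[[id]] <- structure(
      list(id = id,
           preferred_label = rows$preferred_label[1],
           marker_class = rows$marker_class[1],
           short_labels = tiers$short_label,
           exact_synonyms = tiers$exact_synonym,
           manual_synonyms = tiers$manual,
           message = if (rows$marker_class[1] == "disallowed")
             paste0("'", rows$preferred_label[1], "' is a marker cocktail; ",
                    "spell out the component markers used") else ""),
      class = "cellgate_marker_entry")
  }

  # per-tier lookup: folded synonym -> character vector of entry ids
  tier_index <- list()
  ambiguities <- list()
  for (tr in MARKER_TIERS) {
    idx <- list()
    for (id in names(entries)) {
      syns <- switch(tr, short_label = entries[[id]]$short_labels,
                     exact_synonym = entries[[id]]$exact_synonyms,
                     manual = entries[[id]]$manual_synonyms)
      for (s in fold_label(syns)) idx[[s]] <- c(idx[[s]], id)
    }
    dup <- names(idx)[vapply(idx, length, integer(1)) > 1L]
    for (s in dup) {
      ambiguities[[length(ambiguities) + 1L]] <-
        data.frame(tier = tr, synonym = s,
                   ids = paste(idx[[s]], collapse = ","),
                   stringsAsFactors = FALSE)
    }
    tier_index[[tr]] <- idx
  }
  ambiguities <- if (length(ambiguities) > 0L) do.call(rbind, ambiguities)
    else data.frame(tier = character(0), synonym = character(0),
                    ids = character(0), stringsAsFactors = FALSE)

  scatter <- NULL
  if (!is.null(scatter_path)) {
    sdf <- read_tsv_strict(scatter_path,
                           required = c("preferred_label", "basis", "spelling"))
    bad <- setdiff(unique(sdf$basis), SCATTER_BASES)
    if (length(bad) > 0L)
      cg_stop(paste0("unknown scatter-gate basis: ", paste(bad, collapse = ", ")),
              "cellgate_load_error")
    if (any(!nzchar(sdf$spelling)))
      cg_stop("scatter gate spellings must be non-empty", "cellgate_load_error")
    smap <- list()
    basis <- list()
    for (k in seq_len(nrow(sdf))) {
      smap[[fold_label(sdf$spelling[k])]] <- sdf$preferred_label[k]
      basis[[sdf$preferred_label[k]]] <- sdf$basis[k]
    }
    scatter <- list(map = smap, basis = basis, table = sdf)
  }

  structure(list(entries = entries, tier_index = tier_index,
                 ambiguities = ambiguities, scatter = scatter),
            class = "cellgate_marker_catalog")
}

#' @export
print.cellgate_marker_catalog <- function(x, ...) {
  cat("<cellgate marker catalog: ", length(x$entries), " markers, ",
      if (is.null(x$scatter)) 0L else length(unique(x$scatter$table$preferred_label)),
      " scatter/dye gates, ", nrow(x$ambiguities), " ambiguous synonyms>\n",
      sep = "")
  invisible(x)
}

new_constraint <- function(relation, marker_text, marker_id = NA_character_,
                           marker_label = NA_character_) {
  structure(list(relation = relation,
                 marker_text = marker_text,
                 marker_id = marker_id,
                 marker_label = if (is.na(marker_label)) marker_text else marker_label,
                 key = if (is.na(marker_id)) fold_label(marker_text) else marker_id),
            class = "cellgate_constraint")
}

#' Parse a Manchester-style logical cell definition
#'
#' A definition is a conjunction, joined by `and`, of exactly one named
#' parent class and zero or more `<relation> some <marker>` clauses, with
#' relations drawn from `has_plasma_membrane_part`,
#' `lacks_plasma_membrane_part`, `has_high_plasma_membrane_amount`,
#' `has_low_plasma_membrane_amount`. Marker names are resolved through the
#' marker catalog's lookup cascade when possible and kept verbatim otherwise.
#'
#' @param text raw definition string.
#' @param catalog optional `cellgate_marker_catalog` for marker resolution.
#' @return list with `parent_label` and `constraints` (list of
#'   `cellgate_constraint`, each with fields `relation`, `marker_text`,
#'   `marker_id`, `marker_label`, `key`).
#' @export
parse_logical_definition <- function(text, catalog = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trim(text)))
    cg_stop("definition must be a non-empty string", "cellgate_parse_error")
  conjuncts <- trim(stringi::stri_split_regex(trim(text), "\\s+and\\s+")[[1]])
  parent <- NULL
  constraints <- list()
  for (cj in conjuncts) {
    m <- stringi::stri_match_first_regex(cj, "^(\\S+)\\s+some\\s+(.+)$")
    if (!is.na(m[1, 1]) && !(m[1, 2] %in% names(RELATION_MAP))) {
      cg_stop(paste0("unknown relation: '", m[1, 2], "'"),
              "cellgate_parse_error")
    }
    if (!is.na(m[1, 1])) {
      rel <- unname(RELATION_MAP[m[1, 2]])
      mtext <- trim(m[1, 3])
      cons <- new_constraint(rel, mtext)
      if (!is.null(catalog)) {
        res <- tryCatch(resolve_marker(mtext, catalog),
                        cellgate_error = function(e) NULL)
        if (!is.null(res) && res$kind == "protein_marker") {
          cons <- new_constraint(rel, mtext, res$marker_id, res$canonical_label)
        }
      }
      constraints[[length(constraints) + 1L]] <- cons
    } else {
      if (!is.null(parent))
        cg_stop(paste0("definition has two named classes: '", parent,
                       "' and '", cj, "'"), "cellgate_parse_error")
      parent <- cj
    }
  }
  if (is.null(parent))
    cg_stop("definition has no named parent class", "cellgate_parse_error")
  list(parent_label = parent, constraints = constraints)
}

#' Load the cell-type catalog
#'
#' Reads a cell-type table, parses each logical definition, and indexes cells
#' by id and by case-folded label. Parent chains are checked for cycles, and
#' a cell whose own definition constrains the same marker with two
#' contradictory relations is rejected.
#'
#' @param path TSV with columns `cl_id`, `label`, `parent_id` (empty for
#'   roots), `definition` (Manchester-style conjunction string or empty).
#' @param marker_catalog optional `cellgate_marker_catalog`, used to resolve
#'   marker names inside definitions to accessions.
#' @return an object of class `cellgate_cell_catalog`.
#' @export
load_cell_catalog <- function(path, marker_catalog = NULL) {
  df <- read_tsv_strict(path, required = c("cl_id", "label", "parent_id",
                                           "definition"))
  if (any(!nzchar(df$cl_id)) || anyDuplicated(df$cl_id))
    cg_stop("cell ids must be non-empty and unique", "cellgate_load_error")
  cells <- list()
  for (k in seq_len(nrow(df))) {
    own <- list()
    defsrc <- df$definition[k]
    if (nzchar(trim(defsrc))) {
      parsed <- parse_logical_definition(defsrc, marker_catalog)
      own <- parsed$constraints
    }
    keys <- vapply(own, function(co) co$key, character(1))
    rels <- vapply(own, function(co) co$relation, character(1))
    for (key in unique(keys)) {
      if (length(unique(rels[keys == key])) > 1L)
        cg_stop(paste0("cell ", df$cl_id[k],
                       " constrains marker '", key,
                       "' with contradictory relations"), "cellgate_load_error")
    }
    cells[[df$cl_id[k]]] <- structure(
      list(cl_id = df$cl_id[k], label = df$label[k],
           parent_id = if (nzchar(df$parent_id[k])) df$parent_id[k] else NA_character_,
           own_constraints = own, definition_source = defsrc),
      class = "cellgate_cell")
  }
  # cycle check over parents that exist in the table
  for (id in names(cells)) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur) && cur %in% names(cells)) {
      if (cur %in% seen)
        cg_stop(paste0("cyclic parent chain at ", cur), "cellgate_load_error")
      seen <- c(seen, cur)
      cur <- cells[[cur]]$parent_id
    }
  }
  label_index <- stats::setNames(names(cells),
                                 fold_label(vapply(cells, `[[`, character(1), "label")))
  structure(list(cells = cells, label_index = label_index),
            class = "cellgate_cell_catalog")
}

#' @export
print.cellgate_cell_catalog <- function(x, ...) {
  cat("<cellgate cell catalog: ", length(x$cells), " cell types>\n", sep = "")
  invisible(x)
}

#' Inherited marker-constraint closure of a cell type
#'
#' Unions a cell's own marker constraints with those of all its ancestors.
#' When a descendant constrains the same marker as an ancestor, the
#' descendant's constraint wins (needed to model, e.g., a TEMRA-style sibling
#' re-expressing a marker its parent lacks without manufacturing an internal
#' contradiction). Order is deterministic: root-first, then document order
#' within each cell's definition; an overridden ancestor constraint is
#' replaced at the descendant's position.
#'
#' @param cell_catalog a `cellgate_cell_catalog`.
#' @param cell a cell id (`cl_id`) or a `cellgate_cell`.
#' @param inherit if `FALSE`, return only the cell's own constraints
#'   (the narrower behaviour of checking just the named class's axiom).
#' @return list of `cellgate_constraint`.
#' @export
constraint_closure <- function(cell_catalog, cell, inherit = TRUE) {
  stopifnot(inherits(cell_catalog, "cellgate_cell_catalog"))
  if (is.character(cell)) {
    if (!cell %in% names(cell_catalog$cells))
      cg_stop(paste0("unknown cell id: ", cell), "cellgate_lookup_error")
    cell <- cell_catalog$cells[[cell]]
  }
  stopifnot(inherits(cell, "cellgate_cell"))
  if (!inherit) return(cell$own_constraints)

  chain <- list(cell)
  cur <- cell$parent_id
  while (!is.na(cur)) {
    if (!cur %in% names(cell_catalog$cells))
      cg_stop(paste0("unknown parent cell id: ", cur), "cellgate_lookup_error")
    parent <- cell_catalog$cells[[cur]]
    chain <- c(list(parent), chain)  # root first
    cur <- parent$parent_id
  }

  out <- list()
  keys <- character(0)
  for (node in chain) {
    for (co in node$own_constraints) {
      hit <- match(co$key, keys)
      if (!is.na(hit)) {
        out[[hit]] <- NULL
        keys <- keys[-hit]
      }
      out[[length(out) + 1L]] <- co
      keys <- c(keys, co$key)
    }
  }
  out
}
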