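# Packaged catalog fixtures and the synthetic-corpus generator.
#
# The shipped catalogs are a small, curated extract: the flow-cytometry
# synonym tier (BDCA2, CD161, KI67, PD1, TNFa), the hard cases (CD8 complex,
# CD3 -> CD3e chain, HLA-DR -> DR beta chain, pSTAT1/3/5 phospho forms, the
# disallowed LIN cocktail), the non-protein scatter/dye gate spellings, and
# the CD4 T-cell lineage with its logical definitions (the effector-memory
# class lacking CD45RA, CCR7 and IL2RA). Accessions other than the four
# curated complex/chain/phospho targets (PR:000025402, PR:000001020,
# PR:000036952, PR:000003075) are synthetic placeholders in the PR:9xxxxxxxx
# range: the fixture is test scaffolding, not an ontology release.

fixture_markers_df <- function() {
  mk <- function(id, pref, cls, short = character(0), exact = character(0),
                 manual = character(0)) {
    tiers <- c(rep("short_label", length(short)),
               rep("exact_synonym", length(exact)),
               rep("manual", length(manual)))
    syns <- c(short, exact, manual)
    if (length(syns) == 0L) { tiers <- "manual"; syns <- pref }
    data.frame(id = id, preferred_label = pref, tier = tiers, synonym = syns,
               marker_class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    mk("PR:900000001", "BDCA-2", "protein", short = "BDCA-2",
       manual = "BDCA2"),
    mk("PR:900000002", "KLRB1", "protein", short = "KLRB1",
       manual = "CD161"),
    mk("PR:900000003", "MKI67", "protein", short = "MKI67",
       exact = "KI-67", manual = "KI67"),
    mk("PR:900000004", "PDCD1", "protein", short = "PDCD1",
       exact = "CD279", manual = "PD1"),
    mk("PR:900000005", "TNF-a", "protein", short = "TNF-a",
       manual = "TNFa"),
    mk("PR:000025402", "CD8", "protein_complex",
       exact = "CD8 protein complex", manual = "CD8"),
    mk("PR:000001020", "CD3e", "protein", short = "CD3E",
       exact = "T-cell surface glycoprotein CD3 epsilon chain",
       manual = "CD3"),
    mk("PR:000036952", "HLA-DRB", "protein", short = "HLA-DRB",
       manual = c("HLA-DR", "HLADR")),
    mk("PR:000003075", "pSTAT1", "phospho_protein",
       exact = "phosphorylated STAT1", manual = "pSTAT1"),
    mk("PR:900000010", "pSTAT3", "phospho_protein",
       exact = "phosphorylated STAT3", manual = "pSTAT3"),
    mk("PR:900000011", "pSTAT5", "phospho_protein",
       exact = "phosphorylated STAT5", manual = "pSTAT5"),
    mk("PR:900000012", "LIN", "disallowed", manual = c("LIN", "lineage")),
    mk("PR:900000013", "CD4", "protein", short = "CD4",
       exact = c("CD4 molecule", "T-cell surface glycoprotein CD4")),
    mk("PR:900000014", "CD14", "protein", short = "CD14",
       exact = "monocyte differentiation antigen CD14"),
    mk("PR:900000015", "CD19", "protein", short = "CD19",
       exact = "B-lymphocyte antigen CD19"),
    mk("PR:900000016", "CD20", "protein", short = "CD20",
       exact = "B-lymphocyte antigen CD20"),
    mk("PR:900000017", "CD27", "protein", short = "CD27",
       exact = "CD27 antigen"),
    mk("PR:900000018", "CD38", "protein", short = "CD38",
       exact = "ADP-ribosyl cyclase 1"),
    mk("PR:900000019", "CD45RA", "protein", short = "CD45RA",
       exact = "receptor-type tyrosine-protein phosphatase C isoform CD45RA"),
    mk("PR:900000020", "CCR7", "protein", short = "CCR7",
       exact = "C-C chemokine receptor type 7", manual = "CD197"),
    mk("PR:900000021", "IL2RA", "protein", short = "IL2RA",
       exact = c("interleukin-2 receptor subunit alpha", "CD25")),
    mk("PR:900000022", "BDCA-3", "protein", short = "BDCA-3",
       manual = "BDCA3")
  ))
}

fixture_scatter_df <- function() {
  sc <- function(pref, basis, spellings) {
    data.frame(preferred_label = pref, basis = basis,
               spelling = unique(c(pref, spellings)),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    sc("lymphocyte", "size_fsc_ssc",
       c("ly", "lymp", "lymph", "Lymph", "Lymphs", "Lymp", "Lymphocytes")),
    sc("monocyte", "size_fsc_ssc",
       c("mo", "mono", "monos", "MNC", "Monocytes", "Mono")),
    sc("granulocyte", "size_fsc_ssc", "Gran"),
    sc("intact", "size_fsc_ssc",
       c("Intact_cells", "Intact_cells_population")),
    sc("singlet", "relative_dimensions",
       c("sing", "singlets", "Singlet", "Singlets", "doublet_excluded",
         "sing-F", "intact_singlet")),
    sc("viable", "dye", c("live", "Annexin-", "live/dead stain-?")),
    sc("proliferated", "dye", c("CFSE-", "TracerViolet-"))
  ))
}

fixture_cells_df <- function() {
  effdef <- paste("CD4-positive, alpha-beta memory T cell",
                  "and lacks_plasma_membrane_part some",
                  "receptor-type tyrosine-protein phosphatase C isoform CD45RA",
                  "and lacks_plasma_membrane_part some",
                  "C-C chemokine receptor type 7",
                  "and lacks_plasma_membrane_part some",
                  "interleukin-2 receptor subunit alpha")
  data.frame(
    cl_id = c("CL:0000236", "CL:0000784", "CL:0000789", "CL:0000624",
              "CL:0000897", "CL:0000905"),
    label = c("B cell", "plasmacytoid dendritic cell", "alpha-beta T cell",
              "CD4-positive, alpha-beta T cell",
              "CD4-positive, alpha-beta memory T cell",
              "effector memory CD4-positive, alpha-beta T cell"),
    parent_id = c("", "", "", "CL:0000789", "CL:0000624", "CL:0000897"),
    definition = c("", "", "",
                   "alpha-beta T cell and has_plasma_membrane_part some CD4 molecule",
                   "CD4-positive, alpha-beta T cell",
                   effdef),
    stringsAsFactors = FALSE
  )
}

#' Write the packaged fixture catalogs to a directory
#'
#' Emits `markers.tsv`, `cells.tsv` and `scatter_gates.tsv` — the same
#' content that ships under `inst/extdata/`.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
build_fixture_catalog <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(markers = file.path(dir, "markers.tsv"),
             cells = file.path(dir, "cells.tsv"),
             scatter = file.path(dir, "scatter_gates.tsv"))
  write_tsv_strict(fixture_markers_df(), paths[["markers"]])
  write_tsv_strict(fixture_cells_df(), paths[["cells"]])
  write_tsv_strict(fixture_scatter_df(), paths[["scatter"]])
  invisible(paths)
}

#' Load the packaged fixture catalogs
#'
#' @param dir directory holding `markers.tsv`, `cells.tsv`,
#'   `scatter_gates.tsv`; defaults to the copies shipped with the package.
#' @return list with elements `markers` (a `cellgate_marker_catalog`, scatter
#'   gates included) and `cells` (a `cellgate_cell_catalog`).
#' @export
load_fixture_catalogs <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "cellgate")
  markers <- load_marker_catalog(file.path(dir, "markers.tsv"),
                                 file.path(dir, "scatter_gates.tsv"))
  cells <- load_cell_catalog(file.path(dir, "cells.tsv"), markers)
  list(markers = markers, cells = cells)
}

# --- synthetic corpus -------------------------------------------------------

# Expected match provenance of a synonym, computed by direct scan of the
# fixture tables (deliberately independent of resolve_marker, so generator
# bookkeeping can serve as ground truth for the resolution cascade).
scan_provenance <- function(markers_df, scatter_df) {
  tiers <- c("short_label", "exact_synonym", "manual")
  folded <- fold_label(markers_df$synonym)
  out <- list()
  for (i in seq_len(nrow(markers_df))) {
    s <- folded[i]
    if (!is.null(out[[s]])) next
    first <- NULL
    for (tr in tiers) {
      ids <- unique(markers_df$id[markers_df$tier == tr & folded == s])
      if (length(ids) > 0L) { first <- list(tier = tr, ids = ids); break }
    }
    out[[s]] <- list(
      provenance = c(short_label = "pro_short_label",
                     exact_synonym = "exact_synonym",
                     manual = "manual")[[first$tier]],
      ids = first$ids,
      ambiguous = length(first$ids) > 1L,
      disallowed = any(markers_df$marker_class[markers_df$id %in% first$ids] ==
                         "disallowed"))
  }
  for (s in fold_label(scatter_df$spelling)) {
    if (is.null(out[[s]]))
      out[[s]] <- list(provenance = "manual", ids = character(0),
                       ambiguous = FALSE, disallowed = FALSE)
  }
  out
}

SEP_CHARS <- c(standard = ",", slash = "/", semicolon = ";", colon = ":",
               whitespace = " ")

# intensity spellings per state, preferred symbol first
STATE_SPELLINGS <- list(
  negative = c("\u2212", "-", "neg"),
  positive = c("+", "pos"),
  low = c("+\u2212", "+-", "dim", "lo"),
  intermediate = c("+~", "int", "med"),
  high = c("++", "bright", "hi")
)

SATISFYING_STATES <- list(requires_present = c("positive", "intermediate", "high"),
                          requires_absent = "negative",
                          requires_high = "high",
                          requires_low = "low")
VIOLATING_STATES <- list(requires_present = "negative",
                         requires_absent = c("positive", "low",
                                             "intermediate", "high"),
                         requires_high = c("negative", "low"),
                         requires_low = "high")

#' Generate a synthetic study corpus with known ground truth
#'
#' Seeded pseudo-random generation of study rows against the packaged
#' fixture catalogs. Each row names a cell type with a logical definition,
#' and carries a gating definition whose gates satisfy the cell's constraint
#' closure; with probability `planted_conflict_rate` one closure gate's
#' intensity is flipped to violate its constraint, and each remaining gate
#' is independently replaced by a nonsense token with probability
#' `unmatched_rate`. Gate names are drawn across synonym tiers (the expected
#' provenance is computed by direct table scan, independent of the resolver)
#' and intensities across alternative spellings. Identical seeds give
#' byte-identical corpora.
#'
#' @param n_rows number of rows.
#' @param dialect_mix named nonnegative weights over
#'   `c("standard","slash","semicolon","colon","whitespace")`.
#' @param planted_conflict_rate fraction of rows given one planted conflict.
#' @param unmatched_rate per-gate probability of nonsense replacement.
#' @param seed integer seed.
#' @param catalogs as returned by [load_fixture_catalogs()].
#' @return list with `study` (data.frame: `row_id`, `Population name`,
#'   `Gating definition`, `dialect`) and `truth` (per-row list: `row_id`,
#'   `cl_id`, `dialect`, `planted_key` — constrained marker accession or
#'   `NA` —, and a `tokens` data.frame with `text`, `provenance`,
#'   `planted`).
#' @export
generate_gating_corpus <- function(n_rows = 100,
                                   dialect_mix = c(standard = 0.5, slash = 0.3,
                                                   whitespace = 0.2),
                                   planted_conflict_rate = 0.1,
                                   unmatched_rate = 0.1,
                                   seed = 1L,
                                   catalogs = load_fixture_catalogs()) {
  stopifnot(n_rows >= 1,
            planted_conflict_rate >= 0, planted_conflict_rate <= 1,
            unmatched_rate >= 0, unmatched_rate <= 1)
  if (is.null(names(dialect_mix)) || any(dialect_mix < 0) ||
      sum(dialect_mix) <= 0 ||
      !all(names(dialect_mix) %in% names(SEP_CHARS)))
    cg_stop("dialect_mix must be named nonnegative weights over known dialects",
            "cellgate_fixture_error")

  markers_df <- fixture_markers_df()
  scatter_df <- fixture_scatter_df()
  prov <- scan_provenance(markers_df, scatter_df)

  # candidate cells: those whose closure is non-empty (a conflict can be
  # planted against any of them)
  cand <- c("CL:0000624", "CL:0000897", "CL:0000905")
  closures <- lapply(cand, function(id) constraint_closure(catalogs$cells, id))
  names(closures) <- cand

  # usable (synonym, provenance) pairs per marker accession: unambiguous,
  # not disallowed, expected provenance from the scan
  syn_pool <- list()
  folded_syn <- fold_label(markers_df$synonym)
  for (i in seq_len(nrow(markers_df))) {
    s <- folded_syn[i]
    info <- prov[[s]]
    if (info$ambiguous || info$disallowed) next
    if (length(info$ids) != 1L || info$ids != markers_df$id[i]) next
    syn_pool[[markers_df$id[i]]] <-
      rbind(syn_pool[[markers_df$id[i]]],
            data.frame(text = markers_df$synonym[i],
                       provenance = info$provenance,
                       stringsAsFactors = FALSE))
  }
  scatter_pool <- data.frame(text = scatter_df$spelling,
                             label = scatter_df$preferred_label,
                             stringsAsFactors = FALSE)
  scatter_pool <- scatter_pool[!duplicated(fold_label(scatter_pool$text)), ]

  # accessions usable as non-closure filler gates
  filler_ids <- setdiff(names(syn_pool),
                        markers_df$id[markers_df$marker_class == "disallowed"])

  with_seed(seed, {
    study <- vector("list", n_rows)
    truth <- vector("list", n_rows)
    for (r in seq_len(n_rows)) {
      dname <- sample(names(dialect_mix), 1L, prob = dialect_mix)
      sep <- SEP_CHARS[[dname]]
      ok_text <- function(x) {
        !grepl(sep, x, fixed = TRUE) &&
          (dname != "whitespace" || !grepl("\\s", x))
      }
      cl_id <- sample(cand, 1L)
      closure <- closures[[cl_id]]

      texts <- character(0); provs <- character(0)
      keys <- character(0); planted <- logical(0)

      if (stats::runif(1) < 0.7) {
        pool <- scatter_pool[vapply(scatter_pool$text, ok_text, logical(1)), ]
        k <- sample.int(nrow(pool), 1L)
        texts <- c(texts, pool$text[k]); provs <- c(provs, "manual")
        keys <- c(keys, NA_character_); planted <- c(planted, FALSE)
      }

      plant_row <- stats::runif(1) < planted_conflict_rate
      plant_idx <- if (plant_row) sample.int(length(closure), 1L) else 0L
      planted_key <- NA_character_
      for (ci in seq_along(closure)) {
        co <- closure[[ci]]
        pool <- syn_pool[[co$key]]
        pool <- pool[vapply(pool$text, ok_text, logical(1)), , drop = FALSE]
        k <- sample.int(nrow(pool), 1L)
        states <- if (ci == plant_idx) VIOLATING_STATES[[co$relation]]
          else SATISFYING_STATES[[co$relation]]
        state <- if (length(states) == 1L) states else sample(states, 1L)
        spellings <- STATE_SPELLINGS[[state]]
        suffix <- if (length(spellings) == 1L) spellings
          else sample(spellings, 1L)
        texts <- c(texts, paste0(pool$text[k], suffix))
        provs <- c(provs, pool$provenance[k])
        keys <- c(keys, co$key)
        planted <- c(planted, ci == plant_idx)
        if (ci == plant_idx) planted_key <- co$key
      }

      closure_keys <- vapply(closure, `[[`, character(1), "key")
      n_extra <- sample(0:2, 1L)
      extra_ids <- sample(setdiff(filler_ids, closure_keys),
                          min(n_extra, length(setdiff(filler_ids, closure_keys))))
      for (id in extra_ids) {
        pool <- syn_pool[[id]]
        pool <- pool[vapply(pool$text, ok_text, logical(1)), , drop = FALSE]
        if (nrow(pool) == 0L) next
        k <- sample.int(nrow(pool), 1L)
        state <- sample(names(STATE_SPELLINGS), 1L)
        spellings <- STATE_SPELLINGS[[state]]
        suffix <- sample(c(spellings, ""), 1L)
        texts <- c(texts, paste0(pool$text[k], suffix))
        provs <- c(provs, pool$provenance[k])
        keys <- c(keys, id)
        planted <- c(planted, FALSE)
      }

      # nonsense injection (never on the planted-conflict gate)
      for (i in seq_along(texts)) {
        if (!planted[i] && stats::runif(1) < unmatched_rate) {
          texts[i] <- paste0("QQX", r, "N", i)
          provs[i] <- "not_matched"
          keys[i] <- NA_character_
        }
      }

      pop <- catalogs$cells$cells[[cl_id]]$label
      if (stats::runif(1) < 0.25) pop <- toupper(pop)

      study[[r]] <- data.frame(
        row_id = sprintf("R%04d", r),
        `Population name` = pop,
        `Gating definition` = paste(texts, collapse = sep),
        dialect = dname,
        check.names = FALSE, stringsAsFactors = FALSE)
      truth[[r]] <- list(row_id = sprintf("R%04d", r), cl_id = cl_id,
                         dialect = dname, planted_key = planted_key,
                         tokens = data.frame(text = texts, provenance = provs,
                                             planted = planted,
                                             stringsAsFactors = FALSE))
    }
    list(study = do.call(rbind, study), truth = truth)
  })
}

#' Tally ground-truth provenance counts of a synthetic corpus
#'
#' Generator-side bookkeeping: occurrences and distinct (case-folded) gate
#' names per provenance category, for comparison against
#' [summarize_corpus()] output.
#'
#' @param truth the `truth` element returned by [generate_gating_corpus()].
#' @return list with `occurrences` and `distinct`, both named integer
#'   vectors over the four provenance categories.
#' @export
corpus_truth_counts <- function(truth) {
  occ <- stats::setNames(integer(length(PROVENANCE_LEVELS)), PROVENANCE_LEVELS)
  name_prov <- list()
  for (row in truth) {
    for (i in seq_len(nrow(row$tokens))) {
      p <- row$tokens$provenance[i]
      occ[[p]] <- occ[[p]] + 1L
      key <- fold_label(row$tokens$text[i])
      if (is.null(name_prov[[key]])) name_prov[[key]] <- p
    }
  }
  dist <- stats::setNames(integer(length(PROVENANCE_LEVELS)), PROVENANCE_LEVELS)
  for (p in unlist(name_prov, use.names = FALSE)) dist[[p]] <- dist[[p]] + 1L
  list(occurrences = occ, distinct = dist)
}
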