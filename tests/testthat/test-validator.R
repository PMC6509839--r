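closure_624 <- constraint_closure(cats$cells, "CL:0000624")
closure_905 <- constraint_closure(cats$cells, "CL:0000905")

parse_one <- function(txt) {
  parse_gating_definition(txt, dialect("standard"), cats$markers)[[1]]
}

test_that("assess_gate applies the conflict table", {
  # a CD4-negative gate on a CD4-positive cell type is the canonical clash
  expect_equal(assess_gate(parse_one("CD4-"), closure_624)$status, "conflict")
  expect_equal(assess_gate(parse_one("CD4+"), closure_624)$status, "consistent")
  # TEMRA motivation: CD45RA detected on a class defined to lack it
  a <- assess_gate(parse_one("CD45RA+"), closure_905)
  expect_equal(a$status, "conflict")
  expect_equal(a$constraint$relation, "requires_absent")
  # any detected level clashes with requires_absent
  for (suf in c("+", "+~", "++", "dim")) {
    expect_equal(assess_gate(parse_one(paste0("CCR7", suf)), closure_905)$status,
                 "conflict", info = suf)
  }
  expect_equal(assess_gate(parse_one("CCR7-"), closure_905)$status, "consistent")
  # marker absent from the closure is never a conflict
  expect_equal(assess_gate(parse_one("CD19+"), closure_624)$status, "not_covered")
  # scatter and unmatched gates
  expect_equal(assess_gate(parse_one("singlet"), closure_624)$status, "not_covered")
  expect_equal(assess_gate(parse_one("XYZZY+"), closure_624)$status, "unresolvable")
  # unspecified intensity is read as present-unspecified, non-conflicting
  expect_equal(assess_gate(parse_one("CD4"), closure_624)$status, "consistent")
  expect_equal(assess_gate(parse_one("CD45RA"), closure_905)$status, "consistent")
})

test_that("amount constraints conflict per the intensity scale", {
  cdf <- cells_row("A:1", "amount cell", "",
                   paste("root and has_high_plasma_membrane_amount some CD4",
                         "and has_low_plasma_membrane_amount some CD19"))
  cc <- load_cell_catalog(write_temp_cells(cdf), cats$markers)
  cl <- constraint_closure(cc, "A:1")
  expect_equal(assess_gate(parse_one("CD4-"), cl)$status, "conflict")
  expect_equal(assess_gate(parse_one("CD4dim"), cl)$status, "conflict")
  expect_equal(assess_gate(parse_one("CD4++"), cl)$status, "consistent")
  expect_equal(assess_gate(parse_one("CD19++"), cl)$status, "conflict")
  expect_equal(assess_gate(parse_one("CD19dim"), cl)$status, "consistent")
})

test_that("the worked clash example validates as expected", {
  rep <- validate_row("CD4-positive, alpha-beta T cell",
                      paste0("CD4", MINUS, " CD19+ CD20", MINUS,
                             " CD27++ CD38+", MINUS),
                      dialect("whitespace"), cats$markers, cats$cells)
  expect_equal(rep$verdict, "has_conflicts")
  st <- vapply(rep$assessments, `[[`, character(1), "status")
  expect_equal(st, c("conflict", rep("not_covered", 4)))
  expect_equal(rep$assessments[[1]]$gate$canonical_label, "CD4")
})

test_that("empty closures validate cleanly", {
  rep <- validate_row("B cell", "CD19+", dialect("standard"),
                      cats$markers, cats$cells)
  expect_equal(rep$verdict, "valid")
  expect_equal(rep$assessments[[1]]$status, "not_covered")
})

test_that("population extras that are gates are validated against the closure", {
  rep <- validate_row(
    "'effector memory CD4-positive, alpha-beta T cell' & CD45RA+",
    paste0("CCR7", MINUS), dialect("standard"), cats$markers, cats$cells)
  expect_equal(rep$verdict, "has_conflicts")
  expect_length(rep$assessments, 2L)
  expect_equal(rep$assessments[[1]]$status, "consistent")  # gating CCR7-
  expect_equal(rep$assessments[[2]]$status, "conflict")    # extra CD45RA+
})

test_that("unresolved populations yield unresolvable verdicts with assessments", {
  rep <- validate_row("Temra CD4 T cells", "singlet,CD4+,XYZZY+",
                      dialect("standard"), cats$markers, cats$cells)
  expect_equal(rep$verdict, "unresolvable")
  st <- vapply(rep$assessments, `[[`, character(1), "status")
  expect_equal(st, c("not_covered", "unresolvable", "unresolvable"))
})

test_that("--no-inherit style validation checks only the named class axiom", {
  rep_inh <- validate_row("effector memory CD4-positive, alpha-beta T cell",
                          paste0("CD4", MINUS), dialect("standard"),
                          cats$markers, cats$cells, inherit = TRUE)
  rep_own <- validate_row("effector memory CD4-positive, alpha-beta T cell",
                          paste0("CD4", MINUS), dialect("standard"),
                          cats$markers, cats$cells, inherit = FALSE)
  expect_equal(rep_inh$assessments[[1]]$status, "conflict")
  expect_equal(rep_own$assessments[[1]]$status, "not_covered")
})

test_that("assess_gate agrees with an exhaustive brute-force checker", {
  # independent truth table over every (constraint x gate-state) pair
  brute_conflict <- function(state, relation) {
    present <- c("positive", "low", "intermediate", "high")
    (state == "negative" && relation == "requires_present") ||
      (state %in% present && relation == "requires_absent") ||
      (state == "high" && relation == "requires_low") ||
      (state %in% c("low", "negative") && relation == "requires_high")
  }
  brute_assess <- function(gate, closure) {
    if (gate$kind == "unmatched") return("unresolvable")
    if (gate$kind %in% c("scatter", "dye")) return("not_covered")
    hits <- Filter(function(co) identical(co$key, gate$marker_id), closure)
    if (length(hits) == 0L) return("not_covered")
    if (is.null(gate$intensity)) return("consistent")
    if (brute_conflict(gate$intensity$state, hits[[1]]$relation)) "conflict"
    else "consistent"
  }
  set.seed(13)
  suffixes <- c("", "+", "-", "+~", "++", paste0("+", MINUS),
                "neg", "pos", "dim", "bright")
  names_pool <- c("CD4", "CD45RA", "CCR7", "CD25", "CD19", "CD8", "KI67",
                  "singlet", "live", "NOSUCH")
  closures <- list(closure_624, closure_905, list())
  for (trial in 1:200) {
    tok <- paste0(sample(names_pool, 1), sample(suffixes, 1))
    gate <- parse_one(tok)
    cl <- closures[[sample.int(3, 1)]]
    expect_equal(assess_gate(gate, cl)$status, brute_assess(gate, cl),
                 info = tok)
  }
})

test_that("appending constraints never turns a conflict into consistent", {
  set.seed(17)
  extra <- cellgate:::new_constraint("requires_present", "CD19",
                                     "PR:900000015", "CD19")
  gates <- lapply(c("CD4-", "CD45RA+", "CCR7+", "CD4+", "CD19+"), parse_one)
  for (g in gates) {
    before <- assess_gate(g, closure_905)$status
    after <- assess_gate(g, c(closure_905, list(extra)))$status
    if (before == "conflict") expect_equal(after, "conflict")
  }
})

test_that("validation is deterministic down to bytes", {
  corpus <- generate_gating_corpus(n_rows = 25, planted_conflict_rate = 0.4,
                                   unmatched_rate = 0.1, seed = 99,
                                   catalogs = cats)
  run <- function() {
    reports <- validate_study(corpus$study, marker_catalog = cats$markers,
                              cell_catalog = cats$cells)
    path <- tempfile(fileext = ".tsv")
    write_tsv_strict(reports_to_df(reports), path)
    readBin(path, "raw", file.size(path))
  }
  expect_identical(run(), run())
})
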