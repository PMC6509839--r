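# Shared fixtures: the packaged catalogs, loaded once per test run, and a
# writer for ad-hoc catalogs built inline in tests.

cats <- load_fixture_catalogs()

MINUS <- "\u2212"

write_temp_markers <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

marker_row <- function(id, pref, tier, synonym, cls = "protein") {
  data.frame(id = id, preferred_label = pref, tier = tier, synonym = synonym,
             marker_class = cls, stringsAsFactors = FALSE)
}

cells_row <- function(cl_id, label, parent_id = "", definition = "") {
  data.frame(cl_id = cl_id, label = label, parent_id = parent_id,
             definition = definition, stringsAsFactors = FALSE)
}

write_temp_cells <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}
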