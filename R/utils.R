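# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-fold a label for comparison
#'
#' All label, synonym and spelling comparison in the package happens on
#' NFC-normalized, lower-cased text, so that typographic variants and case
#' differences never matter for lookup.
#'
#' @param x character vector.
#' @return character vector, NFC-normalized and lower-cased.
#' @keywords internal
fold_label <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(x))
}

trim <- function(x) stringi::stri_trim_both(x)

cg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cellgate_error", "error")))
}

# Deterministic TSV I/O: read without quote interpretation (labels may contain
# double quotes), write byte-stable UTF-8 with LF endings regardless of locale.
read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) cg_stop(paste0("file not found: ", path), "cellgate_io_error")
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8",
                          na.strings = NULL)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L)
      cg_stop(paste0("missing required column: ", paste(miss, collapse = ", "),
                     " in ", path), "cellgate_load_error")
  }
  if (nrow(df) == 0L)
    cg_stop(paste0("empty file: ", path), "cellgate_load_error")
  df
}

write_tsv_strict <- function(df, path) {
  df[] <- lapply(df, as.character)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Seed handling: run `expr` under a private RNG state so generators are
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
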