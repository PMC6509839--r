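# Separator dialects.
#
# Different submitting centers separate gates with different characters
# (whitespace, commas, semicolons, slashes, colons, or combinations). The
# proposed standard uses commas, with double quotes protecting the rare
# marker name that itself contains a comma. Per-center conventions are
# configuration data, not code: a name -> separator map, with a custom
# regular-expression escape hatch.

BUILTIN_DIALECTS <- list(
  standard   = list(sep_pattern = ",",     sep_char = ","),
  comma      = list(sep_pattern = ",",     sep_char = ","),
  slash      = list(sep_pattern = "/",     sep_char = "/"),
  semicolon  = list(sep_pattern = ";",     sep_char = ";"),
  colon      = list(sep_pattern = ":",     sep_char = ":"),
  whitespace = list(sep_pattern = "\\s+",  sep_char = " ")
)

#' Construct a separator dialect
#'
#' A dialect names the separator convention used to split a gating definition
#' into gates. Built-in dialects: `standard` (alias `comma`), `slash`,
#' `semicolon`, `colon`, `whitespace`. Further named dialects can be shipped
#' as configuration in a `dialects.json` file (see
#' `system.file("extdata", "dialects.json", package = "cellgate")`), and any
#' regular expression can be supplied directly via `pattern`.
#'
#' @param name dialect name. Ignored (used only as a label) when `pattern`
#'   is given.
#' @param pattern optional custom separator regular expression.
#' @param quote_char quoting character protecting separator characters inside
#'   a gate name; double quote by default, as in the standard convention.
#' @param config_path optional path to a JSON file mapping dialect names to
#'   separator patterns; defaults to the file shipped with the package.
#' @return an object of class `cellgate_dialect`.
#' @export
#' @examples
#' dialect("slash")
#' dialect("mycenter", pattern = "\\s*/\\s*")
dialect <- function(name = "standard", pattern = NULL, quote_char = '"',
                    config_path = NULL) {
  if (!is.null(pattern)) {
    return(structure(list(name = name, sep_pattern = pattern,
                          sep_char = NA_character_, quote_char = quote_char),
                     class = "cellgate_dialect"))
  }
  if (name %in% names(BUILTIN_DIALECTS)) {
    d <- BUILTIN_DIALECTS[[name]]
    return(structure(list(name = name, sep_pattern = d$sep_pattern,
                          sep_char = d$sep_char, quote_char = quote_char),
                     class = "cellgate_dialect"))
  }
  config_path <- config_path %||%
    system.file("extdata", "dialects.json", package = "cellgate")
  if (nzchar(config_path) && file.exists(config_path)) {
    cfg <- jsonlite::read_json(config_path)
    if (name %in% names(cfg)) {
      e <- cfg[[name]]
      return(structure(list(name = name,
                            sep_pattern = e$separator,
                            sep_char = e$sep_char %||% NA_character_,
                            quote_char = quote_char),
                       class = "cellgate_dialect"))
    }
  }
  cg_stop(paste0("unknown dialect: '", name, "' (known: ",
                 paste(names(BUILTIN_DIALECTS), collapse = ", "), ")"),
          "cellgate_dialect_error")
}

#' @export
print.cellgate_dialect <- function(x, ...) {
  cat("<cellgate dialect '", x$name, "': separator /", x$sep_pattern,
      "/, quote ", x$quote_char, ">\n", sep = "")
  invisible(x)
}

#' Tokenize a gating definition into gates
#'
#' Splits a gating definition on the dialect's separator. Text between
#' `quote_char` pairs is never split, and the quotes are stripped from the
#' token text. Empty segments (consecutive separators, leading/trailing
#' separators) are dropped.
#'
#' @param definition non-empty gating definition string.
#' @param dialect a `cellgate_dialect` (default: the comma standard).
#' @return data.frame with columns `position` (0-based) and `raw` (token text,
#'   trimmed, quotes stripped).
#' @export
#' @examples
#' tokenize("singlet/CD14-/CD3+", dialect("slash"))
tokenize <- function(definition, dialect = cellgate::dialect("standard")) {
  if (!is.character(definition) || length(definition) != 1L ||
      !nzchar(trim(definition)))
    cg_stop("gating definition must be a non-empty string",
            "cellgate_parse_error")
  stopifnot(inherits(dialect, "cellgate_dialect"))

  qc <- dialect$quote_char
  chars <- strsplit(definition, "", fixed = TRUE)[[1]]
  quoted <- character(0)
  masked <- character(length(chars))
  inside <- FALSE
  buf <- character(0)
  open_at <- NA_integer_
  out <- character(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == qc) {
      if (inside) {
        quoted <- c(quoted, paste(buf, collapse = ""))
        out <- c(out, paste0("\x01", length(quoted), "\x01"))
        buf <- character(0)
        inside <- FALSE
      } else {
        inside <- TRUE
        open_at <- i
      }
    } else if (inside) {
      buf <- c(buf, ch)
    } else {
      out <- c(out, ch)
    }
  }
  if (inside)
    cg_stop(paste0("unbalanced quote in gating definition at offset ", open_at),
            "cellgate_parse_error")

  parts <- stringi::stri_split_regex(paste(out, collapse = ""),
                                     dialect$sep_pattern)[[1]]
  for (i in seq_along(quoted)) {
    parts <- stringi::stri_replace_all_fixed(parts,
                                             paste0("\x01", i, "\x01"),
                                             quoted[i])
  }
  parts <- trim(parts)
  parts <- parts[nzchar(parts)]
  data.frame(position = seq_along(parts) - 1L, raw = parts,
             stringsAsFactors = FALSE)
}
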