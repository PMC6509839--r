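# Marker intensity grammar.
#
# Five detection states are recognised, each with one preferred symbol chosen
# to avoid alphanumeric characters and common separator characters:
#
#   negative      −   (minus)
#   positive      +
#   low           +−
#   intermediate  +~
#   high          ++
#
# Alternative textual labels in circulation (neg, pos, dim, lo, int, medium,
# med, bright, hi, negative, positive) are normalized onto this scale.
# ASCII hyphen-minus, Unicode minus and en dash are all read as the minus
# symbol: typeset text mixes them freely.

MINUS <- "\u2212"

# state -> preferred symbol, in scale order
INTENSITY_SYMBOLS <- c(
  negative     = "\u2212",
  positive     = "+",
  low          = "+\u2212",
  intermediate = "+~",
  high         = "++"
)

# folded alternative label -> state
INTENSITY_ALTS <- c(
  neg = "negative", negative = "negative",
  pos = "positive", positive = "positive",
  dim = "low", lo = "low",
  int = "intermediate", medium = "intermediate", med = "intermediate",
  bright = "high", hi = "high"
)

# textual suffixes tried longest-first when splitting a gate token
INTENSITY_TEXT_SUFFIXES <- c("positive", "negative", "bright", "medium",
                             "med", "dim", "neg", "pos", "int", "hi", "lo")

# characters that can form a symbolic intensity run (minus variants included)
SYMBOL_RUN_CLASS <- "[+~\\-\u2212\u2013\u2012\u2010]"

normalize_minus <- function(x) {
  stringi::stri_replace_all_regex(x, "[\\-\u2212\u2013\u2012\u2010]", MINUS)
}

#' Marker intensity scale
#'
#' Returns the intensity scale as a data frame: one row per detection state,
#' with its preferred symbol and the alternative labels it normalizes from.
#'
#' @return data.frame with columns `state`, `symbol`, `alternatives`.
#' @export
#' @examples
#' intensity_levels()
intensity_levels <- function() {
  data.frame(
    state = names(INTENSITY_SYMBOLS),
    symbol = unname(INTENSITY_SYMBOLS),
    alternatives = vapply(names(INTENSITY_SYMBOLS), function(s) {
      paste(names(INTENSITY_ALTS)[INTENSITY_ALTS == s], collapse = ", ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

new_intensity <- function(state) {
  structure(list(state = state, symbol = unname(INTENSITY_SYMBOLS[[state]])),
            class = "cellgate_intensity")
}

#' Normalize a marker intensity label
#'
#' Maps a symbolic or textual intensity label onto the five-state scale.
#' Symbols map to themselves (minus variants are unified); textual labels are
#' matched case-insensitively.
#'
#' @param intensity_text non-empty intensity text, e.g. `"++"`, `"dim"`, `"Pos"`.
#' @return an object of class `cellgate_intensity` with fields `state` and
#'   `symbol` (the preferred symbol).
#' @export
#' @examples
#' normalize_intensity("dim")$symbol    # "+-" (low)
#' normalize_intensity("bright")$state  # "high"
normalize_intensity <- function(intensity_text) {
  if (!is.character(intensity_text) || length(intensity_text) != 1L ||
      !nzchar(trim(intensity_text)))
    cg_stop("intensity text must be a non-empty string", "cellgate_parse_error")
  t <- trim(intensity_text)
  sym <- normalize_minus(stringi::stri_replace_all_regex(t, "\\s+", ""))
  hit <- match(sym, INTENSITY_SYMBOLS)
  if (!is.na(hit)) return(new_intensity(names(INTENSITY_SYMBOLS)[hit]))
  state <- INTENSITY_ALTS[fold_label(t)]
  if (is.na(state))
    cg_stop(paste0("unknown intensity label: '", intensity_text, "'"),
            "cellgate_parse_error")
  new_intensity(unname(state))
}

#' Is a marker detected at this intensity?
#'
#' The presence predicate of the scale: every state except `negative` means
#' the marker was detected.
#'
#' @param intensity a `cellgate_intensity`, or `NULL` (unspecified).
#' @return `TRUE`, `FALSE`, or `NA` for `NULL` (intensity unspecified).
#' @export
intensity_present <- function(intensity) {
  if (is.null(intensity)) return(NA)
  intensity$state != "negative"
}

#' Split a gate token into marker text and intensity suffix
#'
#' Strips the longest matching intensity suffix from a token. Symbolic
#' suffixes are tried longest-first (`++`, `+~`, `+-`, `+`, `-`; ASCII
#' hyphen-minus, Unicode minus and en dash are equivalent), with whitespace
#' inside the trailing symbol run collapsed first (so `"CD38 + -"` splits as
#' `"CD38"` / `"+-"`). Textual suffixes (pos, neg, dim, lo, int, medium, med,
#' bright, hi, positive, negative) match case-insensitively, separated from
#' the marker by whitespace or nothing. If no suffix matches, the intensity
#' text is empty.
#'
#' @param token non-empty gate token text.
#' @return list with `marker_text` and `intensity_text` (empty string when
#'   the token carries no recognisable intensity).
#' @export
#' @examples
#' split_intensity("CD27++")   # marker "CD27", intensity "++"
#' split_intensity("CD8bright")
#' split_intensity("singlet")  # no suffix
split_intensity <- function(token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(trim(token)))
    cg_stop("token must be a non-empty string", "cellgate_parse_error")
  t <- trim(token)

  # symbolic suffix: a trailing run of +/~/minus characters, possibly with
  # internal whitespace ("CD38 + -"), collapsed then matched longest-first
  m <- stringi::stri_match_first_regex(
    t, paste0("^(.*?)[ \t]*(", SYMBOL_RUN_CLASS,
              "(?:[ \t]*", SYMBOL_RUN_CLASS, ")*)$"))
  if (!is.na(m[1, 1]) && nzchar(m[1, 2])) {
    marker <- m[1, 2]
    run <- normalize_minus(stringi::stri_replace_all_regex(m[1, 3], "[ \t]+", ""))
    for (suf in c("++", "+~", paste0("+", MINUS), "+", MINUS)) {
      if (endsWith(run, suf)) {
        leftover <- substr(run, 1L, nchar(run) - nchar(suf))
        return(list(marker_text = trim(paste0(marker, leftover)),
                    intensity_text = suf))
      }
    }
  }

  # textual suffix, longest-first, attached directly or after whitespace
  tl <- fold_label(t)
  for (suf in INTENSITY_TEXT_SUFFIXES) {
    if (endsWith(tl, suf) && nchar(t) > nchar(suf)) {
      marker <- trim(substr(t, 1L, nchar(t) - nchar(suf)))
      if (nzchar(marker))
        return(list(marker_text = marker,
                    intensity_text = substr(t, nchar(t) - nchar(suf) + 1L, nchar(t))))
    }
  }

  list(marker_text = t, intensity_text = "")
}
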