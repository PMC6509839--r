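---
title: "Validating flow-cytometry population names against gating definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating flow-cytometry population names against gating definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A flow-cytometry experiment isolates a cell population by passing events
through a sequence of *gates*: criteria on detected surface or intracellular
markers ("CD3+", "CD14−"), on light scatter ("singlet", "lymphocyte"), or on
dyes ("CFSE−"). Study metadata describes the result twice — as a
human-readable cell-type name ("activated B cell") and as the gating
definition string — and in practice both fields are free text, written with
center-specific separators, ad-hoc marker synonyms, and inconsistent
intensity notation. That makes cross-study queries ("all experiments gating
CD4+ memory T cells") unreliable, and it hides outright contradictions
between what a population is called and how it was gated.

`cellgate` implements a reporting standard that addresses both problems.
Marker names are normalized against a Protein Ontology-style catalog;
population names are anchored to Cell Ontology-style cell types; and the
cell type's logical marker axioms are cross-checked against the gating
definition to flag conflicts automatically.

## The normalization pipeline

Parsing a gating definition is a four-stage composition:

1. **Tokenization.** The definition is split on a *dialect* — a named
   separator convention (`standard`/comma, `slash`, `semicolon`, `colon`,
   `whitespace`, or a custom regular expression). The standard convention is
   comma-separated, with double quotes protecting the rare marker name that
   itself contains a comma. Unbalanced quotes abort with the character
   offset; empty segments are dropped.
2. **Intensity splitting.** The longest matching intensity suffix is
   stripped from each token. The scale has five states with preferred
   non-alphanumeric symbols — negative `−`, positive `+`, low `+−`,
   intermediate `+~`, high `++` — and textual alternatives (`neg`, `pos`,
   `dim`/`lo`, `int`/`medium`/`med`, `bright`/`hi`). ASCII hyphen-minus,
   Unicode minus and en dash are unified, and whitespace inside a trailing
   symbol run is collapsed, so `"CD38 + −"` reads as CD38 at low intensity.
   (Printed sources are ambiguous about whether such spaced strings mean low
   or are typographic accidents; this package reads them as low.)
3. **Intensity normalization.** Any alternative label maps onto its
   preferred symbol; unknown labels fail naming the text.
4. **Marker resolution.** A fixed-order, case-insensitive, NFC-normalized
   cascade over synonym tiers: PRO-style *short labels*, then *exact
   synonyms*, then the *manual* tier (curated flow-cytometry synonyms such
   as KI67 → MKI67, complex/chain conventions such as CD8 → the CD8 protein
   complex and CD3 → the CD3e chain, and scatter/dye gate spellings). The
   first hit wins and is recorded as the gate's *provenance* —
   `pro_short_label`, `exact_synonym`, `manual`, or `not_matched` — the same
   four categories used in corpus accounting. Unmatched names become
   `unmatched` gates, never hard errors; lineage cocktails (LIN) are
   rejected with a message asking for the cocktail to be spelled out.

Each raw token is first tried *verbatim* against the catalog before
intensity splitting. This is what lets curated spellings that end in a minus
sign ("Annexin-", "CFSE-") resolve as dye gates rather than being read as
negative gates on unknown markers. The corollary is a documented exception
list: a catalog label that itself ends in `+`, `−` or `~` cannot be used
with an unquoted intensity suffix.

Serialization emits canonical labels plus preferred symbols, comma-joined,
quoting labels that contain commas. Re-parsing a serialized definition
reproduces the same canonical gates (kind, accession, label, intensity).
Match *provenance* is intentionally not preserved by this round trip:
provenance describes how the original raw text matched, and serialization
rewrites raw text to canonical labels, which then match through the
short-label tier.

## Population names and constraint closures

A population name follows the convention `'CL label' & extra & ...`: the
base segment must equal a catalog cell-type label exactly
(case-insensitively; surrounding quotes optional), and each extra is tried
as a single gate token, falling back to free text ("Temra"). There is
deliberately no fuzzy matching: historical free-text names are surfaced as
unresolved for human triage, because automated recognition of such names is
known to fail almost completely and silent guesses would poison downstream
validation.

Cell types carry Manchester-style logical definitions — a conjunction of one
parent class and `<relation> some <marker>` clauses with relations
`has_plasma_membrane_part`, `lacks_plasma_membrane_part`,
`has_high_plasma_membrane_amount`, `has_low_plasma_membrane_amount`.
Unknown relations fail loudly rather than being skipped. The *constraint
closure* of a cell type unions its own constraints with all ancestors',
root-first; when a descendant constrains the same marker as an ancestor the
descendant wins. Override semantics are needed to model TEMRA-style
siblings — classes that re-express a marker their parent lacks — without
manufacturing internal contradictions. `validate_row(..., inherit = FALSE)`
(CLI `--no-inherit`) restores the narrower behavior of checking only the
named class's own axiom.

## The conflict table

Gate identity is by accession, never label text, so the CD8 complex and a
CD8 chain would be distinct markers unless the catalog maps both names to
one accession. Against the closure, each protein gate is classified:

| gate intensity           | constraint         | status    |
|--------------------------|--------------------|-----------|
| negative                 | requires\_present  | conflict  |
| any detected level       | requires\_absent   | conflict  |
| high (`++`)              | requires\_low      | conflict  |
| low (`+−`) or negative   | requires\_high     | conflict  |
| anything else            | (same marker)      | consistent |
| —                        | marker not in closure | not\_covered |

Three deliberate choices where the source material gives no rule:

* A protein gate with no intensity suffix is *present-unspecified* and never
  conflicts — the conservative reading that avoids false alarms.
* Intermediate (`+~`) conflicts only with `requires_absent`; there is no
  guidance for amount relations at intermediate level.
* The amount relations' semantics follow the five-state intensity scale as
  tabulated above; whether the original validator consumed such axioms at
  all is unknown, so this is a package decision.

Scatter/dye gates are `not_covered` (no marker axiom applies); unmatched
gates are `unresolvable`. A marker absent from the closure is never guessed
into a conflict. A row's verdict is `unresolvable` when the population did
not resolve, `has_conflicts` when at least one assessment conflicts, else
`valid`. Population extras that parse as gates are validated against the
closure exactly like gating-definition gates.

The sample-source caveat — the same gating definition applied to PBMC versus
splenocytes yields different cells — is outside the conflict logic by
design; validation cannot catch such errors.

## Corpus accounting

`summarize_corpus()` tallies gate-name occurrences and distinct gate names
by provenance. Distinct names are counted over case-folded raw token text
and are *not* intensity-stripped (a name is what was tokenized). Percentages
are rounded to whole percent for presentation, matching how such tables are
conventionally printed; raw counts are always carried so no information is
lost. Conservation (category counts summing to the total) is asserted on
every run. The external multi-center corpus that motivated these categories
is not redistributable, so the package does not attempt to reproduce its
published tallies; corpus-level behavior is exercised on synthetic corpora
instead.

## What the synthetic generator emulates

`generate_gating_corpus()` produces study rows with generator-side ground
truth. Each row picks a cell type with a non-empty constraint closure,
emits one gate per closure constraint with a satisfying intensity, usually a
leading scatter gate (probability 0.7), and up to two filler gates on
unconstrained markers. Gate names are drawn across synonym tiers, with each
name's expected provenance computed by a direct scan of the fixture tables —
deliberately independent of the resolver, so the bookkeeping can serve as
ground truth for it. Intensities are rendered through random alternative
spellings. With probability `planted_conflict_rate` one closure gate's
intensity is flipped to violate its constraint; every other gate is
independently replaced by a nonsense token with probability
`unmatched_rate`. Defaults (100 rows; dialect mix 0.5 standard / 0.3 slash /
0.2 whitespace; both rates 0.1) describe a plausibly messy submission batch;
the acceptance checks use the rates they state explicitly.

The generator's world is simpler than real submissions in ways that bound
what a green test establishes: population names are always exact catalog
labels (case-jittered), synonyms containing the row's separator are avoided
rather than quoted, at most one conflict is planted per row, and nonsense
tokens are syntactically well-behaved. Recovery being exact on this corpus
demonstrates that the pipeline is sound on its stated grammar — not that it
can repair arbitrarily malformed free text.

## Numerical and engineering choices

* All comparisons fold case after NFC normalization; typographic minus
  variants are unified only in intensity suffixes, never inside names
  ("TNF-a" keeps its hyphen).
* Catalog interchange is flat TSV, not OWL: labels, tiered synonyms, parent
  links and definition strings are all representable as tables, and a DL
  reasoner is out of scope. Synonym ambiguities (one string, two entries,
  same tier) are recorded at load and fail at lookup, so corpus processing
  continues.
* All report writers emit UTF-8 with LF endings through a binary connection,
  making outputs byte-identical across runs and locales.
* Fixture accessions other than the four curated complex/chain/phospho
  targets are synthetic placeholders (`PR:9xxxxxxxx`); the shipped catalogs
  are test scaffolding, not an ontology release, and do not track any live
  release.

## Known limitations

No fuzzy or edit-distance matching; no automatic synonym discovery (new
synonyms belong upstream in the ontologies); no general
post-translational-modification grammar (the three phospho-STAT markers are
curated entries); human-centric catalogs; no OWL reasoning. The HLA-DR
entry follows the curated guidance of mapping to the DR beta chain, which
predates proper complex modeling.
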