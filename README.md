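# cellgate

Parsing and ontology-based validation of flow-cytometry gating definitions
and cell-population names.

## What it is for

Immunology studies report a sorted cell population twice: a cell-type name
("CD4-positive, alpha-beta T cell") and the gating definition used to
isolate it ("singlet/CD14−/CD3+/CD4+"). Submitted as free text, both fields
vary by center — separators, marker synonyms, intensity notation — which
blocks computational cross-study comparison and hides contradictions
between name and gates. `cellgate` implements a reporting standard for
these two fields, for data curators and standards committees who need to
audit and harmonize submissions:

* **Gate normalization.** Gating definitions are tokenized under per-center
  separator *dialects*, each gate is split into marker text and an
  intensity suffix on the five-state scale (− negative, + positive, +− low,
  +~ intermediate, ++ high; textual variants `neg`, `pos`, `dim`, `lo`,
  `int`, `med`, `bright`, `hi`, ... are normalized), and the marker is
  resolved through a fixed, case-insensitive cascade of synonym tiers —
  PRO-style short label, exact synonym, then a manually curated tier that
  also covers scatter/dye gates ("singlet", "lymph", "CFSE-"). Every gate
  carries its match provenance: `pro_short_label`, `exact_synonym`,
  `manual`, or `not_matched`.
* **Population parsing.** Names follow `'CL label' & extras`; the base
  label must match a Cell Ontology-style catalog label exactly, extras are
  parsed as gates when possible ("BDCA3+") and kept as free text otherwise
  ("Temra"). No fuzzy matching, ever.
* **Consistency validation.** Each cell type's logical definition
  (`... and lacks_plasma_membrane_part some <marker> ...`) is parsed into
  marker constraints; the inherited *constraint closure* (root-first,
  descendant overrides) is cross-checked against the parsed gates. A gate
  negative on a marker the cell type requires present (or detected on one
  it must lack, etc.) is flagged as a conflict; markers the closure does
  not mention are reported `not_covered`, never guessed.
* **Corpus accounting.** Occurrences and distinct gate names per provenance
  category, with whole-percent summaries, byte-stable TSV/JSON/text
  reports, and a seeded synthetic-corpus generator with planted ground
  truth for end-to-end testing.

## Worked example

```r
library(cellgate)
cats <- load_fixture_catalogs()   # packaged marker/cell/scatter catalogs

g <- parse_gating_definition("singlet/CD14-/CD3+/ki67bright",
                             dialect("slash"), cats$markers)
gates_to_df(g)[, c("raw", "kind", "marker_id", "canonical_label",
                   "intensity", "provenance")]
#>          raw           kind    marker_id canonical_label intensity      provenance
#> 1    singlet        scatter         <NA>         singlet                    manual
#> 2      CD14- protein_marker PR:900000014            CD14         −  pro_short_label
#> 3       CD3+ protein_marker PR:000001020            CD3e         +          manual
#> 4 ki67bright protein_marker PR:900000003           MKI67        ++          manual
serialize_gating_definition(g)
#> [1] "singlet,CD14−,CD3e+,MKI67++"
```

The scatter gate resolved through the curated spelling list; "CD3" resolved
to the CD3e chain (the invariant TCR-complex subunit actually stained for)
via the manual tier; "ki67bright" was case-folded to the KI67 synonym of
MKI67 with its intensity normalized to `++`. Serialization emits the
canonical comma-separated standard form.

Cross-checking a population name against its gating definition:

```r
rep <- validate_row("CD4-positive, alpha-beta T cell",
                    "CD4- CD19+ CD20- CD27++ CD38+-",
                    dialect("whitespace"), cats$markers, cats$cells)
reports_to_df(rep)[, c("gate_raw", "canonical_gate", "status")]
#>   gate_raw canonical_gate      status
#> 1     CD4-           CD4−    conflict
#> 2    CD19+          CD19+ not_covered
#> 3    CD20-          CD20− not_covered
#> 4   CD27++         CD27++ not_covered
#> 5   CD38+-         CD38+− not_covered
rep$verdict
#> [1] "has_conflicts"
```

The CD4-negative gate conflicts with the cell type's defining axiom
(`has_plasma_membrane_part some CD4 molecule`); the other markers are not
constrained by the definition, so they are reported as not covered rather
than guessed at.

## Command line

```sh
CG=$(Rscript -e 'cat(system.file("exec", "cellgate", package = "cellgate"))')
$CG fixtures  --out fx/
$CG synth     --spec spec.json --out study.tsv --truth truth.json
$CG parse     --dialect standard --markers fx/markers.tsv \
              --scatter fx/scatter_gates.tsv --in study.tsv --out parsed.tsv
$CG validate  --markers fx/markers.tsv --cells fx/cells.tsv \
              --scatter fx/scatter_gates.tsv --in study.tsv \
              --out report.tsv --json report.json [--no-inherit]
$CG summarize --in report.json --out summary.txt
```

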