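---
title: "The PEP processing model: modifiers, merging, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PEP processing model: modifiers, merging, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmeta)
```

## The data model

A Portable Encapsulated Project (PEP) is at most three plain-text files: a
YAML configuration (optional — a bare CSV is a valid project), a CSV sample
table with one header row and one row per sample, and an optional CSV
subsample table. `pepmeta` represents the processed result as a
`pep_project`: the fully resolved configuration plus a `pep_sample_table`
in which each sample is an ordered mapping from attribute name to a
character vector — length one for ordinary cells, longer when a subsample
table contributed several rows to the same sample.

Two representation commitments run through the package. First, **sample
attribute values are always strings**: CSV carries no types, and silently
coercing `"007"` to a number or `"TRUE"` to a logical would change what
downstream pipelines receive. Typed checks are the schema validator's job.
Second, **unknown configuration keys pass through verbatim**: the format is
deliberately open, and a key this package does not interpret may be exactly
what a downstream tool reads.

## Processing order

`load_project()` runs a fixed pipeline:

1. read the config; resolve `$VAR` references and make every path-valued
   field absolute against the directory of the file that states it;
2. resolve `import` project modifiers;
3. apply requested amendments;
4. read the sample table and merge subsample tables;
5. apply sample modifiers in the order
   remove → append → duplicate → imply → derive.

Steps 2–4 cannot be reordered freely: an amendment may replace the
`sample_table` path, so amendments must precede table reading, and since a
child config may activate an amendment defined by a parent it imports,
imports must be resolved before amendments are applied. Within step 5 the
order is a design choice with one hard constraint — derive templates must
be able to reference attributes introduced by append — and we extend the
same courtesy to imply, letting conditions react to appended or duplicated
attributes. The order is a single internal constant
(`sample_modifier_types()` reports it), so revisiting the choice is a
one-line change.

Path resolution against the *declaring* file, never the working directory,
is what makes a PEP relocatable: a project directory can be tarred up,
moved, and unpacked anywhere, and only environment variables (by design)
change meaning.

## Merge and override semantics

**Imports** cascade recursively, most distant files first; for each
top-level key the nearest file that defines it wins, and within one import
list later entries override earlier ones. Override granularity is the whole
top-level key: an imported `sample_table` is *selected or replaced*, never
merged row-wise. Amendment sections are the one exception, unioned at the
amendment-name level so a child can both add its own amendments and
wholesale-replace a parent's same-named one. Cycles are a hard error naming
the chain — a cycle always indicates author error, and silent truncation
would make the winning value depend on traversal details.

**Amendments** replace top-level keys in activation order, later
activations winning ("priority order" read as list order, the least
surprising interpretation). An amendment may not itself add `import` or
nested `amend` sections; the interaction semantics would be genuinely
ambiguous (would the import re-run? could activation recurse?), so the
package rejects it rather than guessing.

**Subsample merging** groups rows by the identifier and turns each
non-identifier column into a list attribute in row order; empty cells
contribute empty strings so all merged attributes of a sample have equal
length (a placeholder is more faithful than a dropped element when columns
are positionally related, e.g. `read1`/`read2` pairs). Identical values are
*not* collapsed to a scalar — two subsample rows mean two elements, even if
equal. A subsample column shadowing a scalar table column replaces it, with
a message.

**append vs. existing values**: `append` is read as *addition* — a table
cell, even an empty string, is ground truth and is never overwritten by a
config constant. Authors who want unconditional overwriting can use
`imply` with a matching condition, or `remove` followed by `append`.

## Templates and degenerate inputs

Derive templates substitute `{attr}` from the sample and `$VAR`/`${VAR}`
from the environment in a **single left-to-right pass**; substituted text
is never re-expanded, so values containing brace characters cannot trigger
injection-style surprises, and resolution always terminates. Matching of a
derived attribute's value against source keys is exact whole-string
equality — no globbing, no substrings — because a path fragment that merely
contains a source key must not be rewritten.

Deliberate edge-case behavior, chosen once and tested:

- `{attr}` referencing an attribute the sample lacks: error naming the
  attribute (the project is unusable as authored);
- `$VAR` unset: warning, token left verbatim — a PEP written for another
  machine should still load for inspection;
- referencing a multi-valued attribute inside a template: error (there is
  no unambiguous scalar to substitute);
- duplicate sample identifiers: error at read time (the identifier is the
  join key for subsamples and reports; merging rows silently would corrupt
  both);
- removing an absent attribute, or duplicating from an attribute a sample
  lacks: warning + no-op (harmless in a shared config applied to many
  tables);
- empty sample table (header only): a valid project with zero samples.

## Validation

Validation is two-stage: stage 1 checks the resolved configuration, stage
2 checks each sample *after* all modifiers have run — attributes added by
`append` or rewritten by `derive` are exactly what pipelines will consume,
so they are what gets validated. Schema documents are YAML or JSON using a
small JSON-Schema subset (`properties` with `type`, `enum`, `pattern`;
`required`) plus two extension keywords: `imports`, a list of schemas that
must *all* hold (kept separate, not deep-merged, so reports can attribute
failures to the schema that raised them), and `required_files`, attribute
names whose values — every element, for list values — must point to
existing regular files (directories do not count; a directory where a
FASTQ should be is a misconfiguration, not data). `required_files` lives at
the sample-rules level alongside `required`. Both stages always run, so a
config failure does not mask sample failures; failures are returned as
data in a report, never thrown. Remote schema URLs are rejected with a
clear message — validation must not depend on network state.

The typed keywords check string values by parsing (`"42"` satisfies
`type: integer`), since CSV cells are strings by construction; `pattern`
is unanchored, as in JSON Schema.

## The fixture generator

`generate_pep()` writes parameterized synthetic projects — sample counts,
modifier subsets, import chain depth, amendment count, subsample
multiplicity — with seeded pseudo-random slug values, byte-identical under
a fixed seed. It emulates the *structure* of real projects (file layout,
modifier shapes, touched data files so `required_files` schemas can pass).
It makes no attempt at biological realism: attribute values are random
slugs, not accessions or organisms with consistent genomes. Passing tests
therefore demonstrate the metadata engine's correctness on well-formed and
deliberately malformed structures, not robustness to the full zoo of
real-world sample sheets (Excel export artifacts, mixed encodings,
semantically inconsistent annotations). `generate_example_peps()` writes
six static worked examples — one per modifier feature plus amendment
activation — whose processed output is hand-derivable; these serve as
golden tests.

## Testing strategy and problem sizes

Beyond unit tests, the suite cross-checks the engine against brute-force
oracles written independently of the implementation: import resolution
against a flatten-then-fold oracle on 100 randomly generated three-file
import graphs, and the modifier engine against a plain per-sample
interpreter (with a character-scan template substituter) on 200 random
tables of at most 5 samples × 5 attributes. These sizes already cover
every structural case the engine distinguishes — deeper graphs only repeat
the same fold, wider tables the same per-sample map — and keep the full
suite in a few seconds. Round-trip (convert → reload), pass-through
byte-equality, schema-import monotonicity, and fixture determinism are
asserted as properties. `scripts/acceptance.R` recomputes all of these
from scratch and writes the agreement rates as JSON.

## Known limitations

- CSV only (RFC 4180, comma, UTF-8): no TSV/Excel dialect detection.
- No remote fetching of configs, tables, or schemas.
- The JSON-Schema subset omits keywords the engine does not need
  (`allOf`, `$ref`, numeric ranges); schemas using them will not error but
  those constraints are ignored.
- Amendments cannot add imports; deep-merge of nested config sections is
  intentionally absent (whole-key replacement is predictable and matches
  the stated table-selection rule).
- `pep_version` is preserved as an ordinary key, never required or
  interpreted.
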