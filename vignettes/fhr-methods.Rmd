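---
title: "FHR metadata for reference genomes: model, canonical form, and checksum design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FHR metadata for reference genomes: model, canonical form, and checksum design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhr)
```

## The problem

Reference genomes circulate in a decentralised ecosystem: assemblies are
downloaded, re-annotated, contig-filtered and re-hosted, and with each hop
the externally stored metadata drifts further from the file it describes.
Two traditional anchors both fail: filenames are freely changed, and whole
file checksums are broken by edits that do not alter the semantics of the
file at all — most famously the carriage returns introduced when a file
made on Linux is opened in a Windows editor.

FHR (FAIR Header Reference genome) keeps a minimal provenance record *in*
the FASTA file, using the legacy semicolon comment block permitted at the
top of the file since the format's 1985 origin, with FHR lines marked by
the prefix `;~`. This package implements the record model, the embedded
and sidecar serializations, validation, and the self-referential checksum.

## The record model

A complete record carries exactly nine required fields:

| field | meaning |
|---|---|
| `schema` | URI of the governing schema document |
| `schemaVersion` | integer version of the record model |
| `genome` | name of the genome (free text, ID or URI) |
| `taxon` | organism, as a `name` plus a registry `uri` |
| `version` | assembly version (free text) |
| `assemblyAuthor` | who built the assembly (list of name/uri pairs) |
| `metadataAuthor` | who wrote this record (list of name/uri pairs) |
| `dateCreated` | ISO-8601 calendar date of the assembly |
| `checksum` | self-referential digest, `<algorithm>:<hex>` |

and up to eleven optional ones (`accessionID`, `assemblySoftware`,
`documentation`, `funding`, `genomeSynonym`, `identifier`, `instrument`,
`relatedLink`, `reuseConditions`, `scholarlyArticle`, `voucherSpecimen`).
The split reflects a recovery thought experiment: were every digital copy
of a genome lost, the required fields identify what the file was and who
made it, while the optional fields record the materials, instruments and
software that produced it. A machine-readable JSON Schema mirroring this
model ships with the package (`fhrSchemaPath()`); the record's `schema`
field is validated as a URI string and never fetched, so validation works
offline.

Decisions taken where the record model leaves latitude, each fixed once:

* **Multiplicity.** Author lists and the other multi-valued fields accept a
  bare scalar on input but are always emitted as lists. Accepting both
  shapes costs nothing; emitting one shape keeps round trips stable.
* **Dates.** `dateCreated` must be `YYYY-MM-DD` with ASCII hyphens and must
  be a real calendar date. Typesetting occasionally substitutes an en dash
  in published examples; on input it is transliterated to a hyphen with a
  warning rather than rejected, since it is an artifact of printing, not of
  data entry.
* **Registry hosts.** Only `taxon/uri` is pinned to a registry
  (`identifiers.org` or `bioregistry.io`), because taxonomic identity is
  the one field whose resolvability the standard insists on. Author and
  accession URIs need only be absolute `http(s)` URIs; an author `uri` is
  optional when a `name` is present, since the model treats the name as
  primary.
* **`schemaVersion`** is an integer ≥ 1; the string `"1"` is accepted on
  input and emitted as an integer. **`version`** is free text: assembly
  versioning practice is too varied for a grammar.
* **Checksum algorithms.** `md5` is the reference algorithm; `sha1` and
  `sha256` are accepted for forward compatibility, with digest length
  enforced per algorithm and lowercase hex required.
* **Unknown keys warn, never fail.** The standard is explicitly
  extensible; an unrecognized field is surfaced (`UNKNOWN_FIELD`, severity
  `warning`) and preserved on output, but does not invalidate a record.

Validation (`validateFhr()`) reports every violation as an issue with a
slash-delimited path, a severity and a stable machine code, and never
throws: tooling decides what to do with the report. A record is valid iff
no issue has severity `error`. The `pre_injection` mode tolerates a missing
checksum, because the checksum can only be computed once the rest of the
header is final.

## Canonical form

Round-trip closure across four serializations and digest determinism both
require a single normal form, produced by `canonicalizeFhr()`: required
fields first in the standard's order with `checksum` last among them, then
optional fields alphabetically, then unknown fields alphabetically;
whitespace trimmed; scalars promoted to lists where the field is
multi-valued; `schemaVersion` coerced to integer; the algorithm token of
the checksum lowercased. Canonicalization is idempotent and insensitive to
input key order (both property-tested).

Emission is deliberately hand-rolled rather than delegated to a generic
YAML dumper, because determinism *is* the requirement: block style only,
two-space indent, and a minimal quoting rule — a scalar is quoted exactly
when the bare token would not read back as the same string (so `2.3` is
emitted as `'2.3'` to keep it a string, while URIs and names stay bare).
Anchors and aliases are rejected on input: every `;~` line must be
self-contained for the line-prefixed embedding to be robust. Input parsing
uses the standard YAML and JSON parsers; only emission is bespoke.

For the Microdata HTML serialization the standard names no vocabulary, so
the only self-consistent choice is used: the record's `schema` URI is the
item type, field names are the property names, and name/uri pairs
(`taxon`, authors, `accessionID`) become nested items. HTML output is a
minimal static document; reading accepts any HTML containing one such
item.

Sidecars follow the naming template `<genome file name>.fhr.<ext>` next to
their FASTA; writing a sidecar with no adjacent FASTA warns, since the
template exists precisely to keep data and metadata coupled. Converting a
sidecar *to* FASTA is refused with guidance — metadata cannot conjure
sequence data; `fasta-combine` exists for that.

## The FASTA codec

`parseFasta()` is byte-faithful: the document is stored as its lines plus
the detected newline convention (LF or CRLF) and trailing-newline flag, and
serializing a freshly parsed document reproduces the input exactly. This
is what makes `fasta-strip` trustworthy: users running FHR-unaware tools
can strip the header and get their original file back byte-for-byte
(`stripFhr(embedFhr(r, d))` ≡ `d`, property-tested). Other conventions:
UTF-8 only; a `;~` line below the first sequence record — the result of
careless concatenation — is ignored by extraction and removed by stripping,
each with a warning; `;~` may be followed by one space on input, none is
emitted; no blank line is emitted between header and first record, though
one is tolerated.

## Checksum design

The checksum is self-referential: it is computed over the document *minus
the checksum itself* and then written into the header, so one value
identifies sequences and provenance together. Two design points deserve
explanation:

* **Whole-line exclusion.** "Minus the checksum" is implemented as
  exclusion of the entire checksum line (key and value), which avoids any
  ambiguity about separators or whitespace around an excluded value.
* **Canonical payload, not raw bytes.** The digest is computed over the
  canonical payload: header serialized in canonical order, all newlines
  normalized to LF, trailing LF guaranteed. This deliberately trades
  bit-exact file identification for robustness against the semantically
  neutral edits that make naive checksums brittle — CRLF/LF churn and
  header key reordering do not change the digest, while any sequence or
  metadata change does. It also makes the embedded and sidecar forms of
  one genome carry the same checksum, since the payload is the same
  canonical header plus the same sequence lines in either case. Users who
  want raw-byte identification can pass `strict = TRUE`
  (`--strict-bytes` on the command line), which digests the serialized
  bytes minus the checksum line, newline style preserved.

`injectChecksum()` is idempotent (the payload never includes the checksum,
so re-injection recomputes the same digest), and `verifyChecksum()`
reports rather than throws, returning a `CHECKSUM_MISMATCH` issue on
header/data divergence. The implementation digests with the `digest`
package; the test suite cross-checks it against `tools::md5sum()` — an
independent md5 implementation — on payload files written to disk. The
digest printed in the standard's own example table is treated as a format
example only, not as an oracle, because the bytes it was computed from are
not published.

## The command-line interface

Five subcommands mirror the standard's toolkit: `convert`, `validate`
(schema only, by design — it must be usable before a checksum exists),
`fasta-combine` (embed + inject), `fasta-validate` (schema *and*
checksum), `fasta-strip`. `combine-fasta` is accepted as an alias for
`fasta-combine`, as both spellings circulate. Exit codes are part of the
contract: 0 success, 1 validation or checksum failure, 2 usage/format/I-O
error. All file output is write-to-temp-then-rename, so a failing command
never leaves a partial output file.

## The fixture generator

All tests run from generated inputs; nothing is downloaded. The generator
(`generateFhrRecord()`, `generateFasta()`) draws from templated pools —
person names, ORCID-shaped URIs, `identifiers.org` taxonomy URIs,
instrument and assembler names — and emits uniform random ACGT sequences,
60-column wrapped, a few hundred bases per contig. Defaults were chosen
once as desk-scale analogues of real headers: 1–2 authors per role, 1–2
values per multi-valued field, 2 contigs per file. `applyDefect()`
produces single-fault records for exercising the validator, one issue per
defect at a predictable path.

What the generator emulates is the *structure* of real FHR usage, not its
content: sequences have no biological composition, records no real
identifiers, and files are kilobytes rather than gigabytes. Passing tests
therefore demonstrate the format contracts — byte-faithful parsing,
round-trip closure, checksum behaviour, exit codes — on well-formed and
single-fault inputs; they say nothing about assembly quality, taxonomic
correctness, or performance on chromosome-scale files (the codec is
line-based and O(file size), but large-genome throughput is untested).
Determinism is promised per implementation: the same seed yields the same
bytes on one R installation, not across different RNG implementations.

## Problem sizes and degenerate inputs

The acceptance script and test suite use 200 seeded records/documents for
the round-trip and checksum contracts, 25–50 for mutation and strip
checks, and 20 for oracle agreement — sizes at which every property is
exercised across both completeness levels, both newline styles and all
format pairs while the whole suite stays in the tens of seconds.
Degenerate inputs are handled explicitly: empty files and non-UTF-8 bytes
are classed errors; an empty record validates (as invalid) rather than
erroring; stripping a header-less file is the identity; a FASTA with no
records is legal as a container but carries no sequence.

## Known limitations

* Mixed newline conventions within one file are preserved byte-wise but
  detected as LF; only uniform LF or CRLF files get the full
  newline-invariance guarantee.
* The YAML dialect is a subset (block style, no anchors/aliases, no
  multi-line block scalars in emission); free-text fields containing
  newlines are emitted in escaped double-quoted form.
* md5 is the reference algorithm for identification, not integrity against
  adversaries; nothing here is a cryptographic guarantee.
* URI and CURIE validation is syntactic; no identifier is resolved over
  the network, and no check is made that a taxon ID actually matches the
  genome.
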