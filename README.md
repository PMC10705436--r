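# fhr: FAIR Header Reference genome metadata for FASTA files

Reference-genome FASTA files carry no intrinsic provenance. Once a file is
renamed, re-hosted or lightly edited, the link to the metadata describing it
— which organism, which assembly version, who built it, under what terms it
may be reused — is easily lost, and a plain file checksum is too brittle to
restore it: opening a Linux-made file in a Windows editor introduces
carriage returns that change every byte-level digest while changing nothing
about the genome.

The FHR (FAIR Header Reference genome) standard addresses this by keeping
data and metadata in one place. A small metadata record is embedded at the
top of the FASTA file itself, using the semicolon comment mechanism that has
been part of the format since 1985, with each metadata line prefixed `;~`:

```
;~genome: cele7
;~taxon:
;~  name: Caenorhabditis elegans
;~  uri: https://identifiers.org/taxonomy:6239
...
>chrI
GCCTAAGCCTAAGCCTAA...
```

The same record can instead travel in a sidecar file
(`<genome file name>.fhr.<yaml|json|html>`) next to the FASTA.

This package is for the two groups the standard serves: repository curators
who attach provenance to the genomes they distribute, and pipeline authors
who need to state *exactly* which assembly an analysis used.

## The record and its checksum

A complete record has nine required fields — `schema`, `schemaVersion`,
`genome`, `taxon`, `version`, `assemblyAuthor`, `metadataAuthor`,
`dateCreated`, `checksum` — and up to eleven optional ones (instruments,
assembly software, accession and voucher identifiers, funding, licensing,
links and publications). The `checksum` field is self-referential:

    checksum = algo( canonical(header \ {checksum}) || sequences )

i.e. the digest (md5 by default; sha1/sha256 supported) of the document with
its header in canonical form and the checksum line itself excluded. One
value therefore pins both the sequences *and* their provenance. Because the
digest is computed over a canonical payload — fixed field order, LF
newlines, trailing newline guaranteed — the newline churn and key
reordering that break naive file checksums do **not** invalidate an FHR
checksum, while any change to sequence content or metadata values does.
A raw-bytes mode (`strict = TRUE`) is available when bit-exact file
identification is wanted instead.

## Worked example

```r
library(fhr)

rec <- FhrRecord(
  schema = "https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json",
  schemaVersion = 1, genome = "Example species",
  taxon = list(name = "Example species",
               uri = "https://identifiers.org/taxonomy:0000"),
  version = "2.3",
  assemblyAuthor = list(list(name = "Jane Doe",
                             uri = "https://orcid.org/0000-0002-9511-5139")),
  metadataAuthor = list(list(name = "John Doe",
                             uri = "https://orcid.org/0000-0002-1983-4588")),
  dateCreated = "2022-03-21")

validateFhr(rec, mode = "pre_injection")
#> FhrValidationReport: valid (0 errors, 0 warnings)

doc <- parseFasta(">chr1\nACGTACGTACGT\n")
combined <- injectChecksum(embedFhr(rec, doc))
cat(fastaText(combined))
#> ;~schema: https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json
#> ;~schemaVersion: 1
#> ;~genome: Example species
#> ;~taxon:
#> ;~  name: Example species
#> ;~  uri: https://identifiers.org/taxonomy:0000
#> ;~version: '2.3'
#> ;~assemblyAuthor:
#> ;~  - name: Jane Doe
#> ;~    uri: https://orcid.org/0000-0002-9511-5139
#> ;~metadataAuthor:
#> ;~  - name: John Doe
#> ;~    uri: https://orcid.org/0000-0002-1983-4588
#> ;~dateCreated: 2022-03-21
#> ;~checksum: md5:2afabcbf865017642d3d98856679aeac
#> >chr1
#> ACGTACGTACGT

verifyChecksum(combined)
#> FhrValidationReport: valid (0 errors, 0 warnings)
```

The validation report lists one issue per violation with a field path
(`/taxon/uri`), severity and stable code; a record is valid iff it has no
error-severity issue. The printed checksum is the md5 of the canonical
payload: flip any sequence base and `verifyChecksum()` reports a
`CHECKSUM_MISMATCH` error at `/checksum`; convert the file to CRLF line
endings and verification still passes.

Sidecars and conversion use the same canonical form:

```r
writeFhr(rec, "genome.fhr.yaml")      # also: .fhr.json, .fhr.html
convertFhr("genome.fhr.yaml", "genome.fhr.json")
readFhr("genome.fhr.json")            # canonically equal to rec
```

## Command line

The installed package ships an executable
(`system.file("exec", "fhr", package = "fhr")`) with five subcommands —
`convert`, `validate`, `fasta-combine`, `fasta-validate`, `fasta-strip` —
plus `fixtures` for generating a deterministic test corpus. Exit codes are
stable: 0 success, 1 validation/checksum failure, 2 usage/format/I-O error.
`fasta-strip` exists because many FASTA consumers ignore the 1985 comment
rule; it removes the `;~` lines and restores the pre-embedding file
byte-for-byte.

## Further reading

The methods vignette (`vignettes/fhr-methods.Rmd`) documents the record
model, the canonical form, the checksum design and its trade-offs, and the
scope of the fixture generator.
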