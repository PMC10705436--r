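Package: fhr
Title: FAIR Header Reference Genome Metadata for FASTA Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Create, validate, serialize and verify FAIR Header Reference
    genome (FHR) metadata records for reference-genome FASTA files.  FHR
    embeds a small provenance record -- organism, assembly and metadata
    authorship, creation date and a self-referential checksum -- directly in
    the FASTA file using the legacy semicolon comment mechanism with a ";~"
    line prefix, or carries the same record in YAML, JSON or Microdata-HTML
    sidecar files.  The package provides a byte-faithful FASTA codec,
    schema validation with field-level diagnostics, deterministic canonical
    serialization, checksum injection and verification that is robust to
    newline-style churn, format interconversion, deterministic fixture
    generation for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    digest,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'fields.R'
    'validate.R'
    'canonical.R'
    'fasta.R'
    'checksum.R'
    'serializers.R'
    'cli.R'
    'fixtures.R'
    'fhr-package.R'
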