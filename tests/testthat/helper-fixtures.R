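# Shared fixtures built in code.

# The worked example of a complete record: one value per field, as published
# in the standard's field table.
workedExampleRecord <- function() {
  FhrRecord(
    schema = "https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json",
    schemaVersion = 1L,
    genome = "Example species",
    taxon = list(name = "Example species",
                 uri = "https://identifiers.org/taxonomy:0000"),
    version = "2.3",
    metadataAuthor = list(list(name = "John Doe",
                               uri = "https://orcid.org/0000-0002-1983-4588")),
    assemblyAuthor = list(list(name = "Jane Doe",
                               uri = "https://orcid.org/0000-0002-9511-5139")),
    dateCreated = "2022-03-21",
    checksum = "md5:a3d5d9146c3992b7ed6724409ba28aa9"
  )
}

# the same record as YAML sidecar text, with the quirks a human would type
# (unquoted scalars, required-first order)
workedExampleYaml <- function() {
  paste(
    "schema: https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json",
    "schemaVersion: 1",
    "genome: Example species",
    "taxon:",
    "  name: Example species",
    "  uri: https://identifiers.org/taxonomy:0000",
    "version: 2.3",
    "metadataAuthor:",
    "  - name: John Doe",
    "    uri: https://orcid.org/0000-0002-1983-4588",
    "assemblyAuthor:",
    "  - name: Jane Doe",
    "    uri: https://orcid.org/0000-0002-9511-5139",
    "dateCreated: 2022-03-21",
    "checksum: md5:a3d5d9146c3992b7ed6724409ba28aa9",
    sep = "\n"
  )
}

# drop one field from a record
without <- function(record, field) {
  f <- fhrFields(record)
  FhrRecord(f[setdiff(names(f), field)])
}

# replace/add fields (whole-value replacement, no recursive merging)
withFields <- function(record, ...) {
  f <- fhrFields(record)
  args <- list(...)
  for (k in names(args)) f[[k]] <- args[[k]]
  FhrRecord(f)
}

# write a sidecar without canonicalization, for deliberately defective input
writeRawSidecar <- function(record, path) {
  writeLines(fhr:::emitFhrYaml(fhrFields(record)), path)
  path
}

# read a file as raw bytes
fileBytes <- function(path) readBin(path, "raw", n = file.size(path))

# run the CLI quietly, returning the exit status
cliRun <- function(...) {
  status <- NULL
  capture.output(status <- fhrCli(c(...)))
  status
}
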