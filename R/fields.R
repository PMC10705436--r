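# Field registry.  The canonical order of the required fields is the order
# in which the standard lists them, with checksum last; optional fields are
# ordered alphabetically.  A machine-readable JSON Schema mirroring this
# registry ships in inst/extdata/fhr-schema.json and is validated against it
# in the test suite.

.requiredFields <- c(
  "schema", "schemaVersion", "genome", "taxon", "version",
  "assemblyAuthor", "metadataAuthor", "dateCreated", "checksum"
)

.optionalFields <- c(
  "accessionID", "assemblySoftware", "documentation", "funding",
  "genomeSynonym", "identifier", "instrument", "relatedLink",
  "reuseConditions", "scholarlyArticle", "voucherSpecimen"
)

# fields that take a list of scalar strings
.listFields <- c("funding", "genomeSynonym", "identifier", "instrument",
                 "relatedLink", "scholarlyArticle")

# fields that are name/uri pairs or lists thereof
.agentListFields <- c("assemblyAuthor", "metadataAuthor")
.pairFields <- c("taxon", "accessionID")

.checksumAlgorithms <- c(md5 = 32L, sha1 = 40L, sha256 = 64L)

#' Names of the required FHR fields
#'
#' The standard mandates nine fields for a complete record: `schema`,
#' `schemaVersion`, `genome`, `taxon`, `version`, `assemblyAuthor`,
#' `metadataAuthor`, `dateCreated` and `checksum`.  Together they identify
#' the metadata format, the organism and assembly, the people behind both the
#' assembly and its metadata, and — through the self-referential checksum —
#' the exact bytes of the genome plus its header.
#'
#' @return Character vector of the nine required field names, in canonical
#'   order (`checksum` last).
#' @examples
#' requiredFhrFields()
#' @export
requiredFhrFields <- function() .requiredFields

#' Names of the optional FHR fields
#'
#' Eleven optional fields carry additional provenance: how the genome was
#' sequenced and assembled (`instrument`, `assemblySoftware`,
#' `accessionID`, `voucherSpecimen`), how to find out more (`identifier`,
#' `relatedLink`, `scholarlyArticle`, `documentation`, `genomeSynonym`),
#' and funding/licensing (`funding`, `reuseConditions`).
#'
#' @return Character vector of the eleven optional field names,
#'   alphabetically ordered.
#' @examples
#' optionalFhrFields()
#' @export
optionalFhrFields <- function() .optionalFields

#' Construct an FHR record
#'
#' Builds an [FhrRecord-class] from field values.  No validation is
#' performed at construction beyond name uniqueness; use [validateFhr()] to
#' check conformance and [canonicalizeFhr()] to normalize.
#'
#' @param ... Named field values, and/or a single named list.
#' @return An [FhrRecord-class].
#' @examples
#' rec <- FhrRecord(
#'   schema = "https://example.org/fhr.json", schemaVersion = 1,
#'   genome = "Example species",
#'   taxon = list(name = "Example species",
#'                uri = "https://identifiers.org/taxonomy:0000"),
#'   version = "2.3",
#'   assemblyAuthor = list(list(name = "Jane Doe")),
#'   metadataAuthor = list(list(name = "John Doe")),
#'   dateCreated = "2022-03-21"
#' )
#' isValid(validateFhr(rec, mode = "pre_injection"))
#' @export
FhrRecord <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args)))
    args <- args[[1L]]
  if (length(args) > 0L && (is.null(names(args)) || any(!nzchar(names(args)))))
    fhrError("fhrInvalidRecord", "all record fields must be named")
  new("FhrRecord", fields = args)
}

#' Path to the bundled machine-readable schema
#'
#' The package ships a local JSON Schema document describing the FHR record
#' model (required and optional fields, types, and formats).  The `schema`
#' field of a record is validated as a URI string; the document is never
#' fetched from the network.
#'
#' @return Path to `fhr-schema.json` inside the installed package.
#' @export
fhrSchemaPath <- function() {
  system.file("extdata", "fhr-schema.json", package = "fhr", mustWork = TRUE)
}

# --- small shared predicates -------------------------------------------------

isScalar <- function(x) {
  (is.character(x) || is.numeric(x) || is.logical(x)) && length(x) == 1L &&
    !is.na(x)
}

# absolute http(s) URI
isAbsoluteUri <- function(x) {
  isScalar(x) && grepl("^https?://[^[:space:]/]+", as.character(x))
}

uriHost <- function(x) {
  host <- sub("^https?://([^/?#]+).*$", "\\1", as.character(x))
  sub(":.*$", "", sub("^.*@", "", tolower(host)))
}

.registryHosts <- c("identifiers.org", "bioregistry.io")

# name/uri mapping shape (taxon, authors, accessionID)
asPair <- function(x) {
  if (is.list(x) && !is.null(names(x))) x else NULL
}
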