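#' Is a validation report (or verification result) free of errors?
#'
#' @param x An [FhrValidationReport-class] object.
#' @return `TRUE` iff no issue in the report has severity `error`.
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname isValid
#' @export
setMethod("isValid", "FhrValidationReport", function(x) {
  !any(x@issues$severity == "error")
})

#' Issue table of a validation report
#'
#' @param x An [FhrValidationReport-class] object.
#' @return A `data.frame` with columns `path`, `severity`, `code`, `message`,
#'   in the order the issues were found.
#' @export
setGeneric("fhrIssues", function(x) standardGeneric("fhrIssues"))

#' @rdname fhrIssues
#' @export
setMethod("fhrIssues", "FhrValidationReport", function(x) x@issues)

#' Fields of an FHR record
#'
#' `fhrFields(x)` returns the ordered named list of all fields;
#' `fhrField(x, name)` returns one field (or `NULL` when absent).
#'
#' @param x An [FhrRecord-class] object.
#' @return A named list, or a single field value.
#' @export
setGeneric("fhrFields", function(x) standardGeneric("fhrFields"))

#' @rdname fhrFields
#' @export
setMethod("fhrFields", "FhrRecord", function(x) x@fields)

#' @rdname fhrFields
#' @param name Field name, e.g. `"genome"` or `"taxon"`.
#' @export
setGeneric("fhrField", function(x, name) standardGeneric("fhrField"))

#' @rdname fhrFields
#' @export
setMethod("fhrField", "FhrRecord", function(x, name) {
  x@fields[[name]]
})
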