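#' @import methods
NULL

#' FhrRecord: a reference-genome metadata record
#'
#' An `FhrRecord` holds one FHR metadata record as an ordered named list of
#' fields.  A record may be incomplete (e.g. freshly parsed, or awaiting
#' checksum injection) and may carry unknown keys; [validateFhr()] reports on
#' its conformance and [canonicalizeFhr()] brings it to the deterministic
#' canonical form used for serialization and checksumming.
#'
#' Structured fields are nested named lists: `taxon` and `accessionID` are
#' `list(name=, uri=)` pairs; `assemblyAuthor` and `metadataAuthor` are lists
#' of such pairs.  Multi-valued fields (`funding`, `identifier`, ...) are
#' unnamed lists of character scalars in canonical form.
#'
#' @slot fields Ordered named list of field values.
#' @seealso [FhrRecord()], [validateFhr()], [canonicalizeFhr()]
#' @exportClass FhrRecord
setClass("FhrRecord", representation(fields = "list"))

setValidity("FhrRecord", function(object) {
  nm <- names(object@fields)
  if (length(object@fields) > 0L && (is.null(nm) || any(!nzchar(nm))))
    return("all fields must be named")
  if (anyDuplicated(nm))
    return("field names must be unique")
  TRUE
})

#' FastaDocument: a byte-faithful parsed FASTA file
#'
#' Stores a FASTA file as its constituent lines plus the detected newline
#' convention, so that [fastaText()] reproduces the input byte-for-byte.
#' Lines are classified on access: `;~`-prefixed metadata lines, plain `;`
#' comments (a legacy feature of the 1985 Pearson format), `>` record
#' headers, and sequence/blank lines.
#'
#' @slot lines Character vector of lines with end-of-line bytes removed.
#' @slot newline `"\n"` or `"\r\n"` as detected on parse.
#' @slot eofNewline Logical; whether the file ended with a newline.
#' @seealso [parseFasta()], [extractFhr()], [embedFhr()], [stripFhr()]
#' @exportClass FastaDocument
setClass("FastaDocument", representation(
  lines = "character", newline = "character", eofNewline = "logical"
))

setValidity("FastaDocument", function(object) {
  if (!object@newline %in% c("\n", "\r\n"))
    return("newline must be \"\\n\" or \"\\r\\n\"")
  if (length(object@eofNewline) != 1L)
    return("eofNewline must be a single logical")
  TRUE
})

#' FhrValidationReport: diagnostics from record validation
#'
#' An ordered collection of issues, each with a slash-delimited field path
#' (e.g. `/taxon/uri`), a severity (`error` or `warning`), a stable machine
#' code and a human-readable message.  A record is valid iff no issue has
#' severity `error`; warnings (unknown keys, cosmetic date fixes) never make
#' a record invalid.
#'
#' @slot issues `data.frame` with columns `path`, `severity`, `code`,
#'   `message`.
#' @seealso [validateFhr()], [isValid()], [fhrIssues()]
#' @exportClass FhrValidationReport
setClass("FhrValidationReport", representation(issues = "data.frame"))

setValidity("FhrValidationReport", function(object) {
  need <- c("path", "severity", "code", "message")
  if (!all(need %in% names(object@issues)))
    return(paste("issues must have columns", paste(need, collapse = ", ")))
  if (!all(object@issues$severity %in% c("error", "warning")))
    return("severity must be \"error\" or \"warning\"")
  TRUE
})

newReport <- function(path = character(), severity = character(),
                      code = character(), message = character()) {
  new("FhrValidationReport", issues = data.frame(
    path = path, severity = severity, code = code, message = message,
    stringsAsFactors = FALSE
  ))
}

setMethod("show", "FhrRecord", function(object) {
  f <- object@fields
  cat(sprintf("FhrRecord with %d field%s\n", length(f),
              if (length(f) == 1L) "" else "s"))
  if (length(f) > 0L) {
    preview <- vapply(f, function(v) {
      if (is.list(v)) sprintf("<%d element%s>", length(v),
                              if (length(v) == 1L) "" else "s")
      else paste(format(v), collapse = ", ")
    }, character(1))
    too <- nchar(preview) > 50L
    preview[too] <- paste0(substr(preview[too], 1L, 47L), "...")
    cat(paste0("  ", format(names(f)), ": ", preview, "\n"), sep = "")
  }
  invisible(object)
})

setMethod("show", "FastaDocument", function(object) {
  cat(sprintf(
    "FastaDocument: %d record%s, %d FHR header line%s, %d plain comment%s (%s)\n",
    length(grep("^>", object@lines)),
    if (length(grep("^>", object@lines)) == 1L) "" else "s",
    length(grep("^;~", object@lines)),
    if (length(grep("^;~", object@lines)) == 1L) "" else "s",
    length(grep("^;($|[^~])", object@lines)),
    if (length(grep("^;($|[^~])", object@lines)) == 1L) "" else "s",
    if (object@newline == "\n") "LF" else "CRLF"
  ))
  invisible(object)
})

setMethod("show", "FhrValidationReport", function(object) {
  iss <- object@issues
  ok <- !any(iss$severity == "error")
  cat(sprintf("FhrValidationReport: %s (%d error%s, %d warning%s)\n",
              if (ok) "valid" else "invalid",
              sum(iss$severity == "error"),
              if (sum(iss$severity == "error") == 1L) "" else "s",
              sum(iss$severity == "warning"),
              if (sum(iss$severity == "warning") == 1L) "" else "s"))
  if (nrow(iss) > 0L)
    cat(sprintf("  [%s] %s %s: %s\n", iss$severity, iss$code, iss$path,
                iss$message), sep = "")
  invisible(object)
})
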