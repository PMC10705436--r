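# Self-referential checksum.  The digest covers the genome sequences AND the
# metadata header, minus the checksum field itself, so that a single value
# pins both data and provenance.  The digest is computed over a canonical
# payload (canonical header order, LF newlines, trailing LF) rather than raw
# file bytes, so semantically neutral edits — CRLF/LF churn, header key
# reordering — do not invalidate it.  A strict raw-bytes variant is
# available for bit-exact file identification.

#' Canonical byte payload for checksum computation
#'
#' Serializes the document with its header in canonical order, excludes the
#' entire checksum line (key and value), normalizes newlines to LF and
#' guarantees a trailing LF.  Two documents that differ only in header key
#' order, newline convention, trailing-newline presence, or the
#' presence/absence of the checksum field itself therefore share a payload.
#'
#' @param doc A [FastaDocument-class].
#' @param record Optional [FhrRecord-class] to use as the header; defaults
#'   to the header embedded in `doc` (if any).  Passing a sidecar record
#'   with a plain FASTA gives the same payload as the embedded form, so both
#'   forms of one genome carry the same checksum.
#' @return A character scalar (UTF-8); digest it with [computeChecksum()].
#' @export
canonicalPayload <- function(doc, record = NULL) {
  idx <- fhrLineIdx(doc)
  if (is.null(record) && length(idx) > 0L)
    record <- suppressWarnings(extractFhr(doc))
  rest <- if (length(idx) > 0L) doc@lines[-idx] else doc@lines
  hdr <- character()
  if (!is.null(record)) {
    can <- canonicalizeFhr(record)
    can@fields[["checksum"]] <- NULL
    hdr <- paste0(";~", emitFhrYaml(can))
  }
  paste0(paste(c(hdr, rest), collapse = "\n"), "\n")
}

# raw serialized bytes minus the checksum line, newline style preserved
strictPayload <- function(doc) {
  idx <- grep("^;~ ?checksum:", doc@lines)
  d <- if (length(idx) > 0L)
    new("FastaDocument", lines = doc@lines[-idx], newline = doc@newline,
        eofNewline = doc@eofNewline)
  else doc
  fastaText(d)
}

#' Compute the FHR checksum of a FASTA document
#'
#' Digests the canonical payload (see [canonicalPayload()]) — or, with
#' `strict = TRUE`, the raw serialized bytes minus the checksum line — and
#' returns the wire form `<algorithm>:<lowercase hex>`.
#'
#' @param doc A [FastaDocument-class].
#' @param algorithm One of `"md5"` (the reference algorithm), `"sha1"`,
#'   `"sha256"`.
#' @param record Optional sidecar [FhrRecord-class]; see
#'   [canonicalPayload()].
#' @param strict Digest raw bytes instead of the canonical payload.
#' @return Character scalar, e.g. `"md5:a3d5..."`.
#' @examples
#' doc <- embedFhr(generateFhrRecord(1, "minimal"), parseFasta(">s\nACGT\n"))
#' computeChecksum(doc)
#' @export
computeChecksum <- function(doc, algorithm = "md5", record = NULL,
                            strict = FALSE) {
  algorithm <- tolower(algorithm)
  if (!algorithm %in% names(.checksumAlgorithms))
    fhrError("fhrUnsupportedAlgorithm",
             sprintf("unsupported checksum algorithm '%s' (use %s)",
                     algorithm,
                     paste(names(.checksumAlgorithms), collapse = ", ")))
  payload <- if (strict) strictPayload(doc)
             else canonicalPayload(doc, record = record)
  dg <- digest::digest(charToRaw(enc2utf8(payload)), algo = algorithm,
                       serialize = FALSE)
  formatChecksum(algorithm, dg)
}

#' Inject the self-referential checksum into an embedded header
#'
#' Computes the checksum of the document (header minus any existing checksum
#' plus sequences) and writes it into the header as the last required field
#' in canonical order, replacing any prior checksum.  Injection is
#' idempotent: injecting twice yields byte-identical output.
#'
#' @param doc A [FastaDocument-class] with an embedded header that is valid
#'   apart from a possibly missing checksum.
#' @param algorithm Digest algorithm (default `"md5"`).
#' @param strict Use the raw-bytes digest (see [computeChecksum()]); the
#'   digest then covers the serialized output bytes minus the checksum line.
#' @return A new [FastaDocument-class] whose header carries the checksum.
#' @examples
#' doc <- embedFhr(generateFhrRecord(1, "minimal"), parseFasta(">s\nACGT\n"))
#' isValid(verifyChecksum(injectChecksum(doc)))
#' @export
injectChecksum <- function(doc, algorithm = "md5", strict = FALSE) {
  record <- extractFhr(doc)
  record@fields[["checksum"]] <- NULL
  base <- suppressWarnings(stripFhr(doc))
  if (strict) {
    # digest covers the output bytes (canonical header, no checksum line)
    staged <- embedFhr(record, base)
    cs <- computeChecksum(staged, algorithm, strict = TRUE)
  } else {
    cs <- computeChecksum(doc, algorithm, record = record)
  }
  record@fields[["checksum"]] <- cs
  embedFhr(record, base)
}

#' Verify the self-referential checksum of an embedded header
#'
#' Recomputes the digest under the algorithm stored in the header and
#' compares it with the stored value.  The result is reported, not thrown:
#' a mismatch — the header/data divergence the checksum exists to catch —
#' appears as an error-severity `CHECKSUM_MISMATCH` issue.
#'
#' @param doc A [FastaDocument-class] with an embedded header carrying a
#'   checksum.
#' @param strict Verify against the raw-bytes digest.
#' @return An [FhrValidationReport-class]; `isValid()` is `TRUE` iff stored
#'   and recomputed digests agree.
#' @export
verifyChecksum <- function(doc, strict = FALSE) {
  record <- extractFhr(doc)
  stored <- record@fields[["checksum"]]
  if (is.null(stored))
    fhrError("fhrMissingChecksum", "header carries no checksum field")
  parsed <- tryCatch(parseChecksum(stored), fhrError = function(e) NULL)
  if (is.null(parsed) || !parsed$algorithm %in% names(.checksumAlgorithms))
    return(newReport("/checksum", "error", "BAD_CHECKSUM_FORMAT",
                     sprintf("stored checksum '%s' is malformed or uses an unsupported algorithm",
                             stored)))
  recomputed <- computeChecksum(doc, parsed$algorithm, strict = strict)
  if (identical(parseChecksum(recomputed)$digest, parsed$digest))
    newReport()
  else
    newReport("/checksum", "error", "CHECKSUM_MISMATCH",
              sprintf("header/data mismatch: stored %s, recomputed %s",
                      stored, recomputed))
}
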