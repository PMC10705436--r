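# FASTA codec.  The container is deliberately line-based and byte-faithful:
# serializing a freshly parsed document reproduces the input exactly,
# including newline convention and the presence/absence of a final newline.
# Metadata operations only ever add or remove ";~" lines; sequence records
# and plain ";" comments pass through untouched.

#' Parse a FASTA file (or text) into a byte-faithful document
#'
#' Accepts the Pearson dialect with leading semicolon comments: an optional
#' block of `;`-prefixed lines at the top of the file, of which
#' `;~`-prefixed lines carry FHR metadata, followed by `>`-headed sequence
#' records.  The newline convention (LF or CRLF) is detected and preserved.
#' Comments appearing after the first `>` line are retained in place but are
#' never treated as FHR content.
#'
#' @param x A file path, a raw vector, or a character scalar holding the
#'   file text.
#' @return A [FastaDocument-class].
#' @examples
#' doc <- parseFasta(">seq1\nACGT\n")
#' doc
#' @export
parseFasta <- function(x) {
  if (is.raw(x)) {
    bytes <- x
  } else if (is.character(x) && length(x) == 1L) {
    if (!grepl("[\n;>]", x)) {
      # no newline, comment or record marker: this can only be a file path
      if (!file.exists(x))
        fhrError("fhrIOError", sprintf("cannot read '%s': no such file", x))
      bytes <- readBin(x, "raw", n = file.size(x))
    } else {
      bytes <- charToRaw(enc2utf8(x))
    }
  } else {
    fhrError("fhrIOError", "input must be a file path, raw vector or text")
  }
  if (length(bytes) == 0L)
    fhrError("fhrEmptyInput", "empty FASTA input")
  txt <- tryCatch(rawToChar(bytes),
                  error = function(e)
                    fhrError("fhrDecodeError", "input contains NUL bytes"))
  if (!all(validUTF8(txt)))
    fhrError("fhrDecodeError", "input is not valid UTF-8")
  Encoding(txt) <- "UTF-8"

  nLF <- length(gregexpr("\n", txt, fixed = TRUE)[[1L]])
  if (!grepl("\n", txt, fixed = TRUE)) nLF <- 0L
  nCRLF <- if (grepl("\r\n", txt, fixed = TRUE))
    length(gregexpr("\r\n", txt, fixed = TRUE)[[1L]]) else 0L
  newline <- if (nLF > 0L && nLF == nCRLF) "\r\n" else "\n"

  eof <- endsWith(txt, newline) ||
    (newline == "\n" && endsWith(txt, "\n"))
  body <- if (eof) substr(txt, 1L, nchar(txt) - nchar(newline)) else txt
  lines <- if (nzchar(body)) strsplit(body, newline, fixed = TRUE)[[1L]]
           else ""
  # strsplit drops trailing empty fields; restore interior blank lines count
  nSep <- length(gregexpr(newline, body, fixed = TRUE)[[1L]])
  if (!grepl(newline, body, fixed = TRUE)) nSep <- 0L
  if (length(lines) < nSep + 1L)
    lines <- c(lines, rep("", nSep + 1L - length(lines)))

  new("FastaDocument", lines = lines, newline = newline, eofNewline = eof)
}

#' Serialize a FastaDocument back to text
#'
#' @param doc A [FastaDocument-class].
#' @return A character scalar; for a freshly parsed document this is
#'   byte-identical to the input.
#' @export
fastaText <- function(doc) {
  out <- paste(doc@lines, collapse = doc@newline)
  if (doc@eofNewline) out <- paste0(out, doc@newline)
  out
}

#' Write a FastaDocument to a file
#'
#' Bytes are written exactly as [fastaText()] produces them (no newline
#' translation).
#'
#' @param doc A [FastaDocument-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(doc, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(fastaText(doc))), con)
  invisible(path)
}

fhrLineIdx <- function(doc) grep("^;~", doc@lines)

firstRecordIdx <- function(doc) {
  idx <- grep("^>", doc@lines)
  if (length(idx) == 0L) Inf else idx[1L]
}

#' Extract the FHR metadata record embedded in a FASTA document
#'
#' Collects the `;~`-prefixed lines of the top-of-file comment block, strips
#' the prefix (tolerating a single following space), and parses the joined
#' text as a YAML mapping.  `;~` lines appearing after the first sequence
#' record are ignored with a warning — the header belongs at the top of the
#' file.
#'
#' @param doc A [FastaDocument-class].
#' @return The embedded record, un-canonicalized, as an [FhrRecord-class].
#' @examples
#' doc <- parseFasta(";~genome: Example species\n>s\nACGT\n")
#' fhrField(extractFhr(doc), "genome")
#' @export
extractFhr <- function(doc) {
  idx <- fhrLineIdx(doc)
  if (length(idx) == 0L)
    fhrError("fhrMissingHeader", "no FHR header (';~' lines) in document")
  misplaced <- idx[idx > firstRecordIdx(doc)]
  if (length(misplaced) > 0L) {
    fhrWarning("fhrMisplacedHeaderLines",
               sprintf("%d ';~' line(s) after the first sequence record ignored",
                       length(misplaced)))
    idx <- setdiff(idx, misplaced)
    if (length(idx) == 0L)
      fhrError("fhrMissingHeader",
               "all ';~' lines are misplaced below the first record")
  }
  text <- sub("^;~ ?", "", doc@lines[idx])
  parseFhrYaml(text)
}

#' Embed an FHR metadata record into a FASTA document
#'
#' The record is canonicalized, serialized as YAML, line-prefixed with
#' `;~`, and placed before all other content; plain comments and sequence
#' records are preserved byte-for-byte.  An existing FHR header is refused
#' unless `overwrite = TRUE`.
#'
#' @param record An [FhrRecord-class] (a missing checksum is allowed, to
#'   support checksum injection afterwards).
#' @param doc A [FastaDocument-class].
#' @param overwrite Replace an existing FHR header instead of refusing.
#' @return A new [FastaDocument-class] with the header embedded.
#' @examples
#' doc <- parseFasta(">s\nACGT\n")
#' rec <- generateFhrRecord(1, "minimal")
#' doc2 <- embedFhr(rec, doc)
#' fhrEqual(extractFhr(doc2), rec)
#' @export
embedFhr <- function(record, doc, overwrite = FALSE) {
  if (length(fhrLineIdx(doc)) > 0L) {
    if (!overwrite)
      fhrError("fhrReplaceRefused",
               "document already carries an FHR header (use overwrite = TRUE)")
    doc <- suppressWarnings(stripFhr(doc))
  }
  can <- canonicalizeFhr(record)
  hdr <- paste0(";~", emitFhrYaml(can))
  new("FastaDocument", lines = c(hdr, doc@lines),
      newline = doc@newline, eofNewline = doc@eofNewline)
}

#' Remove all FHR metadata lines from a FASTA document
#'
#' Every `;~` line is removed; all other content (plain `;` comments,
#' sequence records, newline style) is unchanged.  Stripping a header-less
#' document is the identity.  A `;~` line below the first sequence record is
#' removed too, with a warning.
#'
#' @param doc A [FastaDocument-class].
#' @return A new [FastaDocument-class] without FHR lines.
#' @export
stripFhr <- function(doc) {
  idx <- fhrLineIdx(doc)
  if (length(idx) == 0L) return(doc)
  if (any(idx > firstRecordIdx(doc)))
    fhrWarning("fhrMisplacedHeaderLines",
               "';~' line(s) found after the first sequence record were removed")
  new("FastaDocument", lines = doc@lines[-idx],
      newline = doc@newline, eofNewline = doc@eofNewline)
}

# (header line, concatenated sequence) pairs — used to assert that metadata
# operations never disturb sequence content
sequenceTable <- function(doc) {
  hdr <- grep("^>", doc@lines)
  if (length(hdr) == 0L)
    return(data.frame(header = character(), sequence = character()))
  ends <- c(hdr[-1L] - 1L, length(doc@lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    body <- doc@lines[(hdr[i] + 1L):ends[i]]
    paste(body[!grepl("^;", body)], collapse = "")
  }, character(1))
  data.frame(header = doc@lines[hdr], sequence = seqs,
             stringsAsFactors = FALSE)
}
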