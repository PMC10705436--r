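# Sidecar serializations.  One record, four carriers: embedded FASTA header,
# YAML (human-readable), JSON (interchange), Microdata HTML (search-engine
# visible).  All writers emit the canonical form, so writing the same record
# twice — from any source format — yields byte-identical files.

.formatPatterns <- c(
  ".fhr.yaml" = "yaml", ".fhr.yml" = "yaml", ".fhr.json" = "json",
  ".fhr.html" = "html", ".yaml" = "yaml", ".yml" = "yaml", ".json" = "json",
  ".html" = "html", ".fasta" = "fasta", ".fa" = "fasta", ".fna" = "fasta"
)

#' Detect the serialization format of a filename
#'
#' Sidecar files follow the naming template
#' `<genome file name>.fhr.<yaml|json|html>`; FASTA files end in
#' `.fasta`/`.fa`/`.fna`.  The longest matching suffix wins, so
#' `mouse.fhr.yaml` is YAML, not FASTA.
#'
#' @param path A filename.
#' @return One of `"yaml"`, `"json"`, `"html"`, `"fasta"`.
#' @examples
#' detectFhrFormat("mouse.fhr.yaml")
#' detectFhrFormat("mouse.fa")
#' @export
detectFhrFormat <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    fhrError("fhrUnsupportedFormat", "path must be a non-empty filename")
  low <- tolower(path)
  pats <- .formatPatterns[order(nchar(names(.formatPatterns)),
                                decreasing = TRUE)]
  for (i in seq_along(pats))
    if (endsWith(low, names(pats)[i])) return(unname(pats[i]))
  fhrError("fhrUnsupportedFormat",
           sprintf("unrecognized file suffix in '%s' (expected %s)", path,
                   paste(unique(names(.formatPatterns)), collapse = ", ")))
}

readTextFile <- function(path) {
  if (!file.exists(path))
    fhrError("fhrIOError", sprintf("cannot read '%s': no such file", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) == 0L)
    fhrError("fhrHeaderParseError", sprintf("'%s' is empty", path))
  txt <- tryCatch(rawToChar(bytes),
                  error = function(e)
                    fhrError("fhrDecodeError",
                             sprintf("'%s' contains NUL bytes", path)))
  if (!all(validUTF8(txt)))
    fhrError("fhrDecodeError", sprintf("'%s' is not valid UTF-8", path))
  Encoding(txt) <- "UTF-8"
  txt
}

#' Read an FHR record from a file in any supported format
#'
#' Dispatches on the (detected or given) format: FASTA files go through the
#' embedded-header extractor, YAML/JSON sidecars are parsed as mappings, and
#' HTML sidecars are read from their Microdata item.  The record is returned
#' un-canonicalized; apply [canonicalizeFhr()] for comparisons.
#'
#' @param path Input filename.
#' @param format Override the format detected from the filename.
#' @return An [FhrRecord-class].
#' @export
readFhr <- function(path, format = NULL) {
  if (is.null(format)) format <- detectFhrFormat(path)
  switch(format,
    fasta = extractFhr(parseFasta(path)),
    yaml = parseFhrYaml(readTextFile(path)),
    json = parseFhrJson(readTextFile(path)),
    html = parseFhrHtml(readTextFile(path)),
    fhrError("fhrUnsupportedFormat",
             sprintf("unknown format token '%s'", format))
  )
}

parseFhrJson <- function(txt) {
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e)
      fhrError("fhrHeaderParseError",
               paste0("not valid JSON: ", conditionMessage(e)))
  )
  if (!is.list(parsed) || is.null(names(parsed)))
    fhrError("fhrHeaderParseError", "JSON document is not an object")
  new("FhrRecord", fields = parsed)
}

# --- Microdata HTML ----------------------------------------------------------

htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

emitFhrHtml <- function(record) {
  f <- if (is(record, "FhrRecord")) record@fields else record
  span <- function(prop, v, pad)
    sprintf("%s<span itemprop=\"%s\">%s</span>", pad, htmlEscape(prop),
            htmlEscape(as.character(v)))
  item <- function(prop, pair, pad) {
    c(sprintf("%s<div itemprop=\"%s\" itemscope>", pad, htmlEscape(prop)),
      unlist(lapply(names(pair), function(k)
        span(k, pair[[k]], paste0(pad, "  ")))),
      sprintf("%s</div>", pad))
  }
  body <- character()
  for (k in names(f)) {
    v <- f[[k]]
    body <- c(body,
      if (isYamlMapping(v)) item(k, v, "    ")
      else if (is.list(v) && length(v) > 0L && isYamlMapping(v[[1L]]))
        unlist(lapply(v, function(p) item(k, p, "    ")))
      else if (is.list(v) || length(v) > 1L)
        vapply(as.list(v), function(e) span(k, e, "    "), character(1))
      else span(k, v, "    "))
  }
  typeUri <- if (!is.null(f[["schema"]])) as.character(f[["schema"]]) else ""
  title <- if (!is.null(f[["genome"]])) as.character(f[["genome"]])
           else "reference genome"
  c("<!DOCTYPE html>",
    "<html>",
    "<head>",
    "  <meta charset=\"utf-8\" />",
    sprintf("  <title>FHR metadata: %s</title>", htmlEscape(title)),
    "</head>",
    "<body>",
    sprintf("  <div itemscope itemtype=\"%s\">", htmlEscape(typeUri)),
    body,
    "  </div>",
    "</body>",
    "</html>")
}

microdataProps <- function(node) {
  props <- character()
  vals <- list()
  walk <- function(n) {
    for (ch in xml2::xml_children(n)) {
      prop <- xml2::xml_attr(ch, "itemprop")
      if (!is.na(prop)) {
        v <- if (!is.na(xml2::xml_attr(ch, "itemscope")))
          microdataProps(ch)
        else if (xml2::xml_name(ch) %in% c("a", "link") &&
                 !is.na(xml2::xml_attr(ch, "href")))
          xml2::xml_attr(ch, "href")
        else xml2::xml_text(ch)
        props[[length(props) + 1L]] <<- prop
        vals[[length(vals) + 1L]] <<- v
      } else {
        walk(ch)
      }
    }
  }
  walk(node)
  out <- list()
  for (i in seq_along(props)) {
    p <- props[[i]]
    out[[p]] <- if (is.null(out[[p]])) list(vals[[i]])
                else c(out[[p]], list(vals[[i]]))
  }
  multi <- c(.listFields, .agentListFields)
  for (p in names(out))
    if (length(out[[p]]) == 1L && !p %in% multi) out[[p]] <- out[[p]][[1L]]
  out
}

parseFhrHtml <- function(txt) {
  doc <- tryCatch(xml2::read_html(txt),
                  error = function(e)
                    fhrError("fhrMicrodataError",
                             paste0("not parseable HTML: ",
                                    conditionMessage(e))))
  node <- xml2::xml_find_first(doc, "//*[@itemscope and @itemtype]")
  if (inherits(node, "xml_missing"))
    fhrError("fhrMicrodataError", "HTML document contains no Microdata item")
  fields <- microdataProps(node)
  if (length(fields) == 0L)
    fhrError("fhrMicrodataError", "Microdata item has no properties")
  new("FhrRecord", fields = fields)
}

# --- writing -----------------------------------------------------------------

fhrFormatText <- function(record, format) {
  can <- canonicalizeFhr(record)
  switch(format,
    yaml = paste0(paste(emitFhrYaml(can), collapse = "\n"), "\n"),
    json = paste0(jsonlite::toJSON(can@fields, auto_unbox = TRUE,
                                   pretty = 2), "\n"),
    html = paste0(paste(emitFhrHtml(can), collapse = "\n"), "\n"),
    fhrError("fhrRefusedConversion",
             "metadata alone cannot be written as FASTA; combine it with its sequence file (embedFhr() / fhr-fasta-combine)")
  )
}

writeTextAtomically <- function(txt, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  con <- tryCatch(file(tmp, open = "wb"),
                  error = function(e)
                    fhrError("fhrIOError",
                             sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e))))
  writeBin(charToRaw(enc2utf8(txt)), con)
  close(con)
  if (!file.rename(tmp, path))
    fhrError("fhrIOError", sprintf("cannot move output into place at '%s'",
                                   path))
  ok <- TRUE
  invisible(path)
}

#' Write an FHR record to a sidecar file
#'
#' The record is canonicalized and emitted deterministically in the chosen
#' format.  Sidecars are meant to sit next to the FASTA file they describe,
#' named `<genome file name>.fhr.<ext>`; a warning is raised when no
#' matching FASTA is adjacent.  Writing is atomic (write-to-temp, then
#' rename): no partial file is left behind on failure.
#'
#' @param record An [FhrRecord-class] (pre-injection records without a
#'   checksum are accepted).
#' @param path Output filename.
#' @param format Override the format detected from the filename.  The
#'   `fasta` format is refused: metadata alone cannot produce sequence data.
#' @param checkSidecar Warn when a `*.fhr.*` sidecar has no adjacent FASTA.
#' @return `path`, invisibly.
#' @export
writeFhr <- function(record, path, format = NULL, checkSidecar = TRUE) {
  if (is.null(format)) format <- detectFhrFormat(path)
  txt <- fhrFormatText(record, format)
  if (checkSidecar &&
      grepl("\\.fhr\\.(yaml|yml|json|html)$", tolower(basename(path)))) {
    base <- sub("\\.fhr\\.[A-Za-z]+$", "", path)
    # the template's <genome file name> may or may not carry its own suffix
    companions <- c(base, paste0(base, c(".fasta", ".fa", ".fna")))
    if (!any(file.exists(companions) & !dir.exists(companions)))
      fhrWarning("fhrSidecarNaming",
                 sprintf("no FASTA matching '%s' found next to the sidecar",
                         basename(base)))
  }
  writeTextAtomically(txt, path)
}

#' Convert FHR metadata between file formats
#'
#' Reads the record from the input (FASTA with an embedded header, or a
#' YAML/JSON/HTML sidecar), canonicalizes it, and writes it in the format
#' implied by the output filename.  Converting a sidecar *to* FASTA is
#' refused — metadata alone cannot produce sequence data; combine it with
#' its sequence file instead ([embedFhr()], or `fhr-fasta-combine` on the
#' command line).
#'
#' @param inPath Input filename (format detected from its suffix).
#' @param outPath Output filename (format detected from its suffix).
#' @return `outPath`, invisibly.
#' @export
convertFhr <- function(inPath, outPath) {
  inFmt <- detectFhrFormat(inPath)
  outFmt <- detectFhrFormat(outPath)
  if (outFmt == "fasta")
    fhrError("fhrRefusedConversion",
             "cannot convert metadata alone to FASTA; use embedFhr() / fhr-fasta-combine with the companion sequence file")
  rec <- readFhr(inPath, inFmt)
  writeFhr(rec, outPath, outFmt, checkSidecar = FALSE)
}
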