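# Canonical form and the deterministic YAML emitter.
#
# Round-trip closure across YAML/JSON/HTML/embedded-FASTA and checksum
# stability both hinge on one deterministic serialization, so emission is
# done by a small purpose-built emitter rather than a generic YAML dumper:
# fixed field order, fixed quoting rules, block style, two-space indent, no
# anchors or aliases.

#' Canonicalize an FHR record
#'
#' Produces the deterministic normal form used for serialization, equality
#' comparison and checksum computation:
#' * fields ordered required-first in standard order (`checksum` last among
#'   the required), then optional fields alphabetically, then any unknown
#'   fields alphabetically;
#' * scalar values given for multi-valued fields promoted to one-element
#'   lists;
#' * whitespace trimmed; the en dash occasionally introduced by typesetting
#'   in dates transliterated to an ASCII hyphen;
#' * `schemaVersion` coerced to integer; the checksum algorithm token
#'   lowercased.
#'
#' Canonicalization is idempotent and insensitive to input key order.
#'
#' @param record An [FhrRecord-class] or named list; must be free of
#'   error-severity validation issues in `pre_injection` mode.
#' @return A canonical [FhrRecord-class].
#' @examples
#' r <- generateFhrRecord(3, "minimal")
#' shuffled <- FhrRecord(fhrFields(r)[sample(seq_along(fhrFields(r)))])
#' identical(fhrFields(canonicalizeFhr(shuffled)), fhrFields(canonicalizeFhr(r)))
#' @export
canonicalizeFhr <- function(record) {
  f <- if (is(record, "FhrRecord")) record@fields else record
  rep <- validateFhr(f, mode = "pre_injection")
  if (!isValid(rep)) {
    bad <- rep@issues[rep@issues$severity == "error", , drop = FALSE]
    fhrError("fhrInvalidRecord",
             paste0("record has validation errors: ",
                    paste(sprintf("%s (%s)", bad$path, bad$code),
                          collapse = "; ")))
  }

  normScalar <- function(v) trimws(as.character(v))

  normPair <- function(v) {
    out <- list(name = normScalar(v[["name"]]))
    if (!is.null(v[["uri"]])) out$uri <- normScalar(v[["uri"]])
    extra <- setdiff(names(v), c("name", "uri"))
    for (k in sort(extra)) out[[k]] <- v[[k]]
    out
  }

  out <- list()
  for (k in .requiredFields) {
    v <- f[[k]]
    if (is.null(v)) next  # checksum may be absent pre-injection
    out[[k]] <- switch(k,
      schemaVersion = as.integer(as.numeric(trimws(as.character(v)))),
      taxon = normPair(v),
      assemblyAuthor = ,
      metadataAuthor = {
        if (!is.null(asPair(v))) v <- list(v)
        lapply(v, normPair)
      },
      dateCreated = gsub("–", "-", normScalar(v)),
      checksum = {
        parts <- strsplit(normScalar(v), ":", fixed = TRUE)[[1L]]
        paste0(tolower(parts[1L]), ":",
               paste(parts[-1L], collapse = ":"))
      },
      normScalar(v)
    )
  }
  for (k in .optionalFields) {
    v <- f[[k]]
    if (is.null(v)) next
    out[[k]] <-
      if (k %in% .listFields) {
        if (isScalar(v)) v <- list(v)
        lapply(as.list(v), normScalar)
      } else if (k == "accessionID") {
        normPair(v)
      } else {
        normScalar(v)
      }
  }
  for (k in sort(setdiff(names(f), c(.requiredFields, .optionalFields))))
    out[[k]] <- f[[k]]

  new("FhrRecord", fields = out)
}

#' Test two records for canonical equality
#'
#' @param a,b Records (or named lists) comparable after [canonicalizeFhr()].
#' @return `TRUE` iff the canonical forms are identical.
#' @export
fhrEqual <- function(a, b) {
  identical(fhrFields(canonicalizeFhr(a)), fhrFields(canonicalizeFhr(b)))
}

# --- YAML emission -----------------------------------------------------------

# Quote iff the bare token would not read back as exactly this string.
needsYamlQuote <- function(v) {
  parsed <- tryCatch(yaml::yaml.load(v), error = function(e) NULL)
  !(is.character(parsed) && length(parsed) == 1L && identical(parsed, v))
}

yamlScalar <- function(v) {
  if (is.numeric(v) || is.integer(v))
    return(format(v, scientific = FALSE))
  if (is.logical(v)) return(if (v) "true" else "false")
  v <- as.character(v)
  if (grepl("[\x01-\x1f]", v)) {
    esc <- gsub("\\", "\\\\", v, fixed = TRUE)
    esc <- gsub("\"", "\\\"", esc, fixed = TRUE)
    esc <- gsub("\n", "\\n", esc, fixed = TRUE)
    esc <- gsub("\r", "\\r", esc, fixed = TRUE)
    esc <- gsub("\t", "\\t", esc, fixed = TRUE)
    return(paste0("\"", esc, "\""))
  }
  if (needsYamlQuote(v)) paste0("'", gsub("'", "''", v), "'") else v
}

isYamlMapping <- function(v) is.list(v) && !is.null(names(v)) &&
  all(nzchar(names(v)))

emitYamlMapping <- function(x, indent) {
  pad <- strrep(" ", indent)
  out <- character()
  for (k in names(x)) {
    v <- x[[k]]
    if (isYamlMapping(v)) {
      out <- c(out, paste0(pad, k, ":"), emitYamlMapping(v, indent + 2L))
    } else if (is.list(v) || length(v) > 1L) {
      out <- c(out, paste0(pad, k, ":"), emitYamlSequence(v, indent + 2L))
    } else {
      out <- c(out, paste0(pad, k, ": ", yamlScalar(v)))
    }
  }
  out
}

emitYamlSequence <- function(x, indent) {
  pad <- strrep(" ", indent)
  out <- character()
  for (v in as.list(x)) {
    if (isYamlMapping(v)) {
      sub <- emitYamlMapping(v, indent + 2L)
      sub[1L] <- paste0(pad, "- ", sub("^ +", "", sub[1L]))
      out <- c(out, sub)
    } else {
      out <- c(out, paste0(pad, "- ", yamlScalar(v)))
    }
  }
  out
}

# canonical YAML lines of a record (no trailing newline handling here)
emitFhrYaml <- function(record) {
  f <- if (is(record, "FhrRecord")) record@fields else record
  emitYamlMapping(f, 0L)
}

# Parse YAML text into an un-canonicalized record.  Anchors and aliases are
# rejected: the ";~" line-prefixed embedding assumes each line is
# self-contained, and aliasing would make canonical emission ambiguous.
parseFhrYaml <- function(text) {
  if (!nzchar(trimws(paste(text, collapse = "\n"))))
    fhrError("fhrHeaderParseError", "empty metadata document")
  if (any(grepl("(^|[[:space:]:,[{-])[&*][A-Za-z0-9_-]", text)))
    fhrError("fhrHeaderParseError",
             "YAML anchors and aliases are not accepted in FHR metadata")
  parsed <- tryCatch(
    yaml::yaml.load(paste(text, collapse = "\n")),
    error = function(e)
      fhrError("fhrHeaderParseError",
               paste0("metadata is not a valid YAML mapping: ",
                      conditionMessage(e)))
  )
  if (!is.list(parsed) || is.null(names(parsed)))
    fhrError("fhrHeaderParseError", "metadata is not a key/value mapping")
  new("FhrRecord", fields = parsed)
}

# checksum wire form helpers ---------------------------------------------------

parseChecksum <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9]+):([0-9a-fA-F]+)$",
                             as.character(x)))[[1L]]
  if (length(m) != 3L)
    fhrError("fhrUnsupportedAlgorithm",
             sprintf("malformed checksum value '%s'", x))
  list(algorithm = tolower(m[2L]), digest = tolower(m[3L]))
}

formatChecksum <- function(algorithm, digest) {
  paste0(tolower(algorithm), ":", tolower(digest))
}
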