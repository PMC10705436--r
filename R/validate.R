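#' Validate an FHR record against the field rules of the standard
#'
#' Checks presence of the nine required fields, the syntactic rules for each
#' field (absolute URIs, registry-hosted taxon URI, ISO-8601 calendar date,
#' `<algorithm>:<hex>` checksum form, non-empty names), and the shape of the
#' optional fields.  All problems are reported, never thrown: each violation
#' becomes one issue with a field path, a severity and a stable code.
#'
#' In `pre_injection` mode a missing `checksum` is not an error, supporting
#' the compute-then-inject workflow where the checksum can only be written
#' after the rest of the header is final.  Unknown keys yield warnings, not
#' errors: the standard is deliberately extensible.
#'
#' @param record An [FhrRecord-class] or a named list of fields.
#' @param mode `"strict"` (default; all nine required fields must be
#'   present) or `"pre_injection"` (checksum may be absent).
#' @return An [FhrValidationReport-class]; `isValid()` on it is `TRUE` iff
#'   no issue has severity `error`.
#' @examples
#' rec <- generateFhrRecord(1, completeness = "minimal")
#' isValid(validateFhr(rec))
#' rec2 <- FhrRecord(modifyList(fhrFields(rec), list(dateCreated = "21-03-2022")))
#' fhrIssues(validateFhr(rec2))
#' @export
validateFhr <- function(record, mode = c("strict", "pre_injection")) {
  mode <- match.arg(mode)
  f <- if (is(record, "FhrRecord")) record@fields else record
  if (!is.list(f))
    return(newReport("/", "error", "BAD_TYPE", "record is not a mapping"))

  iss <- list()
  add <- function(path, severity, code, message) {
    iss[[length(iss) + 1L]] <<- data.frame(
      path = path, severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  }

  present <- function(name) !is.null(f[[name]])

  # -- required-field presence
  for (name in .requiredFields) {
    if (!present(name)) {
      if (name == "checksum" && mode == "pre_injection") next
      add(paste0("/", name), "error", "MISSING_REQUIRED",
          sprintf("required field '%s' is missing", name))
    }
  }

  checkScalar <- function(name, path = paste0("/", name)) {
    v <- f[[name]]
    if (!isScalar(v)) {
      add(path, "error", "BAD_TYPE",
          sprintf("'%s' must be a single scalar value", name))
      return(NULL)
    }
    v <- trimws(as.character(v))
    if (!nzchar(v)) {
      add(path, "error", "EMPTY_VALUE", sprintf("'%s' is empty", name))
      return(NULL)
    }
    v
  }

  checkPair <- function(name, value, path, uriRequired = FALSE,
                        registry = FALSE) {
    if (!is.list(value) || is.null(names(value))) {
      add(path, "error", "BAD_TYPE",
          sprintf("'%s' must be a name/uri mapping", name))
      return(invisible(NULL))
    }
    nm <- value[["name"]]
    if (is.null(nm) || !isScalar(nm) || !nzchar(trimws(as.character(nm))))
      add(paste0(path, "/name"), "error",
          if (is.null(nm)) "MISSING_REQUIRED" else "EMPTY_VALUE",
          sprintf("'%s' needs a non-empty name", name))
    uri <- value[["uri"]]
    if (is.null(uri)) {
      if (uriRequired)
        add(paste0(path, "/uri"), "error", "MISSING_REQUIRED",
            sprintf("'%s' needs a uri", name))
    } else if (!isAbsoluteUri(uri)) {
      add(paste0(path, "/uri"), "error", "BAD_URI",
          sprintf("'%s' uri must be an absolute http(s) URI", name))
    } else if (registry && !uriHost(uri) %in% .registryHosts) {
      add(paste0(path, "/uri"), "error", "BAD_TAXON_HOST",
          sprintf("'%s' uri must be hosted at %s", name,
                  paste(.registryHosts, collapse = " or ")))
    }
    extra <- setdiff(names(value), c("name", "uri"))
    for (k in extra)
      add(paste0(path, "/", k), "warning", "UNKNOWN_FIELD",
          sprintf("unknown key '%s' in '%s'", k, name))
  }

  # accept a scalar-or-list of name/uri pairs (a single pair is promoted on
  # canonicalization)
  checkAgentList <- function(name) {
    v <- f[[name]]
    path <- paste0("/", name)
    if (!is.list(v)) {
      add(path, "error", "BAD_TYPE",
          sprintf("'%s' must be a list of name/uri mappings", name))
      return(invisible(NULL))
    }
    if (!is.null(asPair(v))) v <- list(v)
    if (length(v) == 0L) {
      add(path, "error", "EMPTY_VALUE",
          sprintf("'%s' must list at least one author", name))
      return(invisible(NULL))
    }
    for (i in seq_along(v))
      checkPair(name, v[[i]], paste0(path, "/", i))
  }

  checkStringList <- function(name, uri = FALSE, curie = FALSE) {
    v <- f[[name]]
    path <- paste0("/", name)
    if (isScalar(v)) v <- list(v)
    if (!is.list(v) && !(is.atomic(v) && length(v) >= 1L)) {
      add(path, "error", "BAD_TYPE",
          sprintf("'%s' must be a string or list of strings", name))
      return(invisible(NULL))
    }
    v <- as.list(v)
    for (i in seq_along(v)) {
      el <- v[[i]]
      p <- paste0(path, "/", i)
      if (!isScalar(el) || !nzchar(trimws(as.character(el)))) {
        add(p, "error", "BAD_TYPE",
            sprintf("'%s' entries must be non-empty strings", name))
      } else if (uri && !isAbsoluteUri(el)) {
        add(p, "error", "BAD_URI",
            sprintf("'%s' entries must be absolute http(s) URIs", name))
      } else if (curie &&
                 !grepl("^[A-Za-z0-9._-]+:[^[:space:]]+$",
                        trimws(as.character(el)))) {
        add(p, "error", "BAD_CURIE",
            sprintf("'%s' entries must be prefix:accession CURIEs", name))
      }
    }
  }

  # -- per-field rules (only for fields that are present)
  if (present("schema")) {
    v <- checkScalar("schema")
    if (!is.null(v) && !isAbsoluteUri(v))
      add("/schema", "error", "BAD_URI",
          "'schema' must be an absolute http(s) URI")
  }

  if (present("schemaVersion")) {
    v <- f[["schemaVersion"]]
    ok <- (is.numeric(v) && length(v) == 1L && !is.na(v) && v == trunc(v) &&
             v >= 1) ||
          (is.character(v) && length(v) == 1L && grepl("^[0-9]+$", trimws(v)) &&
             as.numeric(trimws(v)) >= 1)
    if (!ok)
      add("/schemaVersion", "error", "BAD_TYPE",
          "'schemaVersion' must be a positive integer")
  }

  if (present("genome")) checkScalar("genome")
  if (present("version")) checkScalar("version")

  if (present("taxon"))
    checkPair("taxon", f[["taxon"]], "/taxon", uriRequired = TRUE,
              registry = TRUE)

  for (name in .agentListFields) if (present(name)) checkAgentList(name)

  if (present("dateCreated")) {
    v <- checkScalar("dateCreated")
    if (!is.null(v)) {
      if (grepl("–", v)) {
        add("/dateCreated", "warning", "DATE_EN_DASH",
            "en dash in date transliterated to ASCII hyphen")
        v <- gsub("–", "-", v)
      }
      bad <- !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", v) ||
        is.na(as.Date(v, format = "%Y-%m-%d"))
      if (bad)
        add("/dateCreated", "error", "BAD_DATE",
            "'dateCreated' must be an ISO-8601 calendar date (YYYY-MM-DD)")
    }
  }

  if (present("checksum")) {
    v <- checkScalar("checksum")
    if (!is.null(v)) {
      m <- regmatches(v, regexec("^([A-Za-z0-9]+):([0-9a-f]+)$", v))[[1L]]
      algos <- names(.checksumAlgorithms)
      if (length(m) != 3L || !tolower(m[2L]) %in% algos) {
        add("/checksum", "error", "BAD_CHECKSUM_FORMAT",
            sprintf("'checksum' must be <algorithm>:<lowercase hex> with algorithm one of %s",
                    paste(algos, collapse = ", ")))
      } else if (nchar(m[3L]) != .checksumAlgorithms[[tolower(m[2L])]]) {
        add("/checksum", "error", "BAD_CHECKSUM_FORMAT",
            sprintf("%s digest must be %d hex characters, got %d",
                    tolower(m[2L]), .checksumAlgorithms[[tolower(m[2L])]],
                    nchar(m[3L])))
      }
    }
  }

  for (name in c("assemblySoftware", "documentation", "reuseConditions",
                 "voucherSpecimen"))
    if (present(name)) checkScalar(name)

  if (present("funding")) checkStringList("funding")
  if (present("genomeSynonym")) checkStringList("genomeSynonym")
  if (present("instrument")) checkStringList("instrument")
  if (present("identifier")) checkStringList("identifier", curie = TRUE)
  if (present("relatedLink")) checkStringList("relatedLink", uri = TRUE)
  if (present("scholarlyArticle")) checkStringList("scholarlyArticle",
                                                   uri = TRUE)
  if (present("accessionID"))
    checkPair("accessionID", f[["accessionID"]], "/accessionID")

  known <- c(.requiredFields, .optionalFields)
  for (k in setdiff(names(f), known))
    add(paste0("/", k), "warning", "UNKNOWN_FIELD",
        sprintf("unknown field '%s' (ignored by the standard, preserved on output)", k))

  if (length(iss) == 0L) return(newReport())
  new("FhrValidationReport", issues = do.call(rbind, iss))
}
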