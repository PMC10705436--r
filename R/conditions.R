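# Structured conditions so callers (and the CLI) can dispatch on failure
# category rather than matching message text.

fhrError <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fhrError", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

fhrWarning <- function(class, message, ...) {
  warning(structure(
    class = c(class, "fhrWarning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

#' @name fhr-conditions
#' @title Condition classes signalled by the package
#' @description
#' All failures are signalled as classed conditions inheriting from
#' `fhrError` so that callers can use `tryCatch(..., fhrError = )` or match a
#' specific class:
#' \describe{
#'   \item{fhrDecodeError}{input bytes are not valid UTF-8}
#'   \item{fhrEmptyInput}{zero-byte input where content is required}
#'   \item{fhrMissingHeader}{no `;~` metadata lines in a FASTA document}
#'   \item{fhrMissingChecksum}{header present but carries no checksum field}
#'   \item{fhrHeaderParseError}{`;~` block (or sidecar text) is not a valid
#'     mapping}
#'   \item{fhrReplaceRefused}{an embedded header already exists and
#'     `overwrite = FALSE`}
#'   \item{fhrUnsupportedFormat}{filename suffix maps to no known format}
#'   \item{fhrUnsupportedAlgorithm}{checksum algorithm outside md5/sha1/sha256}
#'   \item{fhrRefusedConversion}{metadata-only conversion cannot produce
#'     sequence data (sidecar to FASTA)}
#'   \item{fhrMicrodataError}{HTML sidecar lacks a Microdata item}
#'   \item{fhrUsageError}{bad command-line arguments}
#'   \item{fhrInvalidRecord}{canonicalization attempted on a record with
#'     error-severity validation issues}
#'   \item{fhrIOError}{file could not be read or written}
#' }
#' Warnings inherit from `fhrWarning`.
NULL
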