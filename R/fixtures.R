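# Deterministic fixture generation.  The whole test surface runs without
# downloads: records are drawn from templated pools (names, ORCID-shaped
# URIs, identifiers.org taxon URIs) and sequences are seeded ACGT strings.
# Same seed + same parameters => identical values on one R installation
# (Mersenne-Twister); cross-implementation byte equality is not promised.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

.pools <- list(
  first = c("Ada", "Grace", "Rosalind", "Barbara", "Linus", "Margaret",
            "Frederick", "Nettie", "Esther", "David"),
  last = c("Lovelace", "Hopper", "Franklin", "McClintock", "Pauling",
           "Dayhoff", "Sanger", "Stevens", "Lederberg", "Molik"),
  genus = c("Carya", "Apis", "Danio", "Caenorhabditis", "Drosophila",
            "Arabidopsis", "Saccharomyces", "Anopheles"),
  species = c("illinoinensis", "mellifera", "rerio", "elegans",
              "melanogaster", "thaliana", "cerevisiae", "gambiae"),
  assembler = c("hifiasm 0.19.8", "Flye 2.9.2", "Canu 2.2", "SPAdes 3.15.5",
                "MaSuRCA 4.1.0"),
  instrument = c("PacBio Sequel IIe", "Oxford Nanopore PromethION 24",
                 "Illumina NovaSeq 6000", "PacBio Revio",
                 "Illumina MiSeq"),
  licence = c("CC0 1.0", "CC BY 4.0", "public domain",
              "Creative Commons 4.0")
)

randHex <- function(n) paste(sample(c(0:9, letters[1:6]), n, replace = TRUE),
                             collapse = "")

randPerson <- function() {
  list(
    name = paste(sample(.pools$first, 1L), sample(.pools$last, 1L)),
    uri = paste0("https://orcid.org/",
                 paste(vapply(1:4, function(i)
                   paste(sample(0:9, 4L, replace = TRUE), collapse = ""),
                   character(1)), collapse = "-"))
  )
}

#' Generate a deterministic FHR record
#'
#' `minimal` records carry exactly the nine required fields; `full` records
#' carry all twenty (nine required + eleven optional).  The generated
#' checksum field is syntactically valid but unbound to any file — inject a
#' real one with [injectChecksum()] after embedding.  The same seed always
#' yields the same record.
#'
#' @param seed Integer seed.
#' @param completeness `"minimal"` or `"full"`.
#' @return A valid [FhrRecord-class].
#' @examples
#' length(fhrFields(generateFhrRecord(1, "minimal")))
#' length(fhrFields(generateFhrRecord(1, "full")))
#' @export
generateFhrRecord <- function(seed, completeness = c("minimal", "full")) {
  completeness <- match.arg(completeness)
  withSeed(seed, {
    genus <- sample(.pools$genus, 1L)
    species <- sample(.pools$species, 1L)
    taxonName <- paste(genus, species)
    genome <- paste0(tolower(substr(genus, 1L, 1L)), substr(species, 1L, 3L),
                     sample(1:9, 1L))
    f <- list(
      schema = "https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json",
      schemaVersion = 1L,
      genome = genome,
      taxon = list(
        name = taxonName,
        uri = paste0("https://identifiers.org/taxonomy:",
                     sample(1000:999999, 1L))
      ),
      version = paste0(sample(1:9, 1L), ".", sample(0:9, 1L)),
      assemblyAuthor = replicate(sample(1:2, 1L), randPerson(),
                                 simplify = FALSE),
      metadataAuthor = replicate(sample(1:2, 1L), randPerson(),
                                 simplify = FALSE),
      dateCreated = format(as.Date("2015-01-01") + sample(0:3650, 1L),
                           "%Y-%m-%d"),
      checksum = paste0("md5:", randHex(32L))
    )
    if (completeness == "full") {
      acc <- sprintf("SAMN%08d", sample(1:99999999, 1L))
      f <- c(f, list(
        accessionID = list(
          name = paste0("BioSample:", acc),
          uri = paste0("https://identifiers.org/biosample/", acc)
        ),
        assemblySoftware = sample(.pools$assembler, 1L),
        documentation = paste("Assembly of", taxonName,
                              "generated for fixture testing."),
        funding = as.list(sprintf("Project number %07d",
                                  sample(1:9999999, sample(1:2, 1L)))),
        genomeSynonym = as.list(paste0(genome, "_syn",
                                       seq_len(sample(1:2, 1L)))),
        identifier = list(paste0("biosample:", acc)),
        instrument = as.list(sample(.pools$instrument, sample(1:2, 1L))),
        reuseConditions = sample(.pools$licence, 1L),
        relatedLink = list(paste0("https://example.org/genomes/", genome)),
        scholarlyArticle = list(sprintf("https://doi.org/10.%04d/%s",
                                        sample(1000:9999, 1L), genome)),
        voucherSpecimen = sprintf(
          "Located in Freezer %d, Drawer %d at Example Organisation",
          sample(1:40, 1L), sample(1:200, 1L))
      ))
    }
    FhrRecord(f)
  })
}

#' Generate a deterministic FASTA document
#'
#' Sequences are uniform random ACGT wrapped at 60 columns — a structural
#' stand-in for genome data, with no biological realism intended.
#'
#' @param seed Integer seed.
#' @param nRecords Number of sequence records.
#' @param lengthRange Two-element integer vector; sequence lengths are drawn
#'   uniformly from this range.
#' @param newline `"\n"` (default) or `"\r\n"`.
#' @param comments Number of plain `;` comment lines to place at the top.
#' @return A [FastaDocument-class].
#' @examples
#' generateFasta(1, nRecords = 2)
#' @export
generateFasta <- function(seed, nRecords = 2L, lengthRange = c(60L, 240L),
                          newline = "\n", comments = 0L) {
  withSeed(seed, {
    lines <- character()
    if (comments > 0L)
      lines <- sprintf("; fixture comment %d", seq_len(comments))
    for (i in seq_len(nRecords)) {
      len <- sample(lengthRange[1L]:lengthRange[2L], 1L)
      seqchr <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
      wrapped <- substring(seqchr, seq(1L, len, 60L),
                           pmin(seq(1L, len, 60L) + 59L, len))
      lines <- c(lines, sprintf(">contig%d length=%d", i, len), wrapped)
    }
    new("FastaDocument", lines = lines, newline = newline,
        eofNewline = TRUE)
  })
}

.defectKinds <- c("missing_required", "bad_date", "bad_taxon_host",
                  "bad_checksum_format", "scalar_where_list_forbidden",
                  "unknown_key")

#' Introduce a single known defect into a record
#'
#' Used to exercise the validator: each defect kind produces exactly one
#' issue at a predictable field path.
#'
#' @param record An [FhrRecord-class].
#' @param kind One of `missing_required` (drop a required field),
#'   `bad_date` (day-first date), `bad_taxon_host` (taxon URI outside the
#'   identifiers.org/bioregistry.io registries), `bad_checksum_format`
#'   (non-hex digest), `scalar_where_list_forbidden` (bare string where a
#'   name/uri mapping is required), `unknown_key` (extra field; yields a
#'   warning, not an error).
#' @param path Field to target for `missing_required` (default
#'   `/dateCreated`) or the key name for `unknown_key` (default
#'   `/favouriteColour`).
#' @return The defective [FhrRecord-class].
#' @examples
#' bad <- applyDefect(generateFhrRecord(1, "minimal"), "bad_date")
#' fhrIssues(validateFhr(bad))
#' @export
applyDefect <- function(record, kind, path = NULL) {
  kind <- match.arg(kind, .defectKinds)
  f <- fhrFields(record)
  key <- if (!is.null(path)) sub("^/", "", path) else NULL
  f <- switch(kind,
    missing_required = {
      key <- if (is.null(key)) "dateCreated" else key
      f[setdiff(names(f), key)]
    },
    bad_date = { f$dateCreated <- "21-03-2022"; f },
    bad_taxon_host = {
      f$taxon$uri <- "https://example.com/taxonomy:9606"; f
    },
    bad_checksum_format = { f$checksum <- "md5:notahexdigest"; f },
    scalar_where_list_forbidden = { f$taxon <- "a bare string"; f },
    unknown_key = {
      key <- if (is.null(key)) "favouriteColour" else key
      f[[key]] <- "blue"
      f
    }
  )
  FhrRecord(f)
}

#' Write a deterministic corpus of paired FASTA and sidecar files
#'
#' For each genome `i`, writes `genomeNN.fasta` and a matching
#' `genomeNN.fhr.yaml` sidecar (minimal and full records alternate).
#'
#' @param dir Output directory (created if needed).
#' @param n Number of genomes.
#' @param seed Base seed; genome `i` uses `seed + i`.
#' @return Character vector of the paths written, invisibly.
#' @export
writeFixtureCorpus <- function(dir, n = 3L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_len(n)) {
    rec <- generateFhrRecord(seed + i,
                             if (i %% 2L == 0L) "full" else "minimal")
    doc <- generateFasta(seed + i, comments = i %% 2L)
    base <- file.path(dir, sprintf("genome%02d", i))
    writeFasta(doc, paste0(base, ".fasta"))
    writeFhr(rec, paste0(base, ".fhr.yaml"))
    paths <- c(paths, paste0(base, ".fasta"), paste0(base, ".fhr.yaml"))
  }
  invisible(paths)
}
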