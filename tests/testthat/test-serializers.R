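test_that("format detection uses longest-suffix matching", {
  expect_identical(detectFhrFormat("mouse.fhr.yaml"), "yaml")
  expect_identical(detectFhrFormat("mouse.fhr.json"), "json")
  expect_identical(detectFhrFormat("mouse.fhr.html"), "html")
  expect_identical(detectFhrFormat("mouse.fa"), "fasta")
  expect_identical(detectFhrFormat("mouse.fhr.fasta"), "fasta")
  expect_identical(detectFhrFormat("MOUSE.FHR.YAML"), "yaml")
  expect_error(detectFhrFormat("mouse.txt"), class = "fhrUnsupportedFormat")
  expect_error(detectFhrFormat(""), class = "fhrUnsupportedFormat")
})

test_that("the worked-example YAML sidecar parses to the expected values", {
  path <- withr::local_tempfile(fileext = ".fhr.yaml")
  writeLines(workedExampleYaml(), path)
  rec <- canonicalizeFhr(readFhr(path))
  expect_identical(fhrField(rec, "dateCreated"), "2022-03-21")
  expect_identical(fhrField(rec, "version"), "2.3")
  expect_identical(fhrField(rec, "schemaVersion"), 1L)
  expect_identical(fhrField(rec, "genome"), "Example species")
  expect_true(isValid(validateFhr(rec, mode = "strict")))
})

test_that("every ordered pair of sidecar formats round-trips to the same canonical form", {
  d <- withr::local_tempdir()
  formats <- c("yaml", "json", "html")
  for (seed in c(2L, 3L)) {
    rec <- generateFhrRecord(seed, if (seed %% 2L) "minimal" else "full")
    can <- canonicalizeFhr(rec)
    for (a in formats) for (b in formats) {
      pa <- file.path(d, paste0("g.fhr.", a))
      pb <- file.path(d, paste0("g.fhr.", b))
      writeFhr(rec, pa, checkSidecar = FALSE)
      back <- readFhr(pa)
      writeFhr(back, pb, checkSidecar = FALSE)
      expect_identical(fhrFields(canonicalizeFhr(readFhr(pb))),
                       fhrFields(can), info = paste(seed, a, b))
    }
  }
})

test_that("canonical emission is deterministic", {
  d <- withr::local_tempdir()
  rec <- generateFhrRecord(9L, "full")
  shuffled <- FhrRecord(fhrFields(rec)[rev(names(fhrFields(rec)))])
  for (fmt in c("yaml", "json", "html")) {
    p1 <- file.path(d, paste0("a.fhr.", fmt))
    p2 <- file.path(d, paste0("b.fhr.", fmt))
    writeFhr(rec, p1, checkSidecar = FALSE)
    writeFhr(shuffled, p2, checkSidecar = FALSE)
    expect_identical(fileBytes(p1), fileBytes(p2), info = fmt)
  }
})

test_that("JSON output is conforming JSON with typed values and real arrays", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.fhr.json")
  writeFhr(workedExampleRecord(), p, checkSidecar = FALSE)
  parsed <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(parsed$schemaVersion, 1L)
  expect_identical(parsed$genome, "Example species")
  expect_true(is.list(parsed$assemblyAuthor))
  expect_identical(parsed$assemblyAuthor[[1L]]$name, "Jane Doe")
})

test_that("HTML output is a Microdata document keyed by the record's schema URI", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.fhr.html")
  writeFhr(workedExampleRecord(), p, checkSidecar = FALSE)
  html <- xml2::read_html(p)
  item <- xml2::xml_find_first(html, "//*[@itemscope and @itemtype]")
  expect_identical(xml2::xml_attr(item, "itemtype"),
                   fhrField(workedExampleRecord(), "schema"))
  genome <- xml2::xml_find_first(html, "//*[@itemprop='genome']")
  expect_identical(xml2::xml_text(genome), "Example species")
  # and it reads back canonically equal
  expect_true(fhrEqual(readFhr(p), workedExampleRecord()))
})

test_that("HTML special characters survive the round trip", {
  rec <- withFields(workedExampleRecord(),
                    documentation = "a <b> & \"c\" assembly",
                    genome = "Tom & Jerry")
  d <- withr::local_tempdir()
  p <- file.path(d, "g.fhr.html")
  writeFhr(rec, p, checkSidecar = FALSE)
  expect_true(fhrEqual(readFhr(p), rec))
})

test_that("unparseable sidecars raise classed errors", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "e.fhr.yaml")
  file.create(empty)
  expect_error(readFhr(empty), class = "fhrHeaderParseError")

  anchors <- file.path(d, "a.fhr.yaml")
  writeLines(c("genome: &g name", "genomeSynonym: *g"), anchors)
  expect_error(readFhr(anchors), class = "fhrHeaderParseError")

  noitem <- file.path(d, "n.fhr.html")
  writeLines("<html><body><p>no item</p></body></html>", noitem)
  expect_error(readFhr(noitem), class = "fhrMicrodataError")

  badjson <- file.path(d, "b.fhr.json")
  writeLines("{\"genome\": ", badjson)
  expect_error(readFhr(badjson), class = "fhrHeaderParseError")

  expect_error(readFhr(file.path(d, "missing.fhr.yaml")),
               class = "fhrIOError")
})

test_that("convert composes reads and canonical writes", {
  d <- withr::local_tempdir()
  y1 <- file.path(d, "g.fhr.yaml")
  j <- file.path(d, "g.fhr.json")
  y2 <- file.path(d, "g2.fhr.yaml")
  writeLines(workedExampleYaml(), y1)
  convertFhr(y1, j)
  convertFhr(j, y2)
  # canonical emission: converting back and forth reaches a fixed point
  y3 <- file.path(d, "g3.fhr.yaml")
  convertFhr(y2, file.path(d, "g2.fhr.json"))
  convertFhr(file.path(d, "g2.fhr.json"), y3)
  expect_identical(fileBytes(y2), fileBytes(y3))

  # embedded FASTA -> sidecar carries all nine required keys
  fa <- file.path(d, "g.fhr.fasta")
  writeFasta(injectChecksum(embedFhr(workedExampleRecord(), generateFasta(1))), fa)
  out <- file.path(d, "fromfa.fhr.yaml")
  convertFhr(fa, out)
  rec <- readFhr(out)
  expect_true(all(requiredFhrFields() %in% names(fhrFields(rec))))

  # metadata alone cannot become FASTA
  expect_error(convertFhr(y1, file.path(d, "out.fasta")),
               class = "fhrRefusedConversion")
})

test_that("a sidecar written without an adjacent FASTA warns about decoupling", {
  d <- withr::local_tempdir()
  expect_warning(writeFhr(workedExampleRecord(), file.path(d, "lonely.fhr.yaml")),
                 class = "fhrSidecarNaming")
  # with the companion present, no warning
  writeFasta(generateFasta(1), file.path(d, "paired.fasta"))
  expect_no_warning(writeFhr(workedExampleRecord(), file.path(d, "paired.fhr.yaml")))
})
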