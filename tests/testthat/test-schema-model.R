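test_that("the field registry exposes nine required and eleven optional fields", {
  req <- requiredFhrFields()
  opt <- optionalFhrFields()
  expect_length(req, 9L)
  expect_identical(req[1L], "schema")
  expect_identical(req[9L], "checksum")
  expect_identical(req, c("schema", "schemaVersion", "genome", "taxon",
                          "version", "assemblyAuthor", "metadataAuthor",
                          "dateCreated", "checksum"))
  expect_length(opt, 11L)
  expect_true("voucherSpecimen" %in% opt)
  expect_length(intersect(req, opt), 0L)
  expect_length(union(req, opt), 20L)
  expect_false(anyDuplicated(c(req, opt)) > 0L)
})

test_that("the bundled JSON schema mirrors the field registry", {
  sch <- jsonlite::fromJSON(fhrSchemaPath())
  expect_identical(sch$required, requiredFhrFields())
  expect_setequal(names(sch$properties),
                  c(requiredFhrFields(), optionalFhrFields()))
})

test_that("a complete worked-example record validates with zero errors", {
  rep <- validateFhr(workedExampleRecord(), mode = "strict")
  expect_true(isValid(rep))
  expect_identical(nrow(fhrIssues(rep)), 0L)
})

test_that("removing any one required field invalidates the record with exactly one error", {
  rec <- workedExampleRecord()
  for (field in requiredFhrFields()) {
    rep <- validateFhr(without(rec, field), mode = "strict")
    iss <- fhrIssues(rep)
    expect_false(isValid(rep), info = field)
    expect_identical(sum(iss$severity == "error"), 1L, info = field)
    expect_identical(iss$path[iss$severity == "error"], paste0("/", field))
  }
})

test_that("a missing checksum is tolerated only in pre_injection mode", {
  rec <- without(workedExampleRecord(), "checksum")
  expect_false(isValid(validateFhr(rec, mode = "strict")))
  expect_true(isValid(validateFhr(rec, mode = "pre_injection")))
})

test_that("the taxon URI must live in a public identifier registry", {
  bad <- withFields(workedExampleRecord(),
                    taxon = list(name = "Example species",
                                 uri = "https://example.com/taxonomy:0000"))
  iss <- fhrIssues(validateFhr(bad))
  expect_identical(iss$path[iss$severity == "error"], "/taxon/uri")
  expect_identical(iss$code[iss$severity == "error"], "BAD_TAXON_HOST")

  for (host in c("identifiers.org", "bioregistry.io")) {
    ok <- withFields(workedExampleRecord(),
                     taxon = list(name = "x",
                                  uri = sprintf("https://%s/taxonomy:9606",
                                                host)))
    expect_true(isValid(validateFhr(ok)), info = host)
  }
})

test_that("dates must be ISO-8601 calendar dates", {
  bad <- withFields(workedExampleRecord(), dateCreated = "21-03-2022")
  iss <- fhrIssues(validateFhr(bad))
  expect_identical(iss$path, "/dateCreated")
  expect_identical(iss$code, "BAD_DATE")
  expect_identical(iss$severity, "error")

  # an impossible calendar date is rejected even though the shape matches
  expect_false(isValid(validateFhr(
    withFields(workedExampleRecord(), dateCreated = "2022-02-30"))))

  # a typeset en dash is transliterated with a warning, not an error
  endash <- withFields(workedExampleRecord(), dateCreated = "2022–03-21")
  rep <- validateFhr(endash)
  expect_true(isValid(rep))
  expect_identical(fhrIssues(rep)$code, "DATE_EN_DASH")
})

test_that("checksum wire form is <algorithm>:<lowercase hex> with correct digest length", {
  ok <- c(paste0("md5:", strrep("a", 32)), paste0("sha1:", strrep("0", 40)),
          paste0("sha256:", strrep("f", 64)))
  for (cs in ok)
    expect_true(isValid(validateFhr(withFields(workedExampleRecord(),
                                               checksum = cs))), info = cs)
  bad <- c("md5:tooshort", paste0("md5:", strrep("A", 32)),
           paste0("crc32:", strrep("a", 8)), "a3d5d9146c",
           paste0("sha1:", strrep("a", 32)))
  for (cs in bad) {
    iss <- fhrIssues(validateFhr(withFields(workedExampleRecord(), checksum = cs)))
    expect_identical(iss$code, "BAD_CHECKSUM_FORMAT", info = cs)
  }
})

test_that("unknown keys warn but never invalidate", {
  rec <- withFields(workedExampleRecord(), favouriteColour = "blue")
  rep <- validateFhr(rec, mode = "strict")
  expect_true(isValid(rep))
  iss <- fhrIssues(rep)
  expect_identical(iss$severity, "warning")
  expect_identical(iss$path, "/favouriteColour")
  expect_identical(iss$code, "UNKNOWN_FIELD")
})

test_that("author lists accept a single name/uri pair and require non-empty names", {
  single <- withFields(workedExampleRecord(),
                       assemblyAuthor = list(name = "Solo Author"))
  expect_true(isValid(validateFhr(single)))
  can <- canonicalizeFhr(single)
  expect_identical(fhrField(can, "assemblyAuthor"),
                   list(list(name = "Solo Author")))

  noname <- withFields(workedExampleRecord(),
                       metadataAuthor = list(list(uri = "https://orcid.org/0000-0001-0000-0000")))
  iss <- fhrIssues(validateFhr(noname))
  expect_identical(iss$path[iss$severity == "error"], "/metadataAuthor/1/name")
})

test_that("canonicalization is idempotent and insensitive to key order", {
  for (seed in c(1L, 7L, 23L)) {
    rec <- generateFhrRecord(seed, "full")
    can1 <- canonicalizeFhr(rec)
    expect_identical(fhrFields(canonicalizeFhr(can1)), fhrFields(can1))
    for (rep_i in 1:5) {
      shuffled <- FhrRecord(fhrFields(rec)[sample(length(fhrFields(rec)))])
      can2 <- canonicalizeFhr(shuffled)
      expect_identical(fhrFields(can2), fhrFields(can1))
    }
  }
})

test_that("canonicalization orders required-first then optional alphabetically and normalizes values", {
  rec <- generateFhrRecord(11L, "full")
  f <- fhrFields(rec)
  messy <- FhrRecord(modifyList(
    f[rev(names(f))],
    list(schemaVersion = "1", checksum = paste0("MD5:", strrep("b", 32)),
         genome = "  padded  ")))
  can <- canonicalizeFhr(messy)
  expect_identical(names(fhrFields(can)),
                   c(requiredFhrFields(), optionalFhrFields()))
  expect_identical(fhrField(can, "schemaVersion"), 1L)
  expect_identical(fhrField(can, "checksum"), paste0("md5:", strrep("b", 32)))
  expect_identical(fhrField(can, "genome"), "padded")
})

test_that("canonicalization refuses records with validation errors", {
  expect_error(canonicalizeFhr(withFields(workedExampleRecord(),
                                          dateCreated = "not a date")),
               class = "fhrInvalidRecord")
})

test_that("validation reports problems instead of throwing", {
  expect_s4_class(validateFhr(list()), "FhrValidationReport")
  expect_false(isValid(validateFhr(list())))
  expect_s4_class(validateFhr(list(taxon = "scalar", schemaVersion = "x")),
                  "FhrValidationReport")
})
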