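test_that("drug names are folded, trimmed and synonym-mapped", {
  syn <- c(crysvita = "burosumab")
  expect_equal(normalize_drug_name("CRYSVITA ", syn), "burosumab")
  expect_equal(normalize_drug_name("burosumab", syn), "burosumab")
  expect_equal(normalize_drug_name("  BurOSUmab\t", syn), "burosumab")
  expect_equal(normalize_drug_name("Vitamin  D", NULL), "vitamin d")
  # idempotence
  x <- normalize_drug_name(c("CRYSVITA", "Aspirin"), syn)
  expect_equal(normalize_drug_name(x, syn), x)
})

test_that("deduplication keeps the highest version, latest quarter on ties", {
  st <- make_store(
    list(id = "A", v = 1, pts = "pt_001"),
    list(id = "A", v = 2, pts = "pt_002", drugs = c(burosumab = "PS")),
    list(id = "B", v = 1, pts = "pt_003")
  )
  dd <- deduplicate(st)
  expect_equal(dd$reports$case_id, c("A", "B"))
  expect_equal(dd$reports$version[1], 2L)
  expect_equal(dd$reports$reactions[[1]], "pt_002")

  # version tie -> later quarter wins
  st2 <- make_store(
    list(id = "A", v = 1, yq = c(2019, 2), pts = "pt_001"),
    list(id = "A2", v = 1, yq = c(2020, 4), pts = "pt_002")
  )
  st2$reports$case_id <- c("A", "A") # force a same-version duplicate
  dd2 <- deduplicate(st2)
  expect_equal(dd2$reports$year, 2020L)

  # idempotence on unique stores and on its own output
  st3 <- make_store(list(id = "X", pts = "pt_001"), list(id = "Y", pts = "pt_002"))
  expect_equal(deduplicate(st3)$reports, st3$reports)
  expect_equal(deduplicate(deduplicate(st))$reports, dd$reports)
})

test_that("primary-suspect filter keeps exactly PS reports for the drug", {
  st <- make_store(
    list(id = "1", drugs = c(burosumab = "PS"), pts = "pt_001"),
    list(id = "2", drugs = c(burosumab = "SS", other = "PS"), pts = "pt_001"),
    list(id = "3", drugs = c(other = "PS"), pts = "pt_002"),
    list(id = "4", drugs = c(burosumab = "PS", other = "C"), pts = "pt_003"),
    list(id = "5", drugs = c(burosumab = "C"), pts = "pt_001")
  )
  kept <- filter_primary_suspect(st, "burosumab")
  expect_equal(kept$reports$case_id, c("1", "4"))
  expect_true(all(kept$reports$case_id %in% st$reports$case_id))
  # empty store passes through
  empty <- filter_primary_suspect(st, "no_such_drug")
  expect_equal(n_reports(filter_primary_suspect(empty, "burosumab")), 0)
})

test_that("quarter window is inclusive on both ends", {
  st <- make_store(
    list(id = "pre", yq = c(2017, 4), pts = "pt_001"),
    list(id = "lo", yq = c(2018, 1), pts = "pt_001"),
    list(id = "mid", yq = c(2021, 2), pts = "pt_001"),
    list(id = "hi", yq = c(2024, 3), pts = "pt_001"),
    list(id = "post", yq = c(2024, 4), pts = "pt_001")
  )
  w <- filter_period(st, c(2018, 1), c(2024, 3))
  expect_equal(w$reports$case_id, c("lo", "mid", "hi"))
  expect_error(filter_period(st, c(2024, 1), c(2018, 1)), "argument error")
})

test_that("period and primary-suspect filters commute and never invent reports", {
  st <- generate_reports(tiny_sim_config(seed = 21, n_reports = 500))
  a <- filter_period(
    filter_primary_suspect(st, "drug_002"),
    c(2019, 1), c(2022, 4)
  )
  b <- filter_primary_suspect(
    filter_period(st, c(2019, 1), c(2022, 4)),
    "drug_002"
  )
  expect_equal(a$reports, b$reports)
  expect_lte(n_reports(a), n_reports(st))
  key_in <- paste(st$reports$case_id, st$reports$version)
  key_out <- paste(a$reports$case_id, a$reports$version)
  expect_true(all(key_out %in% key_in))
})

test_that("the hand-written FAERS fixture ingests field-for-field", {
  dir <- system.file("extdata", "faers_mini", package = "pvsignal")
  syn <- read_synonyms(system.file("extdata", "synonyms.tsv", package = "pvsignal"))
  expect_warning(st <- read_faers_tables(dir, synonyms = syn), "without reaction rows")
  r <- st$reports
  expect_equal(nrow(r), 3) # CASE004 has no reactions and is dropped
  expect_equal(r$case_id, c("CASE001", "CASE002", "CASE003"))
  expect_equal(r$year, c(2018L, 2019L, 2024L))
  expect_equal(r$quarter, c(1L, 3L, 3L))
  expect_equal(r$sex, c("female", "unknown", "male"))
  expect_equal(r$age_group, c("under18", "unknown", "18plus"))
  expect_equal(r$country, c("United States", "unknown", "United Kingdom"))
  expect_equal(r$drug_names[[1]], c("burosumab", "calcitriol")) # CRYSVITA mapped
  expect_equal(r$drug_roles[[1]], c("PS", "C"))
  expect_equal(r$reactions[[1]], c("injection site pain", "pyrexia"))
  expect_equal(r$outcomes[[1]], "hospitalization")
  expect_equal(r$indication[1], "hereditary hypophosphataemic rickets")
  expect_equal(r$version[3], 2L)
  # the SS-only report is excluded by the PS filter
  expect_equal(n_reports(filter_primary_suspect(st, "burosumab")), 2)
})

test_that("FAERS reader guards mandatory tables and malformed rows", {
  dir <- withr::local_tempdir()
  st <- generate_reports(tiny_sim_config(seed = 8, n_reports = 50))
  paths <- write_faers_tables(st, dir)
  expect_error(
    read_faers_tables(paths[c("DRUG", "REAC")]),
    "mandatory table DEMO"
  )
  # corrupt one DEMO date -> logged skip, not an error
  demo <- readLines(paths["DEMO"])
  demo[2] <- sub("20[0-9]{6}", "notadate", demo[2])
  writeLines(demo, paths["DEMO"])
  expect_warning(st2 <- read_faers_tables(dir), "malformed")
  expect_equal(n_reports(st2), n_reports(st) - 1)
  # unknown role codes downgrade to concomitant with a warning
  drug <- readLines(paths["DRUG"])
  drug[2] <- sub("\\$(PS|SS|C|I)$", "$XX", drug[2])
  writeLines(drug, paths["DRUG"])
  w <- capture_warnings(read_faers_tables(dir)) # malformed-date warning persists
  expect_true(any(grepl("role code", w)))
})
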