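test_that("read_faers_tables loads the fixture trio and counts rejects", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo_lines = c("1-1$1$1$63$YR$F", "2-1$2$1$720$MON$M", "3-1$3$1$$$"),
    drug_lines = c("1-1$Avastin", "1-1$ omeprazole 20mg ", "2-1$BEVACIZUMAB",
                   "2-1$ASPIRIN", "3-1$IBUPROFEN"),
    reac_lines = c("1-1$Hypertension", "1-1$NAUSEA", "2-1$RASH",
                   "3-1$headache"))
  syn <- c(`AVASTIN` = "BEVACIZUMAB", `OMEPRAZOLE 20MG` = "OMEPRAZOLE")
  raw <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"],
                           synonyms = syn)
  expect_equal(nrow(raw$demo_rows), 3)
  expect_equal(nrow(raw$drug_rows), 5)
  expect_equal(nrow(raw$reac_rows), 4)
  expect_length(raw$rejects, 0)
  # age unit conversion and sex normalization
  expect_equal(raw$demo_rows$age_years, c(63, 60, NA))
  expect_equal(raw$demo_rows$sex, c("F", "M", "unknown"))
  # synonym mapping and canonicalization applied at read time
  expect_setequal(raw$drug_rows$drug[raw$drug_rows$report_id == "1-1"],
                  c("BEVACIZUMAB", "OMEPRAZOLE"))
  expect_true("HYPERTENSION" %in% raw$reac_rows$pt)
})

test_that("malformed rows are recorded as rejects, not dropped silently", {
  dir <- withr::local_tempdir()
  good <- sprintf("%d-1$%d$1$50$YR$F", 1:9, 1:9)
  paths <- write_faers_fixture(dir, demo_lines = c(good[1:5], "oops$only$three",
                                                   good[6:9]),
                               drug_lines = sprintf("%d-1$DRUGX", 1:9),
                               reac_lines = sprintf("%d-1$NAUSEA", 1:9))
  expect_message(raw <- read_faers_tables(paths["demo"], paths["drug"],
                                          paths["reac"]),
                 "1 malformed")
  expect_equal(nrow(raw$demo_rows), 9)
  expect_equal(raw$rejects, "oops$only$three")
})

test_that("empty DRUG file loads with a warning; missing file is fatal", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, demo_lines = "1-1$1$1$50$YR$F",
                               drug_lines = character(),
                               reac_lines = "1-1$NAUSEA")
  expect_warning(raw <- read_faers_tables(paths["demo"], paths["drug"],
                                          paths["reac"]),
                 "DRUG table is empty")
  expect_equal(nrow(raw$drug_rows), 0)
  expect_error(read_faers_tables(file.path(dir, "nope.txt"), paths["drug"],
                                 paths["reac"]),
               "not found")
})

test_that("deduplicate keeps the latest version only, unioning its rows", {
  raw <- make_raw(case_id = c("100", "100", "200"),
                  version = c(1, 2, 1),
                  drugs = list(c("X", "Y"), "X", "Z"),
                  reactions = list("NAUSEA", c("RASH", "RASH"), "NAUSEA"))
  reports <- deduplicate(raw)
  expect_equal(nrow(reports), 2)
  r100 <- reports[reports$case_id == "100", ]
  # version 2 lists drug X only; version 1's Y must not leak in
  expect_equal(r100$drugs[[1]], "X")
  expect_equal(r100$reactions[[1]], "RASH")  # de-duplicated within version
})

test_that("deduplicate is idempotent and preserves distinct case count", {
  cfg <- report_gen_config(n_cases = 500, duplication_rate = 0.3, seed = 42)
  g <- gen_reports(cfg)
  reports <- deduplicate(g$raw)
  expect_equal(nrow(reports), length(unique(g$raw$demo_rows$case_id)))
  expect_equal(nrow(reports), 500)
  # idempotence: rebuilding a raw set from the deduplicated reports and
  # deduplicating again changes nothing
  raw2 <- make_raw(case_id = reports$case_id, version = rep(1, nrow(reports)),
                   drugs = reports$drugs, reactions = reports$reactions,
                   age = reports$age_years, sex = reports$sex)
  reports2 <- deduplicate(raw2)
  data.table::setkey(reports2, case_id)
  sorted <- data.table::copy(reports)
  data.table::setkey(sorted, case_id)
  expect_equal(lapply(reports2$drugs, sort), lapply(sorted$drugs, sort))
  expect_equal(reports2$age_years, sorted$age_years)
})

test_that("version ties break towards the later file row, with a warning", {
  raw <- make_raw(case_id = c("7", "7"), version = c(3, 3),
                  drugs = list("FIRST", "SECOND"),
                  reactions = list("NAUSEA", "NAUSEA"))
  expect_warning(reports <- deduplicate(raw), "tied version")
  expect_equal(reports$drugs[[1]], "SECOND")
})

test_that("normalize_drug_name trims, uppercases and maps synonyms", {
  expect_equal(normalize_drug_name(" omeprazole 20mg ",
                                   c(`OMEPRAZOLE 20MG` = "OMEPRAZOLE")),
               "OMEPRAZOLE")
  expect_equal(normalize_drug_name("BEVACIZUMAB"), "BEVACIZUMAB")
  expect_equal(normalize_drug_name("Avastin", c(AVASTIN = "BEVACIZUMAB")),
               "BEVACIZUMAB")
  expect_error(normalize_drug_name("  "), "empty")
})

test_that("has_event is an any-match over the term set and monotone in it", {
  reports <- make_reports(drugs = list("A", "A", "A"),
                          reactions = list("HYPERTENSION", "NAUSEA",
                                           c("BLOOD PRESSURE INCREASED", "NAUSEA")))
  terms <- default_hypertension_terms()
  expect_equal(has_event(reports, terms), c(TRUE, FALSE, TRUE))
  # monotonicity: adding terms never flips TRUE -> FALSE
  set.seed(11)
  for (i in 1:20) {
    base_terms <- sample(c("T1", "T2", "T3", "T4"), 2)
    bigger <- c(base_terms, "T5", sample(c("T6", "T7"), 1))
    reacts <- replicate(15, sample(paste0("T", 1:8), sample(1:3, 1)),
                        simplify = FALSE)
    rs <- make_reports(drugs = rep(list("A"), 15), reactions = reacts)
    expect_true(all(has_event(rs, base_terms) <= has_event(rs, bigger)))
  }
})

test_that("case-report round trip through the canonical table is lossless", {
  cfg <- report_gen_config(n_cases = 200, seed = 9,
                           comedications = data.frame(
                             name = "OMEPRAZOLE", prevalence = 0.3,
                             or_within_base = 0.5))
  reports <- deduplicate(gen_reports(cfg)$raw)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_case_reports(reports, path)
  back <- read_case_reports(path)
  expect_equal(back$case_id, reports$case_id)
  expect_equal(back$age_years, reports$age_years)
  expect_equal(back$sex, reports$sex)
  expect_equal(back$drugs, reports$drugs)
  expect_equal(back$reactions, reports$reactions)
})

test_that("term sets load from text, normalize and reject empties", {
  ts <- default_hypertension_terms()
  expect_s3_class(ts, "event_term_set")
  expect_length(ts$terms, 10)
  expect_error(event_term_set(character()), "empty")
  path <- withr::local_tempfile(lines = c("# comment", " hypertension ", "RASH"))
  ts2 <- load_term_set(path)
  expect_setequal(ts2$terms, c("HYPERTENSION", "RASH"))
})
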