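# Independent oracles and tiny fixture builders used across the suite.

# Brute-force two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins via dhyper and sum the probabilities of
# tables no more probable than the observed one. Independent of the
# package implementation (dhyper vs lchoose arithmetic); a 1e-7 relative
# factor absorbs floating-point ties on symmetric tables.
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  if (row1 == 0 || row2 == 0 || col1 == 0 || col1 == row1 + row2) return(1)
  k <- max(0, col1 - row2):min(col1, row1)
  probs <- dhyper(k, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumerating all rank assignments
# (combn over which positions belong to x). Feasible for nx+ny <= ~12.
oracle_mwu <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(all_u - mu) >= abs(U_obs - mu) - 1e-9)
}

# Minimal deduplicated report set from parallel vectors.
make_reports <- function(drugs, reactions, age = NA_real_, sex = "unknown") {
  n <- length(drugs)
  case_reports(case_id = as.character(seq_len(n)), age_years = age,
               sex = sex, drugs = drugs, reactions = reactions)
}

# Raw record set with one row per (case, version); drug/reac lists are
# given per version so deduplication behaviour can be exercised.
make_raw <- function(case_id, version, drugs, reactions, age = NA_real_,
                     sex = "unknown") {
  n <- length(case_id)
  # a report instance id unique per row, as in real extracts (so tied
  # versions of a case remain distinguishable)
  report_id <- paste0(case_id, "-", version, "-", seq_len(n))
  demo <- data.table::data.table(
    report_id = report_id, case_id = as.character(case_id),
    version = as.numeric(version),
    age_years = rep_len(as.numeric(age), n), sex = rep_len(sex, n))
  drug_rows <- data.table::data.table(
    report_id = rep.int(report_id, lengths(drugs)),
    drug = unlist(drugs, use.names = FALSE))
  reac_rows <- data.table::data.table(
    report_id = rep.int(report_id, lengths(reactions)),
    pt = unlist(reactions, use.names = FALSE))
  raw_record_set(demo, drug_rows, reac_rows)
}

# Write a tiny FAERS-dialect trio of files; returns their paths.
write_faers_fixture <- function(dir, demo_lines, drug_lines, reac_lines,
                                header = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hd <- function(cols) paste(cols, collapse = "$")
  paths <- c(demo = file.path(dir, "DEMO10Q3.txt"),
             drug = file.path(dir, "DRUG10Q3.txt"),
             reac = file.path(dir, "REAC10Q3.txt"))
  writeLines(c(if (header) hd(c("report_id", "case_id", "version", "age",
                                "age_cod", "sex")), demo_lines), paths["demo"])
  writeLines(c(if (header) hd(c("report_id", "drugname")), drug_lines),
             paths["drug"])
  writeLines(c(if (header) hd(c("report_id", "pt")), reac_lines),
             paths["reac"])
  paths
}
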