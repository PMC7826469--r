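#' Construct a deduplicated case-report set
#'
#' The central container of the package: one row per spontaneous report
#' case, with the drug list and reaction list stored as list columns of
#' canonical (uppercase, trimmed) strings. All signal statistics operate
#' on this container.
#'
#' @param case_id character vector, unique case identifiers.
#' @param age_years numeric vector, age in years (`NA` for missing).
#' @param sex character vector, one of `"M"`, `"F"`, `"unknown"`.
#' @param drugs list of character vectors: canonical drug names per case.
#' @param reactions list of character vectors: MedDRA-PT-level reaction
#'   terms per case.
#' @return A `case_reports` object (a `data.table` subclass).
#' @export
#' @examples
#' case_reports(
#'   case_id = c("1", "2"),
#'   age_years = c(63, NA),
#'   sex = c("F", "M"),
#'   drugs = list("BEVACIZUMAB", c("OMEPRAZOLE", "BEVACIZUMAB")),
#'   reactions = list("HYPERTENSION", "NAUSEA")
#' )
case_reports <- function(case_id, age_years = NA_real_, sex = "unknown",
                         drugs = list(), reactions = list()) {
  case_id <- as.character(case_id)
  .assert(!anyDuplicated(case_id), "case_id values must be unique")
  n <- length(case_id)
  .assert(length(drugs) == n && length(reactions) == n,
          "drugs and reactions must have one entry per case")
  sex <- as.character(sex)
  sex[!sex %in% c("M", "F")] <- "unknown"
  dt <- list(
    case_id = case_id,
    age_years = as.numeric(rep_len(age_years, n)),
    sex = rep_len(sex, n),
    drugs = drugs,
    reactions = reactions
  )
  data.table::setDT(dt)   # in place: the fixture set has millions of rows
  data.table::setattr(dt, "class", c("case_reports", class(dt)))
  dt[]
}

#' @export
print.case_reports <- function(x, ...) {
  cat(sprintf("<case_reports> %d cases\n", nrow(x)))
  NextMethod()
  invisible(x)
}

# logical vector: does each report list `drug` among its drugs?
.has_drug <- function(reports, drug) {
  fl <- .flat(reports[["drugs"]])
  hit <- fl$values == drug
  out <- logical(nrow(reports))
  out[fl$row[hit]] <- TRUE
  out
}

# logical vector: does each report list any reaction in `terms`?
.has_any_term <- function(reports, terms) {
  fl <- .flat(reports[["reactions"]])
  hit <- fl$values %chin% terms
  out <- logical(nrow(reports))
  out[fl$row[hit]] <- TRUE
  out
}

#' Test reports for an adverse event definition
#'
#' A report "has the event" when the intersection between its reaction
#' terms and the event term set is non-empty. Matching is exact on
#' canonical terms (uppercase, trimmed); adding terms to the set can only
#' turn `FALSE` into `TRUE`, never the reverse.
#'
#' @param reports a [case_reports] object.
#' @param terms an [event_term_set] (or plain character vector of PTs).
#' @return logical vector, one element per report.
#' @export
has_event <- function(reports, terms) {
  .assert(inherits(reports, "case_reports"), "reports must be a case_reports object")
  .has_any_term(reports, .term_values(terms))
}

#' Write / read the canonical report table
#'
#' The on-disk interchange format for deduplicated reports: one
#' tab-separated row per case with pipe-joined drug and reaction lists.
#' Every downstream stage can be run from this file alone.
#'
#' @param reports a [case_reports] object.
#' @param path file path.
#' @return `write_case_reports` returns `path` invisibly;
#'   `read_case_reports` returns a [case_reports] object.
#' @export
write_case_reports <- function(reports, path) {
  .assert(inherits(reports, "case_reports"), "reports must be a case_reports object")
  out <- data.table::data.table(
    case_id = reports$case_id,
    age_years = reports$age_years,
    sex = reports$sex,
    drugs = vapply(reports$drugs, paste, "", collapse = "|"),
    reactions = vapply(reports$reactions, paste, "", collapse = "|")
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_case_reports
#' @export
read_case_reports <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "case_id"),
                          na.strings = "NA")
  case_reports(
    case_id = dt$case_id,
    age_years = dt$age_years,
    sex = dt$sex,
    drugs = strsplit(dt$drugs, "|", fixed = TRUE),
    reactions = strsplit(dt$reactions, "|", fixed = TRUE)
  )
}
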