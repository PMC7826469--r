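#' FAERS ASCII dialect description
#'
#' Describes how the quarterly "$"-delimited DEMO/DRUG/REAC extract files
#' are laid out: delimiter, header presence, column order and the
#' age-unit conversion table. Each report instance carries a
#' `report_id` (unique per submitted version) and a `case_id` (shared by
#' all versions of the same case), mirroring the primaryid/caseid pair of
#' the public extracts.
#'
#' @param delim field delimiter (default `"$"`).
#' @param header logical, do files carry a header line?
#' @param demo_cols,drug_cols,reac_cols column names, in file order.
#' @param age_units named numeric vector mapping age-unit codes to the
#'   factor that converts the stored value into years. Codes not in the
#'   table yield missing age.
#' @return a list of class `faers_dialect`.
#' @export
faers_dialect <- function(delim = "$",
                          header = TRUE,
                          demo_cols = c("report_id", "case_id", "version",
                                        "age", "age_cod", "sex"),
                          drug_cols = c("report_id", "drugname"),
                          reac_cols = c("report_id", "pt"),
                          age_units = c(YR = 1, DEC = 10, MON = 1 / 12,
                                        WK = 1 / 52.1775, DY = 1 / 365.25,
                                        HR = 1 / 8766)) {
  structure(list(delim = delim, header = header, demo_cols = demo_cols,
                 drug_cols = drug_cols, reac_cols = reac_cols,
                 age_units = age_units),
            class = "faers_dialect")
}

# parse one delimited file; rows with the wrong field count go to rejects
.read_delim_strict <- function(path, cols, dialect) {
  .assert(file.exists(path), sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (dialect$header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty <- as.list(rep(list(character()), length(cols)))
    names(empty) <- cols
    return(list(rows = data.table::as.data.table(empty), rejects = character()))
  }
  parts <- strsplit(lines, dialect$delim, fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; accept n-1 fields only
  # when the line ends with the delimiter
  ends_delim <- endsWith(lines, dialect$delim)
  ok <- nf == length(cols) | (nf == length(cols) - 1L & ends_delim)
  rejects <- lines[!ok]
  parts <- parts[ok]
  mat <- vapply(parts, function(p) {
    length(p) <- length(cols)
    p
  }, character(length(cols)))
  rows <- data.table::as.data.table(t(matrix(mat, nrow = length(cols))))
  data.table::setnames(rows, cols)
  list(rows = rows, rejects = rejects)
}

#' Read FAERS-style DEMO/DRUG/REAC extract files
#'
#' Loads the three quarterly tables, converts ages to years via the
#' dialect's unit table, normalizes sex codes and applies a verbatim-to-
#' canonical drug synonym map. Malformed rows (wrong field count) are
#' counted and kept in a rejects report rather than silently dropped;
#' an empty DRUG or REAC file triggers a warning.
#'
#' @param demo,drug,reac paths to the three files. Each argument may be a
#'   vector of paths (multiple quarters), concatenated in order.
#' @param dialect a [faers_dialect].
#' @param synonyms optional synonym map from [load_synonym_map]; applied
#'   to verbatim drug names.
#' @return a `raw_record_set`: list with `demo_rows`, `drug_rows`,
#'   `reac_rows` data.tables and a `rejects` character vector of the
#'   malformed input lines.
#' @export
read_faers_tables <- function(demo, drug, reac, dialect = faers_dialect(),
                              synonyms = NULL) {
  rd <- function(paths, cols) {
    parsed <- lapply(paths, .read_delim_strict, cols = cols, dialect = dialect)
    list(rows = data.table::rbindlist(lapply(parsed, `[[`, "rows")),
         rejects = unlist(lapply(parsed, `[[`, "rejects"), use.names = FALSE))
  }
  d <- rd(demo, dialect$demo_cols)
  g <- rd(drug, dialect$drug_cols)
  r <- rd(reac, dialect$reac_cols)

  demo_rows <- d$rows
  demo_rows[, `:=`(
    version = suppressWarnings(as.numeric(version)),
    age_years = {
      fac <- dialect$age_units[age_cod]
      suppressWarnings(as.numeric(age)) * as.numeric(fac)
    },
    sex = data.table::fifelse(toupper(sex) %in% c("M", "F"), toupper(sex),
                              "unknown"),
    file_order = seq_len(.N)
  )]
  demo_rows[, c("age", "age_cod") := NULL]

  drug_rows <- g$rows
  if (nrow(drug_rows) == 0L) warning("DRUG table is empty")
  drug_rows[, drug := normalize_drug_name(drugname, synonyms)]
  drug_rows[, drugname := NULL]
  reac_rows <- r$rows
  if (nrow(reac_rows) == 0L) warning("REAC table is empty")
  reac_rows[, pt := .canon(pt)]

  raw <- structure(list(demo_rows = demo_rows, drug_rows = drug_rows,
                        reac_rows = reac_rows,
                        rejects = c(d$rejects, g$rejects, r$rejects)),
                   class = "raw_record_set")
  n_rej <- length(raw$rejects)
  if (n_rej) message(sprintf("%d malformed row(s) recorded in rejects", n_rej))
  raw
}

#' Construct a raw record set in memory
#'
#' Programmatic counterpart of [read_faers_tables], used by the synthetic
#' generator and in tests.
#'
#' @param demo_rows data.table with `report_id`, `case_id`, `version`,
#'   `age_years`, `sex` (and optionally `file_order`).
#' @param drug_rows data.table with `report_id`, `drug`.
#' @param reac_rows data.table with `report_id`, `pt`.
#' @return a `raw_record_set`.
#' @export
raw_record_set <- function(demo_rows, drug_rows, reac_rows) {
  demo_rows <- data.table::as.data.table(demo_rows)
  drug_rows <- data.table::as.data.table(drug_rows)
  reac_rows <- data.table::as.data.table(reac_rows)
  if (!"file_order" %in% names(demo_rows)) {
    demo_rows[, file_order := seq_len(.N)]
  }
  structure(list(demo_rows = demo_rows, drug_rows = drug_rows,
                 reac_rows = reac_rows, rejects = character()),
            class = "raw_record_set")
}

#' @export
print.raw_record_set <- function(x, ...) {
  cat(sprintf("<raw_record_set> %d demo rows, %d drug rows, %d reac rows, %d rejects\n",
              nrow(x$demo_rows), nrow(x$drug_rows), nrow(x$reac_rows),
              length(x$rejects)))
  invisible(x)
}

#' Deduplicate spontaneous reports, keeping the most recent case version
#'
#' Cases are re-reported over time; only the most recent version of each
#' case number is analyzed. For every `case_id` the row with the maximum
#' `version` is kept, and its drug/reaction rows (that version's only)
#' are unioned into canonical sets. Ties on the version key are broken by
#' file order (the later row wins) with a warning.
#'
#' @param raw a `raw_record_set`.
#' @return a [case_reports] object, one row per distinct `case_id`.
#' @export
deduplicate <- function(raw) {
  .assert(inherits(raw, "raw_record_set"), "raw must be a raw_record_set")
  demo <- raw$demo_rows
  .assert(nrow(demo) > 0L, "no demo rows to deduplicate")
  ord <- order(demo$case_id, demo$version, demo$file_order)
  demo_sorted <- demo[ord]
  keep <- !duplicated(demo_sorted$case_id, fromLast = TRUE)
  ties <- demo_sorted[, .N > 1L && anyDuplicated(version) > 0L, by = case_id]$V1
  if (any(ties)) {
    warning(sprintf("%d case(s) had tied version keys; kept the row latest in file order",
                    sum(ties)))
  }
  latest <- demo_sorted[keep]

  dg <- raw$drug_rows[latest, on = "report_id", nomatch = NULL]
  rc <- raw$reac_rows[latest, on = "report_id", nomatch = NULL]

  id <- latest$case_id
  drugs <- .split_by_case(unique(dg[, .(case_id, v = drug)]), id)
  reactions <- .split_by_case(unique(rc[, .(case_id, v = pt)]), id)
  case_reports(case_id = id, age_years = latest$age_years, sex = latest$sex,
               drugs = drugs, reactions = reactions)
}

# split long (case_id, v) pairs into a list aligned with `ids`
.split_by_case <- function(long, ids) {
  f <- factor(long$case_id, levels = ids)
  out <- split(long$v, f)
  names(out) <- NULL
  out
}

#' Normalize a verbatim drug name to its canonical active ingredient
#'
#' Uppercases and trims the verbatim string, then maps it through the
#' synonym table when an entry exists; otherwise the normalized verbatim
#' is returned unchanged. Matching downstream is exact on these canonical
#' names (no substring matching).
#'
#' @param verbatim character vector of drug strings as reported.
#' @param synonyms a synonym map from [load_synonym_map] (or a named
#'   character vector: `names` are normalized verbatims, values canonical
#'   names), or `NULL` for no mapping.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_drug_name(" Bevacizumab ")            # "BEVACIZUMAB"
#' normalize_drug_name("Avastin", c(AVASTIN = "BEVACIZUMAB"))
normalize_drug_name <- function(verbatim, synonyms = NULL) {
  x <- .canon(verbatim)
  .assert(all(nzchar(x)), "empty drug name cannot be normalized")
  if (!is.null(synonyms) && length(synonyms)) {
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

#' Event term sets
#'
#' An event definition is a named, non-empty set of MedDRA preferred
#' terms (for example a standardized query for hypertension). Because the
#' licensed dictionary cannot ship with the package, the term list is a
#' plain-text input, one term per line; the bundled default
#' `hypertension_smq.txt` is a 10-term stand-in for the hypertension SMQ
#' (code 20000147), overridable by the user.
#'
#' @param terms character vector of PT strings.
#' @param name identifier for the set.
#' @param path path to a one-term-per-line UTF-8 file; lines starting
#'   with `#` are ignored.
#' @return an `event_term_set`.
#' @export
event_term_set <- function(terms, name = "event") {
  terms <- unique(.canon(terms))
  terms <- terms[nzchar(terms)]
  .assert(length(terms) > 0L, "an event term set cannot be empty")
  structure(list(name = name, terms = terms), class = "event_term_set")
}

#' @rdname event_term_set
#' @export
load_term_set <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  .assert(file.exists(path), sprintf("term-set file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#")]
  event_term_set(lines, name = name)
}

.term_values <- function(terms) {
  if (inherits(terms, "event_term_set")) terms$terms else unique(.canon(terms))
}

#' @export
print.event_term_set <- function(x, ...) {
  cat(sprintf("<event_term_set> %s: %d terms\n", x$name, length(x$terms)))
  invisible(x)
}

#' Load a drug synonym map
#'
#' Plain UTF-8 text, one `VERBATIM<TAB>CANONICAL` pair per line. Both
#' sides are normalized; canonical names must be consistent (a verbatim
#' cannot map to two different targets).
#'
#' @param path file path.
#' @return named character vector usable by [normalize_drug_name].
#' @export
load_synonym_map <- function(path) {
  .assert(file.exists(path), sprintf("synonym file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(character())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .assert(all(lengths(parts) == 2L),
          "synonym lines must be 'VERBATIM<TAB>CANONICAL'")
  verb <- .canon(vapply(parts, `[[`, "", 1L))
  canon <- .canon(vapply(parts, `[[`, "", 2L))
  dup <- duplicated(verb)
  .assert(!any(dup & canon[dup] != canon[match(verb[dup], verb)]),
          "a verbatim drug name maps to two different canonical names")
  stats::setNames(canon, verb)[!dup]
}
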