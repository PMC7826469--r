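#' Screen comedications for modification of an event's reporting odds
#'
#' Restricts the report set to reports listing the base drug, then treats
#' every other drug co-reported on at least `min_coreports` of those
#' reports as a candidate exposure and computes the within-base-drug
#' reporting odds ratio of the event (candidate present vs absent).
#' Candidates whose confidence interval lies entirely below 1 are
#' "inverse" signals - comedications associated with fewer event reports
#' among users of the base drug - and entirely above 1 "positive".
#'
#' No multiplicity adjustment is applied (each row is a hypothesis in its
#' own right, as is conventional in hypothesis-free screens);
#' [screen_summary] can annotate Benjamini-Hochberg q-values on request.
#'
#' @param reports a [case_reports] object (deduplicated).
#' @param base_drug canonical name of the base drug.
#' @param event_terms an [event_term_set] or character vector of PTs.
#' @param min_coreports minimum number of base-drug reports listing the
#'   candidate (default 100; small counts give unstable odds ratios).
#' @param alpha two-sided level for the CI (default 0.05).
#' @param direction keep only `"inverse"` signals (default), only
#'   `"positive"`, or `"both"` (no class filter: every candidate passing
#'   `min_coreports` is returned, whatever its classification).
#' @param zero_correction passed to [ror()].
#' @return data.frame of class `screen_result`, sorted by ascending ROR
#'   (ties broken alphabetically): `candidate_drug`, `n_with`,
#'   `n_event_with`, `n_without`, `n_event_without`, `ror`, `ci_low`,
#'   `ci_high`, `p_value`, `signal_class`. Zero rows when no candidate
#'   passes.
#' @export
screen_comedications <- function(reports, base_drug, event_terms,
                                 min_coreports = 100, alpha = 0.05,
                                 direction = c("inverse", "positive", "both"),
                                 zero_correction = "haldane") {
  .assert(inherits(reports, "case_reports"), "reports must be a case_reports object")
  direction <- match.arg(direction)
  base_drug <- .canon(base_drug)
  in_base <- .has_drug(reports, base_drug)
  .assert(any(in_base), sprintf("base drug %s appears in no report", base_drug))
  base <- reports[in_base]
  evt <- .has_any_term(base, .term_values(event_terms))
  n_base <- nrow(base)
  n_event <- sum(evt)

  fl <- .flat(base[["drugs"]])
  keep <- fl$values != base_drug
  cand <- data.table::data.table(drug = fl$values[keep], row = fl$row[keep])
  cand <- unique(cand)             # a drug listed twice on a report counts once
  if (nrow(cand) == 0L) return(.empty_screen())
  counts <- cand[, .(n_with = .N, n_event_with = sum(evt[row])), by = drug]
  counts <- counts[n_with >= min_coreports]
  if (nrow(counts) == 0L) return(.empty_screen())

  rows <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$n_event_with[i]
    b <- counts$n_with[i] - a
    c_ <- n_event - a
    d <- (n_base - counts$n_with[i]) - c_
    r <- ror(contingency_table(a, b, c_, d), alpha = alpha,
             zero_correction = zero_correction)
    data.frame(candidate_drug = counts$drug[i],
               n_with = counts$n_with[i], n_event_with = a,
               n_without = n_base - counts$n_with[i], n_event_without = c_,
               ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, signal_class = r$signal_class)
  })
  out <- do.call(rbind, rows)
  out <- switch(direction,
    inverse  = out[out$signal_class == "inverse", , drop = FALSE],
    positive = out[out$signal_class == "positive", , drop = FALSE],
    both     = out
  )
  out <- out[order(out$ror, out$candidate_drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_drug") <- base_drug
  attr(out, "n_base_reports") <- n_base
  attr(out, "n_base_events") <- n_event
  class(out) <- c("screen_result", "data.frame")
  out
}

.empty_screen <- function() {
  out <- data.frame(candidate_drug = character(), n_with = integer(),
                    n_event_with = integer(), n_without = integer(),
                    n_event_without = integer(), ror = numeric(),
                    ci_low = numeric(), ci_high = numeric(),
                    p_value = numeric(), signal_class = character())
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Render a screen result in publication layout
#'
#' One row per candidate with "events/total (percent)" columns for the
#' reports without and with the candidate, the ROR, its CI and p-value.
#' Percentages print with 2 decimals, ROR and CI with 2 decimals.
#'
#' @param rows a `screen_result` from [screen_comedications].
#' @param path optional output file; when given, written tab-separated.
#' @param qvalues add a Benjamini-Hochberg q-value column (default off).
#' @return the formatted data.frame (invisibly when `path` is given).
#' @export
screen_summary <- function(rows, path = NULL, qvalues = FALSE) {
  fmt_frac <- function(num, den) {
    sprintf("%d/%d (%.2f)", num, den, ifelse(den > 0, 100 * num / den, NA))
  }
  out <- data.frame(
    drug = rows$candidate_drug,
    event_without = fmt_frac(rows$n_event_without, rows$n_without),
    event_with = fmt_frac(rows$n_event_with, rows$n_with),
    ror = sprintf("%.2f", rows$ror),
    ci95 = sprintf("%.2f-%.2f", rows$ci_low, rows$ci_high),
    p_value = signif(rows$p_value, 3),
    stringsAsFactors = FALSE
  )
  if (qvalues) out$q_value <- signif(stats::p.adjust(rows$p_value, "BH"), 3)
  if (nrow(out) == 0L) out <- out[0, , drop = FALSE]
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    return(invisible(out))
  }
  out
}
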