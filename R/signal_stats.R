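#' 2x2 contingency table for disproportionality analysis
#'
#' Reports are cross-classified by exposure (the drug of interest on the
#' report or not) and event (the reaction term set hit or not):
#' \describe{
#'   \item{a}{exposed, event reported}
#'   \item{b}{exposed, no event}
#'   \item{c}{not exposed, event reported}
#'   \item{d}{not exposed, no event}
#' }
#'
#' @param a,b,c,d non-negative integer counts.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  .assert(all(is.finite(x)) && all(x >= 0), "counts must be non-negative finite numbers")
  .assert(all(abs(x - round(x)) < 1e-8), "counts must be integers")
  .assert(sum(x) > 0, "the table must contain at least one report")
  structure(as.list(round(x)), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the four-group table from a report set
#'
#' Classifies every deduplicated report by whether it lists the exposure
#' drug and whether it reports the event, so that `a + b + c + d`
#' equals the number of reports.
#'
#' @param reports a [case_reports] object (deduplicated).
#' @param exposure_drug canonical drug name (uppercase).
#' @param event_terms an [event_term_set] or character vector of PTs.
#' @return a [contingency_table].
#' @export
build_contingency <- function(reports, exposure_drug, event_terms) {
  .assert(inherits(reports, "case_reports"), "reports must be a case_reports object")
  if (nrow(reports) == 0L) {
    return(structure(list(a = 0L, b = 0L, c = 0L, d = 0L),
                     class = "contingency_table"))
  }
  expo <- .has_drug(reports, .canon(exposure_drug))
  evt <- .has_any_term(reports, .term_values(event_terms))
  structure(list(a = sum(expo & evt), b = sum(expo & !evt),
                 c = sum(!expo & evt), d = sum(!expo & !evt)),
            class = "contingency_table")
}

#' Reporting odds ratio with Wald confidence interval
#'
#' The ROR is `(a/b) / (c/d)`; its log-scale standard error is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the two-sided confidence interval is
#' `exp(log(ROR) +- z * se)`. At the default `alpha = 0.05` the critical
#' value is exactly 1.96 (the convention in the disproportionality
#' literature); other alphas use the precise normal quantile. A two-sided
#' Fisher exact p-value accompanies the estimate.
#'
#' Zero cells make the estimate degenerate; the default policy applies
#' the Haldane-Anscombe correction (adds 0.5 to all four cells, flags the
#' result as corrected). Policy `"error"` refuses instead.
#'
#' @param table a [contingency_table].
#' @param alpha two-sided significance level (default 0.05).
#' @param zero_correction `"haldane"` (default) or `"error"`.
#' @return a `signal_result`: list with `table`, `ror`, `ci_low`,
#'   `ci_high`, `alpha`, `p_value`, `corrected`, `signal_class`.
#' @seealso [classify_signal()], [fisher_exact()]
#' @export
#' @examples
#' ror(contingency_table(1520, 26768, 83559, 3611907))
ror <- function(table, alpha = 0.05,
                zero_correction = c("haldane", "error")) {
  .assert(inherits(table, "contingency_table"), "table must be a contingency_table")
  zero_correction <- match.arg(zero_correction)
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (zero_correction == "error") {
      stop("contingency table has a zero cell; use zero_correction = \"haldane\"",
           call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  z <- if (identical(alpha, 0.05)) 1.96 else stats::qnorm(1 - alpha / 2)
  est <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(est) + c(-1, 1) * z * se)
  res <- structure(list(table = table, ror = est, ci_low = ci[1],
                        ci_high = ci[2], alpha = alpha,
                        p_value = fisher_exact(table),
                        corrected = corrected, signal_class = NA_character_),
                   class = "signal_result")
  res$signal_class <- classify_signal(res)
  res
}

#' @export
print.signal_result <- function(x, digits = 2, ...) {
  cat(sprintf("ROR %.2f (%.0f%% CI %.2f-%.2f), p = %.3g, class: %s%s\n",
              x$ror, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$p_value,
              x$signal_class,
              if (isTRUE(x$corrected)) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities
#' of all tables no more probable than the observed one (the usual
#' two-sided convention). Probabilities within a relative factor of
#' `1e-7` of the observed table's probability count as ties, guarding
#' against floating-point noise on exactly symmetric tables.
#'
#' @param table a [contingency_table] (zero cells allowed).
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact <- function(table) {
  .assert(inherits(table, "contingency_table"), "table must be a contingency_table")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  row1 <- a + b; row2 <- c + d; col1 <- a + c; n <- row1 + row2
  if (row1 == 0 || row2 == 0 || col1 == 0 || col1 == n) return(1)
  k <- max(0, col1 - row2):min(col1, row1)
  logp <- lchoose(row1, k) + lchoose(row2, col1 - k) - lchoose(n, col1)
  logp_obs <- lchoose(row1, a) + lchoose(row2, col1 - a) - lchoose(n, col1)
  p <- sum(exp(logp)[logp <= logp_obs + log(1 + 1e-7)])
  min(p, 1)
}

#' Classify a disproportionality signal from its confidence interval
#'
#' `"positive"` when the lower CI limit is above 1 (the drug-event pair
#' is reported disproportionately often), `"inverse"` when the upper
#' limit is below 1 (disproportionately rarely), `"none"` otherwise.
#'
#' @param result a `signal_result` from [ror()].
#' @return one of `"positive"`, `"inverse"`, `"none"`.
#' @export
classify_signal <- function(result) {
  .assert(is.list(result) && !is.null(result$ci_low) && !is.null(result$ci_high),
          "result must carry ci_low and ci_high")
  if (result$ci_low > 1) "positive"
  else if (result$ci_high < 1) "inverse"
  else "none"
}

#' Stratification specification
#'
#' Default age bins follow the conventional pharmacovigilance banding:
#' `<40`, `40-49`, `50-59`, `60-69`, `70-100` (bounds inclusive as
#' labelled; ages above 100 fall in no stratum). The sex variable uses
#' strata `M` and `F`; reports with unknown sex fall in no stratum.
#' Reports with a missing stratifier are excluded from every stratum, so
#' stratum totals may be smaller than the grand total.
#'
#' @param variable `"age"` or `"sex"`.
#' @param bins for `variable = "age"`: data.frame with columns `label`,
#'   `lo`, `hi` (both bounds inclusive).
#' @return a `stratum_spec`.
#' @export
stratum_spec <- function(variable = c("age", "sex"), bins = NULL) {
  variable <- match.arg(variable)
  if (variable == "age" && is.null(bins)) {
    bins <- data.frame(label = c("<40", "40-49", "50-59", "60-69", "70-100"),
                       lo = c(-Inf, 40, 50, 60, 70),
                       hi = c(39.999999, 49.999999, 59.999999, 69.999999, 100))
  }
  structure(list(variable = variable, bins = bins), class = "stratum_spec")
}

#' Stratified reporting odds ratios
#'
#' Runs [build_contingency] + [ror] within each stratum of a demographic
#' variable. A stratum whose table has an empty margin (no exposed or no
#' event reports, say) is flagged `insufficient` and gets no interval.
#'
#' @param reports a [case_reports] object.
#' @param exposure_drug canonical drug name.
#' @param event_terms an [event_term_set] or character vector.
#' @param spec a [stratum_spec].
#' @inheritParams ror
#' @return data.frame with one row per stratum: counts, `ror`, `ci_low`,
#'   `ci_high`, `p_value`, `signal_class`, `insufficient`.
#' @export
stratified_ror <- function(reports, exposure_drug, event_terms,
                           spec = stratum_spec("age"), alpha = 0.05,
                           zero_correction = "haldane") {
  .assert(inherits(spec, "stratum_spec"), "spec must be a stratum_spec")
  if (spec$variable == "sex") {
    labels <- c("M", "F")
    member <- lapply(labels, function(s) !is.na(reports$sex) & reports$sex == s)
  } else {
    bins <- spec$bins
    labels <- bins$label
    age <- reports$age_years
    member <- lapply(seq_len(nrow(bins)), function(i) {
      !is.na(age) & age >= bins$lo[i] & age <= bins$hi[i]
    })
  }
  expo <- .has_drug(reports, .canon(exposure_drug))
  evt <- .has_any_term(reports, .term_values(event_terms))
  rows <- lapply(seq_along(labels), function(i) {
    m <- member[[i]]
    tab <- structure(list(a = sum(expo & evt & m), b = sum(expo & !evt & m),
                          c = sum(!expo & evt & m), d = sum(!expo & !evt & m)),
                     class = "contingency_table")
    n_str <- tab$a + tab$b + tab$c + tab$d
    insufficient <- n_str == 0 ||
      (tab$a + tab$b) == 0 || (tab$c + tab$d) == 0 ||
      (tab$a + tab$c) == 0 || (tab$b + tab$d) == 0
    if (insufficient) {
      return(data.frame(stratum = labels[i], a = tab$a, b = tab$b, c = tab$c,
                        d = tab$d, ror = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        signal_class = NA_character_, insufficient = TRUE))
    }
    r <- ror(tab, alpha = alpha, zero_correction = zero_correction)
    data.frame(stratum = labels[i], a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, signal_class = r$signal_class,
               insufficient = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- spec$variable
  out
}

#' Write a signal table
#'
#' Tab-separated output mirroring the published table layout: one row per
#' analysis or stratum with counts, ROR, CI bounds, p-value and class.
#' ROR and CI are presentation-rounded to 2 decimals; internal objects
#' keep full precision.
#'
#' @param x data.frame as returned by [stratified_ror], or a single
#'   `signal_result`.
#' @param path output file path.
#' @param exposure,event labels for the first two columns.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path, exposure = "", event = "") {
  if (inherits(x, "signal_result")) {
    x <- data.frame(stratum = "total", a = x$table$a, b = x$table$b,
                    c = x$table$c, d = x$table$d, ror = x$ror,
                    ci_low = x$ci_low, ci_high = x$ci_high,
                    p_value = x$p_value, signal_class = x$signal_class,
                    insufficient = FALSE)
  }
  out <- data.frame(exposure = exposure, event = event, x)
  for (col in c("ror", "ci_low", "ci_high")) out[[col]] <- round(out[[col]], 2)
  out$p_value <- signif(out$p_value, 3)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
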