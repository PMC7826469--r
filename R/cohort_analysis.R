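#' RECIST (v1.0) response classification from lesion diameter sums
#'
#' Classifies tumor response from the sum of longest lesion diameters:
#' complete response (CR) when all lesions have disappeared (current sum
#' 0), partial response (PR) on a decrease of at least 30% from baseline,
#' progressive disease (PD) on an increase of at least 20% over the nadir
#' (the smallest sum observed), stable disease (SD) otherwise. Both
#' cutoffs are inclusive, and PD takes precedence over PR when both
#' trigger.
#'
#' @param baseline_sum_mm positive baseline sum (mm).
#' @param nadir_sum_mm positive nadir sum (mm).
#' @param current_sum_mm non-negative current sum (mm).
#' @return character vector of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
#' @examples
#' classify_recist(100, 100, 70)  # "PR": exactly 30% down
#' classify_recist(100, 50, 60)   # "PD": 20% over nadir
classify_recist <- function(baseline_sum_mm, nadir_sum_mm, current_sum_mm) {
  n <- max(length(baseline_sum_mm), length(nadir_sum_mm), length(current_sum_mm))
  baseline <- rep_len(as.numeric(baseline_sum_mm), n)
  nadir <- rep_len(as.numeric(nadir_sum_mm), n)
  cur <- rep_len(as.numeric(current_sum_mm), n)
  .assert(all(baseline > 0) && all(nadir > 0) && all(cur >= 0),
          "diameter sums must be positive (current may be zero)")
  out <- rep("SD", n)
  out[(cur - nadir) / nadir >= 0.2] <- "PD"
  pr <- (baseline - cur) / baseline >= 0.3 & out != "PD"
  out[pr] <- "PR"
  out[cur == 0] <- "CR"
  out
}

#' Objective response and disease control rates per arm
#'
#' ORR = (CR + PR) / n, DCR = (CR + PR + SD) / n, computed per arm and
#' overall. The between-arm comparison of responders (and of disease
#' control) uses [compare_categorical] (Fisher's exact test when any cell
#' is below 5, Pearson chi-square otherwise).
#'
#' @param patients data.frame with a `response` column (`CR`/`PR`/`SD`/`PD`)
#'   and the arm column named by `arm_field`.
#' @param arm_field name of the grouping column (default `"ppi_user"`).
#' @return list of class `response_summary`: `counts` (arm x category),
#'   `orr`, `dcr` (named per-arm proportions plus `"overall"`),
#'   `orr_test`, `dcr_test` (from [compare_categorical]).
#' @export
response_rates <- function(patients, arm_field = "ppi_user") {
  .assert(arm_field %in% names(patients), sprintf("no column '%s'", arm_field))
  resp <- factor(patients$response, levels = c("CR", "PR", "SD", "PD"))
  .assert(!anyNA(resp), "every patient must have a CR/PR/SD/PD response")
  arm <- factor(patients[[arm_field]])
  .assert(nlevels(arm) >= 1 && all(table(arm) > 0), "empty arm")
  counts <- table(arm, resp)
  n <- rowSums(counts)
  orr <- (counts[, "CR"] + counts[, "PR"]) / n
  dcr <- orr + counts[, "SD"] / n
  orr <- c(orr, overall = sum(counts[, c("CR", "PR")]) / sum(n))
  dcr <- c(dcr, overall = sum(counts[, c("CR", "PR", "SD")]) / sum(n))
  orr_test <- dcr_test <- NULL
  testable <- function(x) all(rowSums(x) > 0) && all(colSums(x) > 0)
  if (nlevels(arm) >= 2) {
    responder <- cbind(counts[, "CR"] + counts[, "PR"],
                       n - counts[, "CR"] - counts[, "PR"])
    controlled <- round(cbind(n * dcr[seq_len(nlevels(arm))],
                              n * (1 - dcr[seq_len(nlevels(arm))])))
    # a table with an empty margin (e.g. no responder anywhere) carries
    # no between-arm information: no test is reported
    if (testable(responder)) orr_test <- compare_categorical(responder)
    if (testable(controlled)) dcr_test <- compare_categorical(controlled)
  }
  structure(list(counts = counts, orr = orr, dcr = dcr,
                 orr_test = orr_test, dcr_test = dcr_test),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  print(x$counts)
  arms <- rownames(x$counts)
  for (a in arms) {
    cat(sprintf("%s: ORR %.0f%%, DCR %.0f%%\n", a, 100 * x$orr[[a]],
                100 * x$dcr[[a]]))
  }
  if (!is.null(x$orr_test)) {
    cat(sprintf("ORR comparison: %s, p = %.3g\n", x$orr_test$test, x$orr_test$p_value))
    cat(sprintf("DCR comparison: %s, p = %.3g\n", x$dcr_test$test, x$dcr_test$p_value))
  }
  invisible(x)
}

#' Categorical comparison with the small-cell selection rule
#'
#' Compares an r x 2 table of counts: Fisher's exact test when any cell
#' is below 5, Pearson chi-square without continuity correction
#' otherwise. The chosen test is returned alongside the p-value.
#'
#' @param x_counts matrix of non-negative counts (r rows, 2 columns).
#' @return list with `test` (`"fisher"` or `"chi-square"`) and `p_value`.
#' @export
compare_categorical <- function(x_counts) {
  x <- as.matrix(x_counts)
  .assert(ncol(x) == 2 && nrow(x) >= 2, "x_counts must be an r x 2 table, r >= 2")
  .assert(all(x >= 0) && all(is.finite(x)), "counts must be non-negative")
  .assert(all(rowSums(x) > 0) && all(colSums(x) > 0),
          "degenerate table: an all-zero row or column")
  if (any(x < 5)) {
    p <- if (nrow(x) == 2) {
      fisher_exact(contingency_table(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
    } else {
      stats::fisher.test(x)$p.value
    }
    list(test = "fisher", p_value = p)
  } else {
    # the selection rule is on observed cells; chisq.test's expected-count
    # warning is redundant with it
    p <- suppressWarnings(stats::chisq.test(x, correct = FALSE)$p.value)
    list(test = "chi-square", p_value = p)
  }
}

#' Mann-Whitney U test
#'
#' U statistic computed from midranks (ties share the average rank). The
#' two-sided p-value is exact (from the null permutation distribution of
#' U) when the combined sample size is at most 20 and there are no ties,
#' and otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `U` (for the `x` sample), `p_value`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  .assert(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  .assert(!anyNA(x) && !anyNA(y), "samples must not contain NA")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && nx + ny <= 20) {
    # exact null distribution of U (equivalent to enumerating all
    # choose(nx+ny, nx) rank assignments)
    p_lo <- stats::pwilcox(U, nx, ny)
    p_hi <- 1 - stats::pwilcox(U - 1, nx, ny)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Flag a treatment-emergent hypertension event (CTCAE-style)
#'
#' TRUE when the on-treatment systolic pressure rose by at least 20 mmHg
#' over baseline, reached at least 150 mmHg at any cycle, or
#' antihypertensive therapy was started or increased.
#'
#' @param baseline_sbp baseline systolic pressure (mmHg), measured before
#'   the first dose.
#' @param on_treatment_sbp numeric vector of on-treatment systolic
#'   measurements (at least one).
#' @param med_change logical: antihypertensive initiation/increase.
#' @param delta_threshold rise over baseline that counts (default 20).
#' @param absolute_threshold absolute systolic level that counts
#'   (default 150).
#' @return logical scalar.
#' @export
flag_hypertension_event <- function(baseline_sbp, on_treatment_sbp,
                                    med_change = FALSE,
                                    delta_threshold = 20,
                                    absolute_threshold = 150) {
  .assert(length(baseline_sbp) == 1 && is.finite(baseline_sbp),
          "a single finite baseline SBP is required")
  .assert(length(on_treatment_sbp) >= 1 && all(is.finite(on_treatment_sbp)),
          "at least one finite on-treatment SBP is required")
  mx <- max(on_treatment_sbp)
  (mx - baseline_sbp >= delta_threshold) || (mx >= absolute_threshold) ||
    isTRUE(med_change)
}

#' Systolic blood-pressure change summary per arm
#'
#' Per-arm mean and SD of the pre-treatment SBP, the on-treatment SBP and
#' the per-patient delta; the between-arm comparison of deltas uses
#' [mann_whitney_u]. Patients missing either measurement are excluded
#' with a warning.
#'
#' @param patients data.frame with numeric `sbp_before`, `sbp_after`
#'   columns and the arm column named by `arm_field`.
#' @param arm_field name of the grouping column (default `"ppi_user"`).
#' @return list with `by_arm` (data.frame: arm, n, mean/SD before, after,
#'   delta) and `p_value` (between-arm Mann-Whitney on deltas; `NA` when
#'   fewer than two arms).
#' @export
sbp_change_summary <- function(patients, arm_field = "ppi_user") {
  .assert(all(c("sbp_before", "sbp_after", arm_field) %in% names(patients)),
          "patients must carry sbp_before, sbp_after and the arm column")
  ok <- is.finite(patients$sbp_before) & is.finite(patients$sbp_after)
  if (!all(ok)) {
    warning(sprintf("%d patient(s) excluded for unpaired SBP measurements",
                    sum(!ok)))
    patients <- patients[ok, , drop = FALSE]
  }
  arm <- factor(patients[[arm_field]])
  delta <- patients$sbp_after - patients$sbp_before
  by_arm <- do.call(rbind, lapply(levels(arm), function(a) {
    i <- arm == a
    data.frame(arm = a, n = sum(i),
               mean_before = mean(patients$sbp_before[i]),
               sd_before = stats::sd(patients$sbp_before[i]),
               mean_after = mean(patients$sbp_after[i]),
               sd_after = stats::sd(patients$sbp_after[i]),
               mean_delta = mean(delta[i]),
               sd_delta = stats::sd(delta[i]))
  }))
  p <- NA_real_
  if (nlevels(arm) == 2) {
    p <- mann_whitney_u(delta[arm == levels(arm)[1]],
                        delta[arm == levels(arm)[2]])$p_value
  }
  list(by_arm = by_arm, p_value = p)
}
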