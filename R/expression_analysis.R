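#' Expression matrix container
#'
#' Genes x samples matrix of log2 intensities with a group label per
#' sample. Microarray preprocessing (normalization, probe summarization)
#' is out of scope: inputs are already log2-scale.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples.
#' @param groups character/factor vector, one label per column.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  .assert(!is.null(rownames(values)), "values must carry gene rownames")
  .assert(length(groups) == ncol(values), "one group label per sample required")
  .assert(!anyNA(groups), "group labels must not be missing")
  structure(list(values = values, groups = as.character(groups)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expected layout: a header line of sample identifiers, a second line
#' starting with `!group` giving the group label of each sample, then one
#' row per gene (identifier in the first column, log2 intensities after).
#'
#' @param path file path.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  .assert(file.exists(path), sprintf("expression file not found: %s", path))
  lines <- readLines(path, n = 2, warn = FALSE)
  .assert(length(lines) >= 2 && startsWith(lines[2], "!group"),
          "expected a '!group' line after the header")
  groups <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  dt <- data.table::fread(path, sep = "\t", skip = 2, header = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  genes <- as.character(dt[[1]])
  values <- as.matrix(dt[, -1])
  dimnames(values) <- list(genes, header[-1])
  expression_matrix(values, groups)
}

#' Read a GEO series-matrix file
#'
#' Minimal loader for the series-matrix layout: metadata lines start with
#' `!`, and the expression table sits between `!series_matrix_table_begin`
#' and `!series_matrix_table_end`. Group labels are derived by matching
#' `group_regex` against the `!Sample_title` line (`TRUE` matches become
#' `group_match`, others `group_other`). The real series file is never
#' required by the package; this loader exists for users who have one.
#'
#' @param path file path.
#' @param group_regex regular expression applied to sample titles.
#' @param group_match,group_other labels assigned on match / no match.
#' @return an `expression_matrix`.
#' @export
read_series_matrix <- function(path, group_regex, group_match = "treated",
                               group_other = "vehicle") {
  .assert(file.exists(path), sprintf("series-matrix file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  title_line <- grep("^!Sample_title", lines, value = TRUE)
  .assert(length(title_line) == 1, "expected exactly one !Sample_title line")
  titles <- gsub("\"", "", strsplit(title_line, "\t", fixed = TRUE)[[1]][-1])
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  .assert(length(beg) == 1 && length(end) == 1 && end > beg + 1,
          "series-matrix table markers not found")
  tbl <- data.table::fread(text = lines[(beg + 1):(end - 1)], sep = "\t")
  genes <- gsub("\"", "", as.character(tbl[[1]]))
  values <- as.matrix(tbl[, -1])
  dimnames(values) <- list(genes, titles)
  groups <- ifelse(grepl(group_regex, titles), group_match, group_other)
  expression_matrix(values, groups)
}

#' Load a pathway gene set
#'
#' Plain text, one gene identifier per line (`#` comments allowed). The
#' bundled `vegf_pathway_map04370.txt` carries the VEGF signaling pathway
#' members used in the worked example.
#'
#' @param path file path.
#' @param name set name.
#' @return list of class `pathway_gene_set` with `name` and `genes`.
#' @export
load_gene_set <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  .assert(file.exists(path), sprintf("gene-set file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  genes <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  .assert(length(genes) > 0, "a pathway gene set cannot be empty")
  structure(list(name = name, genes = genes), class = "pathway_gene_set")
}

#' Two-group comparison on a pathway gene subset
#'
#' For each pathway gene present in the matrix: group means of the log2
#' values, the fold change on the original scale `2^(meanA - meanB)`, and
#' a two-sided t-test p-value on the log2 values (Welch by default, since
#' group sizes are often very unequal; pooled via `var_equal = TRUE`).
#' Genes absent from the matrix are listed in the `skipped` attribute; a
#' group with a single sample yields the fold change but no p-value.
#'
#' @param mat an [expression_matrix].
#' @param genes a `pathway_gene_set`, or character vector of identifiers.
#' @param grpA,grpB group labels to compare (fold change is A over B).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame: `gene`, `mean_A`, `mean_B` (log2 scale),
#'   `fold_change` (original scale), `p_value`; attribute `skipped`.
#' @export
pathway_compare <- function(mat, genes, grpA, grpB, var_equal = FALSE) {
  .assert(inherits(mat, "expression_matrix"), "mat must be an expression_matrix")
  wanted <- if (inherits(genes, "pathway_gene_set")) genes$genes else as.character(genes)
  present <- wanted[wanted %in% rownames(mat$values)]
  skipped <- setdiff(wanted, present)
  iA <- mat$groups == grpA
  iB <- mat$groups == grpB
  .assert(sum(iA) >= 1 && sum(iB) >= 1, "both groups must have at least one sample")
  vals <- mat$values[present, , drop = FALSE]
  mA <- rowMeans(vals[, iA, drop = FALSE])
  mB <- rowMeans(vals[, iB, drop = FALSE])
  nA <- sum(iA); nB <- sum(iB)
  p <- rep(NA_real_, length(present))
  if (nA >= 2 && nB >= 2) {
    vA <- apply(vals[, iA, drop = FALSE], 1, stats::var)
    vB <- apply(vals[, iB, drop = FALSE], 1, stats::var)
    if (var_equal) {
      sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
      se <- sqrt(sp2 * (1 / nA + 1 / nB))
      df <- rep(nA + nB - 2, length(present))
    } else {
      se <- sqrt(vA / nA + vB / nB)
      df <- (vA / nA + vB / nB)^2 /
        ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    }
    tstat <- (mA - mB) / se
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se == 0 & mA == mB] <- 1    # identical constant groups
  }
  out <- data.frame(gene = present, mean_A = unname(mA), mean_B = unname(mB),
                    fold_change = unname(2^(mA - mB)), p_value = unname(p))
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(A = grpA, B = grpB)
  out
}

#' Relative qPCR quantification (delta-delta-Cq)
#'
#' Per sample, the target quantification cycle is normalized to the
#' reference gene (`dCq = Cq_target - Cq_reference`); each condition's
#' `ddCq` is its mean dCq minus the control condition's mean dCq, and the
#' relative expression is `2^(-ddCq)` (one cycle earlier = doubling).
#' The SEM is taken over the per-sample fold changes
#' `2^-(dCq - mean control dCq)`. Samples missing the reference well are
#' excluded with a warning. Adding a constant to every Cq on the plate
#' leaves all results unchanged.
#'
#' @param plate data.frame with columns `sample`, `condition`, `gene`,
#'   `cq` (long format; `gene` holds target and reference gene names).
#' @param control_condition the calibrator condition label.
#' @param reference_gene housekeeping gene (default `"36B4"`).
#' @param target_gene target gene; default: the single non-reference gene
#'   on the plate.
#' @return data.frame: `condition`, `n`, `ddcq`, `rel_expr`, `sem`.
#' @export
ddct <- function(plate, control_condition, reference_gene = "36B4",
                 target_gene = NULL) {
  .assert(all(c("sample", "condition", "gene", "cq") %in% names(plate)),
          "plate needs columns sample, condition, gene, cq")
  .assert(all(plate$cq > 0 & plate$cq < 45), "Cq values must lie in (0, 45)")
  genes <- unique(plate$gene)
  .assert(reference_gene %in% genes,
          sprintf("reference gene %s not on the plate", reference_gene))
  if (is.null(target_gene)) {
    tg <- setdiff(genes, reference_gene)
    .assert(length(tg) == 1, "target_gene must be named when several targets present")
    target_gene <- tg
  }
  dt <- data.table::as.data.table(plate)
  wide <- data.table::dcast(dt[gene %in% c(target_gene, reference_gene)],
                            sample + condition ~ gene, value.var = "cq",
                            fun.aggregate = mean)
  miss <- !is.finite(wide[[target_gene]]) | !is.finite(wide[[reference_gene]])
  if (any(miss)) {
    warning(sprintf("%d sample(s) excluded: missing target or reference well",
                    sum(miss)))
    wide <- wide[!miss]
  }
  .assert(control_condition %in% wide$condition, "control condition absent")
  wide[, dcq := get(target_gene) - get(reference_gene)]
  ctrl_mean <- mean(wide$dcq[wide$condition == control_condition])
  wide[, fold := 2^-(dcq - ctrl_mean)]
  out <- wide[, .(n = .N, ddcq = mean(dcq) - ctrl_mean,
                  rel_expr = 2^-(mean(dcq) - ctrl_mean),
                  sem = stats::sd(fold) / sqrt(.N)),
              by = condition]
  as.data.frame(out)
}

#' Dunnett many-to-one comparisons
#'
#' Compares every treated group mean against a shared control under
#' equal-variance pooling, adjusting the family-wise error by Monte Carlo
#' sampling of the max-|t| null distribution (the draws share the pooled
#' variance estimate across comparisons, as the Dunnett statistic
#' requires). Adjusted p-values never fall below the unadjusted
#' two-sided t p-value. Set the RNG seed before calling for reproducible
#' adjustment; Monte Carlo error with the default 100,000 draws is about
#' 0.003.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param control the control group label.
#' @param n_draws Monte Carlo draws (default 1e5).
#' @return data.frame: `group`, `n`, `mean`, `t`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_test <- function(values, groups, control, n_draws = 1e5) {
  groups <- as.character(groups)
  .assert(control %in% groups, "control group absent")
  labs <- unique(groups)
  .assert(length(labs) >= 2, "need at least one non-control group")
  ns <- vapply(labs, function(g) sum(groups == g), 0L)
  .assert(all(ns >= 2), "every group needs at least 2 samples")
  means <- vapply(labs, function(g) mean(values[groups == g]), 0)
  ssq <- sum(vapply(labs, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, 0))
  df <- length(values) - length(labs)
  s2 <- ssq / df
  trt <- setdiff(labs, control)
  n0 <- ns[[control]]
  se <- sqrt(s2 * (1 / ns[trt] + 1 / n0))
  tstat <- (means[trt] - means[[control]]) / se
  tstat[se == 0] <- 0                       # all-constant data: no evidence
  p_un <- 2 * stats::pt(-abs(tstat), df)
  p_un[!is.finite(tstat)] <- NA_real_

  # null draws: group-mean normals plus a shared chi-square variance
  m0 <- stats::rnorm(n_draws, sd = sqrt(1 / n0))
  s2b <- stats::rchisq(n_draws, df) / df
  maxt <- rep(0, n_draws)
  for (g in trt) {      # group draws in fixed order: max is monotone in k
    mg <- stats::rnorm(n_draws, sd = sqrt(1 / ns[[g]]))
    tg <- abs(mg - m0) / sqrt(s2b * (1 / ns[[g]] + 1 / n0))
    maxt <- pmax(maxt, tg)
  }
  p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), 0)
  p_adj <- pmax(p_adj, p_un)
  data.frame(group = trt, n = as.integer(ns[trt]), mean = unname(means[trt]),
             t = unname(tstat), p_unadjusted = unname(p_un),
             p_adjusted = unname(p_adj), row.names = NULL)
}
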