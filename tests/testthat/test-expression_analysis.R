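make_matrix <- function(values, groups) {
  expression_matrix(values, groups)
}

test_that("pathway_compare computes log2 means and original-scale fold change", {
  # the published VEGF row: group means 11.57 vs 11.07 -> fold change 2^0.5
  vals <- rbind(VEGFA = c(11.47, 11.57, 11.67, 10.97, 11.07, 11.17))
  mat <- make_matrix(vals, rep(c("treated", "vehicle"), each = 3))
  out <- pathway_compare(mat, "VEGFA", "treated", "vehicle")
  expect_equal(out$mean_A, 11.57)
  expect_equal(out$mean_B, 11.07)
  expect_equal(out$fold_change, 2^0.5)
})

test_that("identical groups give fold change 1 and p = 1", {
  vals <- matrix(rep(c(5, 6, 7), 2), nrow = 1,
                 dimnames = list("G1", NULL))
  mat <- make_matrix(vals, rep(c("a", "b"), each = 3))
  out <- pathway_compare(mat, "G1", "a", "b")
  expect_equal(out$fold_change, 1)
  expect_equal(out$p_value, 1)
})

test_that("single-gene pathway_compare equals a direct Welch t-test", {
  set.seed(61)
  vals <- matrix(rnorm(12, 8), nrow = 2,
                 dimnames = list(c("G1", "G2"), NULL))
  groups <- rep(c("a", "b"), each = 3)
  mat <- make_matrix(vals, groups)
  out <- pathway_compare(mat, "G1", "a", "b")
  ref <- t.test(vals[1, groups == "a"], vals[1, groups == "b"])
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-12)
  pooled <- pathway_compare(mat, "G1", "a", "b", var_equal = TRUE)
  refp <- t.test(vals[1, groups == "a"], vals[1, groups == "b"],
                 var.equal = TRUE)
  expect_equal(pooled$p_value, refp$p.value, tolerance = 1e-12)
})

test_that("fold changes invert when the groups swap", {
  set.seed(67)
  ge <- gen_expression(n_genes = 20, sigma = 0.3, seed = 67)
  ab <- pathway_compare(ge$mat, rownames(ge$mat$values), "treated", "vehicle")
  ba <- pathway_compare(ge$mat, rownames(ge$mat$values), "vehicle", "treated")
  expect_equal(ab$fold_change * ba$fold_change, rep(1, 20), tolerance = 1e-12)
})

test_that("absent genes are skipped with a report; 1-sample groups get no p", {
  vals <- matrix(rnorm(8, 8), nrow = 2, dimnames = list(c("G1", "G2"), NULL))
  mat <- make_matrix(vals, c("a", "a", "a", "b"))
  out <- pathway_compare(mat, c("G1", "G2", "MISSING"), "a", "b")
  expect_equal(attr(out, "skipped"), "MISSING")
  expect_equal(nrow(out), 2)
  expect_true(all(is.na(out$p_value)))
  expect_true(all(is.finite(out$fold_change)))
})

test_that("planted shifts are detected and unplanted p-values behave", {
  ge <- gen_expression(n_genes = 50, group_sizes = c(treated = 5, vehicle = 5),
                       sigma = 0.2,
                       planted_effects = c(VEGFA = 1, G0010 = 1, G0020 = 1),
                       seed = 71)
  out <- pathway_compare(ge$mat, rownames(ge$mat$values), "treated", "vehicle")
  hits <- out$gene[out$p_value < 0.01]
  expect_setequal(hits, c("VEGFA", "G0010", "G0020"))
})

test_that("noiseless planted shift gives the exact fold change", {
  ge <- gen_expression(n_genes = 5, sigma = 0,
                       planted_effects = c(VEGFA = 0.5), seed = 73)
  out <- pathway_compare(ge$mat, "VEGFA", "treated", "vehicle")
  expect_equal(out$fold_change, 2^0.5, tolerance = 1e-12)
})

test_that("expression matrices round-trip through the tab-separated format", {
  ge <- gen_expression(n_genes = 8, seed = 79)
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- ge$mat
  con <- file(path, "w")
  writeLines(paste(c("gene", colnames(m$values)), collapse = "\t"), con)
  writeLines(paste(c("!group", m$groups), collapse = "\t"), con)
  write.table(m$values, con, sep = "\t", quote = FALSE, col.names = FALSE)
  close(con)
  back <- read_expression_matrix(path)
  expect_equal(back$groups, m$groups)
  expect_equal(back$values, m$values, tolerance = 1e-12)
})

test_that("series-matrix loader extracts the table and group labels", {
  path <- withr::local_tempfile()
  writeLines(c(
    '!Series_title\t"toxicogenomics"',
    '!Sample_title\t"omeprazole_1"\t"omeprazole_2"\t"vehicle_1"\t"vehicle_2"',
    "!series_matrix_table_begin",
    paste("ID_REF", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("VEGFA", "11.5", "11.6", "11.0", "11.1", sep = "\t"),
    "!series_matrix_table_end"), path)
  mat <- read_series_matrix(path, "^omeprazole")
  expect_equal(mat$groups, c("treated", "treated", "vehicle", "vehicle"))
  expect_equal(unname(mat$values["VEGFA", ]), c(11.5, 11.6, 11.0, 11.1))
})

test_that("ddct normalizes to the reference gene and control condition", {
  plate <- data.frame(
    sample = rep(c("c1", "c2", "t1", "t2"), each = 2),
    condition = rep(c("control", "control", "treated", "treated"), each = 2),
    gene = rep(c("VEGFA", "36B4"), 4),
    cq = c(25.0, 20.0, 25.2, 20.0, 24.0, 20.0, 24.2, 20.0))
  out <- ddct(plate, "control")
  ctrl <- out[out$condition == "control", ]
  trt <- out[out$condition == "treated", ]
  # control dCq {5.0, 5.2}, treated {4.0, 4.2}: ddCq = -1, fold = 2
  expect_equal(ctrl$rel_expr, 1)
  expect_equal(trt$ddcq, -1)
  expect_equal(trt$rel_expr, 2)
  # identity: a condition matching the control is at fold 1
  expect_equal(ctrl$ddcq, 0)
})

test_that("ddct is invariant to a constant plate offset", {
  set.seed(83)
  plate <- data.frame(
    sample = rep(paste0("s", 1:9), each = 2),
    condition = rep(c("control", "omeprazole", "famotidine"), each = 6),
    gene = rep(c("TARGET", "36B4"), 9),
    cq = runif(18, 18, 30))
  base <- ddct(plate, "control", target_gene = "TARGET")
  shifted <- plate
  shifted$cq <- shifted$cq + 3.7
  expect_equal(ddct(shifted, "control", target_gene = "TARGET"), base)
})

test_that("ddct excludes samples missing a reference well, with warning", {
  plate <- data.frame(
    sample = c("c1", "c1", "c2", "c2", "t1"),
    condition = c("control", "control", "control", "control", "treated"),
    gene = c("VEGFA", "36B4", "VEGFA", "36B4", "VEGFA"),
    cq = c(25, 20, 25.5, 20, 24))
  expect_warning(out <- ddct(plate, "control"), "missing target or reference")
  expect_false("treated" %in% out$condition)
})

test_that("dunnett with two groups degenerates to the pooled t-test", {
  set.seed(89)
  values <- c(rnorm(7, 10), rnorm(7, 11))
  groups <- rep(c("control", "treated"), each = 7)
  set.seed(97)
  out <- dunnett_test(values, groups, "control")
  ref <- t.test(values[groups == "treated"], values[groups == "control"],
                var.equal = TRUE)
  expect_equal(out$p_unadjusted, ref$p.value, tolerance = 1e-12)
  expect_lt(abs(out$p_adjusted - ref$p.value), 0.005)  # Monte-Carlo error
})

test_that("dunnett on identical constant groups reports p = 1", {
  values <- rep(5, 12)
  groups <- rep(c("control", "a", "b"), each = 4)
  set.seed(101)
  out <- dunnett_test(values, groups, "control", n_draws = 1e4)
  expect_equal(out$p_adjusted, c(1, 1))
})

test_that("dunnett flags only the shifted group and adjusts upwards", {
  # one of three treated groups shifted by 3 sigma at n = 7
  hits <- vapply(1:200, function(s) {
    set.seed(200 + s)
    values <- c(rnorm(7, 0), rnorm(7, 0), rnorm(7, 3), rnorm(7, 0))
    groups <- rep(c("control", "g1", "g2", "g3"), each = 7)
    out <- dunnett_test(values, groups, "control", n_draws = 2e4)
    sig <- out$group[out$p_adjusted < 0.05]
    identical(sig, "g2")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # adjusted p never falls below unadjusted
  set.seed(103)
  values <- rnorm(28)
  groups <- rep(c("control", "a", "b", "c"), each = 7)
  out <- dunnett_test(values, groups, "control")
  expect_true(all(out$p_adjusted >= out$p_unadjusted))
})

test_that("dunnett adjusted p is monotone in the number of comparisons", {
  set.seed(107)
  values <- c(rnorm(6, 0), rnorm(6, 1))
  groups <- rep(c("control", "a"), each = 6)
  set.seed(109)
  p1 <- dunnett_test(values, groups, "control")$p_adjusted[1]
  # duplicate the treated group: same draws stream, one more comparison
  values2 <- c(values, values[groups == "a"])
  groups2 <- c(groups, rep("a2", 6))
  set.seed(109)
  out2 <- dunnett_test(values2, groups2, "control")
  expect_gte(out2$p_adjusted[out2$group == "a"], p1 - 0.01)
})
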