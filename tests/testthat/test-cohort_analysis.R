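test_that("classify_recist applies inclusive thresholds with PD precedence", {
  expect_equal(classify_recist(100, 100, 70), "PR")   # exactly 30% down
  expect_equal(classify_recist(100, 50, 60), "PD")    # exactly 20% over nadir
  expect_equal(classify_recist(100, 90, 85), "SD")
  expect_equal(classify_recist(100, 100, 0), "CR")
  # PD beats PR when both trigger (deep response then regrowth past 20%)
  expect_equal(classify_recist(100, 40, 60), "PD")
  expect_equal(classify_recist(c(100, 100), c(100, 50), c(70, 60)),
               c("PR", "PD"))
  expect_error(classify_recist(-1, 10, 10), "positive")
})

test_that("response_rates reproduces the published cohort endpoints", {
  patients <- gen_cohort(fixture = TRUE)
  rr <- response_rates(patients, arm_field = "ppi_user")
  # arms: FALSE = non-PPI (42), TRUE = PPI (16)
  expect_equal(unname(rowSums(rr$counts)), c(42, 16))
  expect_equal(round(100 * rr$orr[["FALSE"]]), 50)
  expect_equal(round(100 * rr$orr[["TRUE"]]), 25)
  expect_equal(round(100 * rr$dcr[["FALSE"]]), 90)
  expect_equal(round(100 * rr$dcr[["TRUE"]]), 69)
  # responder-vs-arm table has a cell below 5, so Fisher is selected
  expect_equal(rr$orr_test$test, "fisher")
  expect_true(rr$orr_test$p_value > 0.05)   # not significant, as reported
  # all-CR arm
  allcr <- data.frame(response = rep("CR", 5), arm = "x")
  rr2 <- response_rates(allcr, arm_field = "arm")
  expect_equal(unname(rr2$orr[["x"]]), 1)
  expect_equal(unname(rr2$dcr[["x"]]), 1)
})

test_that("ORR never exceeds DCR on random cohorts", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    patients <- data.frame(
      response = sample(c("CR", "PR", "SD", "PD"), n, replace = TRUE),
      arm = sample(c("a", "b"), n, replace = TRUE))
    if (min(table(patients$arm)) == 0) next
    rr <- response_rates(patients, arm_field = "arm")
    expect_true(all(rr$orr <= rr$dcr + 1e-12))
    expect_true(all(rr$orr >= 0 & rr$dcr <= 1))
  }
})

test_that("compare_categorical picks Fisher below the 5-count rule", {
  fish <- compare_categorical(rbind(c(21, 4), c(21, 12)))
  expect_equal(fish$test, "fisher")
  chi <- compare_categorical(rbind(c(20, 20), c(20, 20)))
  expect_equal(chi$test, "chi-square")
  expect_equal(chi$p_value, 1)
  # perfectly separated table, Fisher p from the enumeration oracle
  sep <- compare_categorical(rbind(c(10, 0), c(0, 10)))
  expect_equal(sep$test, "fisher")
  expect_equal(sep$p_value, oracle_fisher(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(compare_categorical(rbind(c(0, 0), c(3, 4))), "degenerate")
  # rule assertable on random tables: fisher iff any cell < 5
  set.seed(17)
  for (i in 1:40) {
    x <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    got <- compare_categorical(x)
    expect_equal(got$test, if (any(x < 5)) "fisher" else "chi-square")
  }
  # r x 2 tables with r > 2 are accepted
  rx2 <- compare_categorical(rbind(c(1, 2), c(5, 1), c(3, 3)))
  expect_equal(rx2$test, "fisher")
})

test_that("mann_whitney_u matches exact enumeration for small samples", {
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(out$method, "exact")
  set.seed(41)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:1000, nx); y <- setdiff(sample(1:1000, ny + nx), x)[1:ny]
    out <- mann_whitney_u(x, y)
    expect_equal(out$p_value, oracle_mwu(x, y), tolerance = 1e-12)
  }
})

test_that("mann_whitney_u handles ties and large samples sensibly", {
  x <- c(1, 2, 2, 3)
  out <- mann_whitney_u(x, x)   # identical multisets
  expect_equal(out$U, length(x)^2 / 2)
  expect_equal(out$p_value, 1)
  # strongly separated samples are highly significant
  big <- mann_whitney_u(101:110, 1:10)
  expect_lt(big$p_value, 0.001)
  # agreement with the normal-approximation reference implementation
  set.seed(43)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  out <- mann_whitney_u(x, y)
  expect_equal(out$U, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("mann_whitney_u is invariant to common monotone transforms", {
  set.seed(47)
  x <- rexp(12); y <- rexp(15) * 1.5
  base <- mann_whitney_u(x, y)
  for (f in list(function(v) log(v), function(v) v^3, function(v) 10 * v + 2)) {
    tr <- mann_whitney_u(f(x), f(y))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("hypertension event flag implements the three CTCAE-style criteria", {
  expect_true(flag_hypertension_event(120, c(130, 145)))        # delta >= 20
  expect_false(flag_hypertension_event(130, c(135, 139)))
  expect_true(flag_hypertension_event(140, c(142, 152)))        # absolute >= 150
  expect_true(flag_hypertension_event(130, 131, med_change = TRUE))
  expect_true(flag_hypertension_event(120, 140))                # boundary: exactly 20
  expect_error(flag_hypertension_event(NA, 140), "baseline")
  # monotone: raising any on-treatment value never flips TRUE -> FALSE
  set.seed(53)
  for (i in 1:30) {
    base <- runif(1, 100, 140)
    sbp <- runif(4, 100, 160)
    before <- flag_hypertension_event(base, sbp)
    j <- sample(4, 1)
    sbp[j] <- sbp[j] + runif(1, 0, 30)
    expect_true(flag_hypertension_event(base, sbp) >= before)
  }
})

test_that("sbp_change_summary computes arm deltas and between-arm p", {
  patients <- data.frame(
    ppi_user = c(FALSE, FALSE, TRUE, TRUE),
    sbp_before = c(120, 130, 118, 122),
    sbp_after = c(130, 150, 128, 132))
  out <- sbp_change_summary(patients)
  expect_equal(out$by_arm$mean_delta, c(15, 10))
  expect_equal(out$by_arm$n, c(2, 2))
  # all-zero deltas in both arms: no separation
  flat <- data.frame(ppi_user = rep(c(FALSE, TRUE), each = 3),
                     sbp_before = 120, sbp_after = 120)
  expect_equal(sbp_change_summary(flat)$p_value, 1)
  # unpaired patients are excluded with a warning
  patients$sbp_after[1] <- NA
  expect_warning(out2 <- sbp_change_summary(patients), "unpaired")
  expect_equal(sum(out2$by_arm$n), 3)
})

test_that("arms with published-scale SBP noise rarely separate", {
  # deltas drawn at the published means differ by ~0.4 mmHg: no signal
  set.seed(59)
  cfg <- cohort_gen_config(seed = 59)
  patients <- gen_cohort(cfg)
  out <- sbp_change_summary(patients)
  expect_gt(out$p_value, 0.05)
})
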