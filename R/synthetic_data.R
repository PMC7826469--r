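#' Configuration for the spontaneous-report generator
#'
#' Describes a synthetic reporting world: a base drug with a configurable
#' event odds ratio, comedications occurring only among base-drug reports
#' with their own within-base odds multipliers (multiplicative on the
#' odds scale, so the true conditional odds ratio equals the configured
#' multiplier exactly), a Zipf-weighted pool of background noise drugs,
#' demographic missingness, and case re-reporting (duplicate versions).
#'
#' @param n_cases number of distinct cases.
#' @param p_baseline_event event probability for an unexposed report.
#' @param base_drug canonical base drug name.
#' @param base_drug_prevalence probability a case lists the base drug.
#' @param or_base_drug event odds multiplier for base-drug reports.
#' @param comedications `NULL`, or data.frame with columns `name`,
#'   `prevalence` (among base-drug reports) and `or_within_base`.
#' @param background_drug_pool number of distinct noise drugs; report
#'   frequencies decay like 1/rank.
#' @param drugs_per_case_lambda each case lists `1 + Poisson(lambda)`
#'   noise drugs.
#' @param event_terms PT(s) recorded when the event occurs.
#' @param noise_reaction_pool number of distinct non-event PTs; each case
#'   lists `1 + Poisson(0.8)` of them.
#' @param duplication_rate probability a case is re-reported; a
#'   duplicated case carries `1 + Geometric(0.5)` extra earlier versions.
#' @param missing_age_rate,missing_sex_rate demographic missingness.
#' @param age_mean,age_sd age distribution (normal, clamped to 18-100).
#' @param seed integer RNG seed.
#' @return list of class `report_gen_config`.
#' @export
report_gen_config <- function(n_cases = 10000,
                              p_baseline_event = 0.05,
                              base_drug = "BEVACIZUMAB",
                              base_drug_prevalence = 0.1,
                              or_base_drug = 2.45,
                              comedications = NULL,
                              background_drug_pool = 50,
                              drugs_per_case_lambda = 1.5,
                              event_terms = "HYPERTENSION",
                              noise_reaction_pool = 30,
                              duplication_rate = 0.05,
                              missing_age_rate = 0.1,
                              missing_sex_rate = 0.05,
                              age_mean = 62, age_sd = 15,
                              seed = 1L) {
  probs <- c(p_baseline_event, base_drug_prevalence, duplication_rate,
             missing_age_rate, missing_sex_rate)
  .assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  .assert(or_base_drug > 0, "odds multipliers must be positive")
  .assert(n_cases >= 1, "n_cases must be positive")
  if (!is.null(comedications)) {
    .assert(all(c("name", "prevalence", "or_within_base") %in% names(comedications)),
            "comedications needs columns name, prevalence, or_within_base")
    .assert(all(comedications$prevalence >= 0 & comedications$prevalence <= 1),
            "comedication prevalences must lie in [0, 1]")
    .assert(all(comedications$or_within_base > 0), "odds multipliers must be positive")
  }
  structure(list(n_cases = as.integer(n_cases),
                 p_baseline_event = p_baseline_event,
                 base_drug = .canon(base_drug),
                 base_drug_prevalence = base_drug_prevalence,
                 or_base_drug = or_base_drug,
                 comedications = comedications,
                 background_drug_pool = as.integer(background_drug_pool),
                 drugs_per_case_lambda = drugs_per_case_lambda,
                 event_terms = .canon(event_terms),
                 noise_reaction_pool = as.integer(noise_reaction_pool),
                 duplication_rate = duplication_rate,
                 missing_age_rate = missing_age_rate,
                 missing_sex_rate = missing_sex_rate,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "report_gen_config")
}

#' Generate a synthetic spontaneous-report set
#'
#' A pure function of `cfg` (including its seed): reruns are identical.
#' Case-level truth (exposure, comedications, event) is drawn first;
#' duplicate earlier versions are drawn afterwards, so the deduplicated
#' output does not depend on the duplication rate.
#'
#' @param cfg a [report_gen_config].
#' @param write_dir optional directory: writes `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt` in the FAERS ASCII dialect plus `truth.json`.
#' @return list with `raw` (a `raw_record_set`), `truth` (data.table of
#'   per-case true exposure/event) and `params` (the config).
#' @export
gen_reports <- function(cfg, write_dir = NULL) {
  .assert(inherits(cfg, "report_gen_config"), "cfg must be a report_gen_config")
  set.seed(cfg$seed)
  n <- cfg$n_cases
  case_id <- as.character(seq_len(n))

  # --- case-level truth -------------------------------------------------
  exposed <- stats::runif(n) < cfg$base_drug_prevalence
  comeds <- cfg$comedications
  comed_mat <- NULL
  odds <- cfg$p_baseline_event / (1 - cfg$p_baseline_event) *
    cfg$or_base_drug^exposed
  if (!is.null(comeds) && nrow(comeds)) {
    comed_mat <- matrix(FALSE, n, nrow(comeds),
                        dimnames = list(NULL, comeds$name))
    for (j in seq_len(nrow(comeds))) {
      comed_mat[, j] <- exposed & stats::runif(n) < comeds$prevalence[j]
      odds <- odds * comeds$or_within_base[j]^comed_mat[, j]
    }
  }
  event <- stats::runif(n) < odds / (1 + odds)

  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 18), 100)
  age[stats::runif(n) < cfg$missing_age_rate] <- NA
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[stats::runif(n) < cfg$missing_sex_rate] <- "unknown"

  # noise drugs, Zipf-weighted by rank
  pool <- sprintf("NOISEDRUG%03d", seq_len(cfg$background_drug_pool))
  w <- 1 / seq_len(cfg$background_drug_pool)
  k_noise <- 1L + stats::rpois(n, cfg$drugs_per_case_lambda)
  noise_flat <- sample(pool, sum(k_noise), replace = TRUE, prob = w)
  noise_row <- rep.int(seq_len(n), k_noise)

  drug_flat <- c(noise_flat, rep(cfg$base_drug, sum(exposed)),
                 if (!is.null(comed_mat)) colnames(comed_mat)[col(comed_mat)][comed_mat])
  drug_row <- c(noise_row, which(exposed),
                if (!is.null(comed_mat)) row(comed_mat)[comed_mat])

  rpool <- sprintf("NOISEREACTION%03d", seq_len(cfg$noise_reaction_pool))
  k_reac <- 1L + stats::rpois(n, 0.8)
  reac_flat <- c(sample(rpool, sum(k_reac), replace = TRUE),
                 sample(cfg$event_terms, sum(event), replace = TRUE))
  reac_row <- c(rep.int(seq_len(n), k_reac), which(event))

  # --- duplicate earlier versions (downstream of truth) -----------------
  n_versions <- rep(1L, n)
  if (cfg$duplication_rate > 0) {
    dup <- stats::runif(n) < cfg$duplication_rate
    n_versions[dup] <- 2L + stats::rgeom(sum(dup), 0.5)
  }

  report_id <- paste0(case_id, "-", n_versions)
  demo <- data.table::data.table(report_id = report_id, case_id = case_id,
                                 version = as.numeric(n_versions),
                                 age_years = age, sex = sex)
  drug_rows <- data.table::data.table(report_id = report_id[drug_row],
                                      drug = drug_flat)
  reac_rows <- data.table::data.table(report_id = report_id[reac_row],
                                      pt = reac_flat)

  if (any(n_versions > 1L)) {
    # earlier versions repeat the case with a lower version key; the
    # drug list may be incomplete there (re-reporting adds information)
    extra_case <- rep.int(which(n_versions > 1L), n_versions[n_versions > 1L] - 1L)
    extra_ver <- unlist(lapply(n_versions[n_versions > 1L] - 1L, seq_len),
                        use.names = FALSE)
    extra_id <- paste0(case_id[extra_case], "-", extra_ver)
    demo <- rbind(demo, data.table::data.table(
      report_id = extra_id, case_id = case_id[extra_case],
      version = as.numeric(extra_ver), age_years = age[extra_case],
      sex = sex[extra_case]))
    first_noise <- noise_flat[match(extra_case, noise_row)]
    drug_rows <- rbind(drug_rows,
                       data.table::data.table(report_id = extra_id,
                                              drug = first_noise))
    first_reac <- reac_flat[match(extra_case, reac_row)]
    reac_rows <- rbind(reac_rows,
                       data.table::data.table(report_id = extra_id,
                                              pt = first_reac))
  }

  truth <- data.table::data.table(case_id = case_id, exposed = exposed,
                                  event = event)
  if (!is.null(comed_mat)) {
    for (nm in colnames(comed_mat)) truth[[paste0("comed_", nm)]] <- comed_mat[, nm]
  }
  raw <- raw_record_set(demo, drug_rows, reac_rows)
  out <- list(raw = raw, truth = truth, params = cfg)
  if (!is.null(write_dir)) write_faers_files(out, write_dir)
  out
}

#' Write a generated report set as FAERS-dialect files
#'
#' @param gen output of [gen_reports].
#' @param dir output directory (created if needed).
#' @param quarter tag appended to the file names, e.g. `"15Q2"`.
#' @return the directory, invisibly.
#' @export
write_faers_files <- function(gen, dir, quarter = "15Q2") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- gen$raw$demo_rows
  demo_out <- data.table::data.table(
    report_id = d$report_id, case_id = d$case_id, version = d$version,
    age = d$age_years, age_cod = data.table::fifelse(is.na(d$age_years), "", "YR"),
    sex = data.table::fifelse(d$sex == "unknown", "", d$sex))
  data.table::fwrite(demo_out, file.path(dir, paste0("DEMO", quarter, ".txt")),
                     sep = "$", quote = FALSE, na = "")
  data.table::fwrite(gen$raw$drug_rows,
                     file.path(dir, paste0("DRUG", quarter, ".txt")),
                     sep = "$", quote = FALSE)
  data.table::fwrite(gen$raw$reac_rows,
                     file.path(dir, paste0("REAC", quarter, ".txt")),
                     sep = "$", quote = FALSE)
  truth <- c(list(params = unclass(gen$params)),
             list(cases = as.data.frame(gen$truth)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Configuration for the chart-review cohort generator
#'
#' @param n_per_arm named integer vector: patients per arm (names are the
#'   arm labels; the first arm is the reference).
#' @param response_probs list of per-arm probability vectors over
#'   `CR`, `PR`, `SD`, `PD` (each summing to 1).
#' @param sbp_baseline list of per-arm `c(mean, sd)` for pre-treatment
#'   systolic pressure.
#' @param sbp_delta list of per-arm `c(mean, sd)` for the on-treatment
#'   rise.
#' @param p_male,p_xelox,p_antihypertensive per-arm probabilities for the
#'   binary covariates.
#' @param stage_probs list of per-arm probabilities over stages
#'   `I`, `II`, `IIIa`, `IV`.
#' @param seed integer RNG seed.
#' @return list of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_per_arm = c(non_PPI = 42, PPI = 16),
                              response_probs = list(
                                non_PPI = c(CR = 0, PR = 0.5, SD = 0.405, PD = 0.095),
                                PPI = c(CR = 0, PR = 0.25, SD = 0.4375, PD = 0.3125)),
                              sbp_baseline = list(non_PPI = c(130, 15.33),
                                                  PPI = c(120, 5.39)),
                              sbp_delta = list(non_PPI = c(13.55, 5),
                                               PPI = c(13.94, 5)),
                              p_male = c(non_PPI = 0.5, PPI = 0.63),
                              p_xelox = c(non_PPI = 0.5, PPI = 0.75),
                              p_antihypertensive = c(non_PPI = 0.17, PPI = 0.19),
                              stage_probs = list(
                                non_PPI = c(I = 0.024, II = 0.024, IIIa = 0.119, IV = 0.833),
                                PPI = c(I = 0, II = 0, IIIa = 0.0625, IV = 0.9375)),
                              seed = 1L) {
  .assert(all(n_per_arm >= 1), "every arm needs at least one patient")
  .assert(!is.null(names(n_per_arm)), "n_per_arm must be named by arm")
  for (a in names(n_per_arm)) {
    .assert(abs(sum(response_probs[[a]]) - 1) < 1e-8,
            sprintf("response_probs for arm %s must sum to 1", a))
    .assert(abs(sum(stage_probs[[a]]) - 1) < 1e-8,
            sprintf("stage_probs for arm %s must sum to 1", a))
  }
  structure(list(n_per_arm = n_per_arm, response_probs = response_probs,
                 sbp_baseline = sbp_baseline, sbp_delta = sbp_delta,
                 p_male = p_male, p_xelox = p_xelox,
                 p_antihypertensive = p_antihypertensive,
                 stage_probs = stage_probs, seed = as.integer(seed)),
            class = "cohort_gen_config")
}

#' Generate a chart-review cohort table
#'
#' Stochastic mode draws every field from the config distributions;
#' fixture mode (`fixture = TRUE`) ignores the distributions and emits
#' the embedded published-count cohort exactly (58 colorectal-cancer
#' patients: 42 non-PPI with responses 0/21/17/4 and 16 PPI with
#' 0/4/7/5, plus matching covariate counts), so downstream endpoint
#' statistics reproduce the reference table deterministically.
#'
#' @param cfg a [cohort_gen_config] (ignored in fixture mode).
#' @param fixture logical: emit the embedded deterministic cohort.
#' @return data.frame, one row per patient: `patient_id`, `ppi_user`,
#'   `age_years`, `sex`, `stage`, `ps`, `regimen`,
#'   `antihypertensive_baseline`, `response`, `sbp_before`, `sbp_after`.
#' @export
gen_cohort <- function(cfg = cohort_gen_config(), fixture = FALSE) {
  if (fixture) {
    path <- system.file("extdata", "table3_cohort_counts.tsv",
                        package = "pvscreen", mustWork = TRUE)
    counts <- utils::read.delim(path, check.names = FALSE)
    rows <- lapply(seq_len(nrow(counts)), function(i) {
      k <- counts[i, ]
      n <- k$n
      sbp0 <- if (k$arm == "PPI") 120 else 130
      sbp1 <- if (k$arm == "PPI") 134 else 143
      data.frame(
        patient_id = paste0(k$arm, "_", seq_len(n)),
        ppi_user = k$arm == "PPI",
        age_years = if (k$arm == "PPI") 62 else 68,
        sex = rep(c("M", "F"), c(k$male, n - k$male)),
        stage = rep(c("I", "II", "IIIa", "IV"),
                    c(k$stage_I, k$stage_II, k$stage_IIIa, k$stage_IV)),
        ps = rep(c(0, 1, 2), c(k$ps0, k$ps1, k$ps2)),
        regimen = rep(c("XELOX", "mFOLFOX6"), c(k$xelox, n - k$xelox)),
        antihypertensive_baseline = rep(c(TRUE, FALSE),
                                        c(k$antihypertensive, n - k$antihypertensive)),
        response = rep(c("CR", "PR", "SD", "PD"), c(k$CR, k$PR, k$SD, k$PD)),
        sbp_before = sbp0, sbp_after = sbp1)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  .assert(inherits(cfg, "cohort_gen_config"), "cfg must be a cohort_gen_config")
  set.seed(cfg$seed)
  rows <- lapply(names(cfg$n_per_arm), function(a) {
    n <- cfg$n_per_arm[[a]]
    sbp0 <- stats::rnorm(n, cfg$sbp_baseline[[a]][1], cfg$sbp_baseline[[a]][2])
    data.frame(
      patient_id = paste0(a, "_", seq_len(n)),
      ppi_user = a == names(cfg$n_per_arm)[2],
      age_years = round(pmin(pmax(stats::rnorm(n, 66, 10), 18), 95)),
      sex = sample(c("M", "F"), n, TRUE,
                   prob = c(cfg$p_male[[a]], 1 - cfg$p_male[[a]])),
      stage = sample(names(cfg$stage_probs[[a]]), n, TRUE,
                     prob = cfg$stage_probs[[a]]),
      ps = sample(0:2, n, TRUE, prob = c(0.5, 0.45, 0.05)),
      regimen = sample(c("XELOX", "mFOLFOX6"), n, TRUE,
                       prob = c(cfg$p_xelox[[a]], 1 - cfg$p_xelox[[a]])),
      antihypertensive_baseline = stats::runif(n) < cfg$p_antihypertensive[[a]],
      response = sample(names(cfg$response_probs[[a]]), n, TRUE,
                        prob = cfg$response_probs[[a]]),
      sbp_before = sbp0,
      sbp_after = sbp0 + stats::rnorm(n, cfg$sbp_delta[[a]][1],
                                      cfg$sbp_delta[[a]][2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic log2 expression matrix with planted effects
#'
#' Values are `Normal(gene baseline + group shift, sigma)`; planted
#' shifts (in log2 units) apply to `effect_group`. Gene baselines are
#' drawn uniformly on `baseline_range`. Named planted effects introduce
#' those gene identifiers into the matrix.
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector of samples per group.
#' @param sigma residual SD of the log2 intensities.
#' @param planted_effects named numeric vector: gene -> log2 shift.
#' @param effect_group group receiving the shift (default: first group).
#' @param baseline_range range of gene baseline log2 intensities.
#' @param seed integer RNG seed.
#' @return list with `mat` (an [expression_matrix]) and `truth` (the
#'   planted effects and parameters).
#' @export
gen_expression <- function(n_genes = 50,
                           group_sizes = c(treated = 3, vehicle = 3),
                           sigma = 0.2, planted_effects = numeric(),
                           effect_group = names(group_sizes)[1],
                           baseline_range = c(5, 12), seed = 1L) {
  .assert(all(group_sizes >= 1), "every group needs at least one sample")
  .assert(!is.null(names(group_sizes)), "group_sizes must be named")
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  nm <- names(planted_effects)
  if (length(planted_effects)) {
    .assert(!is.null(nm), "planted_effects must be named by gene")
    extra <- setdiff(nm, genes)
    .assert(length(extra) <= n_genes, "more planted genes than n_genes")
    genes[seq_along(extra)] <- extra
  }
  groups <- rep(names(group_sizes), group_sizes)
  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  shift <- numeric(n_genes)
  shift[match(nm, genes)] <- planted_effects
  mu <- outer(baseline, rep(1, length(groups))) +
    outer(shift, as.numeric(groups == effect_group))
  noise <- matrix(stats::rnorm(length(mu), 0, sigma), nrow(mu), ncol(mu))
  values <- mu + noise
  dimnames(values) <- list(genes,
                           paste0(groups, "_", unlist(lapply(group_sizes, seq_len))))
  list(mat = expression_matrix(values, groups),
       truth = list(planted_effects = planted_effects,
                    effect_group = effect_group, sigma = sigma,
                    group_sizes = group_sizes, seed = as.integer(seed)))
}
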