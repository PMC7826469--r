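.config_error <- function(msg) {
  stop(structure(class = c("pvscreen_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
.data_error <- function(msg) {
  stop(structure(class = c("pvscreen_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.known_stages <- c("simulate", "dedup", "signal", "screen", "cohort",
                   "expression")

#' Read a pipeline run configuration
#'
#' YAML (preferred, when the yaml package is available) or JSON file with
#' the fields of [run_pipeline]'s `config` argument.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      .config_error("yaml package not installed; supply a JSON config")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.validate_config <- function(config) {
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) stages <- .known_stages
  bad <- setdiff(stages, .known_stages)
  if (length(bad)) {
    .config_error(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  for (f in c("term_set_file", "synonym_file", "pathway_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      .config_error(sprintf("%s does not exist: %s", f, config[[f]]))
    }
  }
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config$exposure_drug <- config$exposure_drug %||% "BEVACIZUMAB"
  config
}

# stable hash of the effective analytic configuration (md5 of its
# serialization); the output location does not alter the analysis
.config_hash <- function(config) {
  config$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 3, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the end-to-end analysis pipeline
#'
#' Wires the stages together: simulate (or load) a report set,
#' deduplicate, compute the total and stratified signal statistics for
#' the exposure drug, screen comedications, summarize the chart-review
#' cohort endpoints, and run the expression comparison. Each stage writes
#' a tab-separated artifact into `out_dir`; a machine-readable
#' `manifest.json` records the package version, seed, configuration hash
#' and an md5 checksum per artifact, so identical config + seed yields
#' byte-identical artifacts. On stage failure the partial artifacts are
#' kept next to a `FAILED` marker file.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `stages` (subset of simulate/dedup/signal/screen/cohort/expression,
#'   or `"all"`), `out_dir`, `seed`, `exposure_drug`, `alpha`,
#'   `term_set_file`, `synonym_file`, `pathway_file`, `faers` (list of
#'   `demo`/`drug`/`reac` paths when not simulating), `simulate_reports`
#'   (arguments for [report_gen_config]), `screen` (arguments for
#'   [screen_comedications]), `cohort` (`patients` path or
#'   `fixture = TRUE` or [cohort_gen_config] arguments; `arm`),
#'   `expression` (`matrix` path or [gen_expression] arguments;
#'   `group_a`, `group_b`).
#' @return invisibly, a list with `out_dir`, `artifacts` (paths) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- .validate_config(config)
  out_dir <- config$out_dir %||% .config_error("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  artifacts <- character()
  stages <- config$stages

  run <- function() {
    terms <- if (!is.null(config$term_set_file)) {
      load_term_set(config$term_set_file)
    } else default_hypertension_terms()
    synonyms <- if (!is.null(config$synonym_file)) {
      load_synonym_map(config$synonym_file)
    } else NULL

    reports <- NULL
    if ("simulate" %in% stages) {
      args <- config$simulate_reports %||% list()
      args$seed <- args$seed %||% config$seed
      cfg <- do.call(report_gen_config, args)
      sim_dir <- file.path(out_dir, "simulated")
      gen <- gen_reports(cfg, write_dir = sim_dir)
      artifacts <<- c(artifacts, file.path(sim_dir, "truth.json"))
      raw <- gen$raw
    } else if (!is.null(config$faers)) {
      raw <- read_faers_tables(config$faers$demo, config$faers$drug,
                               config$faers$reac, synonyms = synonyms)
      if (length(raw$rejects)) {
        rej <- file.path(out_dir, "rejects.txt")
        writeLines(raw$rejects, rej)
        artifacts <<- c(artifacts, rej)
      }
    } else raw <- NULL

    if ("dedup" %in% stages) {
      if (is.null(raw)) .data_error("dedup stage needs simulated or loaded FAERS tables")
      reports <- deduplicate(raw)
      p <- file.path(out_dir, "reports.tsv")
      write_case_reports(reports, p)
      artifacts <<- c(artifacts, p)
    } else if (!is.null(config$reports_file)) {
      reports <- read_case_reports(config$reports_file)
    }

    if ("signal" %in% stages) {
      if (is.null(reports)) .data_error("signal stage needs a deduplicated report set")
      total <- ror(build_contingency(reports, config$exposure_drug, terms),
                   alpha = config$alpha)
      p <- file.path(out_dir, "signal_total.tsv")
      write_signal_table(total, p, exposure = config$exposure_drug,
                         event = terms$name)
      artifacts <<- c(artifacts, p)
      for (v in c("sex", "age")) {
        s <- stratified_ror(reports, config$exposure_drug, terms,
                            spec = stratum_spec(v), alpha = config$alpha)
        p <- file.path(out_dir, sprintf("signal_by_%s.tsv", v))
        write_signal_table(s, p, exposure = config$exposure_drug,
                           event = terms$name)
        artifacts <<- c(artifacts, p)
      }
    }

    if ("screen" %in% stages) {
      if (is.null(reports)) .data_error("screen stage needs a deduplicated report set")
      sc <- config$screen %||% list()
      rows <- screen_comedications(reports, config$exposure_drug, terms,
                                   min_coreports = sc$min_coreports %||% 100,
                                   alpha = config$alpha,
                                   direction = sc$direction %||% "inverse")
      p <- file.path(out_dir, "screen.tsv")
      screen_summary(rows, path = p, qvalues = isTRUE(sc$qvalues))
      artifacts <<- c(artifacts, p)
    }

    if ("cohort" %in% stages) {
      cc <- config$cohort %||% list()
      patients <- if (!is.null(cc$patients)) {
        utils::read.delim(cc$patients, check.names = FALSE)
      } else if (isTRUE(cc$fixture)) {
        gen_cohort(fixture = TRUE)
      } else {
        args <- cc$config %||% list()
        args$seed <- args$seed %||% config$seed
        gen_cohort(do.call(cohort_gen_config, args))
      }
      arm <- cc$arm %||% "ppi_user"
      rr <- response_rates(patients, arm_field = arm)
      arm_names <- rownames(rr$counts)
      summ <- data.frame(
        arm = arm_names, n = rowSums(rr$counts),
        CR = rr$counts[, "CR"], PR = rr$counts[, "PR"],
        SD = rr$counts[, "SD"], PD = rr$counts[, "PD"],
        orr_pct = round(100 * rr$orr[arm_names]),
        dcr_pct = round(100 * rr$dcr[arm_names]),
        orr_test = rr$orr_test$test %||% NA, orr_p = rr$orr_test$p_value %||% NA,
        dcr_test = rr$dcr_test$test %||% NA, dcr_p = rr$dcr_test$p_value %||% NA)
      p <- file.path(out_dir, "cohort_summary.tsv")
      data.table::fwrite(summ, p, sep = "\t", quote = FALSE)
      artifacts <<- c(artifacts, p)
      sbp <- sbp_change_summary(patients, arm_field = arm)
      sbp$by_arm$p_between <- sbp$p_value
      p <- file.path(out_dir, "sbp_summary.tsv")
      data.table::fwrite(sbp$by_arm, p, sep = "\t", quote = FALSE)
      artifacts <<- c(artifacts, p)
    }

    if ("expression" %in% stages) {
      ec <- config$expression %||% list()
      mat <- if (!is.null(ec$matrix)) {
        read_expression_matrix(ec$matrix)
      } else {
        args <- ec$config %||% list()
        args$seed <- args$seed %||% config$seed
        do.call(gen_expression, args)$mat
      }
      gset <- if (!is.null(config$pathway_file)) {
        load_gene_set(config$pathway_file)
      } else default_vegf_pathway()
      grps <- unique(mat$groups)
      res <- pathway_compare(mat, gset,
                             grpA = ec$group_a %||% grps[1],
                             grpB = ec$group_b %||% grps[2])
      p <- file.path(out_dir, "expression.tsv")
      data.table::fwrite(res, p, sep = "\t", quote = FALSE)
      artifacts <<- c(artifacts, p)
    }
  }

  res <- tryCatch({ run(); TRUE }, error = function(e) e)
  if (inherits(res, "pvscreen_config_error") || inherits(res, "pvscreen_data_error")) {
    stop(res)
  }
  ok <- isTRUE(res)
  if (!ok) {
    writeLines(conditionMessage(res), failed_marker)
    message("stage failure: ", conditionMessage(res))
  }

  manifest <- list(
    package = "pvscreen",
    version = as.character(utils::packageVersion("pvscreen")),
    seed = config$seed,
    config_hash = .config_hash(config),
    status = if (ok) "ok" else "failed",
    artifacts = lapply(artifacts, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!ok) {
    stop(structure(class = c("pvscreen_stage_error", "error", "condition"),
                   list(message = sprintf("pipeline failed; partial artifacts in %s",
                                          out_dir),
                        call = NULL)))
  }
  invisible(list(out_dir = out_dir, artifacts = artifacts, manifest = manifest))
}
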