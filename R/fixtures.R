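#' Embedded published-count fixtures
#'
#' Accessors for the count tables shipped under `extdata`: the total and
#' stratified bevacizumab-hypertension contingency counts
#' (`fixture_strata_counts`) and the comedication screen counts
#' (`fixture_comed_counts`). These are the package's reference inputs
#' for deterministic reproduction of the published signal statistics.
#'
#' @return data.frame of counts.
#' @export
fixture_strata_counts <- function() {
  utils::read.delim(system.file("extdata", "table1_strata_counts.tsv",
                                package = "pvscreen", mustWork = TRUE),
                    check.names = FALSE)
}

#' @rdname fixture_strata_counts
#' @export
fixture_comed_counts <- function() {
  utils::read.delim(system.file("extdata", "table2_comed_counts.tsv",
                                package = "pvscreen", mustWork = TRUE),
                    check.names = FALSE)
}

#' Deterministic fixture report set matching the embedded counts
#'
#' Builds a [case_reports] object whose four-group contingency table,
#' sex and age stratum tables and comedication co-report counts all equal
#' the embedded published counts exactly. Only marginal counts are
#' published, so the joint assignment of sex, age and comedication within
#' each exposure-by-event cell is by position (each marginal constraint
#' is satisfied independently); reports beyond the stratum sums carry
#' unknown sex or missing age, which is why stratum totals fall short of
#' the grand total. Drug and reaction list columns share storage across
#' reports, so the full ~3.7 million-report set stays lightweight.
#'
#' @param subset `"all"` for the full four-group set, `"exposed"` for
#'   only the base-drug reports (sufficient for the comedication screen
#'   and much faster).
#' @param base_drug,event_term the canonical names planted in the set.
#' @return a [case_reports] object.
#' @export
fixture_reports <- function(subset = c("all", "exposed"),
                            base_drug = "BEVACIZUMAB",
                            event_term = "HYPERTENSION") {
  subset <- match.arg(subset)
  strata <- fixture_strata_counts()
  comed <- fixture_comed_counts()
  tot <- strata[strata$variable == "total", ]
  a <- tot$event_exposed
  b <- tot$n_exposed - tot$event_exposed
  c_ <- tot$event_unexposed
  d <- tot$n_unexposed - tot$event_unexposed

  sexes <- strata[strata$variable == "sex", ]
  ages <- strata[strata$variable == "age", ]
  age_mid <- c(`<40` = 30, `40-49` = 45, `50-59` = 55, `60-69` = 65,
               `70-100` = 75)

  # per-cell marginal counts: (event among exposed, non-event among
  # exposed, event among unexposed, non-event among unexposed)
  cell_counts <- function(ev, n) c(ev[1], n[1] - ev[1], ev[2], n[2] - ev[2])
  # columns: one row per stratum; cells derived from the printed margins
  sex_cells <- mapply(function(ev_un, n_un, ev_ex, n_ex) {
    c(ev_ex, n_ex - ev_ex, ev_un, n_un - ev_un)
  }, sexes$event_unexposed, sexes$n_unexposed, sexes$event_exposed,
     sexes$n_exposed)
  age_cells <- mapply(function(ev_un, n_un, ev_ex, n_ex) {
    c(ev_ex, n_ex - ev_ex, ev_un, n_un - ev_un)
  }, ages$event_unexposed, ages$n_unexposed, ages$event_exposed,
     ages$n_exposed)

  build_cell <- function(n_cell, cell_idx, exposed, event) {
    sx <- sex_cells[cell_idx, ]
    sex <- rep(c(sexes$stratum, "unknown"), c(sx, n_cell - sum(sx)))
    ag <- age_cells[cell_idx, ]
    age <- rep(c(age_mid[ages$stratum], NA), c(ag, n_cell - sum(ag)))
    base <- if (exposed) base_drug else "NOBASE"
    if (exposed) {
      cm <- if (event) comed$event_with else comed$n_with - comed$event_with
      drugs <- c(lapply(seq_len(nrow(comed)), function(j) {
        rep(list(c(base_drug, comed$drug[j])), cm[j])
      }), list(rep(list(base_drug), n_cell - sum(cm))))
      drugs <- do.call(c, drugs)
    } else {
      drugs <- rep(list(base), n_cell)
    }
    reactions <- rep(list(if (event) event_term else "NAUSEA"), n_cell)
    list(sex = sex, age = age, drugs = drugs, reactions = reactions)
  }

  cells <- list(build_cell(a, 1, TRUE, TRUE), build_cell(b, 2, TRUE, FALSE))
  if (subset == "all") {
    cells <- c(cells, list(build_cell(c_, 3, FALSE, TRUE),
                           build_cell(d, 4, FALSE, FALSE)))
  }
  n_total <- sum(vapply(cells, function(x) length(x$sex), 0L))
  case_reports(
    case_id = as.character(seq_len(n_total)),
    age_years = unlist(lapply(cells, `[[`, "age"), use.names = FALSE),
    sex = unlist(lapply(cells, `[[`, "sex"), use.names = FALSE),
    drugs = do.call(c, lapply(cells, `[[`, "drugs")),
    reactions = do.call(c, lapply(cells, `[[`, "reactions"))
  )
}

#' Bundled default event definition and pathway set
#'
#' Convenience loaders for the packaged hypertension term list and the
#' VEGF-pathway gene list.
#'
#' @return an [event_term_set] / `pathway_gene_set`.
#' @export
default_hypertension_terms <- function() {
  load_term_set(system.file("extdata", "hypertension_smq.txt",
                            package = "pvscreen", mustWork = TRUE),
                name = "hypertension_smq")
}

#' @rdname default_hypertension_terms
#' @export
default_vegf_pathway <- function() {
  load_gene_set(system.file("extdata", "vegf_pathway_map04370.txt",
                            package = "pvscreen", mustWork = TRUE),
                name = "VEGF signaling (map04370)")
}
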