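#' Simulation options for the relatedness check
#'
#' Controls the simulation stage of [run_ibdcheck()].  By default no pairs
#' are simulated (`simulate = FALSE`): the run returns study-pair estimates
#' only.  When simulation is requested, the default relationship set is
#' unrelated, duplicates/MZ, parent-offspring, full siblings and half
#' siblings; first cousins (rarely distinguishable from unrelated with
#' candidate-gene panels) and user pedigrees are simulated only on request.
#'
#' @param simulate simulate reference pairs and build ellipses?
#' @param relationships character vector of relationship names; may include
#'   `"cousins"` and `"user"` (the latter requires `user_pedigree`).
#' @param n_pairs simulated pairs per relationship (default 200).
#' @param ellipse_coverage nominal prediction-ellipse coverage (default 0.95).
#' @param fit_ld fit the Markov LD model (`TRUE`, default) or assume
#'   independent SNPs (`FALSE`).
#' @param ld_dir directory of previously saved model files; when given,
#'   fitting is skipped and the files are reloaded.
#' @param user_pedigree pedigree data frame for the `"user"` relationship.
#' @param mimic_missingness copy study missingness patterns onto simulated
#'   pairs (default TRUE).
#' @return a list of class `sim_control`.
#' @export
sim_control <- function(simulate = FALSE,
                        relationships = c("unrelated", "dup.mz",
                                          "parent.offspring", "full.sibs",
                                          "half.sibs"),
                        n_pairs = 200, ellipse_coverage = 0.95,
                        fit_ld = TRUE, ld_dir = NULL, user_pedigree = NULL,
                        mimic_missingness = TRUE) {
  if (n_pairs < 3) stop("n_pairs must be at least 3")
  if (ellipse_coverage <= 0 || ellipse_coverage >= 1)
    stop("ellipse_coverage must lie in (0, 1)")
  known <- c("unrelated", "dup.mz", "parent.offspring", "full.sibs",
             "half.sibs", "cousins", "user")
  bad <- setdiff(relationships, known)
  if (length(bad)) stop("unknown relationship(s): ", paste(bad, collapse = ", "))
  if ("user" %in% relationships && !is.data.frame(user_pedigree))
    stop("relationship 'user' requires a user_pedigree data frame")
  if (!"unrelated" %in% relationships)
    relationships <- c("unrelated", relationships)
  structure(list(simulate = isTRUE(simulate), relationships = relationships,
                 n_pairs = n_pairs, ellipse_coverage = ellipse_coverage,
                 fit_ld = isTRUE(fit_ld), ld_dir = ld_dir,
                 user_pedigree = user_pedigree,
                 mimic_missingness = isTRUE(mimic_missingness)),
            class = "sim_control")
}

#' Run the cryptic-relatedness check
#'
#' End-to-end pipeline: quality control, conditional IBS tables from the
#' reference pool, method-of-moments IBD estimates for all study pairs, and
#' (optionally) LD-model fitting or reloading, gene-drop simulation of
#' reference pairs, prediction-ellipse construction and automatic flagging.
#' The unrelated ellipse used for flagging and in the overview plot is
#' Bonferroni-adjusted for the number of study pairs; relationship ellipses
#' use the nominal coverage.
#'
#' @param data a [genotype_table()].
#' @param filter a [filter_control()] object.
#' @param sim a [sim_control()] object.
#' @param seed optional integer seed; recorded in the result.
#' @param ld_out directory where fitted model files are written (default: a
#'   fresh directory under `tempdir()`).
#' @return object of class `ibd_result`: `study` (pair estimates), `sim`
#'   (per-relationship simulated estimates), `ellipses` (nominal coverage,
#'   plus `unrelated_adjusted`), `flagged`, `ld_files`, `qc_report`,
#'   `config` and `seed`.
#' @export
run_ibdcheck <- function(data, filter = filter_control(), sim = sim_control(),
                         seed = NULL, ld_out = NULL) {
  if (!inherits(data, "genotype_table")) stop("data must be a genotype_table")
  if (!is.null(seed)) set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  qc <- stage("qc", apply_qc(data, filter))
  tables <- stage("conditional_tables", cond_ibs_tables(qc$data))
  study <- stage("study_estimates", estimate_all_pairs(qc$data, tables))

  sims <- list(); ellipses <- list(); flagged <- NULL
  ld_files <- character(); models <- NULL
  if (sim$simulate) {
    if (!is.null(sim$ld_dir)) {
      paths <- sort(list.files(sim$ld_dir, pattern = "^ldmodel_chr.*\\.txt$",
                               full.names = TRUE))
      if (!length(paths)) stop("no model files found in ", sim$ld_dir)
      models <- stage("ld_load", load_models(paths))
      ld_files <- paths
      message("run_ibdcheck: reusing ", length(paths),
              " model file(s) from ", sim$ld_dir, "; fitting skipped")
    } else {
      models <- stage("ld_fit", fit_all_models(qc$data, fit_ld = sim$fit_ld))
      if (is.null(ld_out))
        ld_out <- file.path(tempdir(),
                            paste0("ldmodels_", format(Sys.time(), "%H%M%S"),
                                   "_", sample.int(1e6, 1)))
      ld_files <- stage("ld_save", save_models(models, ld_out))
    }

    for (rel in sim$relationships) {
      relspec <- if (rel == "user") sim$user_pedigree else rel
      est <- stage(paste0("simulate_", rel),
                   simulate_reference_pairs(relspec, sim$n_pairs, models,
                                            qc$data, tables,
                                            sim$mimic_missingness))
      sims[[rel]] <- est
      ok <- est[est$status == "ok", ]
      ellipses[[rel]] <- fit_ellipse(ok[, c("k0", "k1")],
                                     sim$ellipse_coverage, rel)
    }
    adj <- bonferroni_adjust(sim$ellipse_coverage, nrow(study))
    unrel_ok <- sims$unrelated[sims$unrelated$status == "ok", ]
    ellipses$unrelated_adjusted <-
      fit_ellipse(unrel_ok[, c("k0", "k1")], adj, "unrelated")
    flag_set <- ellipses[setdiff(names(ellipses),
                                 c("unrelated", "unrelated_adjusted"))]
    flag_set$unrelated <- ellipses$unrelated_adjusted
    flagged <- stage("flagging", flag_pairs(study, flag_set))
  }

  structure(list(study = study, sim = sims, ellipses = ellipses,
                 flagged = flagged, ld_files = ld_files,
                 qc_report = qc$report,
                 config = list(filter = filter, sim = sim), seed = seed),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat("ibd_result:", nrow(x$study), "study pairs")
  if (length(x$sim))
    cat(";", length(x$sim), "simulated relationship cluster(s);",
        if (is.null(x$flagged)) 0L else nrow(x$flagged), "flagged pair(s)")
  cat("\n")
  if (!is.null(x$flagged) && nrow(x$flagged)) {
    cat("flagged pairs:\n")
    print(x$flagged)
  }
  invisible(x)
}
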