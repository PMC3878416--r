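#' Run the full design / simulate / fit / rank pipeline
#'
#' Orchestrates the end-to-end workflow on a synthetic world: generate the
#' per-trial field and laboratory designs, simulate the phenotype table
#' from the configured variance components, fit the requested models by
#' REML, and derive heritabilities, variance tables, likelihood-ratio
#' tests, top-k rankings and the cross-model concordance report. All
#' stage outputs are written to `out_dir` together with a manifest of MD5
#' checksums, and the run is reproducible from the config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; one run per directory).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the designs, phenotype table, fits and
#'   summary; the same content is on disk under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                                 sprintf(...))
  t_all <- proc.time()[3]
  seed <- config$seed
  trials <- names(config$trials)

  stage <- "designs"
  res <- tryCatch({
    log_stage("stage designs: %d trials", length(trials))
    designs <- generate_trial_designs(config, seed)
    for (tr in trials) {
      write_design(designs$field[[tr]], file.path(out_dir, paste0("field_", tr, ".csv")))
      write_design(designs$lab[[tr]], file.path(out_dir, paste0("lab_", tr, ".csv")))
      write_cultivar_list(config$trials[[tr]]$cultivars,
                          file.path(out_dir, paste0("cultivars_", tr, ".txt")))
    }
    confound <- do.call(rbind, lapply(trials, function(tr)
      cbind(trial = tr, check_confounding(designs$field[[tr]], designs$lab[[tr]]))))
    data.table::fwrite(confound, file.path(out_dir, "confounding.csv"))

    stage <- "simulate"
    log_stage("stage simulate")
    pheno <- simulate_met(designs$field, designs$lab, config$vc, config$means,
                          seed = (seed * 977L + 11L) %% .Machine$integer.max)
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    log_stage("  %d wells simulated", nrow(pheno))

    stage <- "fit"
    term_lists <- realized_term_lists(config$vc)
    fits <- list()
    prev_theta <- NULL
    for (kind in intersect(c("A", "B", "C"), config$models)) {
      log_stage("stage fit: model %s", kind)
      sp <- spec_model(kind, pheno, term_lists = term_lists)
      fits[[kind]] <- fit_reml(sp, pheno, opts = list(start = prev_theta))
      prev_theta <- fits[[kind]]$theta
      write_fit(fits[[kind]], file.path(out_dir, paste0("fit_", kind, ".json")))
      log_stage("  loglik %.2f (%d params)", fits[[kind]]$loglik,
                fits[[kind]]$n_params)
    }

    stage <- "summaries"
    log_stage("stage summaries")
    herit <- do.call(rbind, lapply(names(fits), function(kind)
      do.call(rbind, lapply(trials, function(tr) data.frame(
        model = kind, trial = tr,
        heritability = heritability(fits[[kind]], tr),
        avg_pev = mean(diag(fits[[kind]]$pev_blocks[[tr]])),
        stringsAsFactors = FALSE)))))
    data.table::fwrite(herit, file.path(out_dir, "heritability.csv"))
    for (kind in names(fits)) for (tr in trials)
      data.table::fwrite(variance_table(fits[[kind]], tr),
                         file.path(out_dir, sprintf("varcomp_%s_%s.csv", kind, tr)))
    lrts <- NULL
    pairs_nested <- list(c("A", "B"), c("B", "C"))
    for (pr in pairs_nested) {
      if (all(pr %in% names(fits))) {
        tst <- lrt(fits[[pr[1]]], fits[[pr[2]]])
        lrts <- rbind(lrts, cbind(nested = pr[1], full = pr[2], tst))
      }
    }
    if (!is.null(lrts)) data.table::fwrite(lrts, file.path(out_dir, "lrt.csv"))

    stage <- "ranking"
    log_stage("stage ranking: top-%d", config$k)
    rank_tabs <- do.call(rbind, lapply(names(fits), function(kind)
      do.call(rbind, lapply(trials, function(tr)
        cbind(model = kind, trial = tr, top_k(fits[[kind]], tr, config$k))))))
    data.table::fwrite(rank_tabs, file.path(out_dir, "rankings.csv"))
    conc <- concordance_report(fits, k = config$k)
    data.table::fwrite(conc$cross_trial, file.path(out_dir, "concordance_cross_trial.csv"))
    if (!is.null(conc$model_pairs))
      data.table::fwrite(conc$model_pairs, file.path(out_dir, "concordance_model_pairs.csv"))
    sel <- selection_index(fits[[length(fits)]])
    data.table::fwrite(sel, file.path(out_dir, "selection_index.csv"))
    ## figure-style scatter data: per-trial predictions (both tau + g and
    ## centred EBLUP) with top-k flags
    last <- fits[[length(fits)]]
    scatter <- do.call(rbind, lapply(trials, function(tr) {
      v <- cultivar_values(last, tr)
      tk <- top_k(last, tr, config$k)$cultivar
      data.frame(trial = tr, cultivar = names(v), prediction = unname(v),
                 centred = unname(v) - mean(v),
                 in_top_k = names(v) %in% tk, stringsAsFactors = FALSE)
    }))
    data.table::fwrite(scatter, file.path(out_dir, "scatter_predictions.csv"))

    stage <- "summary"
    summary <- list(
      preset = config$preset, seed = seed, k = config$k,
      trials = trials, models = names(fits),
      n_wells = nrow(pheno),
      loglik = lapply(fits, `[[`, "loglik"),
      n_params = lapply(fits, `[[`, "n_params"),
      heritability = split(setNames(herit$heritability,
                                    paste(herit$model, herit$trial)),
                           herit$model),
      concordance = setNames(conc$cross_trial$count, conc$cross_trial$model))
    if ("C" %in% names(fits))
      summary$genetic_correlation <- genetic_correlation(fits$C)
    if (!is.null(lrts)) summary$lrt <- lrts
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.csv"))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    data.table::fwrite(manifest[order(manifest$file), ],
                       file.path(out_dir, "manifest.csv"))
    log_stage("pipeline complete in %.1f s", proc.time()[3] - t_all)
    list(designs = designs, phenotypes = pheno, fits = fits,
         heritability = herit, concordance = conc, summary = summary,
         out_dir = out_dir)
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e),
          " (partial outputs kept in ", out_dir, ")")
  })
  invisible(res)
}
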