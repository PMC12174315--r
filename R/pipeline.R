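## End-to-end orchestration: generate -> incidence -> heritability ->
## attenuation -> risk factors -> mediation, from one config and one root
## seed, with per-stage seeds derived from the stage name so any stage is
## replayable in isolation.  Every stage writes tidy CSV (plus JSON for
## scalar results) into the output directory and is fingerprinted in a run
## manifest.

.STAGES <- c("generate", "incidence", "heritability", "attenuate",
             "riskfactors", "mediate")

.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, .STAGES) * 1009L) %% .Machine$integer.max
}

.digest_file <- function(path) unname(tools::md5sum(path))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  `generate` writes the
#' cohort CSV; downstream stages read it back from `out_dir`, so deleting a
#' downstream output and re-running only that stage reproduces it from the
#' cached cohort.
#'
#' @param config A [generator_config()] or the path of a YAML/JSON config
#'   file.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("generate", "incidence", "heritability", "attenuate", "riskfactors",
#'   "mediate")`.
#' @param seed Root seed; per-stage seeds are derived from it and the stage
#'   name.
#' @param debug_latent Emit the latent liability columns in the cohort CSV.
#' @param heritability_B Bootstrap replicates for the heritability CIs
#'   (0 skips the bootstrap).
#' @param risk_factor_names Factors analysed in the `riskfactors` and
#'   `mediate` stages (must be cohort columns).
#' @param mediate_years Cohort pair for the mediation stage.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, stages = .STAGES, seed = 1L,
                         debug_latent = FALSE, heritability_B = 0,
                         risk_factor_names = c("maternal_smoking",
                                               "maternal_bmi"),
                         mediate_years = c(1982, 2000)) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  unknown <- setdiff(stages, .STAGES)
  if (length(unknown)) {
    stop("run_pipeline: unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- .STAGES[.STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(out_dir, "cohort.csv")

  cfg_json <- jsonlite::serializeJSON(config)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(config_hash = .digest_file(tmp), seed = seed,
                   package_version = as.character(utils::packageVersion("aetrend")),
                   stages = list())
  unlink(tmp)

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    files <- fun()
    manifest$stages[[name]] <<- list(
      seed = .stage_seed(seed, name),
      outputs = lapply(files, .digest_file),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  need_cohort <- setdiff(stages, "generate")
  if (length(need_cohort) && !"generate" %in% stages &&
      !file.exists(cohort_path)) {
    stop("run_pipeline: stage '", need_cohort[1],
         "' needs the cohort; run 'generate' first or keep cohort.csv",
         call. = FALSE)
  }

  if ("generate" %in% stages) {
    run_stage("generate", function() {
      coh <- simulate_cohort(config, seed = .stage_seed(seed, "generate"),
                             debug_latent = debug_latent)
      write_cohort(coh, cohort_path)
      stats::setNames(list(cohort_path), "cohort")
    })
  }

  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) cohort <<- read_cohort(cohort_path)
    cohort
  }

  if ("incidence" %in% stages) {
    run_stage("incidence", function() {
      rec <- as_survival_records(get_cohort())
      trend <- cox_birth_year_trend(rec,
                                    reference_year = min(rec$birth_year))
      curves <- incidence_curves(rec)
      p1 <- file.path(out_dir, "incidence_trend.csv")
      p2 <- file.path(out_dir, "incidence_curves.csv")
      data.table::fwrite(as.data.frame(trend), p1)
      data.table::fwrite(curves, p2)
      list(trend = p1, curves = p2)
    })
  }

  if ("heritability" %in% stages) {
    run_stage("heritability", function() {
      coh <- get_cohort()
      cells <- make_sibling_pairs(coh)
      fits <- lapply(c("model1", "model2", "model3", "model4"),
                     function(m) fit_ae(cells, model = m,
                                        ref_year = config$ref_year))
      cmp <- compare_models(fits)
      years <- sort(unique(coh$birth_year))
      best <- fits[[which.min(cmp$aic)]]
      if (heritability_B >= 2) {
        curve <- bootstrap_ci(coh, model = best$model, years = years,
                              B = heritability_B,
                              seed = .stage_seed(seed, "heritability"),
                              ref_year = config$ref_year)
      } else {
        curve <- h2_curve(best, years)
      }
      p1 <- file.path(out_dir, "heritability_curve.csv")
      p2 <- file.path(out_dir, "model_comparison.csv")
      p3 <- file.path(out_dir, "model_fits.json")
      p4 <- file.path(out_dir, "model_lrt.csv")
      data.table::fwrite(as.data.frame(curve), p1)
      data.table::fwrite(as.data.frame(cmp), p2)
      data.table::fwrite(attr(cmp, "lrt"), p4)
      jsonlite::write_json(lapply(fits, function(f) {
        list(model = f$model, loglik = f$loglik, aic = f$aic,
             n_free_params = f$n_free_params, converged = f$converged,
             params = unclass(f$params))
      }), p3, auto_unbox = TRUE, digits = NA)
      list(curve = p1, comparison = p2, fits = p3, lrt = p4)
    })
  }

  if ("attenuate" %in% stages) {
    run_stage("attenuate", function() {
      res <- list(
        variance_inflation = unclass(
          attenuated_h2(config$a0^2, 0.005, 0.004,
                        mechanism = "variance_inflation")),
        exposure_shift = unclass(
          attenuated_h2(config$a0^2, 0.005, 0.004,
                        mechanism = "exposure_shift")))
      p <- file.path(out_dir, "attenuation.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
      list(attenuation = p)
    })
  }

  if ("riskfactors" %in% stages) {
    run_stage("riskfactors", function() {
      rec <- as_survival_records(get_cohort())
      rows <- list()
      for (f in risk_factor_names) {
        rows[[length(rows) + 1L]] <- cox_full_cohort(rec, f)
        el <- eligibility_check(f)
        if (el$sibling_appropriate) {
          sib <- tryCatch(cox_sibling_stratified(rec, f),
                          error = function(e) NULL)
          if (!is.null(sib)) rows[[length(rows) + 1L]] <- sib
        }
      }
      tab <- do.call(rbind, lapply(rows, as.data.frame))
      p <- file.path(out_dir, "risk_factors.csv")
      data.table::fwrite(tab, p)
      list(associations = p)
    })
  }

  if ("mediate" %in% stages) {
    run_stage("mediate", function() {
      rec <- as_survival_records(get_cohort())
      rows <- lapply(risk_factor_names, function(f) {
        as.data.frame(unclass(mediate_trend(
          rec, f, year0 = mediate_years[1], year1 = mediate_years[2]))[
            c("factor", "year0", "year1", "total_increase", "nie", "nde",
              "proportion_explained", "n_used")])
      })
      tab <- do.call(rbind, rows)
      p <- file.path(out_dir, "mediation.csv")
      data.table::fwrite(tab, p)
      list(mediation = p)
    })
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
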