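## End-to-end orchestration: simulate -> features -> prep -> fit -> report,
## reproducible from one config and one seed.

#' Build a pipeline run configuration
#'
#' Aggregates the analysis constants (100 m clustering epsilon, 10 m risk
#' cells, Z > 3 outlier threshold, 3 experience strata) with the simulation
#' settings. Serializes losslessly to/from YAML.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_matches Number of simulated matches.
#' @param map_name Map.
#' @param eps_m Clustering epsilon in meters (default 100).
#' @param cell_m Risk-grid cell in meters (default 10).
#' @param z_max Z-score outlier threshold (default 3).
#' @param k_strata Number of experience strata (default 3).
#' @param q_low,q_high Risk-category quantiles (default both 0.5).
#' @param models Character subset of
#'   `c("full1", "full2", "strata", "interaction", "top5", "top10")`.
#' @param sim Extra arguments passed to [sim_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_matches = 50L, map_name = "Erangel",
                       eps_m = 100, cell_m = 10, z_max = 3, k_strata = 3,
                       q_low = 0.5, q_high = 0.5,
                       models = c("full1", "full2", "strata", "interaction",
                                  "top5", "top10"),
                       sim = list()) {
  stopifnot(eps_m > 0, cell_m > 0, z_max > 0, k_strata >= 2,
            q_low >= 0, q_low <= 1, q_high >= 0, q_high <= 1)
  structure(list(seed = as.integer(seed), n_matches = as.integer(n_matches),
                 map_name = map_name, eps_m = eps_m, cell_m = cell_m,
                 z_max = z_max, k_strata = k_strata, q_low = q_low,
                 q_high = q_high, models = models, sim = sim),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Serialize one rank_clm fit (plus diagnostics) to a plain list.
.fit_to_list <- function(fit, label) {
  s <- summary(fit)
  vifs <- if (ncol(fit$X) >= 2L) vif(fit$X) else
    setNames(rep(1, ncol(fit$X)), colnames(fit$X))
  pvo <- predicted_vs_observed(fit)$summary
  list(model = label,
       coefficients = as.list(coef(fit)),
       std_errors = as.list(setNames(s$coefficients[, "Std. Error"],
                                     rownames(s$coefficients))),
       ci_low = as.list(setNames(s$coefficients[, "lwr"],
                                 rownames(s$coefficients))),
       ci_high = as.list(setNames(s$coefficients[, "upr"],
                                  rownames(s$coefficients))),
       thresholds = as.numeric(fit$thresholds),
       logLik = fit$logLik, logLik_null = fit$logLik_null,
       r2_ml = fit$r2_ml, n = fit$n, converged = fit$converged,
       vif = as.list(vifs),
       predicted_vs_observed = pvo)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, extracts behavior and risk features, assembles and
#' filters the analysis records, fits the model battery, and writes every
#' stage artifact plus a manifest to `out_dir`. Re-running with the same
#' config reproduces all numbers exactly.
#'
#' @param config A [run_config()] or path to its YAML.
#' @param out_dir Output directory (created).
#' @param write_telemetry_files Write per-match JSON-Lines telemetry
#'   (default `FALSE`; the files are bulky and only needed for archival).
#' @return Invisibly, a list with `records`, `fits`, `manifest`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, write_telemetry_files = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- utils::modifyList(
    list(seed = config$seed, map_name = config$map_name,
         n_matches = config$n_matches, eps_cm = config$eps_m * 100,
         cell_cm = config$cell_m * 100),
    config$sim)
  scfg <- do.call(sim_config, sim_args)

  cohort <- simulate_cohort(scfg, out_dir = if (write_telemetry_files)
    out_dir else NULL)
  prep <- prepare_cohort(cohort, eps_cm = config$eps_m * 100,
                         z_max = config$z_max, q_low = config$q_low,
                         q_high = config$q_high,
                         strata_seed = config$seed)
  utils::write.csv(prep$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(prep$risk, file.path(out_dir, "risk.csv"),
                   row.names = FALSE)
  utils::write.csv(prep$records, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  tabs <- cohort_tables(cohort$matches)
  conj <- conjoint_experience(tabs$rosters)
  prep_report <- list(
    n_records_in = nrow(prep$records) + nrow(prep$dropped),
    n_dropped = nrow(prep$dropped),
    dropped = prep$filter_report,
    conjoint_experience = as.list(conj),
    stratum_centers = prep$strata$centers,
    stratum_sizes = prep$strata$sizes,
    strata_seed = prep$strata$seed,
    z_filter = "single pass, mean/sd on input table")
  jsonlite::write_json(prep_report, file.path(out_dir, "prep_report.json"),
                       auto_unbox = TRUE, digits = NA)

  fit_dir <- file.path(out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  fml <- default_rank_formula()
  rec <- prep$records
  fits <- list()
  if ("full1" %in% config$models) fits$full1 <- rank_clm(fml, rec)
  if ("full2" %in% config$models) {
    fits$full2 <- fit_quadratic(fml, rec,
                                quad_terms = c("share_high", "share_med",
                                               "share_low"))
  }
  if ("strata" %in% config$models) {
    sf <- fit_stratified(rec, fml, min_n = 30, fitter = fit_quadratic)
    for (s in names(sf)) fits[[paste0("stratum_", s)]] <- sf[[s]]
  }
  if ("interaction" %in% config$models) {
    fits$interaction <- fit_interaction(fml, rec)
  }
  for (nm in names(fits)) {
    jsonlite::write_json(.fit_to_list(fits[[nm]], nm),
                         file.path(fit_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  topk <- list()
  for (k in c(5, 10)) {
    if (!paste0("top", k) %in% config$models) next
    tf <- fit_logistic_topk(fml, rec, k = k)
    topk[[paste0("top", k)]] <- tf
    jsonlite::write_json(list(model = paste0("top", k),
                              coefficients = as.list(stats::coef(tf)),
                              separation = tf$separation),
                         file.path(fit_dir, paste0("top", k, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(fits)) {
    utils::write.csv(coef_table(fits),
                     file.path(fit_dir, "coefficients.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_matches = config$n_matches,
    n_teams_simulated = nrow(cohort$truth),
    n_records_assembled = nrow(prep$records) + nrow(prep$dropped),
    n_records_dropped = nrow(prep$dropped),
    n_records_kept = nrow(prep$records),
    stratum_sizes = prep$strata$sizes,
    models = names(c(fits, topk)),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  make_report(out_dir)
  invisible(list(records = prep$records, fits = fits, topk = topk,
                 manifest = manifest, out_dir = out_dir))
}

#' Write a run report
#'
#' Emits `report.md` (coefficient table, fit statistics, calibration and
#' risk-category summaries) assembled purely from the run's stage files, so
#' report numbers cannot drift from the fit artifacts.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Path of the report, invisibly.
#' @export
make_report <- function(run_dir) {
  fit_dir <- file.path(run_dir, "fits")
  if (!dir.exists(fit_dir) || !length(list.files(fit_dir, "[.]json$"))) {
    stop("make_report: no fits found under ", fit_dir)
  }
  lines <- c("# Pipeline run report", "")
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                             simplifyVector = TRUE)
  lines <- c(lines,
             sprintf("Seed %d; %d matches; %d team-records kept (%d dropped by the Z-filter).",
                     man$seed, man$n_matches, man$n_records_kept,
                     man$n_records_dropped), "")
  cf <- file.path(fit_dir, "coefficients.csv")
  if (file.exists(cf)) {
    tab <- utils::read.csv(cf, check.names = FALSE)
    lines <- c(lines, "## Coefficients (negative = better placement)", "",
               paste(colnames(tab), collapse = " | "),
               paste(rep("---", ncol(tab)), collapse = " | "),
               apply(tab, 1, function(r)
                 paste(ifelse(is.na(r), "", format(r, digits = 4)),
                       collapse = " | ")),
               "")
  }
  for (f in sort(list.files(fit_dir, "[.]json$", full.names = TRUE))) {
    fj <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (!is.null(fj$r2_ml)) {
      lines <- c(lines, sprintf("- **%s**: n = %d, logLik = %.3f, r2ML = %.4f%s",
                                fj$model, fj$n, fj$logLik, fj$r2_ml,
                                if (isTRUE(fj$converged)) "" else
                                  " (NOT CONVERGED)"))
    } else if (!is.null(fj$separation)) {
      lines <- c(lines, sprintf("- **%s**: logistic robustness fit%s",
                                fj$model,
                                if (isTRUE(fj$separation))
                                  " (separation flagged)" else ""))
    }
  }
  coh <- file.path(run_dir, "cohort.csv")
  if (file.exists(coh)) {
    rec <- utils::read.csv(coh)
    rc <- table(factor(rec$risk_category, levels = c(-1, 0, 1)))
    lines <- c(lines, "", "## Risk-category counts",
               sprintf("- low (-1): %d", rc[["-1"]]),
               sprintf("- medium (0): %d", rc[["0"]]),
               sprintf("- high (+1): %d", rc[["1"]]))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
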