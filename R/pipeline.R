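# End-to-end workflows and report writers. Two headline pipelines:
# "assess" (predict somatotype from BIA + reduced anthropometry for a given
# cohort CSV) and "study" (simulate or load a cohort, develop equations on a
# stratified development group, cross-validate on the held-out group).

#' Build and validate a run configuration
#'
#' Central place for every tunable the pipelines use, with the statistical
#' thresholds at their conventional defaults: entry p 0.05, removal p 0.10
#' (entry strictly below removal), VIF cut-off 5, limits-of-agreement
#' multiplier 1.96, validation fraction 1/3.
#'
#' @param input optional cohort CSV path; when `NULL` the study pipeline
#'   simulates a cohort instead.
#' @param output_dir directory for artifacts (created if needed).
#' @param n cohort size when simulating (default 176).
#' @param equation_set equation registry id (see [somatotype_equations()]).
#' @param seed integer seed for every stochastic step.
#' @param p_enter,p_remove stepwise entry/removal thresholds.
#' @param vif_max multicollinearity flag threshold.
#' @param loa_z limits-of-agreement multiplier.
#' @param split_fraction validation fraction for the stratified split.
#' @param formats report formats, subset of `c("csv", "json")`.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("somatobia_run_"),
                       n = 176, equation_set = "soccer_male_50khz", seed = 1,
                       p_enter = 0.05, p_remove = 0.10, vif_max = 5,
                       loa_z = 1.96, split_fraction = 1 / 3,
                       formats = c("csv", "json")) {
  stopifnot(all(formats %in% c("csv", "json")), length(formats) >= 1)
  for (v in c(p_enter = p_enter, p_remove = p_remove, vif_max = vif_max,
              loa_z = loa_z, split_fraction = split_fraction)) {
    if (!is.finite(v) || v <= 0) {
      stop("run_config: all thresholds must be positive", call. = FALSE)
    }
  }
  if (p_enter >= p_remove) {
    stop("run_config: 'p_enter' must be strictly below 'p_remove'",
         call. = FALSE)
  }
  if (split_fraction >= 1) {
    stop("run_config: 'split_fraction' must be below 1", call. = FALSE)
  }
  somatotype_equations(equation_set)  # fail fast on unknown id
  structure(list(input = input, output_dir = output_dir, n = as.integer(n),
                 equation_set = equation_set, seed = as.integer(seed),
                 p_enter = p_enter, p_remove = p_remove, vif_max = vif_max,
                 loa_z = loa_z, split_fraction = split_fraction,
                 formats = formats),
            class = "run_config")
}

# metadata stamped into every artifact
run_metadata <- function(config) {
  c(package = "somatoBIA",
    version = as.character(utils::packageVersion("somatoBIA")),
    equation_set = config$equation_set,
    seed = as.character(config$seed))
}

# Table-2-shaped model summary rows
model_report <- function(models) {
  do.call(rbind, lapply(names(models), function(resp) {
    m <- models[[resp]]
    data.frame(response = resp,
               predictors = paste(m$predictors, collapse = "+"),
               r = m$r, r_squared = m$r_squared, see = m$see,
               vif = paste(sprintf("%.2f", m$vif), collapse = "+"),
               n = m$n,
               equation = equation_string(m))
  }))
}

write_report <- function(df, stem, config, meta) {
  paths <- character(0)
  if ("csv" %in% config$formats) {
    p <- file.path(config$output_dir, paste0(stem, ".csv"))
    con <- file(p, "wt", encoding = "UTF-8")
    writeLines(paste0("# ", paste(names(meta), meta, sep = ": ",
                                  collapse = "; ")), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  if ("json" %in% config$formats) {
    p <- file.path(config$output_dir, paste0(stem, ".json"))
    jsonlite::write_json(list(metadata = as.list(meta),
                              data = as.data.frame(df)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  paths
}

#' Run the full study pipeline
#'
#' Simulate (or load) a cohort, compute reference somatotype and BIA body
#' composition for every athlete, predict the somatotype with the configured
#' equation set, stratified-split, develop fresh stepwise equations for the
#' three components on the development group, and cross-validate both the
#' fresh models and the bundled equations on the validation group. Every
#' artifact embeds the equation-set id, package version and seed; reruns of
#' the same configuration are numerically identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory objects (`cohort`, `split`,
#'   `models`, `agreement_fitted`, `agreement_registry`, `diagnostics`) and
#'   the `paths` of all written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- run_metadata(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("ingest", {
    if (is.null(config$input)) {
      generate_cohort(cohort_spec(n = config$n, mode = "linked",
                                  seed = config$seed))
    } else {
      read_cohort_csv(config$input)
    }
  })
  paths <- character(0)
  paths <- c(paths, write_cohort_csv(
    cohort, file.path(config$output_dir, "cohort.csv"), metadata = meta))
  reference <- stage("reference somatotype", somatotype_reference(cohort))
  composition <- stage("body composition", body_composition(cohort))
  predicted <- stage("prediction", predict_somatotype(
    cohort, somatotype_equations(config$equation_set)))
  split <- stage("stratified split", stratified_split(
    cohort, config$split_fraction, strata = "position", seed = config$seed))
  dev_ref <- somatotype_reference(split$development)
  dev_data <- cbind(candidate_set(split$development),
                    dev_ref[c("endomorphy", "mesomorphy", "ectomorphy")])
  models <- stage("model development", {
    lapply(stats::setNames(nm = c("endomorphy", "mesomorphy", "ectomorphy")),
           function(resp) {
             stepwise_ols(dev_data, resp,
                          candidates = names(candidate_set(split$development)),
                          p_enter = config$p_enter, p_remove = config$p_remove)
           })
  })
  diagnostics <- lapply(models, fit_diagnostics)
  agreement_fitted <- stage("cross-validation (fitted models)",
                            cross_validate(split$validation, models = models,
                                           z = config$loa_z))
  agreement_registry <- stage("cross-validation (equation registry)",
                              cross_validate(split$validation,
                                             equations = somatotype_equations(config$equation_set),
                                             z = config$loa_z))
  paths <- c(paths,
             write_report(reference[setdiff(names(reference), "floored")],
                          "reference_somatotype", config, meta),
             write_report(composition, "body_composition", config, meta),
             write_report(predicted, "predicted_somatotype", config, meta),
             write_report(model_report(models), "models", config, meta),
             write_report(as.data.frame(agreement_fitted),
                          "agreement_fitted", config, meta),
             write_report(as.data.frame(agreement_registry),
                          "agreement_registry", config, meta))
  if ("json" %in% config$formats) {
    p <- file.path(config$output_dir, "run_metadata.json")
    jsonlite::write_json(c(as.list(meta),
                           list(p_enter = config$p_enter,
                                p_remove = config$p_remove,
                                vif_max = config$vif_max,
                                loa_z = config$loa_z,
                                split_fraction = config$split_fraction,
                                n = config$n,
                                input = if (is.null(config$input)) "simulated"
                                        else config$input)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(list(cohort = cohort, reference = reference,
                 composition = composition, predicted = predicted,
                 split = split, models = models, diagnostics = diagnostics,
                 agreement_fitted = agreement_fitted,
                 agreement_registry = agreement_registry,
                 paths = paths))
}
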