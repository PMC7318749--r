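#' Read a simulation scenario from a YAML file
#'
#' The file may specify any [scenario()] argument. Signatures are given as
#' a list of `{name, markers, prevalence}` where `markers` is a named list
#' of required marker states (1 = mutated, 0 = wild-type), e.g.
#' `{tp53: 0, ar: 0}`; omitted markers are unconstrained. Effects are a
#' list of `{treatment, signature, months}`.
#'
#' @param path Path to the YAML scenario file.
#' @return A validated [scenario()] object.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  catalog <- if (!is.null(cfg$signatures)) {
    sg <- enumerate_subgroups()
    sigs <- lapply(cfg$signatures, function(s) {
      keep <- rep(TRUE, 16L)
      for (mk in names(s$markers))
        keep <- keep & sg[[mk]] == s$markers[[mk]]
      biomarker_signature(s$name, sg$index[keep], s$prevalence)
    })
    names(sigs) <- vapply(sigs, `[[`, character(1), "name")
    structure(sigs, class = "signature_catalog")
  } else default_catalog()
  effects <- numeric(0)
  if (!is.null(cfg$effects)) {
    effects <- vapply(cfg$effects, function(e) as.numeric(e$months),
                      numeric(1))
    names(effects) <- vapply(cfg$effects, function(e)
      pair_key(e$treatment, e$signature), character(1))
  }
  args <- list(catalog = catalog, effects = effects)
  for (f in c("treatments", "baseline_mean_pfs", "shape_k", "accrual_rate",
              "p_nonevaluable", "horizon", "burn_in_n", "rerandomize",
              "dropout_prob", "confirmatory_alpha", "confirmatory_events"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$treatments)) args$treatments <- unlist(cfg$treatments)
  if (!is.null(cfg$control_mix)) args$control_mix <- unlist(cfg$control_mix)
  if (!is.null(cfg$thresholds))
    args$thresholds <- do.call(decision_thresholds, cfg$thresholds)
  if (!is.null(cfg$prior))
    args$prior <- do.call(prior_spec, cfg$prior)
  do.call(scenario, args)
}

#' Write a trial result's ledgers to CSV files
#'
#' Writes `patients.csv` (one row per patient-line), `decisions.csv` and,
#' when logged, `allocation.csv`, plus `confirmatory.json` and a
#' `manifest.json` recording the seed for bit-exact replay.
#'
#' @param result A `trial_result` from [run_trial()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_trial <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(result$decisions, file.path(dir, "decisions.csv"),
                   row.names = FALSE)
  if (!is.null(result$allocation))
    utils::write.csv(result$allocation, file.path(dir, "allocation.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$confirmatory,
                       file.path(dir, "confirmatory.json"),
                       auto_unbox = TRUE, null = "null")
  jsonlite::write_json(list(seed = result$seed,
                            months_run = result$months_run,
                            status = as.list(result$status)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
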