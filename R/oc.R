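#' Truth table of a scenario
#'
#' Which (treatment, signature) pairs are truly effective (positive added
#' mean PFS) under the scenario's data-generating mechanism. Used to score
#' simulated decisions as true or false positives.
#'
#' @param scn A [scenario()].
#' @return Named logical vector over all scenario pair keys.
#' @export
truth_table <- function(scn) {
  pairs <- scenario_pairs(scn)
  out <- stats::setNames(rep(FALSE, length(pairs)), pairs)
  eff <- names(scn$effects)[scn$effects > 0]
  out[eff] <- TRUE
  out
}

#' Estimate operating characteristics by replicated simulation
#'
#' Runs [run_trial()] `n_reps` times with seeds `base_seed + 0, 1, ...` and
#' aggregates the decision histories into per-pair graduation and drop
#' probabilities, sample sizes and durations at graduation, plus the raw
#' per-replicate outcome table needed for error-rate and power scoring.
#'
#' @param scn A [scenario()].
#' @param n_reps Number of replicates.
#' @param base_seed Integer base seed; replicate i uses `base_seed + i - 1`.
#' @return An `oc_report` list with elements `pairs` (per-pair summary data
#'   frame with Monte Carlo standard errors), `outcomes` (one row per
#'   replicate x pair), `n_reps`, `base_seed`.
#' @export
run_replicates <- function(scn, n_reps, base_seed = 1) {
  stopifnot(n_reps >= 1)
  pairs <- scenario_pairs(scn)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    res <- run_trial(scn, seed = base_seed + i - 1L, keep_allocation = FALSE)
    dec <- res$decisions
    m <- match(pairs, dec$pair)
    rows[[i]] <- data.frame(
      replicate = i, pair = pairs,
      decision = ifelse(is.na(m), "none", dec$decision[m]),
      month = ifelse(is.na(m), NA_integer_, dec$month[m]),
      n_treated = ifelse(is.na(m), NA_integer_, dec$n_treated[m]),
      n_participants = ifelse(is.na(m), NA_integer_, dec$n_participants[m]),
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, rows)
  agg <- lapply(pairs, function(k) {
    o <- outcomes[outcomes$pair == k, ]
    grad <- o$decision == "graduate"
    p_g <- mean(grad); p_d <- mean(o$decision == "drop")
    data.frame(
      pair = k,
      treatment = sub("\\|.*$", "", k),
      signature = sub("^.*\\|", "", k),
      p_graduate = p_g,
      se_graduate = sqrt(p_g * (1 - p_g) / n_reps),
      p_drop = p_d,
      se_drop = sqrt(p_d * (1 - p_d) / n_reps),
      mean_n_at_graduation = if (any(grad)) mean(o$n_treated[grad]) else NA_real_,
      mean_participants_at_graduation =
        if (any(grad)) mean(o$n_participants[grad]) else NA_real_,
      mean_months_at_graduation = if (any(grad)) mean(o$month[grad]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  structure(list(pairs = do.call(rbind, agg), outcomes = outcomes,
                 n_reps = n_reps, base_seed = base_seed),
            class = "oc_report")
}

#' Type-I error rates from a replicate report
#'
#' Per-drug rate: the fraction of replicates in which a truly ineffective
#' drug graduates in at least one truly-null signature. Familywise rate:
#' the fraction of replicates with at least one false graduation anywhere.
#'
#' @param report An `oc_report` from [run_replicates()].
#' @param truth Named logical vector from [truth_table()].
#' @return List with `per_drug` (named rates), `familywise`, and Monte
#'   Carlo standard errors `se_per_drug`, `se_familywise`.
#' @export
type_one_error <- function(report, truth) {
  o <- report$outcomes
  if (!all(o$pair %in% names(truth)))
    stop("truth table does not cover all pairs in the report")
  null_pairs <- names(truth)[!truth]
  o <- o[o$pair %in% null_pairs, ]
  o$drug <- sub("\\|.*$", "", o$pair)
  n <- report$n_reps
  fg <- o[o$decision == "graduate", ]
  per_drug <- vapply(unique(sub("\\|.*$", "", null_pairs)), function(d)
    length(unique(fg$replicate[fg$drug == d])) / n, numeric(1))
  fw <- length(unique(fg$replicate)) / n
  list(per_drug = per_drug,
       se_per_drug = sqrt(per_drug * (1 - per_drug) / n),
       familywise = fw,
       se_familywise = sqrt(fw * (1 - fw) / n))
}

#' Power and expected sample size for effective pairs
#'
#' @param report An `oc_report`.
#' @param truth Named logical vector from [truth_table()]; must contain at
#'   least one effective pair.
#' @return Data frame per effective pair: `power`, `mean_n_at_graduation`
#'   (treatment-arm patients), `mean_participants_at_graduation`
#'   (treatment-arm plus signature-restricted control comparators) and
#'   `mean_months_at_graduation`, averaged over graduating replicates only
#'   (`NA` when no replicate graduates).
#' @export
power_and_sample_size <- function(report, truth) {
  eff <- names(truth)[truth]
  if (length(eff) == 0L) stop("no effective pairs in the truth table")
  p <- report$pairs[report$pairs$pair %in% eff,
                    c("pair", "treatment", "signature", "p_graduate",
                      "mean_n_at_graduation",
                      "mean_participants_at_graduation",
                      "mean_months_at_graduation")]
  names(p)[names(p) == "p_graduate"] <- "power"
  rownames(p) <- NULL
  p
}

#' Overall two-stage type-I error under independence
#'
#' The familywise error of graduate-then-confirm: the screening stage's
#' false-graduation bound multiplied by the confirmatory one-sided alpha.
#' With a 30% screening bound and a 15% confirmatory level the overall
#' type-I error is 4.5%.
#'
#' @param screening_bound Screening-stage familywise error bound.
#' @param confirmatory_alpha Confirmatory one-sided level.
#' @return The product, in [0, 1].
#' @export
#' @examples
#' two_stage_type_one(0.30, 0.15)  # 0.045
two_stage_type_one <- function(screening_bound, confirmatory_alpha) {
  stopifnot(screening_bound >= 0, screening_bound <= 1,
            confirmatory_alpha >= 0, confirmatory_alpha <= 1)
  screening_bound * confirmatory_alpha
}

#' Export an operating-characteristics report to disk
#'
#' Writes `pairs.csv`, `outcomes.csv` and `summary.json` (which records
#' `n_reps` and `base_seed`) into a directory. [import_report()] reads them
#' back losslessly.
#'
#' @param report An `oc_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(n_reps = report$n_reps,
                            base_seed = report$base_seed),
                       file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname export_report
#' @export
import_report <- function(dir) {
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  structure(list(
    pairs = utils::read.csv(file.path(dir, "pairs.csv"),
                            stringsAsFactors = FALSE),
    outcomes = utils::read.csv(file.path(dir, "outcomes.csv"),
                               stringsAsFactors = FALSE),
    n_reps = s$n_reps, base_seed = s$base_seed), class = "oc_report")
}

#' @export
print.oc_report <- function(x, ...) {
  cat("Operating characteristics over", x$n_reps, "replicates (base seed",
      paste0(x$base_seed, ")\n"))
  print(x$pairs[, c("pair", "p_graduate", "p_drop", "mean_n_at_graduation",
                    "mean_months_at_graduation")], row.names = FALSE)
  invisible(x)
}
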