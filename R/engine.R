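#' Define a simulation scenario for the platform trial
#'
#' A scenario fixes the design configuration (arms, signatures, thresholds,
#' burn-in, prior) together with the data-generating truth: baseline mean
#' PFS, Weibull shape, and per (treatment, signature) effects expressed as
#' added months of mean PFS. The control arm is a physician's-choice mix of
#' the same drugs, sampled from `control_mix`; because the physician chooses
#' without biomarker knowledge, a control patient receives the signature
#' effect of whichever drug was actually chosen for them.
#'
#' @param treatments Character vector of active treatment identifiers.
#' @param catalog A `signature_catalog`. Default [default_catalog()].
#' @param candidates Named list: candidate signature names per treatment.
#'   Default: every treatment is a candidate in every catalog signature.
#' @param baseline_mean_pfs Control mean PFS in months. Default 8.
#' @param shape_k Weibull shape. Default 1 (exponential).
#' @param effects Named numeric vector of added months of mean PFS, with
#'   names `"treatment|signature"` ([pair_key()]). Missing pairs have
#'   effect 0. A patient in several effective signatures of the same drug
#'   receives the maximum applicable effect.
#' @param control_mix Named probability vector over `treatments`: what
#'   standard-of-care physicians choose. Default uniform.
#' @param accrual_rate Expected patients per month (Poisson). Default 7.
#' @param p_nonevaluable Probability that a patient's biomarker profile
#'   cannot be inferred (undetectable ctDNA, technical failure, MSI
#'   routing), sending them to the observational arm. Default 0.1.
#' @param horizon Trial horizon in months. Default 60.
#' @param burn_in_n Platform-wide active-arm accrual before adaptation
#'   starts. Default 50.
#' @param thresholds A [decision_thresholds()].
#' @param prior A [prior_spec()].
#' @param rerandomize Re-randomize first-line progressors on active arms?
#'   Default `FALSE`.
#' @param dropout_prob Probability that an eligible progressor discontinues
#'   instead of re-randomizing. Default 0.1.
#' @param confirmatory_alpha One-sided level of the nested confirmatory
#'   log-rank test. Default 0.15.
#' @param confirmatory_events Event target for the confirmatory analysis;
#'   `NULL` (default) sizes it for 80% power against the pair's own scenario
#'   effect, falling back to 40 events for a truly-null graduation.
#' @param joint Optional `joint_prevalence` over the 16 subgroups; by
#'   default calibrated from the catalog with
#'   [calibrate_joint_prevalence()].
#' @return A validated `scenario` object.
#' @export
scenario <- function(treatments = paste0("T", 1:4),
                     catalog = default_catalog(),
                     joint = NULL,
                     candidates = NULL,
                     baseline_mean_pfs = 8,
                     shape_k = 1,
                     effects = numeric(0),
                     control_mix = NULL,
                     accrual_rate = 7,
                     p_nonevaluable = 0.1,
                     horizon = 60,
                     burn_in_n = 50,
                     thresholds = decision_thresholds(),
                     prior = prior_spec(shape_k = shape_k),
                     rerandomize = FALSE,
                     dropout_prob = 0.1,
                     confirmatory_alpha = 0.15,
                     confirmatory_events = NULL) {
  stopifnot(length(treatments) >= 1, baseline_mean_pfs > 0, shape_k > 0,
            accrual_rate > 0, p_nonevaluable >= 0, p_nonevaluable <= 1,
            horizon >= 0, burn_in_n >= 0,
            confirmatory_alpha > 0, confirmatory_alpha < 1)
  if (is.null(candidates))
    candidates <- stats::setNames(
      rep(list(names(catalog)), length(treatments)), treatments)
  stopifnot(setequal(names(candidates), treatments))
  if (is.null(control_mix))
    control_mix <- stats::setNames(
      rep(1 / length(treatments), length(treatments)), treatments)
  if (abs(sum(control_mix) - 1) > 1e-9 || any(control_mix < 0) ||
      !setequal(names(control_mix), treatments))
    stop("control_mix must be a probability vector over the treatments")
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be named by pair key 'treatment|signature'")
    valid <- unlist(lapply(treatments,
                           function(t) pair_key(t, candidates[[t]])))
    bad <- setdiff(names(effects), valid)
    if (length(bad)) stop("unknown effect pairs: ", paste(bad, collapse = ", "))
    if (any(effects < 0)) stop("effects must be non-negative months")
  }
  if (!isTRUE(all.equal(prior$shape_k, shape_k)))
    stop("prior shape_k must match the scenario shape_k")
  if (is.null(joint)) joint <- calibrate_joint_prevalence(catalog)
  if (length(joint) != 16L || abs(sum(joint) - 1) > 1e-9 || any(joint < 0))
    stop("joint must be a probability vector over the 16 subgroups")
  structure(list(
    treatments = treatments, catalog = catalog, joint = joint,
    candidates = candidates,
    baseline_mean_pfs = baseline_mean_pfs, shape_k = shape_k,
    effects = effects, control_mix = control_mix,
    accrual_rate = accrual_rate, p_nonevaluable = p_nonevaluable,
    horizon = horizon, burn_in_n = burn_in_n, thresholds = thresholds,
    prior = prior, rerandomize = rerandomize, dropout_prob = dropout_prob,
    confirmatory_alpha = confirmatory_alpha,
    confirmatory_events = confirmatory_events
  ), class = "scenario")
}

#' All (treatment, signature) pair keys of a scenario
#' @param scn A [scenario()].
#' @return Character vector of pair keys.
#' @export
scenario_pairs <- function(scn) {
  unlist(lapply(scn$treatments,
                function(t) pair_key(t, scn$candidates[[t]])),
         use.names = FALSE)
}

# Added months of mean PFS for a drug given a patient's subgroup:
# the maximum effect over all catalog signatures containing the subgroup.
scenario_effect <- function(scn, drug, subgroup) {
  if (!length(scn$effects)) return(0)
  sigs <- signature_membership(scn$catalog, subgroup)
  keys <- intersect(pair_key(drug, sigs), names(scn$effects))
  if (!length(keys)) return(0)
  max(scn$effects[keys])
}

# Draw one true PFS time for a patient on `drug` (the drug actually
# administered; for control/observational this is the sampled SOC choice).
draw_pfs <- function(scn, drug, subgroup) {
  m <- scn$baseline_mean_pfs + scenario_effect(scn, drug, subgroup)
  lam <- rate_for_mean(m, scn$shape_k)
  stats::rweibull(1L, shape = scn$shape_k, scale = lam^(-1 / scn$shape_k))
}

# Sized for 80% power of a one-sided log-rank test against the pair's own
# scenario effect; 40 events when the pair is truly null.
confirmatory_event_target <- function(scn, pair) {
  if (!is.null(scn$confirmatory_events)) return(scn$confirmatory_events)
  eff <- if (pair %in% names(scn$effects)) scn$effects[[pair]] else 0
  if (eff <= 0) return(40L)
  hr <- rate_for_mean(scn$baseline_mean_pfs + eff, scn$shape_k) /
    rate_for_mean(scn$baseline_mean_pfs, scn$shape_k)
  as.integer(ceiling(4 * (stats::qnorm(1 - scn$confirmatory_alpha) +
                            stats::qnorm(0.8))^2 / log(hr)^2))
}

#' Run one complete platform trial
#'
#' Simulates the monthly life cycle: Poisson accrual with biomarker
#' profiling, observational routing of non-evaluable patients,
#' subgroup-stratified randomization (fixed equal during burn-in,
#' control-protected outcome-adaptive after), optional re-randomization of
#' first-line progressors, monthly interims that update the conjugate
#' Gamma-Weibull posteriors and the graduation/futility/cap decisions, and
#' nested confirmatory trials for graduated treatment-signature pairs.
#'
#' Analyses are stratified by line of treatment: superiority probabilities
#' are computed per (signature, line) against the pooled control of the
#' same stratum and combined across lines weighted by the number of
#' subjects on the treatment. With re-randomization disabled (the default)
#' everything is first-line.
#'
#' @param scn A [scenario()].
#' @param seed Integer seed; the whole trial is reproducible from
#'   (scenario, seed).
#' @param keep_allocation Log the full allocation table at every interim?
#'   Default `TRUE`.
#' @return A `trial_result` list: `patients` (one row per patient-line),
#'   `decisions` (interim decision history), `allocation` (per-interim
#'   allocation rows), `confirmatory` (nested-trial outcomes), `status`
#'   (final pair states), `seed`.
#' @export
run_trial <- function(scn, seed, keep_allocation = TRUE) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(seed)
  catalog <- scn$catalog
  pairs <- scenario_pairs(scn)
  status <- stats::setNames(rep("active", length(pairs)), pairs)
  superiority <- stats::setNames(rep(0.5, length(pairs)), pairs)
  # membership masks: per signature, logical over subgroup index 0..15
  sig_mask <- lapply(catalog, function(s) {
    m <- rep(FALSE, 16L); m[s$members + 1L] <- TRUE; m
  })

  # patient ledger as parallel vectors, one entry per patient-line record
  P <- list(id = integer(0), entry = integer(0), line = integer(0),
            subgroup = integer(0), arm = character(0), drug = character(0),
            conf_pair = character(0), true_pfs = numeric(0),
            rerand_done = logical(0))
  add_record <- function(id, entry, line, subgroup, arm, drug, conf_pair,
                         true_pfs) {
    P$id <<- c(P$id, id); P$entry <<- c(P$entry, entry)
    P$line <<- c(P$line, line); P$subgroup <<- c(P$subgroup, subgroup)
    P$arm <<- c(P$arm, arm); P$drug <<- c(P$drug, drug)
    P$conf_pair <<- c(P$conf_pair, conf_pair)
    P$true_pfs <<- c(P$true_pfs, true_pfs)
    P$rerand_done <<- c(P$rerand_done, FALSE)
  }

  conf <- list()    # open/closed confirmatory trials keyed by pair
  decisions <- list()
  alloc_log <- list()
  next_id <- 1L
  alloc <- allocation_table(scn$treatments, catalog, superiority,
                            pairs[status == "active"], burn_in = TRUE)

  randomize_one <- function(subgroup, month, line, id) {
    # confirmatory routing: first open nested trial containing the subgroup
    for (key in names(conf)) {
      tr <- conf[[key]]
      if (tr$open && sig_mask[[tr$signature]][subgroup + 1L]) {
        to_trt <- (tr$n_assigned %% 2L) == tr$first_trt
        conf[[key]]$n_assigned <<- tr$n_assigned + 1L
        if (to_trt) {
          add_record(id, month, line, subgroup, tr$treatment, tr$treatment,
                     key, draw_pfs(scn, tr$treatment, subgroup))
        } else {
          soc <- sample(names(scn$control_mix), 1L, prob = scn$control_mix)
          add_record(id, month, line, subgroup, "control", soc, key,
                     draw_pfs(scn, soc, subgroup))
        }
        return(invisible())
      }
    }
    row <- alloc[[as.character(subgroup)]]
    if (is.null(row)) {  # no eligible active arm: observational SOC
      soc <- sample(names(scn$control_mix), 1L, prob = scn$control_mix)
      add_record(id, month, line, subgroup, "observational", soc,
                 NA_character_, draw_pfs(scn, soc, subgroup))
      return(invisible())
    }
    arm <- randomize_patient(row)
    if (arm == "control") {
      soc <- sample(names(scn$control_mix), 1L, prob = scn$control_mix)
      add_record(id, month, line, subgroup, "control", soc, NA_character_,
                 draw_pfs(scn, soc, subgroup))
    } else {
      add_record(id, month, line, subgroup, arm, arm, NA_character_,
                 draw_pfs(scn, arm, subgroup))
    }
    invisible()
  }

  stratum_post <- function(sel, month) {
    # conjugate posterior for one (arm, stratum) selection at calendar month
    expo <- pmin(P$true_pfs[sel], month - P$entry[sel])
    ev <- P$true_pfs[sel] <= (month - P$entry[sel])
    pos <- expo > 0
    posterior_update(scn$prior, survival_data(expo[ev & pos],
                                              expo[!ev & pos]))
  }

  for (month in seq_len(scn$horizon)) {
    ## 1. accrual and randomization
    n_new <- stats::rpois(1L, scn$accrual_rate)
    if (n_new > 0) {
      sgs <- sample.int(16L, n_new, replace = TRUE,
                        prob = as.numeric(scn$joint)) - 1L
      noneval <- stats::runif(n_new) < scn$p_nonevaluable
      for (i in seq_len(n_new)) {
        id <- next_id; next_id <- next_id + 1L
        if (noneval[i]) {
          soc <- sample(names(scn$control_mix), 1L, prob = scn$control_mix)
          add_record(id, month, 1L, sgs[i], "observational", soc,
                     NA_character_, draw_pfs(scn, soc, sgs[i]))
        } else {
          randomize_one(sgs[i], month, 1L, id)
        }
      }
    }

    ## 2. re-randomization of first-line progressors on active arms
    if (scn$rerandomize) {
      prog <- which(!P$rerand_done & P$line == 1L &
                      P$arm %in% scn$treatments & is.na(P$conf_pair) &
                      (P$entry + P$true_pfs) <= month)
      for (i in prog) {
        P$rerand_done[i] <- TRUE
        if (stats::runif(1) < scn$dropout_prob) next
        randomize_one(P$subgroup[i], month, 2L, P$id[i])
      }
    }

    ## 3. interim: posteriors, superiority, decisions
    platform_trt <- is.na(P$conf_pair) & P$arm %in% scn$treatments
    ctrl_pool <- P$arm == "control"         # nested-trial SOC also compares
    active_keys <- names(status)[status == "active"]
    recs <- list()
    for (key in active_keys) {
      ts <- strsplit(key, "|", fixed = TRUE)[[1]]
      trt <- ts[1]; sig <- ts[2]
      in_sig <- sig_mask[[sig]][P$subgroup + 1L]
      sel_t <- platform_trt & P$arm == trt & in_sig
      sel_c <- ctrl_pool & in_sig
      lines <- if (scn$rerandomize) sort(unique(P$line[sel_t | sel_c])) else 1L
      if (length(lines) == 0L) lines <- 1L
      ps <- ws <- numeric(length(lines))
      for (j in seq_along(lines)) {
        lt <- sel_t & P$line == lines[j]
        lc <- sel_c & P$line == lines[j]
        ps[j] <- prob_superiority(stratum_post(lt, month),
                                  stratum_post(lc, month))
        ws[j] <- max(sum(lt), 1L)
      }
      p_sup <- sum(ps * ws) / sum(ws)
      superiority[key] <- p_sup
      n_treated <- sum(sel_t)
      n_ctrl <- sum(ctrl_pool & is.na(P$conf_pair) & in_sig)
      n_total <- sum(platform_trt & in_sig) + n_ctrl
      consistent <- TRUE
      if (p_sup >= scn$thresholds$graduation_prob &&
          n_treated >= scn$thresholds$min_n_signature) {
        members <- catalog[[sig]]$members
        tab <- data.frame(n_treated = integer(0), superiority = numeric(0))
        for (g in members) {
          gt <- sel_t & P$subgroup == g
          ng <- sum(gt)
          if (ng >= scn$thresholds$consistency_min_n) {
            gp <- prob_superiority(stratum_post(gt, month),
                                   stratum_post(ctrl_pool & P$subgroup == g,
                                                month))
            tab <- rbind(tab, data.frame(n_treated = ng, superiority = gp))
          }
        }
        consistent <- subgroup_consistency(tab, scn$thresholds)
      }
      dec <- evaluate_pair(p_sup, n_treated, n_total, consistent,
                           scn$thresholds)
      if (dec != "continue")
        recs[[length(recs) + 1L]] <- data.frame(
          month = month, treatment = trt, signature = sig, pair = key,
          decision = dec, superiority = p_sup, n_treated = n_treated,
          n_participants = n_treated + n_ctrl,
          n_signature_total = n_total, consistency = consistent,
          stringsAsFactors = FALSE)
    }
    if (length(recs)) {
      recs <- do.call(rbind, recs)
      status <- apply_decisions(status, recs)
      decisions[[length(decisions) + 1L]] <- recs
      for (i in which(recs$decision == "graduate")) {
        key <- recs$pair[i]
        conf[[key]] <- list(pair = key, treatment = recs$treatment[i],
                            signature = recs$signature[i],
                            opened_month = month, open = TRUE,
                            n_assigned = 0L, first_trt = sample(0:1, 1L),
                            events_target = confirmatory_event_target(scn, key),
                            outcome = "pending", p_value = NA_real_,
                            closed_month = NA_integer_)
      }
    }

    ## 4. confirmatory analyses at the event target
    for (key in names(conf)) {
      tr <- conf[[key]]
      if (!tr$open) next
      sel <- !is.na(P$conf_pair) & P$conf_pair == key
      if (!any(sel)) next
      expo <- pmin(P$true_pfs[sel], month - P$entry[sel])
      ev <- P$true_pfs[sel] <= (month - P$entry[sel])
      if (sum(ev) >= tr$events_target) {
        grp <- ifelse(P$arm[sel] == tr$treatment, 1L, 0L)
        res <- confirmatory_logrank(expo, ev, grp, scn$confirmatory_alpha)
        conf[[key]]$outcome <- res$outcome
        conf[[key]]$p_value <- res$p_value
        conf[[key]]$open <- FALSE
        conf[[key]]$closed_month <- month
      }
    }

    ## 5. allocation for next month
    active_keys <- names(status)[status == "active"]
    n_active <- sum(platform_trt)
    alloc <- allocation_table(scn$treatments, catalog, superiority,
                              active_keys,
                              burn_in = in_burn_in(n_active, scn$burn_in_n))
    if (keep_allocation) {
      rows <- alloc[!vapply(alloc, is.null, logical(1))]
      if (length(rows))
        alloc_log[[length(alloc_log) + 1L]] <- data.frame(
          month = month,
          subgroup = rep(as.integer(names(rows)),
                         vapply(rows, length, integer(1))),
          arm = unlist(lapply(rows, names), use.names = FALSE),
          probability = unlist(rows, use.names = FALSE),
          stringsAsFactors = FALSE)
    }
    if (all(status != "active") &&
        (length(conf) == 0L ||
         all(!vapply(conf, `[[`, logical(1), "open")))) break
  }

  month_end <- if (scn$horizon == 0L) 0L else month
  patients <- if (length(P$id)) data.frame(
    patient_id = P$id, entry_month = P$entry, line = P$line,
    subgroup_index = P$subgroup, arm = P$arm, drug = P$drug,
    confirmatory_pair = P$conf_pair, true_pfs = P$true_pfs,
    observed_time = pmin(P$true_pfs, pmax(month_end - P$entry, 0)),
    event = P$true_pfs <= (month_end - P$entry),
    stringsAsFactors = FALSE
  ) else empty_patients()
  structure(list(
    patients = patients,
    decisions = if (length(decisions)) do.call(rbind, decisions)
                else empty_decisions(),
    allocation = if (length(alloc_log)) do.call(rbind, alloc_log)
                 else NULL,
    confirmatory = conf,
    status = status,
    months_run = if (scn$horizon == 0) 0L else month_end,
    seed = seed
  ), class = "trial_result")
}

empty_patients <- function() data.frame(
  patient_id = integer(0), entry_month = integer(0), line = integer(0),
  subgroup_index = integer(0), arm = character(0), drug = character(0),
  confirmatory_pair = character(0), true_pfs = numeric(0),
  observed_time = numeric(0), event = logical(0), stringsAsFactors = FALSE)

empty_decisions <- function() data.frame(
  month = integer(0), treatment = character(0), signature = character(0),
  pair = character(0), decision = character(0), superiority = numeric(0),
  n_treated = integer(0), n_participants = integer(0),
  n_signature_total = integer(0), consistency = logical(0),
  stringsAsFactors = FALSE)

# One-sided log-rank comparison: reject when the treatment group (grp == 1)
# has fewer events than expected and the one-sided p-value clears alpha.
confirmatory_logrank <- function(time, event, grp, alpha) {
  if (length(unique(grp)) < 2L)
    return(list(outcome = "fail", p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p_two <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  favors_trt <- sd$obs[2] < sd$exp[2]
  p_one <- if (favors_trt) p_two / 2 else 1 - p_two / 2
  list(outcome = if (p_one <= alpha) "reject" else "fail", p_value = p_one)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Platform trial simulation (seed ", x$seed, ")\n", sep = "")
  cat("  months run:   ", x$months_run, "\n", sep = "")
  cat("  patient-lines:", nrow(x$patients), "\n")
  tb <- table(x$status)
  cat("  pair states:  ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
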