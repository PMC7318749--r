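#' Decision thresholds for the screening stage
#'
#' Defaults follow the trial protocol: a treatment-signature pair graduates
#' when its probability of superiority reaches 85% after at least 20
#' patients have been treated in the pair (and subgroup performance is
#' consistent), is dropped for futility at 15% or below, and is capped when
#' signature-level accrual reaches 150 patients. The consistency check
#' requires subgroup-restricted superiority above 0.5 in every member
#' subgroup with at least 3 treated patients.
#'
#' @param graduation_prob Superiority threshold for graduation. Default 0.85.
#' @param futility_prob Superiority threshold for dropping. Default 0.15.
#' @param min_n_signature Minimum treated patients before graduation.
#'   Default 20.
#' @param max_n_signature Signature-level accrual cap. Default 150.
#' @param consistency_prob Subgroup-level superiority floor. Default 0.5.
#' @param consistency_min_n Minimum treated patients for a subgroup to enter
#'   the consistency check. Default 3.
#' @param futility_needs_min_n Apply the minimum-n rule to futility too?
#'   Default `FALSE`: futility may trigger earlier.
#' @return A `decision_thresholds` list.
#' @export
decision_thresholds <- function(graduation_prob = 0.85, futility_prob = 0.15,
                                min_n_signature = 20, max_n_signature = 150,
                                consistency_prob = 0.5, consistency_min_n = 3,
                                futility_needs_min_n = FALSE) {
  stopifnot(futility_prob >= 0, futility_prob < graduation_prob,
            graduation_prob <= 1, min_n_signature > 0,
            min_n_signature <= max_n_signature)
  structure(list(graduation_prob = graduation_prob,
                 futility_prob = futility_prob,
                 min_n_signature = min_n_signature,
                 max_n_signature = max_n_signature,
                 consistency_prob = consistency_prob,
                 consistency_min_n = consistency_min_n,
                 futility_needs_min_n = futility_needs_min_n),
            class = "decision_thresholds")
}

#' Subgroup-consistency check for a graduating pair
#'
#' A treatment may only graduate in a signature if it performs well in every
#' member subgroup combination: for each member subgroup with at least
#' `consistency_min_n` treated patients, the superiority probability
#' computed from that subgroup's data alone must exceed `consistency_prob`.
#' Vacuously true when no subgroup meets the minimum count.
#'
#' @param per_subgroup Data frame with one row per member subgroup and
#'   columns `n_treated` and `superiority` (subgroup-restricted posterior
#'   probability of superiority).
#' @param thresholds A [decision_thresholds()].
#' @return `TRUE` if consistent.
#' @export
subgroup_consistency <- function(per_subgroup, thresholds = decision_thresholds()) {
  if (NROW(per_subgroup) == 0L) return(TRUE)
  checked <- per_subgroup$n_treated >= thresholds$consistency_min_n
  all(per_subgroup$superiority[checked] > thresholds$consistency_prob)
}

#' Evaluate one treatment-signature pair at an interim
#'
#' Exactly one of four outcomes: `"graduate"` when the superiority
#' probability reaches the graduation threshold with the minimum treated
#' count and consistent subgroup performance; otherwise `"drop"` at or below
#' the futility threshold; otherwise `"cap_reached"` when signature-level
#' accrual has hit the cap; otherwise `"continue"`.
#'
#' @param superiority Probability of superiority for the pair.
#' @param n_treated Patients treated in the pair (treatment arm, member
#'   subgroups).
#' @param n_signature_total All randomized patients (control + active) in
#'   the signature.
#' @param consistency Result of [subgroup_consistency()].
#' @param thresholds A [decision_thresholds()].
#' @return One of `"graduate"`, `"drop"`, `"cap_reached"`, `"continue"`.
#' @export
#' @examples
#' evaluate_pair(0.86, 25, 100, TRUE)   # "graduate"
#' evaluate_pair(0.10, 12, 40, TRUE)    # "drop"
evaluate_pair <- function(superiority, n_treated, n_signature_total,
                          consistency, thresholds = decision_thresholds()) {
  stopifnot(superiority >= 0, superiority <= 1,
            n_treated >= 0, n_signature_total >= 0)
  if (superiority >= thresholds$graduation_prob &&
      n_treated >= thresholds$min_n_signature && isTRUE(consistency))
    return("graduate")
  if (superiority <= thresholds$futility_prob &&
      (!thresholds$futility_needs_min_n ||
       n_treated >= thresholds$min_n_signature))
    return("drop")
  if (n_signature_total >= thresholds$max_n_signature) return("cap_reached")
  "continue"
}

#' Apply interim decisions to the pair status map
#'
#' Graduated and dropped pairs are absorbing: they leave the active set and
#' never return. Capped pairs freeze (no further adaptive evaluation). A
#' graduation opens a nested confirmatory trial for the pair, and the
#' treatment is no longer available in the active arms of that signature.
#'
#' @param status Named character vector, state per pair key (one of
#'   `"active"`, `"graduated"`, `"dropped"`, `"capped"`).
#' @param records Data frame of decision records with columns `pair`
#'   and `decision`.
#' @return Updated status vector.
#' @export
apply_decisions <- function(status, records) {
  if (NROW(records) == 0L) return(status)
  if (anyDuplicated(records$pair))
    stop("conflicting decision records for a single pair")
  for (i in seq_len(nrow(records))) {
    key <- records$pair[i]
    if (!key %in% names(status)) stop("unknown pair: ", key)
    if (status[key] != "active" && records$decision[i] != "continue")
      stop("decision recorded for non-active pair: ", key)
    status[key] <- switch(records$decision[i],
                          graduate    = "graduated",
                          drop        = "dropped",
                          cap_reached = "capped",
                          continue    = status[key])
  }
  status
}
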