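#' Is the platform still in its burn-in phase?
#'
#' Randomization is fixed (equal) within subgroup combinations until a
#' minimum number of patients has accrued across the total of the active
#' arms (default 50), after which outcome adaptation starts.
#'
#' @param total_active_n Patients randomized to active arms so far,
#'   platform-wide.
#' @param burn_in_n Burn-in threshold. Default 50.
#' @return `TRUE` while still in burn-in.
#' @export
in_burn_in <- function(total_active_n, burn_in_n = 50) {
  stopifnot(total_active_n >= 0, burn_in_n >= 0)
  total_active_n < burn_in_n
}

#' Fixed equal randomization row
#'
#' Equal probability for the control and each eligible active arm.
#'
#' @param eligible_arms Character vector of active arm identifiers.
#' @return Named probability vector over `c("control", eligible_arms)`.
#' @export
burn_in_row <- function(eligible_arms) {
  if (length(eligible_arms) == 0L)
    stop("no eligible active arms; patient must be routed upstream")
  m <- length(eligible_arms)
  p <- rep(1 / (m + 1), m + 1)
  names(p) <- c("control", eligible_arms)
  p
}

#' Subgroup-level weight of a treatment arm
#'
#' Superiority probabilities live at signature level while randomization is
#' stratified by subgroup; a treatment's weight in a subgroup is the
#' unweighted mean of its superiority probabilities over all signatures
#' that contain the subgroup and in which the treatment is still active.
#'
#' @param treatment Treatment identifier.
#' @param subgroup Subgroup index 0--15.
#' @param superiority Named numeric vector of superiority probabilities with
#'   names `"treatment|signature"` (see [pair_key()]).
#' @param catalog A `signature_catalog`.
#' @param active_pairs Character vector of `"treatment|signature"` keys still
#'   active.
#' @return The weight in [0, 1], or `NA_real_` if the treatment is active in
#'   no signature containing the subgroup (arm excluded from the row).
#' @export
arm_weight <- function(treatment, subgroup, superiority, catalog, active_pairs) {
  sigs <- signature_membership(catalog, subgroup)
  keys <- pair_key(treatment, sigs)
  keys <- keys[keys %in% active_pairs]
  if (length(keys) == 0L) return(NA_real_)
  mean(superiority[keys])
}

#' Control-protected adaptive randomization row
#'
#' Arms are randomized proportional to their superiority weights, with the
#' control given a pseudo-weight equal to the largest single-arm weight so
#' that the control allocation probability never falls below any single
#' active arm's (mimicking 1:1 randomization against the most promising
#' treatment). When every weight is zero the row falls back to equal
#' randomization.
#'
#' @param weights Named numeric vector of per-arm weights (no control entry).
#' @return Named probability vector over `c("control", names(weights))`,
#'   summing to 1.
#' @export
#' @examples
#' adaptive_row(c(A = 0.9, B = 0.3))  # control matches A at 0.9/2.1
adaptive_row <- function(weights) {
  if (length(weights) == 0L) stop("need at least one weighted arm")
  if (all(weights == 0)) return(burn_in_row(names(weights)))
  ctrl <- max(weights)
  p <- c(ctrl, weights) / (ctrl + sum(weights))
  names(p) <- c("control", names(weights))
  p
}

#' Draw one randomized arm assignment
#'
#' @param row Named probability vector (a burn-in or adaptive row).
#' @return The sampled arm identifier. Uses the current RNG stream.
#' @export
randomize_patient <- function(row) {
  stopifnot(abs(sum(row) - 1) < 1e-9, all(row >= 0))
  names(row)[sample.int(length(row), 1L, prob = row)]
}

#' Key for a (treatment, signature) pair
#'
#' @param treatment,signature Character vectors (recycled).
#' @return `"treatment|signature"` keys.
#' @export
pair_key <- function(treatment, signature) paste(treatment, signature, sep = "|")

#' Build the full allocation table for the current platform state
#'
#' One row per subgroup combination: equal randomization during burn-in,
#' control-protected proportional randomization afterwards. Treatments
#' active in no signature containing a subgroup are excluded from that row;
#' a subgroup with no eligible arms gets an empty row (patients route to
#' the observational arm or an open confirmatory trial upstream).
#'
#' @param arms Character vector of treatment identifiers in the platform.
#' @param catalog A `signature_catalog`.
#' @param superiority Named vector of superiority probabilities by pair key.
#' @param active_pairs Character vector of active pair keys.
#' @param burn_in `TRUE` for equal randomization.
#' @return A list of 16 named probability vectors, one per subgroup index
#'   (list names "0".."15"); entries may be `NULL` where no arm is eligible.
#' @export
allocation_table <- function(arms, catalog, superiority, active_pairs,
                             burn_in = FALSE) {
  rows <- vector("list", 16L)
  names(rows) <- as.character(0:15)
  for (g in 0:15) {
    w <- vapply(arms, arm_weight, numeric(1),
                subgroup = g, superiority = superiority,
                catalog = catalog, active_pairs = active_pairs)
    w <- w[!is.na(w)]
    if (length(w) == 0L) next
    rows[[as.character(g)]] <-
      if (burn_in) burn_in_row(names(w)) else adaptive_row(w)
  }
  rows
}
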