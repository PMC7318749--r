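#' Enumerate the biomarker subgroup combinations
#'
#' Four binary biomarkers (AR, DRD, TP53, TEfus; mutated vs wild-type)
#' jointly define \eqn{2^4 = 16} mutually exclusive subgroup combinations.
#' Each patient belongs to exactly one subgroup; the subgroup is the
#' stratification variable for randomization.
#'
#' Subgroups are indexed 0--15 by the bit convention AR > DRD > TP53 > TEfus
#' (AR most significant), so index 0 is all wild-type and index 15 all
#' mutated.
#'
#' @return A data frame with 16 rows and columns `index` (integer 0--15) and
#'   `ar`, `drd`, `tp53`, `tefus` (integer 0 = wild-type, 1 = mutated).
#' @export
#' @examples
#' sg <- enumerate_subgroups()
#' sg[sg$index %in% c(0, 15), ]
enumerate_subgroups <- function() {
  idx <- 0:15
  data.frame(
    index = idx,
    ar    = idx %/% 8L %% 2L,
    drd   = idx %/% 4L %% 2L,
    tp53  = idx %/% 2L %% 2L,
    tefus = idx %% 2L
  )
}

#' Construct a biomarker signature
#'
#' A signature is an overlapping union of subgroup combinations (e.g. all
#' TP53-mutated patients) at which treatments are evaluated. A patient may
#' belong to several signatures.
#'
#' @param name Signature label.
#' @param members Integer vector of member subgroup indices (subset of 0--15).
#' @param target_prevalence Estimated population prevalence of the signature.
#' @return An object of class `signature`.
#' @export
biomarker_signature <- function(name, members, target_prevalence) {
  members <- sort(unique(as.integer(members)))
  stopifnot(length(members) >= 1L, all(members >= 0L & members <= 15L),
            target_prevalence >= 0, target_prevalence <= 1)
  structure(list(name = name, members = members,
                 target_prevalence = target_prevalence),
            class = "signature")
}

#' Default catalog of candidate biomarker signatures
#'
#' The five candidate signatures with their estimated prevalences:
#' all patients (1), TP53- and AR- double wild-type (0.5), TP53 mutated
#' (0.37), DNA-repair deficient (DRD mutated, 0.19) and TMPRSS2-ERG fusion
#' positive (TEfus mutated, 0.32). Membership is defined logically from
#' marker status, so each single-marker signature has 8 member subgroups and
#' the double-wild-type signature has 4.
#'
#' @return A `signature_catalog`: a named list of [biomarker_signature()] objects.
#' @export
#' @examples
#' cat5 <- default_catalog()
#' vapply(cat5, function(s) length(s$members), integer(1))
default_catalog <- function() {
  sg <- enumerate_subgroups()
  sigs <- list(
    biomarker_signature("All",        sg$index,                            1.00),
    biomarker_signature("TP53-&AR-",  sg$index[sg$tp53 == 0 & sg$ar == 0], 0.50),
    biomarker_signature("TP53+",      sg$index[sg$tp53 == 1],              0.37),
    biomarker_signature("DRD+",       sg$index[sg$drd == 1],               0.19),
    biomarker_signature("TEfus+",     sg$index[sg$tefus == 1],             0.32)
  )
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  structure(sigs, class = "signature_catalog")
}

#' Signatures containing a subgroup combination
#'
#' @param catalog A `signature_catalog`.
#' @param subgroup A subgroup index in 0--15.
#' @return Character vector of signature names whose member set contains the
#'   subgroup. Under the default catalog this is never empty ("All" contains
#'   every subgroup).
#' @export
signature_membership <- function(catalog, subgroup) {
  subgroup <- as.integer(subgroup)
  if (length(subgroup) != 1L || is.na(subgroup) || subgroup < 0L || subgroup > 15L)
    stop("'subgroup' must be a single index in 0..15")
  names(catalog)[vapply(catalog, function(s) subgroup %in% s$members, logical(1))]
}

#' Calibrate a joint subgroup prevalence from signature marginals
#'
#' The trial protocol prints only signature-level prevalences. A full joint
#' distribution over the 16 subgroups is recovered under a product model:
#' TP53, DRD and TEfus marginals are read off their single-marker
#' signatures, and the AR marginal is solved from the double-wild-type
#' constraint \eqn{P(AR- \& TP53-) = p} assuming AR independent of TP53:
#' \eqn{P(AR+) = 1 - p / P(TP53-)}. All four markers are then taken
#' mutually independent, which reproduces every catalog prevalence exactly.
#'
#' @param catalog A `signature_catalog`; defaults to [default_catalog()].
#'   Must contain the signatures "TP53+", "DRD+", "TEfus+" and "TP53-&AR-".
#' @return A `joint_prevalence`: numeric vector of 16 probabilities named by
#'   subgroup index ("0" ... "15"), summing to 1, with the marker marginals
#'   stored in attribute `marginals`.
#' @export
#' @examples
#' jp <- calibrate_joint_prevalence()
#' sum(jp)                     # 1
#' attr(jp, "marginals")["ar"] # P(AR+) = 1 - 0.5/0.63
calibrate_joint_prevalence <- function(catalog = default_catalog()) {
  need <- c("TP53+", "DRD+", "TEfus+", "TP53-&AR-")
  if (!all(need %in% names(catalog)))
    stop("catalog must contain signatures: ", paste(need, collapse = ", "))
  p_tp53  <- catalog[["TP53+"]]$target_prevalence
  p_drd   <- catalog[["DRD+"]]$target_prevalence
  p_tefus <- catalog[["TEfus+"]]$target_prevalence
  p_wtwt  <- catalog[["TP53-&AR-"]]$target_prevalence
  if (p_wtwt > 1 - p_tp53 + 1e-12)
    stop("infeasible constraints: P(AR- & TP53-) exceeds P(TP53-)")
  p_ar <- 1 - p_wtwt / (1 - p_tp53)
  if (p_ar < -1e-12 || p_ar > 1)
    stop("infeasible constraints: implied P(AR+) outside [0, 1]")
  p_ar <- max(p_ar, 0)
  sg <- enumerate_subgroups()
  marg <- c(ar = p_ar, drd = p_drd, tp53 = p_tp53, tefus = p_tefus)
  probs <- ifelse(sg$ar == 1, marg["ar"], 1 - marg["ar"]) *
    ifelse(sg$drd == 1, marg["drd"], 1 - marg["drd"]) *
    ifelse(sg$tp53 == 1, marg["tp53"], 1 - marg["tp53"]) *
    ifelse(sg$tefus == 1, marg["tefus"], 1 - marg["tefus"])
  names(probs) <- as.character(sg$index)
  structure(probs, marginals = marg, class = "joint_prevalence")
}

#' Analytic signature prevalences implied by a joint distribution
#'
#' @param joint A `joint_prevalence` (or any 16-vector over subgroup
#'   indices 0--15).
#' @param catalog A `signature_catalog`.
#' @return Named numeric vector: the probability mass of each signature's
#'   member set.
#' @export
signature_prevalences <- function(joint, catalog = default_catalog()) {
  vapply(catalog, function(s) sum(joint[s$members + 1L]), numeric(1))
}

#' Sample synthetic biomarker profiles
#'
#' Draws i.i.d. subgroup assignments from a calibrated joint prevalence and
#' expands them to per-marker mutation status.
#'
#' @param joint A `joint_prevalence` from [calibrate_joint_prevalence()].
#' @param n Number of patients to draw.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Data frame with columns `patient_id`, `ar`, `drd`, `tp53`,
#'   `tefus`, `subgroup_index`.
#' @export
#' @examples
#' jp <- calibrate_joint_prevalence()
#' prof <- sample_profiles(jp, 1000, seed = 1)
#' mean(prof$tp53)   # close to 0.37
sample_profiles <- function(joint, n, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(16L, size = n, replace = TRUE, prob = as.numeric(joint)) - 1L
  sg <- enumerate_subgroups()
  out <- sg[idx + 1L, c("ar", "drd", "tp53", "tefus")]
  rownames(out) <- NULL
  cbind(patient_id = seq_len(n), out, subgroup_index = idx)
}
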