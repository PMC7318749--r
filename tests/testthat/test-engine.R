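# small scenarios keep the unit suite fast; full study conditions are
# exercised in the acceptance tests
small_null <- function(...) scenario(horizon = 24, ...)

test_that("a zero-horizon trial returns an empty, valid result", {
  res <- run_trial(scenario(horizon = 0), seed = 1)
  expect_s3_class(res, "trial_result")
  expect_equal(nrow(res$patients), 0L)
  expect_equal(nrow(res$decisions), 0L)
  expect_true(all(res$status == "active"))
})

test_that("a trial is bit-reproducible from (scenario, seed)", {
  scn <- small_null()
  a <- run_trial(scn, seed = 42)
  b <- run_trial(scn, seed = 42)
  expect_identical(a$patients, b$patients)
  expect_identical(a$decisions, b$decisions)
  expect_identical(a$allocation, b$allocation)
  c <- run_trial(scn, seed = 43)
  expect_false(identical(a$patients, c$patients))
})

test_that("the patient ledger conserves accrual and respects censoring", {
  scn <- small_null()
  res <- run_trial(scn, seed = 7)
  p <- res$patients
  first <- p[p$line == 1, ]
  # every accrued patient is in exactly one arm category
  expect_true(all(first$arm %in% c("control", "observational",
                                   scn$treatments)))
  expect_equal(anyDuplicated(first$patient_id), 0L)
  # per-subgroup counts sum to total accrual
  expect_equal(sum(table(first$subgroup_index)), nrow(first))
  # censoring sanity
  expect_true(all(p$observed_time <= p$true_pfs + 1e-12))
  expect_true(all(p$observed_time <= res$months_run - p$entry_month + 1e-12))
  expect_true(all(p$true_pfs > 0))
  expect_equal(p$event, p$true_pfs <= res$months_run - p$entry_month)
})

test_that("non-evaluable patients are observational and never randomized", {
  res <- run_trial(small_null(p_nonevaluable = 1), seed = 3)
  expect_true(all(res$patients$arm == "observational"))
  expect_equal(nrow(res$decisions), 0L)  # no data, priors give 0.5 always
})

test_that("null effects give identical PFS distributions across arms", {
  scn <- small_null()
  res <- run_trial(scn, seed = 5)
  p <- res$patients[res$patients$arm != "observational", ]
  # all arms draw from the 8-month baseline; KS across pooled arms vs control
  ks <- suppressWarnings(
    stats::ks.test(p$true_pfs[p$arm == "control"],
                   p$true_pfs[p$arm != "control"]))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p$true_pfs) - 8), 3 * 8 / sqrt(nrow(p)))
})

test_that("signature effects raise the mean PFS of the treated, max rule", {
  eff <- setNames(c(10, 5), pair_key("T1", c("TP53+", "All")))
  scn <- scenario(horizon = 30, effects = eff)
  res <- run_trial(scn, seed = 11)
  p <- res$patients
  on_t1 <- p$drug == "T1"
  sg <- enumerate_subgroups()
  tp53pos <- sg$tp53[p$subgroup_index + 1] == 1
  # TP53+ patients on T1 get +10 (max of the two effects), others on T1 +5
  m_hi <- mean(p$true_pfs[on_t1 & tp53pos])
  m_lo <- mean(p$true_pfs[on_t1 & !tp53pos])
  n_hi <- sum(on_t1 & tp53pos); n_lo <- sum(on_t1 & !tp53pos)
  expect_lt(abs(m_hi - 18), 3 * 18 / sqrt(n_hi))
  expect_lt(abs(m_lo - 13), 3 * 13 / sqrt(n_lo))
})

test_that("logged decisions replay exactly through the rule evaluator", {
  res <- run_trial(small_null(), seed = 19)
  d <- res$decisions
  for (i in seq_len(nrow(d)))
    expect_equal(evaluate_pair(d$superiority[i], d$n_treated[i],
                               d$n_signature_total[i], d$consistency[i]),
                 d$decision[i])
})

test_that("allocation rows log as normalized and control-protected", {
  res <- run_trial(small_null(), seed = 23)
  al <- res$allocation
  sums <- tapply(al$probability, paste(al$month, al$subgroup), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  for (key in unique(paste(al$month, al$subgroup))) {
    row <- al[paste(al$month, al$subgroup) == key, ]
    pc <- row$probability[row$arm == "control"]
    expect_gte(pc + 1e-12, max(row$probability[row$arm != "control"]))
  }
})

test_that("graduated pairs leave the allocation and spawn a confirmatory trial", {
  eff <- setNames(10, pair_key("T1", "TP53+"))
  scn <- scenario(horizon = 60, effects = eff,
                  accrual_rate = 14)  # faster accrual to reach graduation
  found <- FALSE
  for (seed in 1:10) {
    res <- run_trial(scn, seed = seed)
    g <- res$decisions[res$decisions$decision == "graduate" &
                         res$decisions$pair == "T1|TP53+", ]
    if (nrow(g) == 1) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(res$status[["T1|TP53+"]], "graduated")
  expect_true("T1|TP53+" %in% names(res$confirmatory))
  tr <- res$confirmatory[["T1|TP53+"]]
  # 1:1 fixed randomization: assignment counts differ by at most one
  cp <- res$patients[!is.na(res$patients$confirmatory_pair) &
                       res$patients$confirmatory_pair == "T1|TP53+", ]
  if (nrow(cp) > 0) {
    n_trt <- sum(cp$arm == "T1"); n_soc <- sum(cp$arm == "control")
    expect_lte(abs(n_trt - n_soc), 1)
    sgm <- default_catalog()[["TP53+"]]$members
    expect_true(all(cp$subgroup_index %in% sgm))
  }
  if (!tr$open) expect_true(tr$outcome %in% c("reject", "fail"))
})

test_that("re-randomization creates second lines for active-arm progressors only", {
  scn <- scenario(horizon = 36, rerandomize = TRUE, dropout_prob = 0)
  res <- run_trial(scn, seed = 13)
  p <- res$patients
  expect_true(all(p$line <= 2))  # never a third randomization
  l2 <- p[p$line == 2, ]
  expect_gt(nrow(l2), 0)
  l1 <- p[p$line == 1, ]
  for (i in seq_len(nrow(l2))) {
    prev <- l1[l1$patient_id == l2$patient_id[i], ]
    # only first-line active-arm patients re-enter; control/observational stay
    expect_true(prev$arm %in% scn$treatments)
    expect_gte(l2$entry_month[i], prev$entry_month)
  }
  # disabled: everyone stays on a single line
  res0 <- run_trial(scenario(horizon = 36, rerandomize = FALSE), seed = 13)
  expect_true(all(res0$patients$line == 1))
})

test_that("the posterior recovers a +10 month effect over a long horizon", {
  # control mix pinned to the ineffective drug so the contrast is +10
  eff <- setNames(10, pair_key("T1", "All"))
  scn <- scenario(treatments = c("T1", "T2"), horizon = 120, effects = eff,
                  control_mix = c(T1 = 0, T2 = 1),
                  thresholds = decision_thresholds(graduation_prob = 0.999999,
                                                   futility_prob = 1e-9,
                                                   max_n_signature = 1e6))
  res <- run_trial(scn, seed = 29)
  p <- res$patients
  post_for <- function(sel) {
    expo <- pmin(p$true_pfs[sel], res$months_run - p$entry_month[sel])
    ev <- p$event[sel] & expo > 0
    posterior_update(prior_spec(), survival_data(expo[ev], expo[!ev & expo > 0]))
  }
  pt <- post_for(p$arm == "T1"); pc <- post_for(p$arm == "control")
  diff <- mean_pfs(pt$alpha_post / pt$beta_post) -
    mean_pfs(pc$alpha_post / pc$beta_post)
  expect_lt(abs(diff - 10) / 10, 0.1)
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(scenario(effects = c(5)), "named")
  expect_error(scenario(effects = setNames(5, "T9|All")), "unknown effect")
  expect_error(scenario(effects = setNames(-1, "T1|All")), "non-negative")
  expect_error(scenario(control_mix = c(T1 = 1)), "control_mix")
  expect_error(scenario(baseline_mean_pfs = -1))
})
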