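test_that("time-scale screening flags exactly the fast gating variables", {
  rep1 <- identify_ss_candidates(preset_demo(), T_interest = 1,
                                 V_span = c(-50, 50))
  flagged <- sort(rep1$variable[rep1$flagged %in% TRUE])
  expect_equal(flagged, sort(c("x_alpha", "x_beta", "b", "d", "m")))
  retained <- sort(rep1$variable[rep1$flagged %in% FALSE])
  expect_equal(retained, sort(c("g", "f1", "f2", "h")))

  # a millisecond time scale of interest admits no candidates
  rep2 <- identify_ss_candidates(preset_demo(), T_interest = 0.001,
                                 V_span = c(-50, 50))
  expect_equal(sum(rep2$flagged, na.rm = TRUE), 0)

  # a zero threshold admits none either (tau is strictly positive)
  rep3 <- identify_ss_candidates(preset_demo(), T_interest = 1,
                                 V_span = c(-50, 50), threshold_fraction = 0)
  expect_equal(sum(rep3$flagged, na.rm = TRUE), 0)
})

test_that("the flagged set grows monotonically with the time scale of interest", {
  spans <- c(0.01, 0.1, 1, 10, 100)
  sets <- lapply(spans, function(Ti) {
    r <- identify_ss_candidates(preset_demo(), T_interest = Ti,
                                V_span = c(-50, 50))
    r$variable[r$flagged %in% TRUE]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]),
                label = sprintf("T=%g subset of T=%g", spans[i], spans[i + 1]))
  }
})

test_that("declared-only variables are reported unknown, never silently flagged", {
  rep_ftm <- identify_ss_candidates(preset_ftm(), T_interest = 1,
                                    V_span = c(-50, 50))
  k1 <- rep_ftm[rep_ftm$channel == "K1", ]
  expect_true(all(k1$status == "unknown"))
  expect_true(all(is.na(k1$flagged)))
})

test_that("scan-based verification overrides the rule of thumb with evidence", {
  # constant tau far below the horizon: full relaxation, machine-level match
  res <- verify_candidate(chan_cal(), "f1", horizons = 1200)
  expect_lt(res$max_abs_dI, 1e-6)
  # slow CaT inactivation: deviation shrinks as the horizon grows
  res <- verify_candidate(chan_cat(), "g", horizons = c(10, 100))
  expect_lt(res$max_abs_dI[2], res$max_abs_dI[1])
  # fast BK activation passes at the short horizon
  res <- verify_candidate(chan_bk(), "x_alpha", horizons = 10, Ca = 200)
  expect_lt(res$max_abs_dI, 0.01)
  expect_error(verify_candidate(chan_cat(), "zz"), "belong")
})

test_that("trace comparison is zero on identity and scales with a known shift", {
  p <- protocol(-0.5, onset = 0.1, duration = 0.3, t_max = 0.8)
  tr <- simulate_cell(preset_demo(), p)
  cmp <- compare_traces(tr, tr)
  expect_true(all(attr(cmp, "maxima")$max_rel_diff == 0))

  shifted <- tr
  rng <- max(tr$Vm_mV) - min(tr$Vm_mV)
  shifted$Vm_mV <- tr$Vm_mV + 0.01 * rng
  cmp2 <- compare_traces(tr, shifted)
  mx <- attr(cmp2, "maxima")
  expect_equal(mx$max_rel_diff[mx$signal == "Vm"], 0.01, tolerance = 1e-10)

  other <- simulate_cell(preset_demo(), protocol(0, onset = 0, duration = 0, t_max = 0.8))
  expect_error(compare_traces(tr, other), "protocol")
  g <- glance(cmp2)
  expect_true("max_rel_diff_Vm" %in% names(g))
})

test_that("conductance ranking is ordered, class-normalized and deterministic", {
  rk <- rank_conductances(preset_ftm("published"))
  expect_true(all(diff(rk$gbar_nS_pF) <= 0))
  kclass <- rk[rk$ion_class == "K", ]
  expect_equal(kclass$channel, c("K1", "BK", "Ka", "K2", "b"))
  expect_equal(kclass$gbar_nS_pF[kclass$channel == "K1"], 0.65)
  expect_equal(kclass$gbar_nS_pF[kclass$channel == "Ka"], 0.2)
  expect_equal(sum(kclass$class_share), 1)

  # ties broken lexicographically by channel id
  cfg <- model_config("tie", list(chan_cat(gbar = 0.1), chan_cal(gbar = 0.1)))
  expect_equal(rank_conductances(cfg)$channel, c("CaL", "CaT"))

  single <- model_config("one", list(chan_cat(gbar = 0.058)))
  expect_equal(rank_conductances(single)$class_share, 1)
})

test_that("reduction plans are validated, composable and non-destructive", {
  ftm <- preset_ftm()
  plan <- list(disable = c("K2", "Ka", "h"),
               ss = c("x_alpha", "x_beta", "b", "g", "d", "f1", "m", "h"),
               exchangers_off = "NaK",
               overrides = list(gbar = c(K1 = 0.7, Na = 0.0895, CaL = 0.6),
                                beta = 0.0169))
  rtm <- apply_reduction(ftm, plan)
  expect_equal(count_gating_odes(rtm), 5)
  expect_equal(rtm$beta, 0.0169)
  expect_equal(rtm$channels$K1$gbar, 0.7)
  expect_false(rtm$channels$K2$enabled)
  # the original is untouched
  expect_equal(count_gating_odes(ftm), 19)
  expect_true(ftm$channels$K2$enabled)

  expect_identical(apply_reduction(ftm, list()), ftm)
  expect_error(apply_reduction(ftm, list(disable = "K2", ss = "p")),
               "disables channel")
  expect_error(apply_reduction(ftm, list(disable = "nope")), "unknown channel")
  expect_error(apply_reduction(ftm, list(ss = "nope")), "unknown gating")
  expect_error(apply_reduction(ftm, list(bogus = 1)), "unknown plan")

  # disjoint plans commute
  p1 <- list(disable = "K2")
  p2 <- list(ss = c("d", "f1"))
  a <- apply_reduction(apply_reduction(ftm, p1), p2)
  b <- apply_reduction(apply_reduction(ftm, p2), p1)
  expect_identical(a, b)
})
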