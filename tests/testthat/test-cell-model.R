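test_that("gating-ODE bookkeeping matches the full and reduced variants", {
  expect_equal(count_gating_odes(preset_ftm()), 19)
  expect_equal(count_gating_odes(preset_rtm()), 5)
  expect_equal(count_gating_odes(preset_pilot_rtm()), 13)
  ftm_bk_ss <- model_config("ftm-bk-ss", preset_ftm()$channels,
                            exchangers = c(NCX = TRUE, NaK = TRUE, PMCA = TRUE),
                            modes = c(x_alpha = "SS", x_beta = "SS"))
  expect_equal(count_gating_odes(ftm_bk_ss), 17)
})

test_that("the reduction arithmetic decomposes as 19 - 6 - 8 = 5", {
  ftm <- preset_ftm()
  eliminated <- apply_reduction(ftm, list(disable = c("K2", "Ka", "h")))
  expect_equal(count_gating_odes(ftm) - count_gating_odes(eliminated), 6)
  reduced <- apply_reduction(eliminated, list(
    ss = c("x_alpha", "x_beta", "b", "g", "d", "f1", "m", "h")))
  expect_equal(count_gating_odes(eliminated) - count_gating_odes(reduced), 8)
  expect_equal(count_gating_odes(reduced), 5)
})

test_that("force activation is a Hill function with the stated limits", {
  expect_equal(force_model(160)$omega_ss, 0.5)
  expect_lt(force_model(1)$omega_ss, force_model(1000)$omega_ss)
  expect_equal(force_model(1e-6)$tau_omega, 4000, tolerance = 1e-6)
  expect_equal(force_model(1e9)$tau_omega, 4000 * 0.235, tolerance = 1e-6)
  taus <- force_model(10^seq(0, 5, by = 0.25))$tau_omega
  expect_true(all(taus >= 940 & taus <= 4000))
  expect_error(force_model(-1), "Ca")
})

test_that("the membrane equation obeys its sign convention", {
  cfg <- preset_demo()
  for (id in names(cfg$channels)) cfg$channels[[id]]$enabled <- FALSE
  st <- cell_state(Vm = -60, Ca = 100, gating = numeric(0), omega = 0.1)
  expect_equal(cell_rhs(cfg, st, Iapp = 0)$derivs[["Vm"]], 0)
  # a negative (depolarising) applied current raises Vm
  expect_equal(cell_rhs(cfg, st, Iapp = -0.5)$derivs[["Vm"]], 0.5)
})

test_that("the demo rest state is a genuine equilibrium", {
  cfg <- preset_demo()
  rs <- resting_state(cfg)
  expect_lt(max(abs(cell_rhs(cfg, rs)$derivs)), 1e-8)
  expect_true(rs$Vm > -90 && rs$Vm < -50)
  expect_true(rs$Ca > 0)
})

test_that("an all-disabled configuration rests at the initial guess", {
  cfg <- preset_demo()
  for (id in names(cfg$channels)) cfg$channels[[id]]$enabled <- FALSE
  cfg$ca_clearance <- 0
  rs <- resting_state(cfg, guess = -60)
  expect_equal(rs$Vm, -60)
})

test_that("switching a variable to SS drops one state dimension and leaves other derivatives intact", {
  cfg <- preset_demo()
  rs <- resting_state(cfg)
  cfg_ss <- apply_reduction(cfg, list(ss = "b"))
  rs_ss <- resting_state(cfg_ss)
  expect_equal(length(rs_ss$gating), length(rs$gating) - 1)
  # at a state where b sits exactly at its steady state the two RHS agree
  st <- cell_state(Vm = rs$Vm + 5, Ca = rs$Ca,
                   gating = replace(rs$gating, "b",
                                    steady_state(gating_registry()$b, rs$Vm + 5)),
                   omega = rs$omega)
  st_ss <- cell_state(Vm = st$Vm, Ca = st$Ca,
                      gating = st$gating[names(st$gating) != "b"],
                      omega = st$omega)
  d_full <- cell_rhs(cfg, st)$derivs
  d_red <- cell_rhs(cfg_ss, st_ss)$derivs
  expect_equal(d_full[names(d_red)], d_red, tolerance = 1e-12)
})

test_that("the optimised solver RHS matches the reference implementation", {
  cfg <- preset_demo()
  fast <- hhreduce:::make_fast_rhs(cfg)
  for (st in perturbed_states(cfg, n = 5)) {
    y <- c(st$Vm, st$Ca, st$omega, st$gating[fast$ode_names])
    ref <- cell_rhs(cfg, st)$derivs
    expect_equal(unname(fast$derivs(0, y, 0)), unname(ref), tolerance = 1e-12)
  }
})

test_that("enabled exchangers without formulations are rejected loudly", {
  cfg <- preset_demo()
  rs <- resting_state(cfg)
  cfg$exchangers["NCX"] <- TRUE
  expect_error(cell_rhs(cfg, rs), "NCX")
})

test_that("state validation rejects unphysical values", {
  expect_error(cell_state(-60, Ca = 0), "Ca")
  expect_error(cell_state(-60, Ca = 100, omega = 1.5), "omega")
  expect_error(cell_state(-60, Ca = 100, gating = c(b = 2)), "0, 1")
  expect_error(model_config("x", list(chan_cat()), beta = 0), "beta")
  expect_error(model_config("x", list(chan_cat()), modes = c(zz = "SS")),
               "unknown gating")
})
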