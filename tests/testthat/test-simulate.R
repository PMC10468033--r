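# One shared short demo trace keeps the suite fast; dedicated tests reuse it.
demo_cfg <- preset_demo()
demo_rest <- resting_state(demo_cfg)

test_that("the standard protocol carries the published stimulus parameters", {
  p <- ssp()
  expect_equal(p$amplitude, -0.5)
  expect_equal(p$duration, 2)
  expect_equal(p$t_max, 10)
  expect_equal(p$onset, 1)
  expect_equal(stimulus_at(p, 500), 0)
  expect_equal(stimulus_at(p, 1500), -0.5)
  expect_equal(stimulus_at(p, 3500), 0)
  expect_error(protocol(-0.5, onset = 9, duration = 2, t_max = 10), "t_max")
  expect_error(protocol(-0.5, duration = -1, t_max = 10), "duration")
})

test_that("solver settings validate tolerances and step caps", {
  s <- solver_settings()
  expect_equal(s$abs_tol, 1e-7)
  expect_equal(s$max_step, 0.1)
  expect_error(solver_settings(abs_tol = 0), "tolerances")
  expect_error(solver_settings(max_step = -1), "max_step")
})

test_that("a rest-started zero-stimulus run stays at rest", {
  tr <- simulate_cell(demo_cfg, protocol(0, duration = 0, t_max = 2),
                      init = demo_rest)
  expect_lt(max(abs(tr$Vm_mV - tr$Vm_mV[1])), 0.01)
  expect_true(all(diff(tr$time_ms) > 0))
  expect_true(all(tr$Ca_nM > 0))
})

test_that("traces are deterministic and carry complete metadata", {
  p <- protocol(-0.5, onset = 0.2, duration = 0.3, t_max = 1)
  t1 <- simulate_cell(demo_cfg, p, init = demo_rest)
  t2 <- simulate_cell(demo_cfg, p, init = demo_rest)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  meta <- attr(t1, "metadata")
  expect_true(all(c("config_hash", "protocol", "solver", "ode_gating") %in%
                    names(meta)))
  expect_true(all(paste0("I_", names(demo_cfg$channels)) %in% names(t1)))
})

test_that("halving solver tolerances leaves the trace essentially unchanged", {
  p <- protocol(-0.5, onset = 0.2, duration = 0.8, t_max = 2)
  t1 <- simulate_cell(demo_cfg, p, init = demo_rest)
  t2 <- simulate_cell(demo_cfg, p, init = demo_rest,
                      solver = solver_settings(abs_tol = 5e-8, rel_tol = 5e-8))
  expect_lt(max(abs(t1$Vm_mV - t2$Vm_mV)), 0.1)
})

test_that("gating fractions remain bounded along stimulated trajectories", {
  p <- protocol(-0.5, onset = 0.2, duration = 0.8, t_max = 2)
  tr <- simulate_cell(demo_cfg, p, init = demo_rest)
  gnames <- attr(tr, "metadata")$ode_gating
  for (nm in gnames) {
    expect_true(all(tr[[nm]] >= -1e-6 & tr[[nm]] <= 1 + 1e-6), label = nm)
  }
})

test_that("shrinking a variable's tau converges the full model to its SS-mode variant", {
  scale_tau <- function(cfg, var, factor) {
    for (id in names(cfg$channels)) {
      if (var %in% names(cfg$channels[[id]]$gates)) {
        old <- cfg$channels[[id]]$gates[[var]]$tau
        cfg$channels[[id]]$gates[[var]]$tau <- function(Vm) old(Vm) / factor
      }
    }
    cfg
  }
  p <- protocol(-0.5, onset = 0.1, duration = 0.4, t_max = 1)
  cfg_ss <- apply_reduction(demo_cfg, list(ss = "g"))
  ref <- simulate_cell(cfg_ss, p)
  dev <- vapply(c(10, 100), function(f) {
    tr <- simulate_cell(scale_tau(demo_cfg, "g", f), p)
    max(abs(tr$Vm_mV - ref$Vm_mV))
  }, numeric(1))
  expect_lt(dev[2], dev[1])   # convergence with increasing scaling
  expect_lt(dev[2], 0.5)      # already close at 100x
})

test_that("an elevated extracellular K+ pulse shifts K+ reversal potentials", {
  p <- protocol(0, onset = 0, duration = 0, t_max = 0.05, initial_Ko = 10)
  tr <- simulate_cell(demo_cfg, p, init = demo_rest)
  expect_equal(attr(tr, "metadata")$fixed_Ko, 10)
  # depolarised K+ equilibrium pushes Vm up from the normal rest
  expect_gt(tr$Vm_mV[nrow(tr)], tr$Vm_mV[1])
})

test_that("simulating a variant with declared-only channels fails informatively", {
  expect_error(simulate_cell(preset_rtm(), ssp()), "transcribed|registry")
})
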