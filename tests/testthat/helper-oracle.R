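# Independent oracle for first-order gating relaxation at constant Vm:
# numerical integration of dx/dt = (xss - x)/tau with a stiff solver at
# tight tolerances. Deliberately does not use relax_closed_form().
integrate_gating_ode <- function(gv, x0, Vm, T_ms, Ca = NULL,
                                 tol = 1e-10) {
  xss <- steady_state(gv, Vm, Ca)
  tv <- tau(gv, Vm)
  sol <- deSolve::ode(
    y = c(x = x0), times = c(0, T_ms),
    func = function(t, y, p) list((xss - y[1]) / tv),
    parms = NULL, method = "lsoda", atol = tol, rtol = tol
  )
  unname(sol[nrow(sol), "x"])
}

# Small deterministic state perturbations for consistency checks.
perturbed_states <- function(cfg, n = 5, seed = 42) {
  set.seed(seed)
  base <- resting_state(cfg)
  lapply(seq_len(n), function(i) {
    cell_state(
      Vm = base$Vm + stats::runif(1, -30, 30),
      Ca = base$Ca * stats::runif(1, 0.5, 3),
      gating = pmin(pmax(base$gating + stats::runif(length(base$gating),
                                                    -0.2, 0.2), 0), 1),
      omega = min(max(base$omega + stats::runif(1, -0.1, 0.1), 0), 1)
    )
  })
}
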