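# Voltage-clamp engine: the analytic segment propagator against a direct
# ODE solution, limit-cycle behaviour, and the trapped/non-trapped
# signatures under Milnes-style pacing.

test_that("analytic propagator matches direct ODE integration", {
  m <- herg_model("sd", drug = drug_N)
  p <- voltage_protocol(c(500, 1000), c(-80, 0), name = "mini")
  D <- 1000
  tr <- simulate_voltage_clamp(m, p, D = D, sweeps = 2, dt = 10,
                               keep_states = TRUE)
  # independent route: lsoda over the same piecewise-constant waveform
  genf <- hergblock:::make_generator_fn(m, D)
  x0 <- herg_steady_state(m, -80, D = 0)
  Aneg <- genf(-80); Apos <- genf(0)
  rhs <- function(t, y, p) {
    tm <- t %% 1500
    list((if (tm < 500) Aneg else Apos) %*% y)
  }
  times <- seq(0, 2990, by = 10)
  sol <- deSolve::lsoda(as.numeric(x0), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-13)
  o_ref <- sol[, 1 + m$conducting]
  o_prop <- attr(tr, "states")[m$conducting, ]
  expect_equal(length(o_prop), length(o_ref))
  expect_lt(max(abs(o_prop - o_ref)), 1e-7)
  # occupancies stay a probability vector throughout
  sums <- colSums(attr(tr, "states"))
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("drug-free pacing settles to a limit cycle within sweeps", {
  m <- herg_model("cs")
  ss <- vclamp_steady_state(m, default_protocol("milnes"), D = 0, dt = 10,
                            max_sweeps = 20, tol = 0)
  pk <- ss$peaks
  rel <- abs(diff(pk[15:20])) / pk[15]
  expect_true(all(rel < 1e-4))
})

test_that("SD and CS variants coincide without drug", {
  p <- voltage_protocol(c(500, 500), c(-80, 20), name = "step1s")
  tr_sd <- simulate_voltage_clamp(herg_model("sd", drug = drug_T), p,
                                  D = 0, sweeps = 1, dt = 5)
  tr_cs <- simulate_voltage_clamp(herg_model("cs"), p,
                                  D = 0, sweeps = 1, dt = 5)
  expect_lt(max(abs(tr_sd$current - tr_cs$current)), 1e-8)
})

test_that("trapped drugs accumulate block across sweeps, non-trapped do not", {
  mil <- default_protocol("milnes")
  # trapped example: per-sweep peak decreases monotonically over 10 sweeps
  run_T <- hergblock:::vclamp_run(herg_model("sd", drug = drug_T), mil,
                                  D = 30, dt = 10, max_sweeps = 10, tol = 0)
  expect_true(all(diff(run_T$peaks) < 0))
  # non-trapped example: peaks approximately constant after sweep 1
  run_N <- hergblock:::vclamp_run(herg_model("sd", drug = drug_N), mil,
                                  D = 1000, dt = 10, max_sweeps = 10, tol = 0)
  rel_N <- abs(diff(run_N$peaks[-1])) / run_N$peaks[2]
  expect_true(all(rel_N < 0.05))
  # steady state takes longer for the trapped parameterisation at matched
  # block (~80% for both compounds at these concentrations)
  ss_T <- vclamp_steady_state(herg_model("sd", drug = drug_T), mil, D = 30,
                              dt = 10)
  ss_N <- vclamp_steady_state(herg_model("sd", drug = drug_N), mil, D = 1000,
                              dt = 10)
  expect_gt(ss_T$n_sweeps, ss_N$n_sweeps)
})

test_that("AP-clamp retains drug-bound occupancy between beats for both
           trapped and non-trapped compounds", {
  # prolonged AP-like command waveform (1 s): sharp upstroke, slow
  # repolarising ramp back to rest
  tw <- seq(0, 1000, by = 5)
  vw <- ifelse(tw < 10, -80 + (tw / 10) * 115,
               pmax(-80, 35 - (tw - 10) * 115 / 700))
  wf <- data.frame(t = tw, v = vw)
  for (dd in list(drug_T, drug_N)) {
    D <- if (identical(dd$name, "dofetilide")) 30 else 1000
    m <- herg_model("sd", drug = dd)
    tr <- simulate_ap_clamp(m, wf, D = D, sweeps = 6, dt = 5)
    occ <- attr(tr, "states")
    bound <- colSums(occ[c("IOstar", "Ostar", "Cstar"), ])
    last <- tr$t >= 5000  # final repetition, including its diastole
    expect_gt(min(bound[last]), 0.5 * max(bound[last]))
    expect_gt(max(bound[last]), 0.05)
  }
})
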