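# The nine-state hERG Markov model: rate laws, generator structure,
# conservation, microscopic reversibility and analytic limits.

test_that("binding rate follows the saturating Hill law in concentration", {
  dp <- drug_params(Kmax = 10, Ku = 1e-3, n = 1, EC50 = 100, Vhalf_trap = -50)
  expect_identical(binding_rate(dp, 0), 0)
  expect_equal(binding_rate(dp, 100), 1e-3 * 10 / 2)  # D = EC50 -> half max
  # half-maximum at D = EC50 independent of the Hill coefficient
  dp2 <- drug_params(Kmax = 10, Ku = 1e-3, n = 2.7, EC50 = 100, Vhalf_trap = -50)
  expect_equal(binding_rate(dp2, 100), 1e-3 * 10 / 2)
  # monotone non-decreasing and bounded by Ku * Kmax
  D <- c(0, 1, 10, 100, 1e3, 1e5, 1e8)
  kb <- binding_rate(dp, D)
  expect_true(all(diff(kb) >= 0))
  expect_true(all(kb <= dp$Ku * dp$Kmax))
  expect_error(binding_rate(dp, -1), "D")
})

test_that("untrapping rate is a sigmoid between 0 and the trapping rate", {
  dp <- drug_params(Kmax = 10, Ku = 1e-3, n = 1, EC50 = 100, Vhalf_trap = -50)
  expect_equal(untrap_rate(dp, -50), 3.5e-5 / 2)  # half Kt at Vhalf_trap
  expect_equal(untrap_rate(dp, -1e4), 0, tolerance = 1e-12)
  expect_equal(untrap_rate(dp, 1e4), 3.5e-5)
  V <- seq(-120, 60, by = 5)
  kn <- untrap_rate(dp, V)
  expect_true(all(diff(kn) > 0))
  expect_true(all(kn > 0 & kn < dp$Kt))
})

test_that("K_r closes the drug-binding cycle to microscopic reversibility", {
  base <- herg_base_rates()
  dp <- drug_T
  # loop O -> O* -> C* -> IO* -> IO -> O: clockwise and counter-clockwise
  # rate products agree to 1e-10 relative at any (V, D)
  m <- herg_model("sd", drug = dp)
  for (V in c(-120, -80, -40, 0, 40, 60)) {
    for (D in c(1, 30, 1000)) {
      A <- build_generator(m, V, D)
      cw <- A["Ostar", "O"] * A["Cstar", "Ostar"] * A["IOstar", "Cstar"] *
            A["IO", "IOstar"] * A["O", "IO"]
      ccw <- A["IO", "O"] * A["IOstar", "IO"] * A["Cstar", "IOstar"] *
             A["Ostar", "Cstar"] * A["O", "Ostar"]
      expect_equal(cw / ccw, 1, tolerance = 1e-10)
    }
  }
  # at the voltage where the O->IO and IO->O rates cross, K_r equals K_u
  r_ratio <- function(V) {
    r <- hergblock:::base_rates_at(base, V)
    r[["a53"]] - r[["a63"]]
  }
  Vstar <- uniroot(r_ratio, c(-150, 150), tol = 1e-12)$root
  expect_equal(reversibility_rate(dp, base, Vstar), dp$Ku, tolerance = 1e-8)
  # K_r does not depend on concentration
  expect_identical(reversibility_rate(dp, base, 0, D = 0),
                   reversibility_rate(dp, base, 0, D = 1e4))
})

test_that("generator conserves probability and restricts to the base model", {
  m_sd <- herg_model("sd", drug = drug_T)
  m_cs <- herg_model("cs")
  for (V in c(-80, 0, 40)) {
    A <- build_generator(m_sd, V, D = 30)
    expect_lt(max(abs(colSums(A))), 1e-12)
    offdiag <- A - diag(diag(A))
    expect_true(all(offdiag >= 0))
    # drug-free: no flux into bound states, restriction equals base model
    A0 <- build_generator(m_sd, V, D = 0)
    expect_equal(A0["Ostar", "O"], 0)
    expect_equal(A0["IOstar", "IO"], 0)
    B <- build_generator(m_cs, V)
    expect_equal(A0[1:6, 1:6][upper.tri(A0[1:6, 1:6]) |
                               lower.tri(A0[1:6, 1:6])],
                 B[upper.tri(B) | lower.tri(B)])
  }
})

test_that("occupancy sums to one under long fixed-voltage evolution", {
  m <- herg_model("sd", drug = drug_N)
  A <- build_generator(m, V = 0, D = 500)
  x0 <- herg_steady_state(m, -80, D = 0)
  sol <- deSolve::lsoda(as.numeric(x0), seq(0, 10000, by = 500),
                        function(t, y, p) list(A %*% y), NULL,
                        rtol = 1e-8, atol = 1e-7)
  sums <- rowSums(sol[, -1])
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(sol[, -1] > -1e-9))
})

test_that("steady-state solver returns the generator's null vector", {
  m <- herg_model("sd", drug = drug_T)
  for (V in c(-80, 0)) {
    x <- herg_steady_state(m, V, D = 10)
    A <- build_generator(m, V, D = 10)
    expect_equal(sum(x), 1, tolerance = 1e-12)
    expect_lt(max(abs(A %*% x)), 1e-12)
  }
})

test_that("two-state reduction gives the analytic bound fraction Kb/(Kb+Ku)", {
  # freeze all states but O and O*: the 2x2 sub-generator built from the
  # model's own binding/unbinding entries must equilibrate to Kb/(Kb+Ku)
  m <- herg_model("sd", drug = drug_N)
  D <- 800
  A <- build_generator(m, V = 0, D = D)
  kb <- A["Ostar", "O"]
  ku <- A["O", "Ostar"]
  expect_equal(kb, binding_rate(drug_N, D))
  expect_equal(ku, drug_N$Ku)
  A2 <- matrix(c(-kb, kb, ku, -ku), 2, 2)
  sol <- deSolve::lsoda(c(1, 0), c(0, 1e6), function(t, y, p) list(A2 %*% y),
                        NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, 3]), kb / (kb + ku), tolerance = 1e-6)
})

test_that("open-state current is ohmic in driving force and occupancy", {
  m <- herg_model("cs")
  ek <- m$base$ek
  expect_equal(ikr_current(m, 0, 0), 0)
  expect_equal(ikr_current(m, 0.5, ek), 0)
  expect_equal(ikr_current(m, 0.4, 20), 2 * ikr_current(m, 0.2, 20))
  m2 <- herg_model("cs", scale = 0.25)
  expect_equal(ikr_current(m2, 0.4, 20), 0.25 * ikr_current(m, 0.4, 20))
  expect_error(ikr_current(m, 1.5, 0), "occupancy")
})

test_that("parameter validation rejects non-physical drug parameters", {
  expect_error(drug_params(-1, 1e-3, 1, 100, -50), "Kmax")
  expect_error(drug_params(1, 0, 1, 100, -50), "Ku")
  expect_error(drug_params(1, 1e-3, 0, 100, -50), "n")
  expect_error(drug_params(1, 1e-3, 1, -5, -50), "EC50")
  expect_error(drug_params(1, 1e-3, 1, Inf, -50), "finite")
})
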