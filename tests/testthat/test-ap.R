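# Beat metrics on synthetic geometry and short live AP runs.

test_that("APD90 on a trapezoidal AP reproduces the geometric value", {
  # rest -85 mV, instant rise to +35, 200 ms plateau, linear 100 ms fall:
  # the 90% level (-73 mV) is reached 90% of the way down the ramp
  t <- seq(0, 400, by = 0.1)
  v <- ifelse(t < 10, -85,
       ifelse(t < 210, 35,
       ifelse(t < 310, 35 - (t - 210) * 1.2, -85)))
  tr <- fake_ap_trace(t, v)
  expect_equal(apd90(tr), 290, tolerance = 0.5)
  # invariant to a uniform voltage offset
  tr2 <- fake_ap_trace(t, v + 5)
  expect_equal(apd90(tr2), apd90(tr), tolerance = 1e-9)
  # no repolarisation before the window ends -> undefined, EAD path
  v3 <- ifelse(t < 10, -85, 35)
  tr3 <- fake_ap_trace(t, v3)
  expect_true(is.na(apd90(tr3)))
  expect_true(detect_ead(tr3))
  # a flat trace has no upstroke
  expect_error(apd90(fake_ap_trace(t, rep(-85, length(t)))), "upstroke")
})

test_that("EAD detection flags secondary depolarisations, not smooth APs", {
  t <- seq(0, 800, by = 0.5)
  smooth <- ifelse(t < 10, -85, 35 - (t - 10) * 0.18)
  expect_false(detect_ead(fake_ap_trace(t, pmax(smooth, -85))))
  # inject a 15 mV secondary depolarisation around t = 400 ms
  bump <- 15 * exp(-((t - 400) / 40)^2)
  expect_true(detect_ead(fake_ap_trace(t, pmax(smooth + bump, -85))))
  # a 1 mV wiggle stays below the 2 mV criterion
  small <- 1 * exp(-((t - 400) / 40)^2)
  expect_false(detect_ead(fake_ap_trace(t, pmax(smooth + small, -85))))
})

test_that("qNet is the trapezoidal integral of the six component currents", {
  t <- seq(0, 1000, by = 1)
  z <- rep(0, length(t))
  tr0 <- fake_ap_trace(t, z - 85)
  expect_equal(qnet(tr0), 0)
  cur <- list(IKr = sin(t / 100), INaL = z, ICaL = z, IKs = z, IK1 = z,
              Ito = cos(t / 250))
  tr <- fake_ap_trace(t, z - 85, currents = cur)
  q1 <- qnet(tr)
  cur2 <- lapply(cur, function(x) 3 * x)
  expect_equal(qnet(fake_ap_trace(t, z - 85, currents = cur2)), 3 * q1)
  curm <- lapply(cur, function(x) -x)
  expect_equal(qnet(fake_ap_trace(t, z - 85, currents = curm)), -q1)
  tr$IKs <- NULL
  expect_error(qnet(tr), "IKs")
})

test_that("the paced model produces a physiological drug-free beat and
           conserves hERG occupancy", {
  tr <- pace_ap("cs", n_beats = 2)
  expect_equal(unique(tr$beat), c(1L, 2L))
  b2 <- tr[tr$beat == 2, ]
  expect_lt(b2$v[1], -85)             # diastolic potential
  expect_gt(max(b2$v), 30)            # overshoot
  apd <- apd90(tr, 2)
  expect_gt(apd, 200); expect_lt(apd, 350)
  expect_false(detect_ead(tr, 2))
  expect_gt(qnet(tr, 2), 0)
  y <- attr(tr, "state")
  occ <- sum(y[c("IC1", "IC2", "C1", "C2", "O", "IO",
                 "IObound", "Obound", "Cbound")])
  expect_equal(occ, 1, tolerance = 1e-6)
})

test_that("SD and CS AP variants are identical without drug", {
  init <- prepace_drug_free()
  tr_sd <- pace_ap("sd", drug = drug_T, D = 0, n_beats = 1, init = init)
  tr_cs <- pace_ap("cs", scale = 1, n_beats = 1, init = init)
  expect_lt(max(abs(tr_sd$v - tr_cs$v)), 1e-4)
  expect_lt(max(abs(tr_sd$IKr - tr_cs$IKr)), 1e-7)
})
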