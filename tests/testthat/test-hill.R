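# Hill calibration: dose-response simulation, least-squares fitting,
# parameter recovery and the conductance scale.

test_that("dose-response is 1 at vanishing dose and non-increasing", {
  dr <- dose_response(drug_N, concentrations = c(1e-3, 50, 500, 5e3, 5e4))
  expect_gt(dr$response[1], 0.999)  # D -> 0 limit
  expect_true(all(diff(dr$response) <= 1e-3))
  expect_true(all(dr$response >= 0))
})

test_that("a compound with Kmax = 0 produces no block at any dose", {
  inert <- drug_params(Kmax = 0, Ku = 1e-3, n = 1, EC50 = 100,
                       Vhalf_trap = -50, name = "inert")
  dr <- dose_response(inert, concentrations = c(1, 100, 1e4))
  expect_equal(dr$response, rep(1, 3), tolerance = 1e-6)
})

test_that("Hill fit recovers parameters from noiseless synthetic data", {
  dr <- generate_hill_data(h = 1, IC50 = 50, concs = 10^seq(0, 4, length.out = 8))
  fit <- fit_hill(dr)
  expect_equal(fit$h, 1, tolerance = 0.01)
  expect_equal(fit$IC50, 50, tolerance = 0.01 * 50)
  expect_lt(fit$mse, 1e-8)
  # midpoint response behaviour of the fitted curve
  expect_equal(predict(fit, newdata = fit$IC50), 0.5, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), c(fit$h, fit$IC50))
  # a steeper curve
  dr2 <- generate_hill_data(h = 2.2, IC50 = 300,
                            concs = 10^seq(0.5, 4.5, length.out = 9))
  fit2 <- fit_hill(dr2)
  expect_equal(fit2$h, 2.2, tolerance = 0.022)
  expect_equal(fit2$IC50, 300, tolerance = 3)
})

test_that("median recovered IC50 is within 10% under additive noise", {
  concs <- 10^seq(0, 4, length.out = 12)
  est <- vapply(1:20, function(s) {
    dr <- generate_hill_data(h = 1, IC50 = 50, concs = concs,
                             noise_sd = 0.02, seed = s)
    fit_hill(dr)$IC50
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 50) / 50, 0.10)
})

test_that("degenerate dose-response data are rejected with a clear error", {
  flat1 <- structure(data.frame(conc = 10^(0:4), response = rep(1, 5)),
                     class = c("dose_response", "data.frame"))
  expect_error(fit_hill(flat1), "no transition")
  flat0 <- structure(data.frame(conc = 10^(0:4), response = rep(0.001, 5)),
                     class = c("dose_response", "data.frame"))
  expect_error(fit_hill(flat0), "no transition")
  expect_error(fit_hill(data.frame(conc = 1:3, response = c(1, .5, 0))),
               "at least 4")
})

test_that("conductance scale is the fitted unblocked fraction", {
  dr <- generate_hill_data(h = 1.3, IC50 = 120,
                           concs = 10^seq(0, 4, length.out = 9))
  fit <- fit_hill(dr)
  expect_equal(conductance_scale(0, fit), 1)
  expect_equal(conductance_scale(fit$IC50, fit), 0.5)
  expect_lt(conductance_scale(1e12, fit), 1e-4)
  expect_error(conductance_scale(-1, fit), "D")
})

test_that("calibration closure: CS steady-state peaks match the SD model's
           at the fitted concentrations within the fit residual", {
  concs <- effective_midpoint(drug_N) * 10^seq(-2, 2, length.out = 8)
  dr <- dose_response(drug_N, concentrations = concs)
  fit <- fit_hill(dr)
  # the CS model's current is linear in its conductance scale, so its
  # normalised steady-state peak equals s(D) exactly; verify the linearity
  # on a live simulation at two scales, then the closure against the SD
  # responses
  mil <- default_protocol("milnes")
  ctrl <- vclamp_steady_state(herg_model("cs"), mil, dt = 10)
  s <- conductance_scale(concs[4], fit)
  scaled <- vclamp_steady_state(herg_model("cs", scale = s), mil, dt = 10)
  expect_equal(scaled$peak / ctrl$peak, s, tolerance = 1e-9)
  resid <- abs(predict(fit) - dr$response)
  expect_lt(max(resid), 0.06)
})
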