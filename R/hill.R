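# Hill-curve calibration of the conductance-scaling model against the
# state-dependent model: simulate the SD dose-response under a protocol,
# fit a Hill curve to the normalised steady-state peak currents, and use
# the fitted curve as the CS model's conductance scale.

#' Simulated dose-response of the state-dependent model
#'
#' Simulates the SD model to steady state at each concentration under the
#' given protocol and returns peak currents normalised to the drug-free
#' steady-state peak (final steady-state sweep in both cases).
#'
#' @param drug A [drug_params()] object.
#' @param protocol A [voltage_protocol()] (default: modified Milnes).
#' @param concentrations Concentrations in nM, strictly increasing, all
#'   > 0. Default: 8 log-spaced points over 4 decades centred on the
#'   compound's [effective_midpoint()], which spans the block transition.
#' @param base A [herg_base_rates()] object.
#' @param dt,max_sweeps,tol Passed to [vclamp_steady_state()].
#'
#' @return A `dose_response` data.frame (columns `conc`, `response`,
#'   attributes `drug`, `protocol`, `n_sweeps`).
#' @export
dose_response <- function(drug, protocol = default_protocol("milnes"),
                          concentrations = NULL,
                          base = herg_base_rates(), dt = 10,
                          max_sweeps = 1000L, tol = 1e-3) {
  stopifnot(inherits(drug, "drug_params"))
  if (is.null(concentrations))
    concentrations <- effective_midpoint(drug) * 10^seq(-2, 2, length.out = 8)
  if (any(concentrations <= 0) ||
      is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  model <- herg_model("sd", drug = drug, base = base)
  ctrl <- vclamp_steady_state(model, protocol, D = 0, dt = dt,
                              max_sweeps = max_sweeps, tol = tol)
  if (ctrl$peak <= 0) stop("drug-free reference peak is not positive")
  resp <- numeric(length(concentrations))
  nsw <- integer(length(concentrations))
  for (i in seq_along(concentrations)) {
    ss <- tryCatch(
      vclamp_steady_state(model, protocol, D = concentrations[i], dt = dt,
                          max_sweeps = max_sweeps, tol = tol),
      error = function(e)
        stop(sprintf("dose-response simulation failed at D = %g nM (%s): %s",
                     concentrations[i], protocol$name, conditionMessage(e))))
    resp[i] <- ss$peak / ctrl$peak
    nsw[i] <- ss$n_sweeps
  }
  resp[resp < 0] <- 0  # clip solver noise before fitting
  structure(data.frame(conc = concentrations, response = resp),
            drug = if (is.na(drug$name)) "unnamed" else drug$name,
            protocol = protocol$name, n_sweeps = nsw,
            class = c("dose_response", "data.frame"))
}

# Hill inhibition curve: unblocked fraction at concentration D.
hill_curve <- function(D, h, IC50) IC50^h / (IC50^h + D^h)

#' Effective midpoint concentration of the SD block model
#'
#' The concentration at which the binding rate equals the unbinding rate
#' (`Emax(D) = 1`), i.e. where the open-state pool is half-blocked at
#' equilibrium: `EC50 / (Kmax - 1)^(1/n)`. This — not EC50 itself — is
#' where the dose-response transition sits, because `Kmax` rescales the
#' saturating binding response (in the published parameter sets `Kmax`
#' ranges up to 1e8, putting EC50 far above the functional midpoint).
#' For `Kmax <= 1` (never half-blocked) the nominal EC50 is returned.
#'
#' @param drug A [drug_params()] object.
#' @return Concentration in nM.
#' @export
effective_midpoint <- function(drug) {
  stopifnot(inherits(drug, "drug_params"))
  if (drug$Kmax <= 1 + 1e-12) return(drug$EC50)
  drug$EC50 / (drug$Kmax - 1)^(1 / drug$n)
}

#' Fit a Hill curve to a dose-response by least squares
#'
#' Finds the Hill coefficient `h` and `IC50` minimising the mean squared
#' error between `IC50^h/(IC50^h + D^h)` and the normalised responses,
#' using multi-start bounded optimisation in log-parameter space
#' (`h` in [0.1, 10], `IC50` in [1e-3, 1e8] nM, 5 fixed starts).
#'
#' @param dr A `dose_response` data.frame ([dose_response()] or
#'   [generate_hill_data()]) with >= 4 points spanning the transition.
#' @return An object of class `hill_fit` with elements `h`, `IC50`, `mse`,
#'   `data`, `starts` (per-start results) and `convergence`.
#' @export
#' @examples
#' dr <- generate_hill_data(1.2, 80, 10^seq(0, 4, length.out = 9))
#' fit <- fit_hill(dr)
#' coef(fit)
#' predict(fit, newdata = c(0, 80))
fit_hill <- function(dr) {
  stopifnot(is.data.frame(dr), all(c("conc", "response") %in% names(dr)))
  if (nrow(dr) < 4) stop("need at least 4 concentration points")
  y <- dr$response
  if (all(y > 0.95) || all(y < 0.05))
    stop("no transition in sampled range: responses are all ~1 or all ~0; ",
         "widen the concentration grid")
  D <- dr$conc
  obj <- function(p) {  # p = (log h, log IC50)
    mean((hill_curve(D, exp(p[1]), exp(p[2])) - y)^2)
  }
  lower <- log(c(0.1, 1e-3)); upper <- log(c(10, 1e8))
  # fixed multi-starts: h = 1 with IC50 at the response midpoint estimate,
  # plus spread-out corners of the box
  imid <- which.min(abs(y - 0.5))
  starts <- list(c(0, log(D[imid])),
                 c(log(0.5), log(stats::median(D))),
                 c(log(2), log(stats::median(D))),
                 c(0, log(max(D))),
                 c(0, log(min(D))))
  fits <- lapply(starts, function(s)
    stats::nlminb(pmin(pmax(s, lower), upper), obj,
                  lower = lower, upper = upper))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  structure(list(h = exp(best$par[1]), IC50 = exp(best$par[2]),
                 mse = best$objective, data = dr,
                 starts = length(starts),
                 convergence = best$convergence,
                 iterations = best$iterations),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill curve fit (least squares)\n")
  cat(sprintf("  h    = %.4g\n  IC50 = %.6g nM\n  MSE  = %.3g (%d points, %d starts)\n",
              x$h, x$IC50, x$mse, nrow(x$data), x$starts))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(h = object$h, IC50 = object$IC50)

#' @export
#' @param newdata Concentrations (nM) at which to evaluate the fitted
#'   unblocked fraction; defaults to the fitted data's concentrations.
#' @rdname fit_hill
predict.hill_fit <- function(object, newdata = NULL, ...) {
  D <- if (is.null(newdata)) object$data$conc else newdata
  conductance_scale(D, object)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$response - hill_curve(object$data$conc, object$h, object$IC50)
}

#' @export
plot.hill_fit <- function(x, ...) {
  D <- x$data$conc
  dd <- 10^seq(log10(min(D)) - 0.5, log10(max(D)) + 0.5, length.out = 200)
  graphics::plot(D, x$data$response, log = "x",
                 xlab = "concentration (nM)",
                 ylab = "normalised peak current", ylim = c(0, 1.05), ...)
  graphics::lines(dd, hill_curve(dd, x$h, x$IC50))
  invisible(x)
}

#' Conductance scale of the CS model at a concentration
#'
#' The unblocked fraction `s(D) = IC50^h / (IC50^h + D^h)` from a fitted
#' Hill curve; `s(0) = 1`, `s` decreasing to 0.
#'
#' @param D Concentration(s) in nM, >= 0.
#' @param fit A `hill_fit` object.
#' @return Scale(s) in (0, 1].
#' @export
conductance_scale <- function(D, fit) {
  stopifnot(inherits(fit, "hill_fit"))
  if (any(D < 0)) stop("D must be >= 0")
  hill_curve(D, fit$h, fit$IC50)
}
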