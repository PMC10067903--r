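# Voltage-clamp simulation of the hERG Markov models.
#
# For piecewise-constant protocols the occupancy ODE dx/dt = A(V, D) x is
# linear time-invariant within each segment, so the solution is propagated
# analytically through the eigendecomposition of the segment generator
# (exact up to the 9x9 linear algebra; well below the CVODE tolerances used
# for the AP simulations). AP-clamp waveforms, where V varies continuously,
# are integrated with lsoda at absolute/relative tolerances 1e-7/1e-8.

# Fast generator evaluator: returns function(V) -> generator matrix, with
# coefficient products and matrix indices precomputed for a fixed D.
make_generator_fn <- function(model, D = 0) {
  base <- model$base
  co <- base$coef
  n <- length(model$states)
  qf <- co$q^((base$temp - 20) / 10)
  Av <- co$A * qf
  Bv <- co$B
  idx <- (match(co$from, model$states) - 1L) * n + match(co$to, model$states)
  if (model$variant == "sd") {
    dp <- model$drug
    kb <- binding_rate(dp, D)
    i53 <- match("a53", co$name); i63 <- match("a63", co$name)
    kr0 <- dp$Ku * Av[i53] / Av[i63]
    krB <- Bv[i53] - Bv[i63]
    pos <- function(from, to) (match(from, model$states) - 1L) * n +
                               match(to, model$states)
    didx <- c(pos("O", "Ostar"), pos("Ostar", "O"),
              pos("IO", "IOstar"), pos("IOstar", "IO"),
              pos("Ostar", "Cstar"), pos("Cstar", "Ostar"),
              pos("IOstar", "Cstar"), pos("Cstar", "IOstar"))
    function(V) {
      A <- matrix(0, n, n)
      A[idx] <- Av * exp(Bv * V)
      kn <- dp$Kt / (1 + exp(-(V - dp$Vhalf_trap) / .trap_slope_mV))
      A[didx] <- c(kb, dp$Ku, kb, kr0 * exp(krB * V), dp$Kt, kn, dp$Kt, kn)
      diag(A) <- -colSums(A)
      A
    }
  } else {
    function(V) {
      A <- matrix(0, n, n)
      A[idx] <- Av * exp(Bv * V)
      diag(A) <- -colSums(A)
      A
    }
  }
}

# Eigen propagator for one constant-voltage segment. Returns a list with
# $at(x0, times): occupancy matrix (states x times), times relative to
# segment entry. Falls back to lsoda if the eigenbasis is ill-conditioned.
segment_propagator <- function(A) {
  eg <- eigen(A)
  E <- eg$vectors
  ok <- is.finite(rcond(E)) && rcond(E) > 1e-12
  if (ok) {
    lam <- eg$values
    list(at = function(x0, times) {
      cc <- solve(E, as.complex(x0))
      X <- E %*% (exp(outer(lam, times)) * cc)
      out <- Re(X)
      out[out < 0 & out > -1e-12] <- 0
      out
    })
  } else {
    list(at = function(x0, times) {
      tt <- sort(unique(c(0, times)))
      sol <- deSolve::lsoda(x0, tt, function(t, y, p) list(A %*% y), NULL,
                            rtol = 1e-10, atol = 1e-12)
      t(sol[match(times, tt), -1, drop = FALSE])
    })
  }
}

#' Simulate a hERG model under a voltage-clamp protocol
#'
#' Propagates state occupancy through `sweeps` repetitions of the protocol
#' with no reset between sweeps, and returns the IKr current trace.
#'
#' @param model A [herg_model()].
#' @param protocol A [voltage_protocol()].
#' @param D Drug concentration in nM (SD variant; ignored for CS).
#' @param sweeps Number of sweeps; defaults to the protocol's.
#' @param dt Output sampling interval in ms.
#' @param init Initial occupancy vector; defaults to the drug-free
#'   steady-state occupancy at the first segment's voltage (drug applied at
#'   t = 0).
#' @param keep_states If `TRUE`, attach the occupancy matrix as attribute
#'   `"states"`.
#'
#' @return A data.frame of class `current_trace` with columns `t` (ms),
#'   `v` (mV), `current` (A/F) and `sweep`, carrying the protocol and
#'   concentration as attributes.
#' @export
#' @examples
#' m <- herg_model("cs")
#' tr <- simulate_voltage_clamp(m, default_protocol("milnes"), sweeps = 1)
#' max(tr$current)
simulate_voltage_clamp <- function(model, protocol, D = 0,
                                   sweeps = protocol$sweeps, dt = 5,
                                   init = NULL, keep_states = FALSE) {
  stopifnot(inherits(model, "herg_model"), inherits(protocol, "voltage_protocol"))
  run <- vclamp_run(model, protocol, D, sweeps = sweeps, dt = dt, init = init,
                    keep_trace = TRUE, keep_states = keep_states,
                    max_sweeps = sweeps, tol = 0)
  run$trace
}

# Core sweep loop. Iterates up to max_sweeps; if tol > 0, stops once the
# relative change of the per-sweep peak drops below tol (steady-state
# detection). Optionally accumulates the full trace.
vclamp_run <- function(model, protocol, D, sweeps = protocol$sweeps,
                       dt = 5, init = NULL, keep_trace = FALSE,
                       keep_states = FALSE, max_sweeps = sweeps, tol = 0) {
  genf <- make_generator_fn(model, D)
  nseg <- length(protocol$durations)
  props <- vector("list", nseg)
  tgrids <- vector("list", nseg)
  for (k in seq_len(nseg)) {
    props[[k]] <- segment_propagator(genf(protocol$voltages[k]))
    tg <- seq(0, protocol$durations[k], by = dt)
    tg <- tg[tg < protocol$durations[k]]
    tgrids[[k]] <- tg
  }
  if (is.null(init)) {
    init <- herg_steady_state(
      if (model$variant == "sd") model else model,
      protocol$voltages[1], D = 0)
    if (model$variant == "sd" && length(init) != length(model$states))
      stop("internal: bad initial state length")
  }
  x <- as.numeric(init)
  obs <- protocol$observe
  peaks <- numeric(0)
  trace_parts <- list()
  state_parts <- list()
  sweep_done <- 0L
  for (s in seq_len(max_sweeps)) {
    cur_sweep <- numeric(0); t_sweep <- numeric(0); v_sweep <- numeric(0)
    st_sweep <- NULL
    for (k in seq_len(nseg)) {
      tg <- tgrids[[k]]
      X <- props[[k]]$at(x, c(tg, protocol$durations[k]))
      nt <- length(tg)
      occ <- X[, seq_len(nt), drop = FALSE]
      Vk <- protocol$voltages[k]
      cur_sweep <- c(cur_sweep, ikr_current(model, pmax(occ[model$conducting, ], 0), Vk))
      t_sweep <- c(t_sweep, protocol$starts[k] + tg)
      v_sweep <- c(v_sweep, rep(Vk, nt))
      if (keep_states) st_sweep <- cbind(st_sweep, occ)
      x <- pmax(X[, nt + 1L], 0)
      x <- x / sum(x)
    }
    in_obs <- t_sweep >= obs[1] & t_sweep < obs[2]
    pk <- if (any(in_obs)) max(cur_sweep[in_obs]) else 0
    peaks <- c(peaks, pk)
    if (keep_trace) {
      trace_parts[[s]] <- data.frame(
        t = t_sweep + (s - 1) * protocol$period, v = v_sweep,
        current = cur_sweep, sweep = s)
      if (keep_states) state_parts[[s]] <- st_sweep
    }
    sweep_done <- s
    if (tol > 0 && s >= 2) {
      denom <- max(abs(peaks[s - 1]), 1e-12)
      if (abs(peaks[s] - peaks[s - 1]) / denom < tol) break
    }
  }
  trace <- NULL
  if (keep_trace) {
    trace <- do.call(rbind, trace_parts)
    attr(trace, "protocol") <- protocol
    attr(trace, "D") <- D
    attr(trace, "variant") <- model$variant
    if (keep_states) {
      st <- do.call(cbind, state_parts)
      rownames(st) <- model$states
      attr(trace, "states") <- st
    }
    class(trace) <- c("current_trace", "data.frame")
  }
  list(trace = trace, peaks = peaks, n_sweeps = sweep_done,
       converged = tol > 0 && sweep_done < max_sweeps, state = x)
}

#' Per-sweep peak currents of a voltage-clamp trace
#'
#' The maximum current within each sweep's observation window (the
#' depolarised pulse portion, by protocol construction).
#'
#' @param trace A `current_trace` from [simulate_voltage_clamp()].
#' @return A data.frame with columns `sweep` and `peak` (A/F). An all-zero
#'   sweep yields peak 0.
#' @export
peak_per_sweep <- function(trace) {
  stopifnot(inherits(trace, "current_trace"), nrow(trace) > 0)
  protocol <- attr(trace, "protocol")
  obs <- protocol$observe
  tm <- trace$t %% protocol$period
  in_obs <- tm >= obs[1] & tm < obs[2]
  sw <- sort(unique(trace$sweep))
  pk <- vapply(sw, function(s) {
    sel <- in_obs & trace$sweep == s
    if (!any(sel)) 0 else max(trace$current[sel])
  }, numeric(1))
  data.frame(sweep = sw, peak = pk)
}

#' Fractional block from peak currents
#'
#' `1 - peak_drug / peak_control`. The raw value is returned; values
#' outside `[0, 1]` (solver noise, stimulation artefacts) are the caller's
#' to clip for reporting.
#'
#' @param peak_drug,peak_control Peak currents (A/F), `peak_control > 0`.
#' @return Fractional block (dimensionless).
#' @export
fractional_block <- function(peak_drug, peak_control) {
  if (any(peak_control <= 0)) stop("peak_control must be > 0")
  1 - peak_drug / peak_control
}

#' Pace a voltage-clamp protocol to steady state
#'
#' Repeats sweeps (no reset) until the relative change in per-sweep peak
#' current falls below `tol`, or `max_sweeps` is reached — the operational
#' definition of "steady state" used for dose-response calibration.
#'
#' @inheritParams simulate_voltage_clamp
#' @param max_sweeps Cap on the number of sweeps (default 1000).
#' @param tol Relative peak-change criterion (default 1e-3).
#' @return A list: `peaks` (per sweep), `peak` (final sweep), `n_sweeps`,
#'   `converged`, `state` (occupancy at the end of the last sweep).
#' @export
vclamp_steady_state <- function(model, protocol, D = 0, dt = 5,
                                max_sweeps = 1000L, tol = 1e-3,
                                init = NULL) {
  run <- vclamp_run(model, protocol, D, dt = dt, init = init,
                    keep_trace = FALSE, max_sweeps = max_sweeps, tol = tol)
  list(peaks = run$peaks, peak = run$peaks[run$n_sweeps],
       n_sweeps = run$n_sweeps, converged = run$converged, state = run$state)
}

#' Simulate a hERG model under AP clamp
#'
#' Drives the channel model with a sampled, periodically repeated command
#' waveform (e.g. a prolonged action potential) instead of a rectangular
#' pulse, integrating with lsoda at tolerances abs 1e-7 / rel 1e-8.
#'
#' @param model A [herg_model()].
#' @param waveform A data.frame with columns `t` (ms, from 0) and `v` (mV);
#'   one period of the command waveform.
#' @param D Drug concentration in nM.
#' @param sweeps Number of waveform repetitions.
#' @param dt Output sampling interval (ms).
#' @param init Initial occupancy; defaults to drug-free steady state at the
#'   waveform's initial voltage.
#' @return A `current_trace` data.frame with the occupancy matrix attached
#'   as attribute `"states"`.
#' @export
simulate_ap_clamp <- function(model, waveform, D = 0, sweeps = 10, dt = 1,
                              init = NULL) {
  stopifnot(is.data.frame(waveform), all(c("t", "v") %in% names(waveform)))
  period <- max(waveform$t)
  vfun1 <- stats::approxfun(waveform$t, waveform$v, rule = 2)
  vfun <- function(t) vfun1(t %% period)
  genf <- make_generator_fn(model, D)
  if (is.null(init)) init <- herg_steady_state(model, vfun(0), D = 0)
  times <- seq(0, period * sweeps, by = dt)
  rhs <- function(t, y, p) list(genf(vfun(t)) %*% y)
  sol <- deSolve::lsoda(as.numeric(init), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-7)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("AP-clamp solver failure (D = %g nM, t ~ %g ms)",
                 D, sol[nrow(sol), 1]))
  occ <- t(sol[, -1, drop = FALSE])
  rownames(occ) <- model$states
  v <- vfun(times)
  tr <- data.frame(t = times, v = v,
                   current = ikr_current(model, pmax(occ[model$conducting, ], 0), v),
                   sweep = pmin(floor(times / period) + 1L, sweeps))
  attr(tr, "protocol") <- NULL
  attr(tr, "D") <- D
  attr(tr, "states") <- occ
  class(tr) <- c("current_trace", "data.frame")
  tr
}
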