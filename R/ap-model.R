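# Action-potential simulation: the endocardial ventricular cell model with
# rescaled conductances, carrying either the nine-state SD hERG component
# (AP-SD) or the six-state conductance-scaled component (AP-CS). The ODE
# right-hand side is compiled C (src/ord_cipa.c), integrated beat by beat
# with lsoda at absolute/relative tolerances 1e-7/1e-8.

.ord_state_names <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
  "IC1", "IC2", "C1", "C2", "O", "IO", "IObound", "Obound", "Cbound")

.ord_current_names <- c("IKr", "INaL", "ICaL", "IKs", "IK1", "Ito",
                        "INa", "Istim")

#' Initial state of the AP model
#'
#' The published endocardial steady-state values (1 Hz pacing) for the
#' base model, with the hERG Markov occupancy started in the deep closed
#' state; pre-pacing settles the full system to its limit cycle.
#'
#' @return Named numeric vector of the 48 state variables.
#' @export
ap_initial_state <- function() {
  y <- c(
    v = -87.84, nai = 7.23, nass = 7.23, ki = 143.79, kss = 143.79,
    cai = 8.54e-5, cass = 8.43e-5, cansr = 1.61, cajsr = 1.56,
    m = 0.0074621, hf = 0.692591, hs = 0.692574, j = 0.692477,
    hsp = 0.448501, jp = 0.692413,
    mL = 0.000194015, hL = 0.496116, hLp = 0.265885,
    a = 0.00101185, iF = 0.999542, iS = 0.589579,
    ap = 0.000515567, iFp = 0.999542, iSp = 0.641861,
    d = 2.43015e-9, ff = 1, fs = 0.910671, fcaf = 1, fcas = 0.99982,
    jca = 0.999977, nca = 0.00267171, ffp = 1, fcafp = 1,
    xs1 = 0.270492, xs2 = 0.0001963, xk1 = 0.996801,
    Jrelnp = 2.53943e-5, Jrelp = 3.17262e-7, CaMKt = 0.0124065,
    IC1 = 0, IC2 = 0, C1 = 0, C2 = 1, O = 0, IO = 0,
    IObound = 0, Obound = 0, Cbound = 0)
  stopifnot(identical(names(y), .ord_state_names))
  y
}

#' Configuration of the AP simulations
#'
#' @param cl Pacing cycle length in ms (default 2000, the convention of
#'   the proarrhythmia-metric literature; APD90 and qNet depend on it).
#' @param stim_amp,stim_dur Stimulus amplitude (A/F) and duration (ms).
#' @param atol,rtol Solver tolerances.
#' @param dt_fine,t_fine,dt_coarse Output resolution: `dt_fine` ms
#'   sampling for the first `t_fine` ms of each beat (upstroke), then
#'   `dt_coarse` ms (metric interpolation error is quadratic in the grid
#'   and cancels between the compared variants).
#' @return A list of class `ap_config`.
#' @export
ap_config <- function(cl = 2000, stim_amp = -80, stim_dur = 0.5,
                      atol = 1e-7, rtol = 1e-8,
                      dt_fine = 0.05, t_fine = 10, dt_coarse = 1) {
  stopifnot(cl > 0, stim_dur > 0, atol > 0, rtol > 0, dt_coarse > 0)
  structure(list(cl = cl, stim_amp = stim_amp, stim_dur = stim_dur,
                 atol = atol, rtol = rtol,
                 dt_fine = dt_fine, t_fine = t_fine, dt_coarse = dt_coarse),
            class = "ap_config")
}

# Output time grid for one beat.
.beat_times <- function(config) {
  tt <- c(seq(0, config$t_fine, by = config$dt_fine),
          seq(config$t_fine + config$dt_coarse, config$cl,
              by = config$dt_coarse))
  if (tt[length(tt)] < config$cl) tt <- c(tt, config$cl)
  tt
}

# Parameter vector for the compiled model.
.ord_parms <- function(variant, drug, D, scale, config) {
  if (variant == "sd") {
    stopifnot(inherits(drug, "drug_params"))
    c(mode = 1, D = D, Kmax = drug$Kmax, Ku = drug$Ku, n = drug$n,
      halfmax = drug$EC50^drug$n, Vhalf = drug$Vhalf_trap, Kt = drug$Kt,
      scale = 1, stim_amp = config$stim_amp, stim_dur = config$stim_dur)
  } else {
    c(mode = 0, D = 0, Kmax = 0, Ku = 1e-5, n = 1, halfmax = 1,
      Vhalf = -80, Kt = 3.5e-5, scale = scale,
      stim_amp = config$stim_amp, stim_dur = config$stim_dur)
  }
}

# Integrate one beat from state y0; returns list(trace-part, y_end).
.one_beat <- function(y0, parms, config, times = NULL) {
  if (is.null(times)) times <- .beat_times(config)
  sol <- deSolve::lsoda(y0, times, func = "ord_derivs", parms = parms,
                        dllname = "hergblock", initfunc = "ord_init",
                        nout = 8, outnames = .ord_current_names,
                        rtol = config$rtol, atol = config$atol,
                        maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times))
    stop("AP solver failure within beat (reached t = ",
         sol[nrow(sol), 1], " ms)")
  list(sol = sol, y_end = sol[nrow(sol), 1 + seq_along(y0)])
}

#' Pace the AP model and return the voltage/current traces
#'
#' Runs `n_beats` stimulated beats of the AP model with the chosen hERG
#' variant, starting from `init` (by default the drug-free limit cycle,
#' i.e. drug is added at t = 0).
#'
#' @param variant `"sd"` or `"cs"`.
#' @param drug A [drug_params()] (required for `"sd"`; used by `"cs"` only
#'   through `scale`).
#' @param D Drug concentration in nM (SD variant).
#' @param scale Conductance scale for the CS variant (from
#'   [conductance_scale()]); ignored for SD.
#' @param n_beats Number of beats to simulate and return.
#' @param init Initial state (named vector as [ap_initial_state()]);
#'   defaults to [prepace_drug_free()]'s cached limit cycle.
#' @param config An [ap_config()].
#'
#' @return A data.frame of class `ap_trace` with columns `t` (ms,
#'   continuous across beats), `v` (mV), the component currents (A/F) and
#'   `beat`; the final state vector is attached as attribute `"state"`,
#'   the configuration as `"config"`.
#' @export
pace_ap <- function(variant = c("sd", "cs"), drug = NULL, D = 0, scale = 1,
                    n_beats = 10, init = NULL, config = ap_config()) {
  variant <- match.arg(variant)
  parms <- .ord_parms(variant, drug, D, scale, config)
  if (is.null(init)) init <- prepace_drug_free(config)
  y <- init
  parts <- vector("list", n_beats)
  for (b in seq_len(n_beats)) {
    res <- tryCatch(.one_beat(y, parms, config),
                    error = function(e)
                      stop(sprintf("beat %d: %s", b, conditionMessage(e))))
    sol <- res$sol
    keep <- sol[, 1] < config$cl
    part <- data.frame(t = sol[keep, 1] + (b - 1) * config$cl,
                       v = sol[keep, "v"])
    for (cur in .ord_current_names) part[[cur]] <- sol[keep, cur]
    part$beat <- b
    parts[[b]] <- part
    y <- res$y_end
  }
  out <- do.call(rbind, parts)
  attr(out, "state") <- y
  attr(out, "config") <- config
  attr(out, "variant") <- variant
  attr(out, "D") <- D
  class(out) <- c("ap_trace", "data.frame")
  out
}

# Session cache for drug-free limit cycles, keyed by cycle length.
.prepace_cache <- new.env(parent = emptyenv())

#' Drug-free limit cycle of the AP model
#'
#' Paces the drug-free model (SD and CS variants are identical at D = 0)
#' for `n_beats` beats from the published initial conditions and returns
#' the end-diastolic state. Results are cached per cycle length within the
#' session.
#'
#' @param config An [ap_config()].
#' @param n_beats Pre-pacing beats (default 1000).
#' @return Named state vector at the end of the last beat.
#' @export
prepace_drug_free <- function(config = ap_config(), n_beats = 1000) {
  key <- sprintf("cl%g_n%d_sa%g", config$cl, n_beats, config$stim_amp)
  if (!is.null(.prepace_cache[[key]])) return(.prepace_cache[[key]])
  parms <- .ord_parms("cs", NULL, 0, 1, config)
  y <- ap_initial_state()
  times <- c(0, config$stim_dur, config$cl / 2, config$cl)
  for (b in seq_len(n_beats)) {
    res <- .one_beat(y, parms, config, times = times)
    y <- res$y_end
  }
  .prepace_cache[[key]] <- y
  y
}

#' Pace to steady state after drug addition and measure the last beat
#'
#' Starting from the drug-free limit cycle, paces with drug until the
#' beat-to-beat APD90 change is below `apd_tol` (default 0.02 ms) or
#' `max_beats` is reached. Beats whose APD90 is undefined or that show
#' EAD-like behaviour terminate the run once the flag repeats, since APD
#' convergence is then meaningless.
#'
#' @inheritParams pace_ap
#' @param max_beats Cap on post-drug beats.
#' @param apd_tol Beat-to-beat APD90 convergence tolerance (ms).
#' @return A list: `apd90` (per-beat vector, NA where undefined), `ead`
#'   (per-beat flags), `qnet` (final beat, NA if EAD), `n_beats`,
#'   `converged`, `trace` (final beat's `ap_trace`), `state`.
#' @export
pace_to_steady <- function(variant, drug = NULL, D = 0, scale = 1,
                           init = NULL, config = ap_config(),
                           max_beats = 1000, apd_tol = 0.02) {
  variant <- match.arg(variant, c("sd", "cs"))
  parms <- .ord_parms(variant, drug, D, scale, config)
  if (is.null(init)) init <- prepace_drug_free(config)
  y <- init
  apds <- numeric(0); eads <- logical(0)
  converged <- FALSE
  trace <- NULL
  for (b in seq_len(max_beats)) {
    res <- tryCatch(.one_beat(y, parms, config),
                    error = function(e)
                      stop(sprintf("%s variant, D = %g nM, beat %d: %s",
                                   toupper(variant), D, b,
                                   conditionMessage(e))))
    sol <- res$sol
    part <- data.frame(t = sol[, 1], v = sol[, "v"])
    for (cur in .ord_current_names) part[[cur]] <- sol[, cur]
    part$beat <- 1L
    class(part) <- c("ap_trace", "data.frame")
    attr(part, "config") <- config
    apd <- apd90(part, 1)
    ead <- detect_ead(part, 1)
    apds <- c(apds, if (is.na(apd)) NA_real_ else apd)
    eads <- c(eads, ead)
    y <- res$y_end
    trace <- part
    if (b >= 2) {
      if (ead && eads[b - 1]) { converged <- TRUE; break }
      if (!is.na(apds[b]) && !is.na(apds[b - 1]) &&
          abs(apds[b] - apds[b - 1]) < apd_tol) { converged <- TRUE; break }
    }
    if (b >= 4) {
      # period-2 limit cycle (APD alternans, with or without alternating
      # EAD beats): compare beats two apart
      same <- function(x, z) (is.na(x) && is.na(z)) ||
        (!is.na(x) && !is.na(z) && abs(x - z) < apd_tol)
      if (same(apds[b], apds[b - 2]) && same(apds[b - 1], apds[b - 3]) &&
          eads[b] == eads[b - 2] && eads[b - 1] == eads[b - 3]) {
        converged <- TRUE
        break
      }
    }
  }
  n <- length(apds)
  # steady-state summary over the final (possibly alternating) cycle pair
  ead_final <- if (n >= 2) eads[n] || eads[n - 1] else eads[n]
  apd_final <- if (!is.na(apds[n])) apds[n]
               else if (n >= 2) apds[n - 1] else NA_real_
  qn <- if (eads[n]) NA_real_ else qnet(trace, 1)
  list(apd90 = apds, ead = eads, qnet = qn, n_beats = n,
       converged = converged, trace = trace, state = y,
       apd90_final = apd_final, ead_final = ead_final)
}
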