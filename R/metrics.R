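# Per-beat AP metrics (APD90, qNet, EAD-like flag) and the APD90
# comparison metrics between the AP-SD and AP-CS variants.

.beat_rows <- function(trace, beat) {
  stopifnot(inherits(trace, "ap_trace"))
  sel <- trace$beat == beat
  if (!any(sel)) stop("no such beat: ", beat)
  trace[sel, , drop = FALSE]
}

#' Action potential duration at 90% repolarisation
#'
#' APD90 is measured from the time of maximum upstroke velocity to the
#' voltage crossing `V_peak - 0.9 (V_peak - V_rest)`, where `V_rest` is
#' the pre-stimulus diastolic voltage of the beat. The crossing is
#' linearly interpolated between samples.
#'
#' @param trace An `ap_trace` data.frame (columns `t`, `v`, `beat`).
#' @param beat Beat index.
#' @return APD90 in ms, or `NA` if the beat does not repolarise to the
#'   90% level before the next stimulus (handled by the EAD path).
#' @export
apd90 <- function(trace, beat = 1) {
  tr <- .beat_rows(trace, beat)
  t <- tr$t - tr$t[1]
  v <- tr$v
  dvdt <- diff(v) / diff(t)
  iup <- which.max(dvdt)
  if (!length(iup) || dvdt[iup] < 1)
    stop("no stimulus-evoked upstroke detected in beat ", beat)
  t_up <- t[iup]
  v_rest <- v[1]
  ipk <- which.max(v)
  v_peak <- v[ipk]
  thr <- v_peak - 0.9 * (v_peak - v_rest)
  after <- which(seq_along(v) > ipk & v <= thr)
  if (!length(after)) return(NA_real_)
  k <- after[1]
  # linear interpolation of the crossing between samples k-1 and k
  t_cross <- t[k - 1] + (thr - v[k - 1]) * (t[k] - t[k - 1]) / (v[k] - v[k - 1])
  t_cross - t_up
}

#' Net charge metric qNet over one beat
#'
#' The time integral (trapezoidal rule on the solver output grid) of
#' `INaL + ICaL + IKr + IKs + IK1 + Ito` over one paced beat, in C/F.
#'
#' @param trace An `ap_trace` with the six component currents.
#' @param beat Beat index.
#' @return qNet in C/F (A/F integrated over ms, divided by 1000).
#' @export
qnet <- function(trace, beat = 1) {
  tr <- .beat_rows(trace, beat)
  need <- c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trace is missing component current(s): ",
         paste(miss, collapse = ", "))
  inet <- rowSums(tr[, need])
  t <- tr$t
  sum(diff(t) * (inet[-1] + inet[-length(inet)]) / 2) / 1000
}

#' Detect EAD-like behaviour in one beat
#'
#' Flags a beat as EAD-like if, after plateau onset (>= 50 ms past the
#' maximum upstroke velocity) and before 90% repolarisation, the voltage
#' rises by more than `rise_mV` from a running local minimum, or if APD90
#' is undefined within the beat (repolarisation failure).
#'
#' @param trace An `ap_trace`.
#' @param beat Beat index.
#' @param rise_mV Secondary-depolarisation threshold (default 2 mV).
#' @return Logical.
#' @export
detect_ead <- function(trace, beat = 1, rise_mV = 2) {
  tr <- .beat_rows(trace, beat)
  t <- tr$t - tr$t[1]
  v <- tr$v
  dvdt <- diff(v) / diff(t)
  iup <- which.max(dvdt)
  t_up <- t[iup]
  apd <- apd90(trace, beat)
  if (is.na(apd)) return(TRUE)
  win <- t >= t_up + 50 & t <= t_up + apd
  if (sum(win) < 3) return(FALSE)
  vv <- v[win]
  any(vv - cummin(vv) > rise_mV)
}

# --- paired APD90 comparison metrics --------------------------------------

.paired_clean <- function(sd, cs, ead = NULL) {
  stopifnot(length(sd) == length(cs))
  drop <- is.na(sd) | is.na(cs)
  if (!is.null(ead)) {
    stopifnot(length(ead) == length(sd))
    drop <- drop | ead   # symmetric exclusion: either model's flag drops the pair
  }
  if (all(drop))
    stop("all points EAD-excluded: no pairs left for the metric")
  list(sd = sd[!drop], cs = cs[!drop], n = sum(!drop))
}

#' APD90 difference metrics between the AP-SD and AP-CS models
#'
#' `rmsd()` is the root mean squared difference of paired APD90 values,
#' `mean_difference()` the mean of `SD - CS` (positive when the SD variant
#' predicts longer APs), and `signed_rmsd()` is `RMSD * sign(MD)` (defined
#' as 0 when MD is exactly 0). Pairs where either model shows EAD-like
#' behaviour (or an undefined APD90) are excluded.
#'
#' @param sd,cs Paired APD90 values in ms.
#' @param ead Optional logical vector: `TRUE` drops the pair.
#' @return Metric value in ms.
#' @export
rmsd <- function(sd, cs, ead = NULL) {
  p <- .paired_clean(sd, cs, ead)
  sqrt(mean((p$sd - p$cs)^2))
}

#' @rdname rmsd
#' @export
mean_difference <- function(sd, cs, ead = NULL) {
  p <- .paired_clean(sd, cs, ead)
  mean(p$sd - p$cs)
}

#' @rdname rmsd
#' @export
signed_rmsd <- function(sd, cs, ead = NULL) {
  md <- mean_difference(sd, cs, ead)
  if (md == 0) return(0)
  rmsd(sd, cs, ead) * sign(md)
}

#' Calibrate-then-compare pipeline for one compound
#'
#' The full comparison workflow: simulate the SD model's dose-response
#' under the calibration protocol, fit the Hill curve, scale the CS
#' model's conductance with it, pace both AP variants to steady state at
#' each comparison concentration from the shared drug-free limit cycle,
#' and compute the APD90 comparison metrics with symmetric EAD exclusion.
#'
#' @param drug A [drug_params()] object.
#' @param concentrations Comparison concentrations (nM); default 6
#'   log-spaced points from 0.1 to ~30 times the compound's
#'   [effective_midpoint()].
#' @param calib_concentrations Calibration grid for the Hill fit; default
#'   8 log-spaced points over 4 decades centred on EC50.
#' @param protocol Calibration [voltage_protocol()] (default Milnes).
#' @param config An [ap_config()].
#' @param max_beats,apd_tol Steady-state pacing controls
#'   ([pace_to_steady()]).
#' @param prepace_beats Drug-free pre-pacing beats.
#'
#' @return An object of class `sdcs_comparison`: a list with `table`
#'   (per-concentration APD90/qNet/EAD for both variants), `fit` (the
#'   [fit_hill()] object), `rmsd`, `md`, `signed_rmsd`, `n` (non-excluded
#'   pairs) and `drug`.
#' @export
compare_models <- function(drug, concentrations = NULL,
                           calib_concentrations = NULL,
                           protocol = default_protocol("milnes"),
                           config = ap_config(),
                           max_beats = 1000, apd_tol = 0.02,
                           prepace_beats = 1000) {
  stopifnot(inherits(drug, "drug_params"))
  if (is.null(concentrations))
    concentrations <- effective_midpoint(drug) * 10^seq(-1, 1.5, length.out = 6)
  dr <- dose_response(drug, protocol, calib_concentrations)
  fit <- fit_hill(dr)
  init <- prepace_drug_free(config, n_beats = prepace_beats)
  rows <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    D <- concentrations[i]
    sdres <- pace_to_steady("sd", drug = drug, D = D, init = init,
                            config = config, max_beats = max_beats,
                            apd_tol = apd_tol)
    csres <- pace_to_steady("cs", scale = conductance_scale(D, fit),
                            init = init, config = config,
                            max_beats = max_beats, apd_tol = apd_tol)
    rows[[i]] <- data.frame(
      conc = D,
      apd90_sd = sdres$apd90_final, apd90_cs = csres$apd90_final,
      ead_sd = sdres$ead_final, ead_cs = csres$ead_final,
      qnet_sd = sdres$qnet, qnet_cs = csres$qnet,
      beats_sd = sdres$n_beats, beats_cs = csres$n_beats)
  }
  tab <- do.call(rbind, rows)
  excl <- tab$ead_sd | tab$ead_cs
  met <- if (all(excl | is.na(tab$apd90_sd) | is.na(tab$apd90_cs)))
    list(rmsd = NA_real_, md = NA_real_, srmsd = NA_real_, n = 0L)
  else list(rmsd = rmsd(tab$apd90_sd, tab$apd90_cs, excl),
            md = mean_difference(tab$apd90_sd, tab$apd90_cs, excl),
            srmsd = signed_rmsd(tab$apd90_sd, tab$apd90_cs, excl),
            n = sum(!(excl | is.na(tab$apd90_sd) | is.na(tab$apd90_cs))))
  structure(list(table = tab, fit = fit, rmsd = met$rmsd, md = met$md,
                 signed_rmsd = met$srmsd, n = met$n,
                 drug = if (is.na(drug$name)) "unnamed" else drug$name,
                 config = config),
            class = "sdcs_comparison")
}

#' @export
print.sdcs_comparison <- function(x, ...) {
  cat(sprintf("SD vs CS comparison for %s\n", x$drug))
  cat(sprintf("  Hill calibration: h = %.3g, IC50 = %.4g nM\n",
              x$fit$h, x$fit$IC50))
  cat(sprintf("  %d/%d concentration pairs after EAD exclusion\n",
              x$n, nrow(x$table)))
  if (!is.na(x$rmsd))
    cat(sprintf("  RMSD = %.2f ms, MD = %+.2f ms, signed RMSD = %+.2f ms\n",
                x$rmsd, x$md, x$signed_rmsd))
  invisible(x)
}

#' @export
summary.sdcs_comparison <- function(object, ...) {
  print(object)
  cat("\nPer-concentration APD90 (ms):\n")
  print(object$table, row.names = FALSE, digits = 4)
  invisible(object$table)
}

#' @export
plot.sdcs_comparison <- function(x, ...) {
  tab <- x$table
  ylim <- range(c(tab$apd90_sd, tab$apd90_cs), na.rm = TRUE)
  graphics::plot(tab$conc, tab$apd90_sd, log = "x", pch = 19, ylim = ylim,
                 xlab = "concentration (nM)", ylab = "APD90 (ms)", ...)
  graphics::points(tab$conc, tab$apd90_cs, pch = 1)
  flag <- tab$ead_sd | tab$ead_cs
  if (any(flag))
    graphics::points(tab$conc[flag], pmax(tab$apd90_sd, tab$apd90_cs)[flag],
                     pch = 8)
  graphics::legend("topleft", pch = c(19, 1, 8),
                   legend = c("AP-SD", "AP-CS", "EAD-like"), bty = "n")
  invisible(x)
}
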