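# Virtual-drug sensitivity sweep: repeat the calibrate-then-compare
# pipeline over a lattice of (Vhalf_trap, Kmax, Ku) values of the
# simplified SD model (Hill coefficient fixed at 1, concentration in
# units of EC50), and map where |RMSD| of the steady-state APD90s stays
# below the 30 ms interchangeability bound.

#' Normalised drug concentration
#'
#' Concentration in units of the half-maximal binding concentration:
#' `D / EC50`.
#'
#' @param D Concentration (nM), >= 0.
#' @param EC50 Half-maximal binding concentration (nM), > 0.
#' @return Dimensionless normalised concentration.
#' @export
normalise_concentration <- function(D, EC50) {
  if (any(EC50 <= 0)) stop("EC50 must be > 0")
  if (any(D < 0)) stop("D must be >= 0")
  D / EC50
}

#' Default sweep lattice from the compound library ranges
#'
#' Linear spacing for `Vhalf_trap`, log spacing for `Kmax` and `Ku`,
#' between the min and max of the 12-compound library.
#'
#' @param n Points per axis.
#' @param ranges Min/max matrix as in `attr(load_drug_library(), "ranges")`.
#' @return A list with numeric vectors `Vhalf_trap`, `Kmax`, `Ku`.
#' @export
sweep_grid <- function(n = 5, ranges = NULL) {
  if (is.null(ranges)) ranges <- attr(load_drug_library(), "ranges")
  list(
    Vhalf_trap = seq(ranges["min", "Vhalf_trap"], ranges["max", "Vhalf_trap"],
                     length.out = n),
    Kmax = 10^seq(log10(ranges["min", "Kmax"]), log10(ranges["max", "Kmax"]),
                  length.out = n),
    Ku = 10^seq(log10(ranges["min", "Ku"]), log10(ranges["max", "Ku"]),
                length.out = n))
}

# Run the calibrate-then-compare pipeline for one virtual drug; returns a
# one-row data.frame. Failures are caught and marked, not fatal.
.sweep_point <- function(vd, conc_mult_calib, conc_mult_compare, protocol,
                         config, max_beats, apd_tol, init) {
  # grids in normalised concentration, centred on the virtual drug's
  # effective midpoint (the transition location depends strongly on Kmax)
  mid <- effective_midpoint(vd)
  dtilde_calib <- mid * conc_mult_calib
  dtilde_compare <- mid * conc_mult_compare
  out <- data.frame(Vhalf_trap = vd$Vhalf_trap, Kmax = vd$Kmax, Ku = vd$Ku,
                    signed_rmsd = NA_real_, rmsd = NA_real_, md = NA_real_,
                    hill_h = NA_real_, hill_ic50 = NA_real_,
                    n_points = 0L, status = "failed",
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    cmp <- compare_models(vd, concentrations = dtilde_compare,
                          calib_concentrations = dtilde_calib,
                          protocol = protocol, config = config,
                          max_beats = max_beats, apd_tol = apd_tol)
    out$signed_rmsd <- cmp$signed_rmsd
    out$rmsd <- cmp$rmsd
    out$md <- cmp$md
    out$hill_h <- cmp$fit$h
    out$hill_ic50 <- cmp$fit$IC50
    out$n_points <- cmp$n
    out$status <- if (cmp$n == 0) "all_ead" else "ok"
    out
  }, error = function(e) {
    out$status <- paste0("failed: ", conditionMessage(e))
    out
  })
  res
}

#' Virtual-drug sensitivity sweep
#'
#' Runs the full calibrate-then-compare pipeline at every lattice point of
#' `(Vhalf_trap, Kmax, Ku)` and records the signed RMSD of steady-state
#' APD90 between the AP-SD and AP-CS variants, plus the `|RMSD| < 30 ms`
#' interchangeability flag. Numerically failed points are recorded with a
#' `status` message and do not abort the sweep.
#'
#' @param grid A list as from [sweep_grid()].
#' @param conc_mult_calib Hill-calibration grid, as multipliers of each
#'   virtual drug's [effective_midpoint()] (default: 8 log-spaced points
#'   over 4 decades centred on it).
#' @param conc_mult_compare AP-comparison concentrations, as multipliers
#'   of the effective midpoint (default: 4 log-spaced points over
#'   `[0.1, ~30]` times it).
#' @param protocol Calibration protocol.
#' @param config An [ap_config()].
#' @param max_beats,apd_tol Per-concentration pacing budget.
#' @param interchange_ms Interchangeability bound on |RMSD| (ms).
#' @param verbose Print progress.
#'
#' @return A data.frame of class `vd_sweep` with one row per lattice point
#'   (columns `Vhalf_trap`, `Kmax`, `Ku`, `signed_rmsd`, `rmsd`, `md`,
#'   `hill_h`, `hill_ic50`, `n_points`, `status`, `interchangeable`,
#'   `refined`).
#' @export
sweep_virtual_drugs <- function(grid = sweep_grid(3),
                                conc_mult_calib = 10^seq(-2, 2, length.out = 8),
                                conc_mult_compare = 10^seq(-1, 1.5, length.out = 4),
                                protocol = default_protocol("milnes"),
                                config = ap_config(),
                                max_beats = 300, apd_tol = 0.02,
                                interchange_ms = 30, verbose = FALSE) {
  stopifnot(all(c("Vhalf_trap", "Kmax", "Ku") %in% names(grid)))
  init <- prepace_drug_free(config)
  pts <- expand.grid(Vhalf_trap = grid$Vhalf_trap, Kmax = grid$Kmax,
                     Ku = grid$Ku, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    vd <- virtual_drug(pts$Vhalf_trap[i], pts$Kmax[i], pts$Ku[i])
    rows[[i]] <- .sweep_point(vd, conc_mult_calib, conc_mult_compare,
                              protocol, config, max_beats, apd_tol, init)
    if (verbose)
      message(sprintf("[%d/%d] Vhalf=%.3g Kmax=%.3g Ku=%.3g -> %s (sRMSD %.4g)",
                      i, nrow(pts), pts$Vhalf_trap[i], pts$Kmax[i], pts$Ku[i],
                      rows[[i]]$status, rows[[i]]$signed_rmsd))
  }
  out <- do.call(rbind, rows)
  out$interchangeable <- !is.na(out$rmsd) & out$rmsd < interchange_ms
  out$refined <- FALSE
  attr(out, "grid") <- grid
  attr(out, "interchange_ms") <- interchange_ms
  attr(out, "pipeline_args") <- list(conc_mult_calib = conc_mult_calib,
                                     conc_mult_compare = conc_mult_compare,
                                     max_beats = max_beats,
                                     apd_tol = apd_tol)
  class(out) <- c("vd_sweep", "data.frame")
  out
}

#' Refine the sweep near the interchangeability boundary
#'
#' Finds pairs of axis-neighbouring lattice points whose
#' interchangeability flags disagree, inserts the midpoint between them
#' (log-midpoint on the `Kmax`/`Ku` axes, linear on `Vhalf_trap`), runs
#' the pipeline at the new points and appends them (marked
#' `refined = TRUE`).
#'
#' @param result A `vd_sweep` from [sweep_virtual_drugs()].
#' @param protocol,config As in [sweep_virtual_drugs()].
#' @param verbose Print progress.
#' @return The augmented `vd_sweep`.
#' @export
refine_boundary <- function(result, protocol = default_protocol("milnes"),
                            config = ap_config(), verbose = FALSE) {
  stopifnot(inherits(result, "vd_sweep"))
  grid <- attr(result, "grid")
  pa <- attr(result, "pipeline_args")
  base <- result[!result$refined, , drop = FALSE]
  key <- function(v, k, u) paste(signif(v, 10), signif(k, 10), signif(u, 10))
  flag <- stats::setNames(base$interchangeable,
                          key(base$Vhalf_trap, base$Kmax, base$Ku))
  mids <- list()
  axes <- list(
    Vhalf_trap = list(vals = grid$Vhalf_trap, log = FALSE),
    Kmax = list(vals = grid$Kmax, log = TRUE),
    Ku = list(vals = grid$Ku, log = TRUE))
  for (ax in names(axes)) {
    vals <- axes[[ax]]$vals
    if (length(vals) < 2) next
    for (j in seq_len(length(vals) - 1)) {
      sel1 <- abs(base[[ax]] - vals[j]) < 1e-12 * max(1, abs(vals[j]))
      for (i in which(sel1)) {
        p1 <- base[i, ]
        p2row <- base
        # neighbour: same other coordinates, next value on this axis
        others <- setdiff(c("Vhalf_trap", "Kmax", "Ku"), ax)
        match2 <- which(abs(base[[ax]] - vals[j + 1]) <
                          1e-12 * max(1, abs(vals[j + 1])) &
                        base[[others[1]]] == p1[[others[1]]] &
                        base[[others[2]]] == p1[[others[2]]])
        if (!length(match2)) next
        p2 <- base[match2[1], ]
        if (is.na(p1$interchangeable) || is.na(p2$interchangeable)) next
        if (p1$interchangeable == p2$interchangeable) next
        mid <- p1[, c("Vhalf_trap", "Kmax", "Ku")]
        mid[[ax]] <- if (axes[[ax]]$log) sqrt(p1[[ax]] * p2[[ax]])
                     else (p1[[ax]] + p2[[ax]]) / 2
        mids[[length(mids) + 1]] <- mid
      }
    }
  }
  if (!length(mids)) return(result)
  mids <- unique(do.call(rbind, mids))
  rows <- vector("list", nrow(mids))
  for (i in seq_len(nrow(mids))) {
    vd <- virtual_drug(mids$Vhalf_trap[i], mids$Kmax[i], mids$Ku[i])
    rows[[i]] <- .sweep_point(vd, pa$conc_mult_calib, pa$conc_mult_compare,
                              protocol, config, pa$max_beats, pa$apd_tol,
                              NULL)
    if (verbose)
      message(sprintf("refine [%d/%d]: %s", i, nrow(mids), rows[[i]]$status))
  }
  new <- do.call(rbind, rows)
  new$interchangeable <- !is.na(new$rmsd) &
    new$rmsd < attr(result, "interchange_ms")
  new$refined <- TRUE
  out <- rbind(as.data.frame(result), new)
  attributes(out)[c("grid", "interchange_ms", "pipeline_args")] <-
    attributes(result)[c("grid", "interchange_ms", "pipeline_args")]
  class(out) <- c("vd_sweep", "data.frame")
  out
}
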