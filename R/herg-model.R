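# Six-state hERG (IKr) Markov base model and its nine-state extension with
# drug-bound states O*, IO*, C* (state-dependent binding + trapping).
#
# Base-model rate constants are the 37 degrees C parameterisation of the
# CiPA dynamic IKr model (Li et al. 2017, Circ Arrhythm Electrophysiol;
# public implementation in the FDA CiPA / CiPAORdv1.0 code). Each transition
# rate has the form
#     rate(V) = A * exp(B * V) * q^((T - 20)/10),   T = 37
# in ms^-1 with V in mV. The A/q coefficient products around both closed
# loops of the six-state graph balance exactly (detailed-balance structure
# of the published fit), which is checked in the test suite.

#' Base-model rate table for the six-state hERG Markov model
#'
#' Returns the voltage-dependent transition-rate coefficients of the
#' six-state hERG channel model (states IC1, IC2, C1, C2, O, IO), together
#' with the maximal conductance and the potassium reversal potential used
#' throughout the package.
#'
#' @param gkr Maximal conductance in mS/uF, applied as
#'   `gkr * sqrt(ko/5.4) * [O] * (V - EK)`. The default is the published
#'   CiPA value times the 1.013 IKr rescaling of the optimised ventricular
#'   AP model, so that stand-alone voltage clamp and AP simulations use the
#'   same conductance.
#' @param ko,ki Extracellular and intracellular potassium (mM) from which
#'   the Nernst reversal potential is computed; defaults are the AP model's
#'   ionic conditions for consistency between clamp and AP simulations.
#' @param temp Temperature in degrees C entering the published Q10 factors.
#'
#' @return An object of class `herg_base_rates`: a list with `coef` (a
#'   data.frame of transitions `from`, `to`, `A`, `B`, `q`), `gkr`, `ek`,
#'   `ko` and `temp`.
#' @export
#' @examples
#' base <- herg_base_rates()
#' base$ek
herg_base_rates <- function(gkr = 0.04658545454545456 * 1.013,
                            ko = 5.4, ki = 143.79, temp = 37) {
  # Transition coefficients, CiPA dynamic IKr model at 37 C.
  coef <- data.frame(
    name = c("a11", "a21", "a3",  "a4",  "a1",  "a2",
             "a31", "a41", "a53", "a63", "a51", "a61", "a52", "a62"),
    from = c("IC1", "IC2", "IC2", "IO",  "C1",  "C2",
             "C2",  "O",   "O",   "IO",  "C1",  "IC1", "C2",  "IC2"),
    to   = c("IC2", "IC1", "IO",  "IC2", "C2",  "C1",
             "O",   "C2",  "IO",  "O",   "IC1", "C1",  "IC2", "C2"),
    A = c(0.0007868, 5.455e-06, 0.001214, 1.854e-05, 0.0264, 4.986e-06,
          0.005509, 0.001416, 0.149, 0.008978, 0.4492, 0.01241,
          0.3181, 0.3226),
    B = c(1.535e-08, -0.1688, 0.008516, -0.04641, 4.631e-05, -0.004226,
          7.771e-09, -0.02877, 0.004668, -0.02215, 0.008595, 0.1725,
          3.613e-08, -0.0006575),
    q = c(4.942, 4.156, 4.962, 3.769, 4.843, 4.23,
          4.22, 1.459, 2.412, 5.682, 5.0, 5.568, 4.663, 5.0),
    stringsAsFactors = FALSE
  )
  rtf <- 8314 * (273.15 + temp) / 96485  # RT/F in mV
  structure(list(coef = coef, gkr = gkr, ko = ko, ki = ki,
                 ek = rtf * log(ko / ki), temp = temp),
            class = "herg_base_rates")
}

#' @export
print.herg_base_rates <- function(x, ...) {
  cat("Six-state hERG base-model rate table\n")
  cat(sprintf("  %d voltage-dependent transitions, T = %g C\n",
              nrow(x$coef), x$temp))
  cat(sprintf("  gKr = %.5g mS/uF, E_K = %.2f mV (Nernst, Ko = %g, Ki = %g mM)\n",
              x$gkr, x$ek, x$ko, x$ki))
  invisible(x)
}

# Evaluate every base transition rate at voltage V (mV). Returns a named
# numeric vector in ms^-1.
base_rates_at <- function(base, V) {
  co <- base$coef
  r <- co$A * exp(co$B * V) * co$q^((base$temp - 20) / 10)
  names(r) <- co$name
  r
}

#' Drug-binding parameters of the state-dependent hERG block model
#'
#' Bundles the five drug-specific parameters of the state-dependent (SD)
#' block model together with the fixed trapping rate.
#'
#' @param Kmax Dimensionless maximum response scale; the binding rate
#'   saturates at `Ku * Kmax`.
#' @param Ku Unbinding rate in ms^-1 (O* to O).
#' @param n Hill coefficient of the concentration dependence of binding.
#' @param EC50 Concentration (nM) at which the binding rate is half-maximal.
#' @param Vhalf_trap Membrane voltage (mV) at which the untrapping rate is
#'   half the trapping rate.
#' @param Kt Trapping rate in ms^-1; fixed at 3.5e-5 in the published model.
#' @param name Optional compound name.
#'
#' @return An object of class `drug_params`.
#' @export
#' @examples
#' dp <- drug_params(Kmax = 10, Ku = 1e-3, n = 1, EC50 = 100, Vhalf_trap = -50)
#' binding_rate(dp, D = 100)  # half of Ku * Kmax
drug_params <- function(Kmax, Ku, n, EC50, Vhalf_trap, Kt = 3.5e-5,
                        name = NULL) {
  vals <- c(Kmax = Kmax, Ku = Ku, n = n, EC50 = EC50,
            Vhalf_trap = Vhalf_trap, Kt = Kt)
  if (any(!is.finite(vals)))
    stop("all drug parameters must be finite")
  if (Kmax < 0) stop("Kmax must be >= 0")
  if (Ku <= 0) stop("Ku must be > 0")
  if (n <= 0) stop("n must be > 0")
  if (EC50 <= 0) stop("EC50 must be > 0")
  if (Kt <= 0) stop("Kt must be > 0")
  structure(list(Kmax = Kmax, Ku = Ku, n = n, EC50 = EC50,
                 Vhalf_trap = Vhalf_trap, Kt = Kt,
                 name = if (is.null(name)) NA_character_ else name),
            class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("hERG binding parameters%s\n",
              if (is.na(x$name)) "" else paste0(" [", x$name, "]")))
  cat(sprintf("  Kmax = %.4g, Ku = %.4g ms^-1, n = %.4g, EC50 = %.4g nM\n",
              x$Kmax, x$Ku, x$n, x$EC50))
  cat(sprintf("  Vhalf_trap = %.4g mV, Kt = %.4g ms^-1\n", x$Vhalf_trap, x$Kt))
  invisible(x)
}

# Slope (mV) of the voltage dependence of untrapping, adapted in the
# published model from the steady-state activation of hERG.
.trap_slope_mV <- 6.789

#' Drug binding rate K_b
#'
#' The rate at which a compound at concentration `D` binds to the open or
#' inactivated-open channel: `Kb = Ku * Kmax * D^n / (D^n + EC50^n)`.
#'
#' @param params A [drug_params()] object.
#' @param D Drug concentration in nM (scalar or vector, each >= 0).
#' @return Binding rate(s) in ms^-1, bounded by `Ku * Kmax`.
#' @export
binding_rate <- function(params, D) {
  stopifnot(inherits(params, "drug_params"))
  if (any(!is.finite(D)) || any(D < 0))
    stop("drug concentration D must be finite and >= 0")
  dn <- D^params$n
  # D = 0 handled exactly (0/EC50^n = 0)
  params$Ku * params$Kmax * dn / (dn + params$EC50^params$n)
}

#' Untrapping rate K_n
#'
#' The voltage-dependent rate at which a trapped compound leaves the C*
#' state: `Kn(V) = Kt / (1 + exp(-(V - Vhalf_trap)/6.789))`, a sigmoid
#' increasing from 0 to the trapping rate `Kt`.
#'
#' @param params A [drug_params()] object.
#' @param V Membrane voltage in mV (scalar or vector).
#' @return Untrapping rate(s) in ms^-1, in (0, Kt).
#' @export
untrap_rate <- function(params, V) {
  stopifnot(inherits(params, "drug_params"))
  if (any(!is.finite(V))) stop("V must be finite")
  params$Kt / (1 + exp(-(V - params$Vhalf_trap) / .trap_slope_mV))
}

#' Microscopic-reversibility rate K_r
#'
#' The IO* to IO transition rate, defined so that the product of rates
#' around the closed cycle O -> O* -> C* -> IO* -> IO -> O equals the
#' product in the opposite direction. The trapping/untrapping rates and the
#' binding rate each appear once in both directions and cancel, leaving
#' `Kr = Ku * rate(O->IO) / rate(IO->O)`.
#'
#' @param params A [drug_params()] object.
#' @param base A [herg_base_rates()] object.
#' @param V Membrane voltage in mV.
#' @param D Drug concentration in nM (present for interface symmetry; the
#'   cycle condition makes K_r independent of D).
#' @return Rate in ms^-1.
#' @export
reversibility_rate <- function(params, base, V, D = 0) {
  stopifnot(inherits(params, "drug_params"), inherits(base, "herg_base_rates"))
  r <- base_rates_at(base, V)
  if (any(r[c("a53", "a63")] <= 0) || !all(is.finite(r[c("a53", "a63")])))
    stop("vanishing or non-finite O<->IO rate in the reversibility cycle at V = ", V)
  unname(params$Ku * r[["a53"]] / r[["a63"]])
}

#' Construct a hERG channel Markov model
#'
#' Builds either the six-state conductance-scaling (CS) variant, whose
#' maximal conductance is multiplied by an unblocked fraction `scale`, or
#' the nine-state state-dependent (SD) variant with drug-bound states
#' O*, IO* and C*.
#'
#' @param variant `"sd"` (nine states, explicit binding/trapping) or
#'   `"cs"` (six states, conductance scaling).
#' @param drug A [drug_params()] object; required for the SD variant.
#' @param scale Conductance scale in `[0, 1]` (CS variant; 1 means drug-free).
#' @param base A [herg_base_rates()] object.
#'
#' @return An object of class `herg_model` with fields `states`,
#'   `conducting` (index of O), `variant`, `drug`, `scale`, `base`.
#' @export
#' @examples
#' m <- herg_model("cs")
#' G <- build_generator(m, V = 0)
#' colSums(G)  # probability conservation: all (numerically) zero
herg_model <- function(variant = c("sd", "cs"), drug = NULL, scale = 1,
                       base = herg_base_rates()) {
  variant <- match.arg(variant)
  if (variant == "sd") {
    if (is.null(drug)) stop("the SD variant requires drug parameters")
    stopifnot(inherits(drug, "drug_params"))
    states <- c("IC1", "IC2", "C1", "C2", "O", "IO", "IOstar", "Ostar", "Cstar")
    scale <- 1
  } else {
    states <- c("IC1", "IC2", "C1", "C2", "O", "IO")
    if (!is.numeric(scale) || length(scale) != 1 || scale < 0 || scale > 1)
      stop("scale must be a single number in [0, 1]")
  }
  structure(list(states = states, conducting = match("O", states),
                 variant = variant, drug = drug, scale = scale, base = base),
            class = "herg_model")
}

#' @export
print.herg_model <- function(x, ...) {
  cat(sprintf("hERG Markov model, %s variant (%d states)\n",
              toupper(x$variant), length(x$states)))
  if (x$variant == "sd" && !is.null(x$drug$name) && !is.na(x$drug$name))
    cat(sprintf("  drug: %s\n", x$drug$name))
  if (x$variant == "cs")
    cat(sprintf("  conductance scale s = %.4g\n", x$scale))
  invisible(x)
}

#' Transition-rate matrix of a hERG model at fixed voltage and concentration
#'
#' Assembles the generator matrix `A` such that the state-occupancy vector
#' evolves as `dx/dt = A x`. Entry `A[i, j]` (i != j) is the rate from
#' state `j` to state `i`; each diagonal entry is minus the sum of the rest
#' of its column, so occupancy is conserved.
#'
#' @param model A [herg_model()] object.
#' @param V Membrane voltage in mV.
#' @param D Drug concentration in nM (ignored for the CS variant).
#' @return A square matrix (6x6 for CS, 9x9 for SD) with state dimnames.
#' @export
build_generator <- function(model, V, D = 0) {
  stopifnot(inherits(model, "herg_model"))
  base <- model$base
  r <- base_rates_at(base, V)
  if (any(!is.finite(r)))
    stop("non-finite base rate(s) at V = ", V, ": ",
         paste(names(r)[!is.finite(r)], collapse = ", "))
  n <- length(model$states)
  A <- matrix(0, n, n, dimnames = list(model$states, model$states))
  put <- function(from, to, rate) {
    A[to, from] <<- A[to, from] + rate
  }
  co <- base$coef
  for (k in seq_len(nrow(co))) put(co$from[k], co$to[k], r[[co$name[k]]])
  if (model$variant == "sd") {
    dp <- model$drug
    kb <- binding_rate(dp, D)
    kn <- untrap_rate(dp, V)
    kr <- reversibility_rate(dp, base, V, D)
    drug_rates <- c(kb = kb, kn = kn, kr = kr, ku = dp$Ku, kt = dp$Kt)
    if (any(!is.finite(drug_rates)))
      stop("non-finite drug transition rate(s): ",
           paste(names(drug_rates)[!is.finite(drug_rates)], collapse = ", "))
    put("O", "Ostar", kb);       put("Ostar", "O", dp$Ku)
    put("IO", "IOstar", kb);     put("IOstar", "IO", kr)
    put("Ostar", "Cstar", dp$Kt); put("Cstar", "Ostar", kn)
    put("IOstar", "Cstar", dp$Kt); put("Cstar", "IOstar", kn)
  }
  diag(A) <- 0
  diag(A) <- -colSums(A)
  A
}

#' IKr current from open-state occupancy
#'
#' Ohmic current through the conducting O state:
#' `IKr = s * gKr * sqrt(Ko/5.4) * [O] * (V - E_K)` in A/F.
#'
#' @param model A [herg_model()] object.
#' @param open Occupancy of the O state, in `[0, 1]` (vectorised).
#' @param V Membrane voltage in mV (scalar or same length as `open`).
#' @return Current in A/F.
#' @export
ikr_current <- function(model, open, V) {
  stopifnot(inherits(model, "herg_model"))
  if (any(open < -1e-9 | open > 1 + 1e-9, na.rm = TRUE))
    stop("open-state occupancy must lie in [0, 1]")
  base <- model$base
  model$scale * base$gkr * sqrt(base$ko / 5.4) * open * (V - base$ek)
}

# Steady-state occupancy of the generator at fixed (V, D): null vector of A
# with unit sum. Used for initial conditions at the holding potential.
herg_steady_state <- function(model, V, D = 0) {
  A <- build_generator(model, V, D)
  n <- nrow(A)
  # Solve A x = 0, sum(x) = 1 by replacing one row with the constraint.
  M <- rbind(A[-n, , drop = FALSE], rep(1, n))
  x <- solve(M, c(rep(0, n - 1), 1))
  x[abs(x) < 1e-300] <- 0
  names(x) <- rownames(A)
  x
}
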