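# Voltage-clamp protocols: piecewise-constant periodic waveforms plus an
# AP-clamp mode driven by a sampled waveform.

#' Define a piecewise-constant periodic voltage protocol
#'
#' @param durations Segment durations in ms (all > 0).
#' @param voltages Segment command voltages in mV (same length).
#' @param sweeps Default number of sweeps when simulated.
#' @param name Protocol name.
#' @param observe Length-2 numeric, the observation window (ms, relative to
#'   sweep start, half-open) used for peak-current extraction. Defaults to
#'   the span of the highest-voltage segment, i.e. the depolarised pulse,
#'   which avoids the capacitive edges of the step changes.
#'
#' @return An object of class `voltage_protocol`.
#' @export
#' @examples
#' p <- voltage_protocol(c(100, 100), c(-80, 0), name = "two-step")
#' voltage_at(p, c(50, 100, 150, 250))
voltage_protocol <- function(durations, voltages, sweeps = 10L,
                             name = "custom", observe = NULL) {
  if (length(durations) != length(voltages) || length(durations) == 0)
    stop("durations and voltages must be non-empty and of equal length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("all segment durations must be positive")
  if (any(!is.finite(voltages))) stop("all voltages must be finite")
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  if (is.null(observe)) {
    k <- which.max(voltages)
    observe <- c(starts[k], ends[k])
  }
  structure(list(durations = durations, voltages = voltages,
                 starts = starts, ends = ends,
                 period = ends[length(ends)], sweeps = as.integer(sweeps),
                 observe = observe, name = name),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol '%s': period %g ms, %d segment(s), %d sweep(s)\n",
              x$name, x$period, length(x$durations), x$sweeps))
  for (k in seq_along(x$durations))
    cat(sprintf("  [%8.0f, %8.0f) ms : %+6.1f mV\n",
                x$starts[k], x$ends[k], x$voltages[k]))
  cat(sprintf("  observation window [%g, %g) ms\n", x$observe[1], x$observe[2]))
  invisible(x)
}

#' Command voltage at a given time
#'
#' Piecewise-constant lookup with periodic wrap. Segment intervals are
#' half-open `[start, end)`: a time on a boundary belongs to the later
#' segment.
#'
#' @param protocol A [voltage_protocol()].
#' @param t Time(s) in ms, >= 0.
#' @return Voltage(s) in mV.
#' @export
voltage_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (any(t < 0)) stop("t must be >= 0")
  tm <- t %% protocol$period
  idx <- findInterval(tm, protocol$starts)
  protocol$voltages[idx]
}

# --- shipped protocol definitions -----------------------------------------
#
# The modified Milnes protocol: a long rectangular depolarising pulse to
# 0 mV (25 s) preceded by a holding interval at -80 mV. Trapped compounds
# stay bound across the holding interval so the peak current decays sweep
# by sweep; non-trapped compounds dissociate at -80 mV and every sweep
# looks alike. Peaks are read from the depolarised pulse only.
#
# Pneg80 / P0 / P40: state-selective protocols that hold the channel at
# -80, 0 or +40 mV between 5 s test pulses to 0 mV, biasing the interpulse
# occupancy towards closed, open and inactivated states respectively.

#' Shipped voltage-clamp protocols
#'
#' `protocol_library()` returns the four protocols used throughout the
#' package: the modified Milnes protocol and the state-selective Pneg80,
#' P0 and P40 protocols. `default_protocol(name)` fetches one by name.
#'
#' @return A named list of [voltage_protocol()] objects.
#' @export
#' @examples
#' names(protocol_library())
protocol_library <- function() {
  list(
    milnes = voltage_protocol(c(5000, 25000), c(-80, 0),
                              sweeps = 10L, name = "milnes"),
    pneg80 = voltage_protocol(c(15000, 5000), c(-80, 0),
                              sweeps = 10L, name = "pneg80",
                              observe = c(15000, 20000)),
    p0     = voltage_protocol(c(15000, 5000), c(0, 0),
                              sweeps = 10L, name = "p0",
                              observe = c(15000, 20000)),
    p40    = voltage_protocol(c(15000, 5000), c(40, 0),
                              sweeps = 10L, name = "p40",
                              observe = c(15000, 20000))
  )
}

#' @rdname protocol_library
#' @param name One of `"milnes"`, `"pneg80"`, `"p0"`, `"p40"`.
#' @export
default_protocol <- function(name = c("milnes", "pneg80", "p0", "p40")) {
  name <- match.arg(name)
  protocol_library()[[name]]
}

#' Read / write a protocol as a CSV of segments with a JSON sidecar
#'
#' The CSV holds columns `duration_ms`, `voltage_mV`; the JSON sidecar
#' (same path with extension `.json`) holds the sweep count, period, name
#' and observation window.
#'
#' @param protocol A [voltage_protocol()].
#' @param path CSV file path.
#' @return `read_protocol` returns a [voltage_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  utils::write.csv(data.frame(duration_ms = protocol$durations,
                              voltage_mV = protocol$voltages),
                   path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(name = protocol$name, sweeps = protocol$sweeps,
                            period = protocol$period,
                            observe = protocol$observe),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @param path CSV file path.
#' @export
read_protocol <- function(path) {
  seg <- utils::read.csv(path)
  need <- c("duration_ms", "voltage_mV")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop("protocol CSV is missing column(s): ", paste(miss, collapse = ", "))
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(name = "custom", sweeps = 10L, observe = NULL)
  voltage_protocol(seg$duration_ms, seg$voltage_mV,
                   sweeps = meta$sweeps, name = meta$name,
                   observe = if (is.null(meta$observe)) NULL
                             else as.numeric(meta$observe))
}
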