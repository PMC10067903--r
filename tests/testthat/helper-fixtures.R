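# Shared fixtures: compounds from the shipped library and a fast AP
# configuration. The drug-free AP limit cycle is cached per session by
# prepace_drug_free(), so its cost is paid once across test files.

drug_T <- get_drug("T")   # dofetilide parameterisation (trapped)
drug_N <- get_drug("N")   # verapamil parameterisation (non-trapped)

# small synthetic current trace helper
fake_trace <- function(t, current, protocol, sweep = NULL) {
  if (is.null(sweep)) sweep <- floor(t / protocol$period) + 1L
  tr <- data.frame(t = t, v = voltage_at(protocol, t), current = current,
                   sweep = sweep)
  attr(tr, "protocol") <- protocol
  class(tr) <- c("current_trace", "data.frame")
  tr
}

# synthetic AP trace with the columns the beat metrics expect
fake_ap_trace <- function(t, v, beat = 1L, currents = NULL) {
  tr <- data.frame(t = t, v = v)
  nm <- c("IKr", "INaL", "ICaL", "IKs", "IK1", "Ito")
  for (k in nm) tr[[k]] <- if (is.null(currents)) 0 else currents[[k]]
  tr$beat <- beat
  class(tr) <- c("ap_trace", "data.frame")
  tr
}
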