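# A small standard library of HH-style channels with sigmoid/gaussian
# parameterized kinetics. The parameter values are package fixture choices
# spanning the usual functional classes (transient Na, delayed-rectifier and
# slow K, Ih, high-voltage-activated Ca, Ca-activated K, a stochastic Kv);
# they are not claims about any particular published kinetics.

#' Standard channel library
#'
#' @param regions section types the channel is placed on (can be overridden
#'   per entry after construction)
#' @return named list of [channel_spec()]s keyed by mechanism name
#' @export
default_channel_library <- function(regions = "soma") {
  list(
    NaT = channel_spec(
      "NaT", ion = "na", reversal = 50,
      gates = list(
        gate_spec("m", 3, vhalf = -32, slope = 6, tau_base = 0.08,
                  tau_amp = 0.2, tau_center = -35, tau_width = 20),
        gate_spec("h", 1, vhalf = -60, slope = -6.5, tau_base = 0.5,
                  tau_amp = 7, tau_center = -58, tau_width = 20)),
      gbar_param = "gbar_NaT", regions = regions),
    Kdr = channel_spec(
      "Kdr", ion = "k", reversal = -90,
      gates = list(
        gate_spec("n", 4, vhalf = -25, slope = 9, tau_base = 0.6,
                  tau_amp = 4, tau_center = -50, tau_width = 30)),
      gbar_param = "gbar_Kdr", regions = regions),
    # slow low-threshold K (M-current-like): activates subthreshold, so its
    # role (rheobase, adaptation, slow AHP) is separable from the
    # high-threshold delayed rectifier that shapes the spike itself
    Kslow = channel_spec(
      "Kslow", ion = "k", reversal = -90,
      gates = list(
        gate_spec("m", 1, vhalf = -40, slope = 7, tau_base = 60,
                  tau_amp = 100, tau_center = -45, tau_width = 30)),
      gbar_param = "gbar_Kslow", regions = regions),
    Ih = channel_spec(
      "Ih", ion = "nonspecific", reversal = -45,
      gates = list(
        gate_spec("m", 1, vhalf = -90, slope = -7, tau_base = 40,
                  tau_amp = 60, tau_center = -85, tau_width = 25)),
      gbar_param = "gbar_Ih", regions = regions),
    CaHVA = channel_spec(
      "CaHVA", ion = "ca", nernst = TRUE,
      gates = list(
        gate_spec("m", 2, vhalf = -20, slope = 7, tau_base = 1,
                  tau_amp = 1, tau_center = -30, tau_width = 20),
        gate_spec("h", 1, vhalf = -65, slope = -8, tau_base = 60)),
      gbar_param = "gbar_CaHVA", regions = regions),
    SK = channel_spec(
      "SK", ion = "k", reversal = -90,
      gates = list(ca_gate_spec("z", 1, ca_half = 4e-4, hill = 4, tau = 1)),
      gbar_param = "gbar_SK", regions = regions),
    StochKv = stochastic_channel_spec(channel_spec(
      "StochKv", ion = "k", reversal = -90,
      gates = list(
        gate_spec("m", 1, vhalf = -30, slope = 9, tau_base = 2,
                  tau_amp = 10, tau_center = -40, tau_width = 30)),
      gbar_param = "gbar_StochKv", regions = regions), gamma_pS = 100)
  )
}

#' Write / read mechanism definitions as JSON
#'
#' Serializes a list of channel specs (and optionally a calcium dynamics
#' spec) to the package's JSON mechanism format, so protocols and models can
#' reference mechanisms by file.
#'
#' @param mechanisms list of mechanism specs
#' @param path JSON path
#' @export
write_mechanisms_json <- function(mechanisms, path) {
  ser <- lapply(mechanisms, function(m) {
    if (inherits(m, "emf_ca_dynamics"))
      return(c(list(class = "ca_dynamics"), unclass(m)))
    out <- unclass(m)
    out$class <- if (inherits(m, "emf_stoch_channel")) "stochastic_channel"
                 else "channel"
    out
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mechanisms_json
#' @export
read_mechanisms_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(m) {
    if (identical(m$class, "ca_dynamics"))
      return(calcium_dynamics_spec(m$decay_tau, m$depth, m$ca_min,
                                   unlist(m$regions)))
    gates <- lapply(m$gates, function(g) {
      if (isTRUE(g$ca_dep))
        ca_gate_spec(g$name, g$exponent, g$ca_half, g$hill, g$tau_ca)
      else gate_spec(g$name, g$exponent, g$vhalf, g$slope, g$tau_base,
                     g$tau_amp, g$tau_center, g$tau_width)
    })
    ch <- channel_spec(m$name, m$ion, m$reversal %||% 0, gates, m$gbar_param,
                       unlist(m$regions), isTRUE(m$nernst))
    if (identical(m$class, "stochastic_channel"))
      ch <- stochastic_channel_spec(ch, m$gamma_pS, m$mode %||% "deterministic")
    ch
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
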