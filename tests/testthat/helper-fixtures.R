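# Shared fixtures, cached per test session (several suites reuse the
# noiseless recordings and their extracted targets).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

noiseless_cfg <- function() fixture_config(n_cells = 2, param_jitter_sd = 0,
                                           noise_sd_mV = 0, seed = 1)

noiseless_cells <- function() cached("cells", generate_recordings(noiseless_cfg()))

noiseless_targets <- function()
  cached("targets", bin_and_average(noiseless_cells(),
                                    default_target_specs(noiseless_cfg())))

optimization_targets <- function() {
  tg <- noiseless_targets()
  tg[tg$protocol %in% c("RMP", "Rin", "RinHoldCurrent", "Threshold", "IDrest",
                        "APWaveform", "IV"), ]
}

# a purely passive single-compartment cell with a given input resistance
# (MOhm) and membrane time constant (ms)
passive_cell <- function(R_MOhm = 100, tau_ms = 20, e_pas = -70,
                         diam_um = 30) {
  area_cm2 <- pi * diam_um^2 * 1e-8
  g_pas <- 1 / (R_MOhm * 1e6 * area_cm2)
  cell_model(point_morphology(diam_um),
             mechanisms = list(),
             passive = list(g_pas = g_pas, e_pas = e_pas,
                            cm = tau_ms * g_pas * 1e3, Ra = 100),
             parameters = cell_parameters(character(0), numeric(0)),
             name = sprintf("passive_R%g_tau%g", R_MOhm, tau_ms))
}

# passive cell with dendrites (for attenuation properties)
passive_dendritic_cell <- function(g_pas = 1e-4) {
  cell_model(replace_axon(fixture_morphology()),
             mechanisms = list(),
             passive = list(g_pas = g_pas, e_pas = -70, cm = 1, Ra = 100),
             parameters = cell_parameters(character(0), numeric(0)),
             name = "passive_dendritic")
}

# targets extracted from a single pseudo-cell of the dendritic ground truth
# (trimmed sweep set keeps this affordable)
dendritic_targets <- function() {
  cached("dend_targets", {
    cfg <- fixture_config(n_cells = 1, param_jitter_sd = 0, noise_sd_mV = 0,
                          idrest_pcts = 150, idthresh_pcts = c(80, 100, 120),
                          include_validation = FALSE, seed = 1)
    cells <- generate_recordings(cfg, cell_factory = dendritic_ground_truth_cell)
    bin_and_average(cells, default_target_specs(cfg))
  })
}

# build a synthetic voltage trace with stimulus metadata
make_trace <- function(times, values, on, off, amp, protocol = "IDrest",
                       kind = "voltage") {
  emforge:::new_trace(times, values, kind = kind, location = "soma",
                      protocol = protocol, stim_onset = on, stim_offset = off,
                      stim_amp = amp)
}

# flat trace with triangular spike excursions at given onset times
spiky_trace <- function(spike_times, base = -70, peak = 0, width = 2,
                        t_max = 1000, dt = 0.2, on = 100, off = 900,
                        amp = 0.1, protocol = "IDrest") {
  t <- seq(0, t_max, by = dt)
  v <- rep(base, length(t))
  for (st in spike_times) {
    tri <- pmax(0, 1 - abs(t - st) / (width / 2))
    v <- pmax(v, base + (peak - base) * tri)
  }
  make_trace(t, v, on, off, amp, protocol)
}
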