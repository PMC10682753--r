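# Cell-model containers and the R-side driver of the compiled cable solver.

#' Hodgkin-Huxley gate specification
#'
#' Voltage-gated kinetics are parameterized by a sigmoid steady state
#' `inf(V) = 1 / (1 + exp((vhalf - V) / slope))` (negative `slope` gives an
#' inactivation gate) and a Gaussian-bell time constant
#' `tau(V) = tau_base + tau_amp * exp(-((V - tau_center) / tau_width)^2)` so
#' that `tau(V) > 0` whenever `tau_base > 0`.
#'
#' @param name gate label
#' @param exponent non-negative integer exponent in the open probability
#' @param vhalf,slope steady-state sigmoid half-activation and slope, mV
#' @param tau_base,tau_amp,tau_center,tau_width time-constant curve, ms / mV
#' @return a gate spec list
#' @export
gate_spec <- function(name, exponent, vhalf, slope, tau_base,
                      tau_amp = 0, tau_center = 0, tau_width = 1) {
  stopifnot(exponent >= 0, exponent == round(exponent), tau_base > 0, tau_amp >= 0)
  list(name = name, exponent = as.integer(exponent), ca_dep = FALSE,
       vhalf = vhalf, slope = slope, tau_base = tau_base, tau_amp = tau_amp,
       tau_center = tau_center, tau_width = tau_width,
       ca_half = 0, hill = 0, tau_ca = 1)
}

#' Calcium-activated gate specification
#'
#' Open probability follows a Hill function of the local intracellular
#' calcium concentration, `ca^hill / (ca^hill + ca_half^hill)`, relaxing with
#' a fixed time constant.
#'
#' @param name gate label
#' @param exponent integer exponent
#' @param ca_half half-activation concentration, mM
#' @param hill Hill coefficient
#' @param tau relaxation time constant, ms
#' @export
ca_gate_spec <- function(name, exponent = 1, ca_half = 4e-4, hill = 4, tau = 1) {
  stopifnot(exponent >= 0, tau > 0, ca_half > 0)
  list(name = name, exponent = as.integer(exponent), ca_dep = TRUE,
       vhalf = 0, slope = 1, tau_base = tau, tau_amp = 0, tau_center = 0,
       tau_width = 1, ca_half = ca_half, hill = hill, tau_ca = tau)
}

#' Ion channel specification (HH formalism)
#'
#' @param name mechanism name
#' @param ion one of `"na"`, `"k"`, `"ca"`, `"nonspecific"`
#' @param reversal reversal potential, mV; ignored when `nernst = TRUE`
#' @param gates list of [gate_spec()] / [ca_gate_spec()]
#' @param gbar_param name of the model parameter holding the maximal
#'   conductance density (S/cm^2)
#' @param regions character vector of section types carrying the channel
#' @param nernst compute the reversal from the local calcium concentration
#'   (Nernst, extracellular 2 mM at 34 C); only meaningful for `ion = "ca"`
#' @return a channel spec of class `emf_channel`
#' @export
channel_spec <- function(name, ion = c("na", "k", "ca", "nonspecific"),
                         reversal = 0, gates = list(), gbar_param,
                         regions = "soma", nernst = FALSE) {
  ion <- match.arg(ion)
  structure(list(name = name, ion = ion, reversal = reversal, gates = gates,
                 gbar_param = gbar_param, regions = regions, nernst = nernst,
                 gamma_pS = 0), class = "emf_channel")
}

#' Stochastic channel wrapper
#'
#' Wraps a [channel_spec()] with a single-channel conductance; in
#' `"stochastic"` mode the simulator draws the open-channel count binomially
#' per time step from the gating open probability (channel count =
#' `gbar * area / gamma`, rounded), while in `"deterministic"` mode its
#' currents are exactly those of the underlying channel.
#'
#' @param channel a [channel_spec()]
#' @param gamma_pS single-channel conductance, pS
#' @param mode `"deterministic"` or `"stochastic"` default operating mode
#' @export
stochastic_channel_spec <- function(channel, gamma_pS = 100,
                                    mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  channel$gamma_pS <- gamma_pS
  channel$mode <- mode
  class(channel) <- c("emf_stoch_channel", "emf_channel")
  channel
}

#' Intracellular calcium dynamics specification
#'
#' First-order submembrane shell model: calcium influx from Ca currents into
#' a shell of thickness `depth`, decaying toward `ca_min` with time constant
#' `decay_tau`. The concentration never falls below `ca_min`.
#'
#' @param decay_tau decay time constant, ms (a typical free parameter)
#' @param depth shell depth, um
#' @param ca_min resting/minimum concentration, mM
#' @param regions section types carrying the dynamics
#' @export
calcium_dynamics_spec <- function(decay_tau = 80, depth = 0.1, ca_min = 5e-5,
                                  regions = "soma") {
  stopifnot(decay_tau > 0, depth > 0, ca_min > 0)
  structure(list(decay_tau = decay_tau, depth = depth, ca_min = ca_min,
                 regions = regions), class = "emf_ca_dynamics")
}

#' Parameter table for a cell model
#'
#' @param name parameter names (conductance densities in S/cm^2, the calcium
#'   decay in ms, ...)
#' @param value current values
#' @param lower,upper optimization bounds (free parameters must lie inside)
#' @param frozen logical; frozen parameters are not optimized
#' @return a tibble
#' @export
cell_parameters <- function(name, value, lower = value, upper = value,
                            frozen = FALSE) {
  tibble(name = name, value = value, lower = lower, upper = upper,
         frozen = rep_len(frozen, length(name)))
}

#' Assemble a cell model
#'
#' A cell model couples a morphology with region-assigned membrane
#' mechanisms, passive properties and a named parameter vector with bounds.
#'
#' @param morphology an `emf_morphology`
#' @param mechanisms list of [channel_spec()] / [stochastic_channel_spec()]
#'   objects and at most one [calcium_dynamics_spec()]
#' @param passive list with `g_pas` (S/cm^2), `e_pas` (mV), `cm` (uF/cm^2),
#'   `Ra` (Ohm cm); optionally `myelin_cm_factor` (default 0.04), applied to
#'   both the capacitance and the leak of myelinated sections
#' @param parameters a [cell_parameters()] tibble; must contain every
#'   `gbar_param` referenced by a mechanism
#' @param name model identifier
#' @param e_type electrical-type label
#' @export
cell_model <- function(morphology, mechanisms, passive, parameters,
                       name = "emodel", e_type = "generic") {
  passive <- utils::modifyList(list(myelin_cm_factor = 0.04), passive)
  chans <- Filter(function(x) inherits(x, "emf_channel"), mechanisms)
  for (ch in chans)
    if (!ch$gbar_param %in% parameters$name)
      abort(sprintf("mechanism '%s' references missing parameter '%s'",
                    ch$name, ch$gbar_param))
  free <- !parameters$frozen
  bad <- free & (parameters$value < parameters$lower |
                 parameters$value > parameters$upper)
  if (any(bad))
    abort(sprintf("free parameter out of bounds: %s",
                  paste(parameters$name[bad], collapse = ", ")))
  structure(list(morphology = morphology, mechanisms = mechanisms,
                 passive = passive, parameters = parameters, name = name,
                 e_type = e_type, geometry = NULL),
            class = "emf_cell_model")
}

#' @export
print.emf_cell_model <- function(x, ...) {
  cat(sprintf("<cell model '%s' (%s): %d mechanisms, %d parameters (%d free)>\n",
              x$name, x$e_type, length(x$mechanisms), nrow(x$parameters),
              sum(!x$parameters$frozen)))
  invisible(x)
}

#' Get / set model parameter values
#'
#' @param cell a cell model
#' @param values named numeric vector of parameter values
#' @return `set_parameters`: the updated cell; `get_parameters`: named vector
#'   of the free parameter values
#' @export
set_parameters <- function(cell, values) {
  idx <- match(names(values), cell$parameters$name)
  if (anyNA(idx)) abort(sprintf("unknown parameter: %s",
                                paste(names(values)[is.na(idx)], collapse = ", ")))
  cell$parameters$value[idx] <- unname(values)
  cell
}

#' @rdname set_parameters
#' @export
get_parameters <- function(cell) {
  p <- cell$parameters[!cell$parameters$frozen, ]
  stats::setNames(p$value, p$name)
}

#' Stimulus description
#'
#' Kinds: `step` (constant `amplitude` over the window), `ramp` (linear 0 to
#' `amplitude`), `holding` (constant for the whole run), `paired_pulses`
#' (two `width`-ms steps separated by `gap` ms) and `hyperpol_then_depol`
#' (a hyperpolarizing step of `amp_hyp` for `dur_hyp` ms immediately followed
#' by a depolarizing step of `amplitude` for `dur_dep` ms).
#'
#' @param kind stimulus kind
#' @param amplitude current, nA (absolute)
#' @param onset,offset stimulus window, ms
#' @param location a [loc()]
#' @param width,gap paired-pulse geometry, ms
#' @param amp_hyp,dur_hyp,dur_dep hyperpol-then-depol geometry
#' @export
stimulus <- function(kind = c("step", "ramp", "holding", "paired_pulses",
                              "hyperpol_then_depol"),
                     amplitude, onset = 0, offset = 0, location = loc(),
                     width = 5, gap = 50, amp_hyp = 0, dur_hyp = 0, dur_dep = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 offset = offset, location = location, width = width,
                 gap = gap, amp_hyp = amp_hyp, dur_hyp = dur_hyp,
                 dur_dep = dur_dep), class = "emf_stimulus")
}

#' Synaptic conductance specification (double exponential)
#'
#' `g(t) = g_max * norm * (exp(-t/tau_decay) - exp(-t/tau_rise))` with `norm`
#' chosen so the peak conductance equals `g_max`. An NMDA fraction adds the
#' conventional sigmoidal magnesium block
#' `1 / (1 + exp(-0.062 V) [Mg]/3.57)` with `[Mg]` = 1 mM.
#'
#' @param g_max peak conductance, nS
#' @param tau_rise,tau_decay rise/decay time constants, ms (`tau_rise <
#'   tau_decay`)
#' @param nmda_fraction fraction of the conductance carrying the Mg block
#' @param mg magnesium concentration, mM
#' @param reversal synaptic reversal, mV
#' @param location a [loc()] on a dendrite
#' @export
synapse_spec <- function(g_max, tau_rise = 0.5, tau_decay = 5,
                         nmda_fraction = 0, mg = 1, reversal = 0,
                         location = loc("apical", 0.5)) {
  stopifnot(tau_rise < tau_decay, g_max >= 0, nmda_fraction >= 0,
            nmda_fraction <= 1)
  structure(list(g_max = g_max, tau_rise = tau_rise, tau_decay = tau_decay,
                 nmda_fraction = nmda_fraction, mg = mg, reversal = reversal,
                 location = location), class = "emf_synapse")
}

#' Recording location
#'
#' @param section a section type name (first such section in tree order) or
#'   a section id (integer)
#' @param pos relative position along the section, 0 to 1
#' @export
loc <- function(section = "soma", pos = 0.5) list(section = section, pos = pos)

#' @param location a [loc()]
#' @param kind what to record: `"voltage"` (mV), `"calcium"` (mM),
#'   `"mech_currents"` (per-mechanism membrane currents, nA),
#'   `"capacitive"`, `"axial"`, `"injected"` (nA)
#' @rdname loc
#' @export
recording <- function(location = loc(), kind = "voltage") {
  list(location = location, kind = kind)
}

# ---- discretization --------------------------------------------------------

#' Discretize a cell into iso-potential compartments
#'
#' Each section is split into `ceiling(length / max_seg_length)` segments of
#' equal arc length; per-segment membrane area (frusta), capacitance and
#' axial coupling conductances follow from the geometry, the specific
#' capacitance and the axial resistivity. Myelinated sections get their
#' capacitance scaled by `passive$myelin_cm_factor`. The segment order is
#' root-first so the tree solver can eliminate leaves upward.
#'
#' @param cell a cell model
#' @param max_seg_length maximum segment length, um
#' @return a list with `sys` (solver arrays), `seg` (a tibble with one row
#'   per segment: section id/type, geometry, midpoint path distance) used to
#'   resolve recording locations.
#' @export
build_compartments <- function(cell, max_seg_length = 20) {
  stopifnot(max_seg_length > 0)
  m <- cell$morphology
  pas <- cell$passive
  ord <- tree_order(m)
  sdist <- section_start_distance(m)

  seg_rows <- list()
  parent_of <- integer(0)     # 0-based parent per segment
  last_seg_of_sec <- list()   # section id -> 1-based index of its last segment
  idx <- 0L

  for (i in ord) {
    s <- m$sections[[i]]
    single <- nrow(s$points) < 2
    L <- if (single) s$diam[1] else sum(seg_lengths(s$points))
    # myelinated sections are passive with tiny capacitance; coarse segments
    msl <- if (s$type == "myelin") max(max_seg_length, 250) else max_seg_length
    nseg <- if (single) 1L else max(1L, as.integer(ceiling(L / msl)))

    # arc-length positions and interpolated diameters along the polyline
    if (single) {
      cuml <- c(0, L); dprof <- rep(s$diam[1], 2)
    } else {
      ell <- seg_lengths(s$points)
      cuml <- c(0, cumsum(ell)); dprof <- s$diam
    }
    interp_d <- function(x) stats::approx(cuml, dprof, xout = x, rule = 2)$y

    cmf <- if (s$type == "myelin") pas$cm * pas$myelin_cm_factor else pas$cm
    parent_sec <- s$parent
    for (k in seq_len(nseg)) {
      a <- (k - 1) * L / nseg; b <- k * L / nseg
      xs <- seq(a, b, length.out = 9)
      ds <- interp_d(xs)
      dl <- diff(xs)
      dmid <- (ds[-1] + ds[-length(ds)]) / 2
      area <- if (single) pi * s$diam[1]^2 else sum(pi * dmid * dl)
      raxial <- sum(4e4 * pas$Ra * dl / (pi * dmid^2))  # Ohm
      idx <- idx + 1L
      p <- if (k > 1) idx - 1L
           else if (is.na(parent_sec)) 0L
           else last_seg_of_sec[[as.character(parent_sec)]]
      parent_of[idx] <- p - 1L   # 0-based; root gets -1
      d0 <- if (s$type == "soma") 0 else sdist$start[[as.character(s$id)]]
      seg_rows[[idx]] <- tibble(
        idx = idx, section_id = s$id, type = s$type,
        length_um = L / nseg, diam_um = mean(ds), area_um2 = area,
        raxial_ohm = raxial, cap_nF = cmf * area * 1e-5,
        path_mid_um = if (s$type == "soma") 0 else d0 + (a + b) / 2,
        pos_mid = (a + b) / 2 / L)
    }
    last_seg_of_sec[[as.character(s$id)]] <- idx
  }

  seg <- dplyr::bind_rows(seg_rows)
  # coupling conductance to parent: series of the two half-segment resistances
  gax <- numeric(nrow(seg))
  for (j in seq_len(nrow(seg))) {
    p <- parent_of[j] + 1L
    if (p <= 0) { gax[j] <- 0; next }
    gax[j] <- 1e6 / (seg$raxial_ohm[j] / 2 + seg$raxial_ohm[p] / 2)  # uS
  }
  list(sys = list(parent = as.integer(parent_of), cap_nF = seg$cap_nF,
                  g_axial_uS = gax),
       seg = seg)
}

ensure_geometry <- function(cell, max_seg_length = 20) {
  if (is.null(cell$geometry))
    cell$geometry <- build_compartments(cell, max_seg_length)
  cell
}

resolve_location <- function(geom, location) {
  seg <- geom$seg
  sid <- location$section
  if (is.character(sid)) {
    cand <- seg$section_id[seg$type == sid]
    if (!length(cand)) abort(sprintf("no section of type '%s'", sid))
    sid <- cand[1]
  }
  rows <- which(seg$section_id == sid)
  if (!length(rows)) abort(sprintf("no section with id %s", sid))
  rows[pmin(length(rows), pmax(1L, ceiling(location$pos * length(rows))))]
}

# assemble the per-mechanism arrays consumed by the C++ core
compile_mechanisms <- function(cell, geom) {
  seg <- geom$seg
  pvals <- stats::setNames(cell$parameters$value, cell$parameters$name)
  mechs <- list()
  # passive leak everywhere; myelinated sections get both capacitance and
  # leak scaled down by the myelin factor
  gfac <- ifelse(seg$type == "myelin", cell$passive$myelin_cm_factor, 1)
  mechs[[1]] <- list(name = "pas", segs = as.integer(seg$idx - 1L),
                     gbar_uS = cell$passive$g_pas * gfac * seg$area_um2 * 0.01,
                     erev = cell$passive$e_pas, nernst = FALSE, is_ca = FALSE,
                     gamma_uS = 0, gates = list())
  for (ch in cell$mechanisms) {
    if (!inherits(ch, "emf_channel")) next
    rows <- which(seg$type %in% ch$regions)
    if (!length(rows)) next
    gbar <- pvals[[ch$gbar_param]]
    mechs[[length(mechs) + 1]] <- list(
      name = ch$name, segs = as.integer(seg$idx[rows] - 1L),
      gbar_uS = gbar * seg$area_um2[rows] * 0.01,
      erev = ch$reversal, nernst = isTRUE(ch$nernst),
      is_ca = identical(ch$ion, "ca"),
      gamma_uS = ch$gamma_pS * 1e-6,
      gates = lapply(ch$gates, function(g) g[c("exponent", "ca_dep", "vhalf",
                                               "slope", "tau_base", "tau_amp",
                                               "tau_center", "tau_width",
                                               "ca_half", "hill", "tau_ca")]))
  }
  cadyn <- NULL
  for (mech in cell$mechanisms) {
    if (!inherits(mech, "emf_ca_dynamics")) next
    tau <- if ("decay_tau_ca" %in% names(pvals)) pvals[["decay_tau_ca"]] else mech$decay_tau
    rows <- which(seg$type %in% mech$regions)
    cadyn <- list(segs = as.integer(seg$idx[rows] - 1L),
                  tau = rep(tau, length(rows)),
                  vol_um3 = seg$area_um2[rows] * mech$depth,
                  ca_min = rep(mech$ca_min, length(rows)))
  }
  list(mechs = mechs, ca_dyn = cadyn)
}

stim_primitives <- function(s, geom) {
  sg <- resolve_location(geom, s$location) - 1L
  switch(s$kind,
    step = list(list(seg = sg, kind = 0L, amp = s$amplitude,
                     onset = s$onset, offset = s$offset)),
    ramp = list(list(seg = sg, kind = 1L, amp = s$amplitude,
                     onset = s$onset, offset = s$offset)),
    holding = list(list(seg = sg, kind = 2L, amp = s$amplitude,
                        onset = 0, offset = Inf)),
    paired_pulses = list(
      list(seg = sg, kind = 0L, amp = s$amplitude, onset = s$onset,
           offset = s$onset + s$width),
      list(seg = sg, kind = 0L, amp = s$amplitude,
           onset = s$onset + s$width + s$gap,
           offset = s$onset + 2 * s$width + s$gap)),
    hyperpol_then_depol = list(
      list(seg = sg, kind = 0L, amp = s$amp_hyp, onset = s$onset,
           offset = s$onset + s$dur_hyp),
      list(seg = sg, kind = 0L, amp = s$amplitude, onset = s$onset + s$dur_hyp,
           offset = s$onset + s$dur_hyp + s$dur_dep)))
}

REC_KIND_CODES <- c(voltage = 0L, calcium = 1L, mech_currents = 2L,
                    capacitive = 3L, axial = 4L, injected = 5L)

new_trace <- function(times, values, kind, location = "soma",
                      protocol = "custom", stim_onset = NA_real_,
                      stim_offset = NA_real_, stim_amp = NA_real_,
                      mech_names = NULL, phases = NULL) {
  structure(list(times = times, values = values, kind = kind,
                 location = location, protocol = protocol,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 stim_amp = stim_amp, mech_names = mech_names,
                 phases = phases),
            class = "emf_trace")
}

# measurement-window routing: some protocols measure different features on
# different phases (e.g. IDHyperpol sag on the hyperpolarizing step, firing
# on the depolarizing step). A trace may carry named phases, each c(onset,
# offset, amplitude); routing a feature to a phase re-stamps the stimulus
# metadata the registry definitions read.
apply_route <- function(tr, win) {
  if (is.null(win) || identical(win, "stim")) return(tr)
  ph <- tr$phases[[win]]
  if (is.null(ph)) return(tr)
  tr$stim_onset <- ph[1]; tr$stim_offset <- ph[2]; tr$stim_amp <- ph[3]
  tr
}

#' @export
print.emf_trace <- function(x, ...) {
  cat(sprintf("<trace %s@%s [%s]: %d samples, stim %g nA [%g, %g] ms>\n",
              x$kind, x$location, x$protocol, length(x$times), x$stim_amp,
              x$stim_onset, x$stim_offset))
  invisible(x)
}

#' @export
as_tibble.emf_trace <- function(x, ...) {
  if (is.matrix(x$values)) {
    colnames(x$values) <- x$mech_names
    dplyr::bind_cols(tibble(time_ms = x$times), as_tibble(x$values))
  } else tibble(time_ms = x$times, value = x$values)
}

#' Simulate a cell model
#'
#' Runs the backward-Euler cable solver on the discretized cell under a set
#' of stimuli and returns the requested traces. All stimulus amplitudes are
#' absolute (nA). Deterministic for a given `seed`; stochastic channels
#' consume the seed only in `"stochastic"` mode. An unstable parameter set
#' (any |V| > 1000 mV) marks the result as diverged rather than erroring, so
#' the optimizer can rank it.
#'
#' @param cell a cell model
#' @param stimuli list of [stimulus()] objects
#' @param recordings list of [recording()] entries
#' @param duration simulation length, ms
#' @param dt time step, ms (default 0.025)
#' @param seed integer RNG seed
#' @param mode `"deterministic"` or `"stochastic"` gating of stochastic
#'   channels
#' @param rec_every record every n-th step
#' @param v_init initial voltage, mV (defaults to `e_pas`)
#' @param protocol protocol label stamped on the traces
#' @return list of `emf_trace` objects, with attribute `diverged`
#' @export
simulate <- function(cell, stimuli = list(), recordings = list(recording()),
                     duration = 500, dt = 0.025, seed = 1L,
                     mode = c("deterministic", "stochastic"), rec_every = 1L,
                     v_init = NULL, protocol = "custom",
                     stop_when_v_above = NULL, stop_window = c(0, Inf)) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, duration > 0)
  cell <- ensure_geometry(cell)
  geom <- cell$geometry
  cm <- compile_mechanisms(cell, geom)
  prims <- unlist(lapply(stimuli, stim_primitives, geom = geom),
                  recursive = FALSE)
  if (is.null(prims)) prims <- list()
  for (i in seq_along(prims))
    if (!is.finite(prims[[i]]$offset)) prims[[i]]$offset <- duration
  recs <- lapply(recordings, function(r) {
    list(seg = resolve_location(geom, r$location) - 1L,
         kind = REC_KIND_CODES[[r$kind]])
  })
  if (is.null(v_init)) v_init <- cell$passive$e_pas

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  res <- .sim_run(cm_sys(geom), cm$mechs, cm$ca_dyn, prims, list(), recs,
                  dt, duration, as.integer(rec_every), v_init,
                  identical(mode, "stochastic"), 5e-5,
                  stop_when_v_above %||% NA_real_, stop_window[1],
                  min(stop_window[2], duration + 1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  if (isTRUE(res$stopped_spike)) {
    out <- list()
    attr(out, "diverged") <- FALSE
    attr(out, "stopped_spike") <- TRUE
    return(out)
  }

  meta <- principal_stim(stimuli, duration)
  out <- purrr::imap(recordings, function(r, i) {
    new_trace(res$times, res$traces[[i]],
              kind = if (r$kind == "mech_currents") "current" else
                     if (r$kind == "calcium") "calcium" else
                     if (r$kind == "voltage") "voltage" else "current",
              location = location_label(r$location),
              protocol = protocol, stim_onset = meta$onset,
              stim_offset = meta$offset, stim_amp = meta$amp,
              mech_names = if (r$kind == "mech_currents") res$mech_names)
  })
  attr(out, "diverged") <- res$diverged
  out
}

cm_sys <- function(geom) geom$sys

location_label <- function(location) {
  if (is.character(location$section)) location$section
  else sprintf("sec%d", location$section)
}

# the stimulus whose window stamps the trace metadata: the first
# non-holding stimulus, else a zero-amplitude window covering the tail
principal_stim <- function(stimuli, duration) {
  for (s in stimuli) {
    if (s$kind == "holding") next
    if (s$kind == "hyperpol_then_depol")
      return(list(onset = s$onset, offset = s$onset + s$dur_hyp + s$dur_dep,
                  amp = s$amplitude))
    if (s$kind == "paired_pulses")
      return(list(onset = s$onset, offset = s$onset + 2 * s$width + s$gap,
                  amp = s$amplitude))
    return(list(onset = s$onset, offset = s$offset, amp = s$amplitude))
  }
  list(onset = 0.9 * duration, offset = duration, amp = 0)
}

#' Simulate an excitatory postsynaptic potential
#'
#' Activates a double-exponential synaptic conductance once and records the
#' voltage at the synapse, the soma and any extra locations.
#'
#' @param cell a cell model
#' @param synapse a [synapse_spec()]
#' @param record_at extra [loc()]s to record from
#' @param onset synapse activation time, ms
#' @param duration,dt,seed,mode as in [simulate()]
#' @param holding optional holding current, nA
#' @return list of voltage traces (synapse first, then soma, then extras)
#' @export
simulate_epsp <- function(cell, synapse, record_at = list(), onset = 100,
                          duration = 300, dt = 0.025, seed = 1L,
                          mode = "deterministic", holding = 0,
                          record_current = FALSE) {
  cell <- ensure_geometry(cell)
  geom <- cell$geometry
  cm <- compile_mechanisms(cell, geom)
  syn <- list(list(seg = resolve_location(geom, synapse$location) - 1L,
                   gmax_uS = synapse$g_max * 1e-3,
                   tau_rise = synapse$tau_rise, tau_decay = synapse$tau_decay,
                   onset = onset, erev = synapse$reversal,
                   nmda_frac = synapse$nmda_fraction, mg = synapse$mg))
  locs <- c(list(synapse$location, loc("soma", 0.5)), record_at)
  recs <- lapply(locs, function(l) list(seg = resolve_location(geom, l) - 1L,
                                        kind = 0L))
  if (record_current)
    recs <- c(recs, list(list(seg = syn[[1]]$seg, kind = 1L + 1L)))
  stims <- if (holding != 0)
    list(list(seg = resolve_location(geom, loc("soma", 0.5)) - 1L, kind = 2L,
              amp = holding, onset = 0, offset = duration)) else list()
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  res <- .sim_run(cm_sys(geom), cm$mechs, cm$ca_dyn, stims, syn, recs,
                  dt, duration, 1L, cell$passive$e_pas,
                  identical(mode, "stochastic"), 5e-5, NA_real_, 0, 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out <- purrr::imap(locs, function(l, i)
    new_trace(res$times, res$traces[[i]], "voltage", location_label(l),
              protocol = "EPSP", stim_onset = onset, stim_offset = duration,
              stim_amp = 0))
  if (record_current) {
    cur <- res$traces[[length(recs)]]
    out$syn_current <- cur[, ncol(cur)]   # the synapse column
  }
  attr(out, "diverged") <- res$diverged
  out
}
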