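# Four-step e-model evaluation: RMP -> Rin -> holding/threshold current
# searches -> rheobase-rescaled protocols, scored as Z scores against
# extracted feature targets.

#' Z score of a model feature against a target
#'
#' `|model_value - mean| / sd`, the per-feature optimization objective.
#' Invalid model features (NA) map to the clipped maximum so the optimizer
#' can rank failed models.
#'
#' @param model_value model feature value (NA if invalid)
#' @param mean,sd experimental mean and standard deviation (sd > 0)
#' @param clip maximum score (default 250)
#' @export
z_score <- function(model_value, mean, sd, clip = 250) {
  stopifnot(sd > 0)
  if (is.na(model_value)) return(clip)
  min(abs(model_value - mean) / sd, clip)
}

#' Resting membrane potential of a model
#'
#' Mean somatic voltage over the final 10% of a zero-stimulus simulation.
#'
#' @param cell a cell model
#' @param duration simulation length, ms
#' @param dt time step, ms
#' @return RMP in mV (NA if the model diverges)
#' @export
compute_rmp <- function(cell, duration = 500, dt = 0.025) {
  tr <- simulate(cell, list(), list(recording(loc("soma"), "voltage")),
                 duration = duration, dt = dt, rec_every = 8L,
                 protocol = "RMP")
  if (attr(tr, "diverged")) return(NA_real_)
  v <- tr[[1]]$values; t <- tr[[1]]$times
  mean(v[t >= 0.9 * duration])
}

steady_voltage <- function(cell, current, settle = 600, dt = 0.025) {
  tr <- simulate(cell, list(stimulus("holding", amplitude = current)),
                 list(recording(loc("soma"), "voltage")),
                 duration = settle, dt = dt, rec_every = 8L,
                 protocol = "holding")
  if (attr(tr, "diverged")) return(NA_real_)
  v <- tr[[1]]$values; t <- tr[[1]]$times
  mean(v[t >= 0.9 * settle])
}

#' Bisection search for the holding current
#'
#' Finds the constant current that brings the somatic steady-state voltage
#' within `tol` of `target_potential`, by bisection over `bounds` (at most
#' `max_iter` iterations). Errors if the bounds do not bracket the target.
#'
#' @param cell a cell model
#' @param target_potential target holding potential, mV
#' @param bounds search interval, nA
#' @param tol voltage tolerance, mV
#' @param max_iter iteration cap
#' @param settle settling time per probe, ms
#' @return holding current, nA
#' @export
search_holding_current <- function(cell, target_potential = -70,
                                   bounds = c(-0.5, 0.5), tol = 0.1,
                                   max_iter = 30, settle = 400) {
  cell <- ensure_geometry(cell)
  v_lo <- steady_voltage(cell, bounds[1], settle)
  v_hi <- steady_voltage(cell, bounds[2], settle)
  if (is.na(v_lo) || is.na(v_hi)) abort("model diverges at holding bounds")
  if (!(v_lo < target_potential && target_potential < v_hi))
    abort(sprintf("holding bounds do not bracket target: V(%g)=%.2f, V(%g)=%.2f",
                  bounds[1], v_lo, bounds[2], v_hi))
  lo <- bounds[1]; hi <- bounds[2]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- steady_voltage(cell, mid, settle)
    if (is.na(v)) abort("model diverged during holding search")
    if (abs(v - target_potential) <= tol) return(mid)
    if (v < target_potential) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

spikes_at <- function(cell, step_amp, holding, pre, dur, dt, threshold = -30,
                      fast = TRUE) {
  tr <- simulate(cell,
                 list(stimulus("holding", amplitude = holding),
                      stimulus("step", amplitude = step_amp, onset = pre,
                               offset = pre + dur)),
                 list(recording(loc("soma"), "voltage")),
                 duration = pre + dur + 50, dt = dt, rec_every = 2L,
                 protocol = "Threshold",
                 stop_when_v_above = if (fast) 0 else NULL,
                 stop_window = c(pre, pre + dur + 2))
  if (isTRUE(attr(tr, "stopped_spike"))) return(1L)
  if (attr(tr, "diverged")) return(NA_integer_)
  nrow(detect_spikes(tr[[1]], threshold))
}

#' Bisection search for the threshold (rheobase) current
#'
#' Bisects the "at least one spike during a 2 s step" predicate on top of the
#' holding current until the bracket is narrower than `precision`, returning
#' the spiking upper end. Errors with "subthreshold model" if even the upper
#' bound never spikes.
#'
#' @param cell a cell model
#' @param holding holding current, nA
#' @param bounds step-amplitude search interval, nA
#' @param precision bracket width at convergence, nA
#' @param dur step duration, ms (default 2000)
#' @param pre delay before the step, ms
#' @param dt time step, ms
#' @param max_iter iteration cap
#' @return threshold step current (above holding), nA
#' @export
search_threshold_current <- function(cell, holding = 0, bounds = c(0, 0.6),
                                     precision = 0.001, dur = 2000, pre = 100,
                                     dt = 0.025, max_iter = 30) {
  cell <- ensure_geometry(cell)
  n_hi <- spikes_at(cell, bounds[2], holding, pre, dur, dt)
  if (is.na(n_hi) || n_hi < 1) abort("subthreshold model: upper bound never spikes")
  lo <- bounds[1]; hi <- bounds[2]
  for (i in seq_len(max_iter)) {
    if (hi - lo <= precision) break
    mid <- (lo + hi) / 2
    n <- spikes_at(cell, mid, holding, pre, dur, dt)
    if (is.na(n)) abort("model diverged during threshold search")
    if (n >= 1) hi <- mid else lo <- mid
  }
  hi
}

# ---- protocol suites -------------------------------------------------------

proto_row <- function(protocol, target_pct, features, stim_kind = "step",
                      pre = 250, dur = 2000, post = 250, dt = 0.025,
                      rec_every = 4L, amp_fixed = NA_real_,
                      hyper_pct = NA_real_, route = list()) {
  tibble(protocol = protocol, target_pct = target_pct,
         features = list(features), stim_kind = stim_kind, pre = pre,
         dur = dur, post = post, dt = dt, rec_every = as.integer(rec_every),
         amp_fixed = amp_fixed, hyper_pct = hyper_pct, route = list(route))
}

#' Default optimization protocol suite
#'
#' Mirrors the canonical pyramidal-type optimization set: RMP (no stimulus)
#' and Rin (small negative step) special protocols, holding and threshold
#' current searches, depolarizing IDrest steps at relative amplitudes, a
#' short high-rate APWaveform step and a hyperpolarizing IV step.
#'
#' @param idrest_pcts IDrest step amplitudes, % of rheobase
#' @param apwaveform_pct APWaveform amplitude, % of rheobase
#' @param iv_pct hyperpolarizing IV amplitude, % of rheobase (negative)
#' @param rin_amp fixed Rin stimulus, nA
#' @return a protocol-suite tibble
#' @export
default_protocol_suite <- function(idrest_pcts = c(150, 200, 250),
                                   apwaveform_pct = 300, iv_pct = -100,
                                   rin_amp = -0.04) {
  idrest_feats <- c("voltage_base", "voltage_after_stim", "AP_amplitude",
                    "APlast_amp", "AHP_depth", "inv_time_to_first_spike",
                    "time_to_last_spike", "inv_first_ISI", "inv_second_ISI",
                    "inv_last_ISI", "mean_frequency")
  dplyr::bind_rows(
    proto_row("RMP", NA, c("voltage_base", "Spikecount"), stim_kind = "RMP",
              pre = 0, dur = 500, post = 0, rec_every = 8L),
    proto_row("Rin", NA, c("ohmic_input_resistance_vb_ssse", "voltage_base"),
              stim_kind = "step", pre = 300, dur = 3000, post = 0,
              rec_every = 8L, amp_fixed = rin_amp),
    proto_row("RinHoldCurrent", NA, "bpo_holding_current", stim_kind = "search"),
    proto_row("Threshold", NA, "bpo_threshold_current", stim_kind = "search"),
    purrr::map_dfr(idrest_pcts, function(p)
      proto_row("IDrest", p, idrest_feats, dur = 2000)),
    proto_row("APWaveform", apwaveform_pct,
              c("AP_amplitude", "AP1_amp", "AP_duration_half_width",
                "maximum_voltage_from_voltagebase"),
              pre = 100, dur = 50, post = 100, dt = 0.02, rec_every = 1L),
    proto_row("IV", iv_pct,
              c("voltage_deflection", "voltage_deflection_begin",
                "sag_amplitude"),
              pre = 300, dur = 3000, post = 0, rec_every = 8L))
}

#' Compact protocol suite for parameter-recovery studies
#'
#' A reduced objective set designed so each fixture conductance has a
#' distinct signature: spike height and peak voltage (transient Na), AP
#' width and afterhyperpolarization (delayed-rectifier K), adaptation and
#' firing rate across two step amplitudes (slow K), sag, input resistance
#' and resting potential (Ih). Keeping the objective count small sharpens
#' indicator-based selection at desk-scale population sizes.
#'
#' @param idrest_pcts IDrest step amplitudes, % of rheobase
#' @export
recovery_protocol_suite <- function(idrest_pcts = c(150, 250)) {
  suite <- default_protocol_suite(idrest_pcts = idrest_pcts)
  idr <- which(suite$protocol == "IDrest")
  for (k in idr)
    suite$features[[k]] <- c("voltage_base", "voltage_after_stim",
                             "AP_amplitude", "AHP_depth", "inv_first_ISI",
                             "inv_last_ISI", "mean_frequency")
  suite
}

#' Held-out validation protocol suite
#'
#' Ramp, sAHP and IDHyperpol protocols with feature routing: sag features of
#' the sAHP protocol are measured on the afterhyperpolarization following the
#' short depolarizing step, and IDHyperpol sag features on the
#' hyperpolarizing phase while firing features use the depolarizing phase.
#'
#' @param ramp_pct ramp peak amplitude, % of rheobase
#' @param sahp_pcts sAHP step amplitudes, % of rheobase
#' @param idhyperpol_pct IDHyperpol depolarizing amplitude, % of rheobase
#' @param idhyperpol_hyper_pct hyperpolarizing phase amplitude, % of rheobase
#' @export
validation_protocol_suite <- function(ramp_pct = 150, sahp_pcts = c(150, 350),
                                      idhyperpol_pct = 250,
                                      idhyperpol_hyper_pct = -40) {
  sahp_feats <- c("Spikecount", "AP_amplitude", "inv_time_to_first_spike",
                  "AHP_depth_abs", "sag_ratio",
                  "decay_time_constant_after_stim",
                  "steady_state_voltage_stimend", "minimum_voltage",
                  "steady_state_voltage")
  sahp_route <- list(sag_ratio = "post", sag_amplitude = "post")
  idh_feats <- c("Spikecount", "AP_amplitude", "ISI_values", "ISI_log_slope",
                 "sag_amplitude", "sag_ratio", "minimum_voltage",
                 "steady_state_voltage_stimend")
  idh_route <- list(sag_amplitude = "hyper", sag_ratio = "hyper",
                    minimum_voltage = "hyper",
                    steady_state_voltage_stimend = "hyper")
  dplyr::bind_rows(
    proto_row("Ramp", ramp_pct,
              c("Spikecount", "AP_amplitude", "inv_first_ISI", "AP1_amp",
                "APlast_amp"),
              stim_kind = "ramp", pre = 250, dur = 2000, post = 250),
    purrr::map_dfr(sahp_pcts, function(p)
      proto_row("sAHP", p, sahp_feats, pre = 250, dur = 250, post = 2000,
                route = sahp_route)),
    proto_row("IDHyperpol", idhyperpol_pct, idh_feats,
              stim_kind = "hyperpol_then_depol", pre = 250, dur = 1000,
              post = 750, hyper_pct = idhyperpol_hyper_pct,
              route = idh_route))
}

# simulate one suite row and measure its features, honoring window routing
run_protocol <- function(cell, proto, holding, rheobase, seed = 1L,
                         mode = "deterministic", threshold = -30) {
  amp <- if (!is.na(proto$amp_fixed)) proto$amp_fixed
         else proto$target_pct / 100 * rheobase
  feats <- proto$features[[1]]
  needs_ca <- any(grepl("^maximum_ca", feats))
  recs <- c(list(recording(loc("soma"), "voltage")),
            if (needs_ca) list(recording(loc("soma"), "calcium")))

  if (proto$stim_kind == "RMP") {
    stims <- if (holding != 0) list(stimulus("holding", amplitude = holding)) else list()
    total <- proto$dur
  } else if (proto$stim_kind == "hyperpol_then_depol") {
    dur_h <- proto$dur; dur_d <- proto$dur
    stims <- list(
      if (holding != 0) stimulus("holding", amplitude = holding),
      stimulus("hyperpol_then_depol", amplitude = amp, onset = proto$pre,
               amp_hyp = proto$hyper_pct / 100 * rheobase, dur_hyp = dur_h,
               dur_dep = dur_d))
    total <- proto$pre + dur_h + dur_d + proto$post
  } else {
    kind <- if (proto$stim_kind == "ramp") "ramp" else "step"
    stims <- list(
      if (holding != 0) stimulus("holding", amplitude = holding),
      stimulus(kind, amplitude = amp, onset = proto$pre,
               offset = proto$pre + proto$dur))
    total <- proto$pre + proto$dur + proto$post
  }
  stims <- Filter(Negate(is.null), stims)
  trs <- simulate(cell, stims, recs, duration = total, dt = proto$dt,
                  seed = seed, mode = mode, rec_every = proto$rec_every,
                  protocol = proto$protocol)
  if (attr(trs, "diverged"))
    return(list(values = tibble(feature = feats, value = NA_real_,
                                valid = FALSE, reason = "diverged"),
                traces = trs))
  trs <- purrr::map(trs, stamp_phases, proto = proto, amp = amp,
                    rheobase = rheobase)
  vt <- trs[[1]]
  route <- proto$route[[1]]

  spikes_vt <- if (vt$kind == "voltage") detect_spikes(vt, threshold)
  value <- numeric(length(feats)); valid <- logical(length(feats))
  reason <- character(length(feats))
  for (k in seq_along(feats)) {
    f <- feats[k]
    tr <- if (grepl("^maximum_ca", f)) trs[[2]] else vt
    win <- route[[f]] %||% "stim"
    tr <- apply_route(tr, win)
    sp <- if (identical(win, "stim") && !grepl("^maximum_ca", f) &&
              !inherits(tr, "try-error")) spikes_vt else NULL
    fv <- compute_feature(tr, f, spikes = sp, threshold = threshold)
    value[k] <- fv$value; valid[k] <- fv$valid; reason[k] <- fv$reason
  }
  list(values = tibble(feature = feats, value = value, valid = valid,
                       reason = reason),
       traces = trs)
}

# stamp phase windows on a protocol trace; for hyperpol-then-depol protocols
# the principal stimulus metadata is narrowed to the depolarizing phase so
# unrouted (firing) features are measured there
stamp_phases <- function(tr, proto, amp, rheobase) {
  if (proto$stim_kind == "hyperpol_then_depol") {
    tr$phases <- list(
      hyper = c(proto$pre, proto$pre + proto$dur,
                proto$hyper_pct / 100 * rheobase),
      depol = c(proto$pre + proto$dur, proto$pre + 2 * proto$dur, amp))
    tr$stim_onset <- proto$pre + proto$dur
    tr$stim_offset <- proto$pre + 2 * proto$dur
    tr$stim_amp <- amp
  } else if (proto$protocol == "sAHP") {
    off <- proto$pre + proto$dur
    tr$phases <- list(post = c(off, min(off + 1500, max(tr$times)), 0))
  }
  tr
}

find_target <- function(targets, protocol, pct, feature) {
  hit <- targets$protocol == protocol & targets$feature == feature &
    (is.na(pct) | (!is.na(targets$target_pct) & targets$target_pct == pct))
  if (!any(hit)) return(NULL)
  targets[which(hit)[1], ]
}

#' Evaluate an e-model against feature targets
#'
#' The four-step evaluation: (1) resting membrane potential with no
#' stimulus, (2) input resistance from a small negative step, with an early
#' stop if either deviates by more than `early_stop_sd` standard deviations
#' (all remaining targets then receive the clipped maximum score); (3)
#' bisection searches for the holding current (to the target holding
#' potential) and the threshold current; (4) all relative protocols rescaled
#' by the found rheobase, simulated and scored per Eq. (Z score). Failures
#' never raise: they surface as clipped scores so an optimizer can rank them.
#'
#' @param cell a cell model
#' @param suite a protocol-suite tibble ([default_protocol_suite()])
#' @param targets an extraction result (must have `sd_eff > 0`)
#' @param holding_target target holding potential, mV; defaults to the RMP
#'   voltage_base target mean when present, else -70
#' @param early_stop_sd RMP/Rin early-stop limit, in SD units (default 3)
#' @param clip maximum per-feature score
#' @param seed RNG seed (stochastic channels)
#' @param mode gating mode for stochastic channels during evaluation
#' @param threshold_bounds,holding_bounds search intervals, nA
#' @param threshold spike detection threshold, mV
#' @param threshold_precision,holding_tol search resolutions used during
#'   scoring (finer than the stand-alone search defaults: the searched
#'   rheobase rescales every protocol, so its quantization propagates into
#'   all downstream features)
#' @return an `emf_score_report`: per-target score table, total cost,
#'   early-stop flag, searched holding and threshold currents
#' @export
evaluate_emodel <- function(cell, suite, targets, holding_target = NULL,
                            early_stop_sd = 3, clip = 250, seed = 1L,
                            mode = "deterministic",
                            threshold_bounds = c(0, 0.6),
                            holding_bounds = c(-0.5, 0.5), threshold = -30,
                            threshold_precision = 2.5e-4,
                            holding_tol = 0.025) {
  cell <- ensure_geometry(cell)
  scores <- list()
  add_score <- function(protocol, pct, feature, value, score) {
    scores[[length(scores) + 1]] <<- tibble(
      protocol = protocol, target_pct = pct, feature = feature,
      model_value = value, score = score)
  }
  score_row <- function(tg, value) {
    if (is.null(tg)) return(NULL)
    add_score(tg$protocol, tg$target_pct, tg$feature,
              value, z_score(value, tg$mean, tg$sd_eff, clip))
  }

  special <- c("RMP", "Rin", "RinHoldCurrent", "Threshold")
  rest <- suite[!suite$protocol %in% special, ]
  early_stop <- FALSE; subthreshold <- FALSE
  holding <- NA_real_; thresh_cur <- NA_real_

  # steps 1-2: RMP and Rin
  for (pname in c("RMP", "Rin")) {
    proto <- suite[suite$protocol == pname, ]
    if (!nrow(proto)) next
    res <- run_protocol(cell, proto[1, ], holding = 0, rheobase = NA,
                        seed = seed, mode = mode, threshold = threshold)
    for (i in seq_len(nrow(res$values))) {
      f <- res$values[i, ]
      tg <- find_target(targets, pname, NA, f$feature)
      score_row(tg, if (f$valid) f$value else NA_real_)
    }
  }
  early <- dplyr::bind_rows(scores)
  if (nrow(early) && any(early$score > early_stop_sd)) early_stop <- TRUE

  if (!early_stop) {
    if (is.null(holding_target)) {
      tg <- find_target(targets, "RMP", NA, "voltage_base")
      holding_target <- if (!is.null(tg)) tg$mean else -70
    }
    holding <- tryCatch(
      search_holding_current(cell, holding_target, holding_bounds,
                             tol = holding_tol),
      error = function(e) NA_real_)
    if (is.na(holding)) early_stop <- TRUE
  }
  if (!early_stop) {
    thresh_cur <- tryCatch(
      search_threshold_current(cell, holding, threshold_bounds,
                               precision = threshold_precision, pre = 250),
      error = function(e) NA_real_)
    if (is.na(thresh_cur)) subthreshold <- TRUE
  }
  tg <- find_target(targets, "RinHoldCurrent", NA, "bpo_holding_current")
  if (!is.null(tg)) score_row(tg, if (early_stop) NA_real_ else holding)
  tg <- find_target(targets, "Threshold", NA, "bpo_threshold_current")
  if (!is.null(tg)) score_row(tg, if (early_stop || subthreshold) NA_real_ else thresh_cur)

  # step 4: relative protocols
  for (ri in seq_len(nrow(rest))) {
    proto <- rest[ri, ]
    feats <- proto$features[[1]]
    if (early_stop || subthreshold) {
      for (f in feats) {
        tg <- find_target(targets, proto$protocol, proto$target_pct, f)
        if (!is.null(tg)) add_score(tg$protocol, tg$target_pct, f, NA_real_, clip)
      }
      next
    }
    res <- run_protocol(cell, proto, holding = holding, rheobase = thresh_cur,
                        seed = seed, mode = mode, threshold = threshold)
    for (i in seq_len(nrow(res$values))) {
      f <- res$values[i, ]
      tg <- find_target(targets, proto$protocol, proto$target_pct, f$feature)
      score_row(tg, if (f$valid) f$value else NA_real_)
    }
  }

  tab <- dplyr::bind_rows(scores)
  structure(list(scores = tab, total = sum(tab$score),
                 early_stop = early_stop, subthreshold = subthreshold,
                 holding_current = holding, threshold_current = thresh_cur,
                 clip = clip),
            class = "emf_score_report")
}

#' @export
print.emf_score_report <- function(x, ...) {
  cat(sprintf("<score report: %d features, total cost %.2f%s%s>\n",
              nrow(x$scores), x$total,
              if (x$early_stop) ", EARLY STOP" else "",
              if (x$subthreshold) ", SUBTHRESHOLD" else ""))
  invisible(x)
}

#' Tidy a score report into its per-feature table
#' @param x an `emf_score_report`
#' @param ... unused
#' @export
tidy.emf_score_report <- function(x, ...) x$scores

#' One-row summary of a score report
#' @param x an `emf_score_report`
#' @param ... unused
#' @export
glance.emf_score_report <- function(x, ...) {
  tibble(total_cost = x$total, n_features = nrow(x$scores),
         max_score = max(x$scores$score), early_stop = x$early_stop,
         subthreshold = x$subthreshold,
         holding_current_nA = x$holding_current,
         threshold_current_nA = x$threshold_current)
}

#' Export a score report as JSON
#' @param report an `emf_score_report`
#' @param path JSON path
#' @export
write_score_report_json <- function(report, path) {
  jsonlite::write_json(list(scores = as.data.frame(report$scores),
                            total = report$total,
                            early_stop = report$early_stop,
                            subthreshold = report$subthreshold,
                            holding_current = report$holding_current,
                            threshold_current = report$threshold_current),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
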