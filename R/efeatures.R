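# Electrophysiological feature extraction. Single source of truth for every
# feature name used by the optimization and validation protocol suites.
#
# Conventions pinned here (the registry is normative for this package):
# - voltage_base: mean V over the 100 ms before stimulus onset
# - voltage_after_stim: mean V over [offset+25, offset+75] ms
# - AP_amplitude: peak V minus V at the onset crossing sample
# - AHP_depth: voltage_base minus the per-spike AHP minimum
# - steady state windows use the last 10% of the stimulus
# - ISI_values is summarized as the mean ISI (ms)

#' Detect action potentials in a voltage trace
#'
#' One spike per upward crossing of `threshold` (default -30 mV) whose onset
#' falls inside the stimulus window; spikes outside the stimulus are ignored.
#' The peak is the maximum V between the crossing and the next downward
#' crossing; the AHP minimum is the minimum V between the peak and the next
#' onset (or the stimulus offset for the last spike).
#'
#' @param trace a voltage `emf_trace` with stimulus metadata
#' @param threshold detection threshold, mV
#' @return a tibble (class `emf_spike_train`): onset_time, onset_v,
#'   peak_time, peak_v, ahp_min (NA when no window exists)
#' @export
detect_spikes <- function(trace, threshold = -30) {
  t <- trace$times; v <- trace$values
  n <- length(v)
  up <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
  up <- up[t[up] >= trace$stim_onset & t[up] <= trace$stim_offset]
  if (!length(up)) {
    res <- tibble(onset_time = numeric(0), onset_v = numeric(0),
                  peak_time = numeric(0), peak_v = numeric(0),
                  ahp_min = numeric(0))
    return(structure(res, class = c("emf_spike_train", class(res))))
  }

  down_all <- which(v[-1] < threshold & v[-n] >= threshold) + 1L
  nk <- length(up)
  pk_i <- integer(nk); ahp <- numeric(nk)
  last_in_stim <- {
    off <- which(t <= trace$stim_offset)
    if (length(off)) max(off) else n
  }
  for (k in seq_len(nk)) {
    i <- up[k]
    dn <- down_all[down_all > i]
    j <- if (length(dn)) dn[1] else n
    pk_i[k] <- i - 1L + which.max(v[i:j])
    nxt <- if (k < nk) up[k + 1] else last_in_stim
    ahp[k] <- if (nxt > pk_i[k]) min(v[pk_i[k]:nxt]) else NA_real_
  }
  out <- tibble(onset_time = t[up], onset_v = v[up], peak_time = t[pk_i],
                peak_v = v[pk_i], ahp_min = ahp)
  structure(out, class = c("emf_spike_train", class(out)))
}

#' Feature registry
#'
#' @return tibble of all registered feature names with units and whether
#'   they require spikes
#' @export
feature_registry <- function() {
  reg <- tibble::tribble(
    ~name, ~units, ~needs_spikes,
    "Spikecount", "count", FALSE,
    "mean_frequency", "Hz", FALSE,
    "AP_amplitude", "mV", TRUE,
    "AP1_amp", "mV", TRUE,
    "AP2_amp", "mV", TRUE,
    "APlast_amp", "mV", TRUE,
    "AP_duration_half_width", "ms", TRUE,
    "AHP_depth", "mV", TRUE,
    "AHP_depth_abs", "mV", TRUE,
    "voltage_base", "mV", FALSE,
    "voltage_after_stim", "mV", FALSE,
    "voltage_deflection", "mV", FALSE,
    "voltage_deflection_begin", "mV", FALSE,
    "ohmic_input_resistance_vb_ssse", "MOhm", FALSE,
    "inv_time_to_first_spike", "1/s", TRUE,
    "time_to_last_spike", "ms", TRUE,
    "inv_first_ISI", "1/s", TRUE,
    "inv_second_ISI", "1/s", TRUE,
    "inv_third_ISI", "1/s", TRUE,
    "inv_fourth_ISI", "1/s", TRUE,
    "inv_fifth_ISI", "1/s", TRUE,
    "inv_last_ISI", "1/s", TRUE,
    "ISI_values", "ms", TRUE,
    "ISI_CV", "dimensionless", TRUE,
    "ISI_log_slope", "dimensionless", TRUE,
    "burst_number", "count", TRUE,
    "sag_amplitude", "mV", FALSE,
    "sag_ratio", "dimensionless", FALSE,
    "minimum_voltage", "mV", FALSE,
    "steady_state_voltage", "mV", FALSE,
    "steady_state_voltage_stimend", "mV", FALSE,
    "decay_time_constant_after_stim", "ms", FALSE,
    "maximum_voltage_from_voltagebase", "mV", FALSE,
    "maximum_ca", "mM", FALSE,
    "bpo_holding_current", "nA", FALSE,
    "bpo_threshold_current", "nA", FALSE)
  reg
}

#' Export the registry as JSON
#' @param path output path
#' @export
write_feature_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

invalid_feature <- function(name, reason)
  list(name = name, value = NA_real_, valid = FALSE, reason = reason)
valid_feature <- function(name, value) {
  if (!is.finite(value)) return(invalid_feature(name, "non-finite result"))
  list(name = name, value = value, valid = TRUE, reason = NA_character_)
}

window_mean <- function(t, v, a, b) {
  sel <- t >= a & t < b
  if (!any(sel)) return(NA_real_)
  mean(v[sel])
}

isi_vector <- function(spikes) diff(spikes$onset_time)

#' Compute a single e-feature from a trace
#'
#' @param trace an `emf_trace` (voltage, or calcium for the `maximum_ca`
#'   family) with stimulus metadata
#' @param name registered feature name; names starting with `maximum_ca` are
#'   all routed to the calcium peak feature
#' @param spikes optional precomputed [detect_spikes()] result
#' @param threshold spike detection threshold, mV
#' @return a list: name, value, valid, reason
#' @export
compute_feature <- function(trace, name, spikes = NULL, threshold = -30) {
  base_name <- if (grepl("^maximum_ca", name)) "maximum_ca" else name
  if (!base_name %in% feature_registry()$name)
    abort(sprintf("unknown feature '%s'", name))
  if (base_name %in% c("bpo_holding_current", "bpo_threshold_current"))
    return(invalid_feature(name, "search-based feature, not computed from a trace"))

  t <- trace$times; v <- trace$values
  on <- trace$stim_onset; off <- trace$stim_offset; amp <- trace$stim_amp
  if (anyNA(t)) return(invalid_feature(name, "diverged trace"))
  if (is.null(spikes) && trace$kind == "voltage")
    spikes <- detect_spikes(trace, threshold)
  nsp <- if (is.null(spikes)) 0L else nrow(spikes)

  vb <- function() window_mean(t, v, on - 100, on)
  ssse <- function() window_mean(t, v, off - 0.1 * (off - on), off)
  stim_sel <- t >= on & t <= off

  need <- function(k, what = "spikes") {
    if (nsp < k) invalid_feature(name, sprintf("requires >= %d %s, found %d",
                                               k, what, nsp)) else NULL
  }
  isis <- if (nsp >= 2) isi_vector(spikes) else numeric(0)
  inv_isi <- function(k) {
    chk <- need(k + 1); if (!is.null(chk)) return(chk)
    valid_feature(name, 1000 / isis[k])
  }

  switch(base_name,
    Spikecount = valid_feature(name, nsp),
    mean_frequency = valid_feature(name, nsp / ((off - on) / 1000)),
    AP_amplitude = {
      chk <- need(1); if (!is.null(chk)) chk
      else valid_feature(name, mean(spikes$peak_v - spikes$onset_v))
    },
    AP1_amp = { chk <- need(1); if (!is.null(chk)) chk
      else valid_feature(name, spikes$peak_v[1] - spikes$onset_v[1]) },
    AP2_amp = { chk <- need(2); if (!is.null(chk)) chk
      else valid_feature(name, spikes$peak_v[2] - spikes$onset_v[2]) },
    APlast_amp = { chk <- need(1); if (!is.null(chk)) chk
      else valid_feature(name, spikes$peak_v[nsp] - spikes$onset_v[nsp]) },
    AP_duration_half_width = {
      chk <- need(1); if (!is.null(chk)) chk
      else {
        w <- vapply(seq_len(nsp), function(k) {
          half <- spikes$onset_v[k] + (spikes$peak_v[k] - spikes$onset_v[k]) / 2
          i0 <- which(t == spikes$onset_time[k])[1]
          ip <- which(t == spikes$peak_time[k])[1]
          r1 <- i0 - 1L + which(v[i0:ip] >= half)[1]
          after <- which(v[(ip + 1):length(v)] < half)
          if (!length(after)) return(NA_real_)
          r2 <- ip + after[1]
          # linear interpolation at both crossings
          t1 <- if (r1 > 1 && v[r1] != v[r1 - 1])
            t[r1 - 1] + (half - v[r1 - 1]) / (v[r1] - v[r1 - 1]) * (t[r1] - t[r1 - 1])
          else t[r1]
          t2 <- if (v[r2] != v[r2 - 1])
            t[r2 - 1] + (half - v[r2 - 1]) / (v[r2] - v[r2 - 1]) * (t[r2] - t[r2 - 1])
          else t[r2]
          t2 - t1
        }, numeric(1))
        if (all(is.na(w))) invalid_feature(name, "no falling half-crossing")
        else valid_feature(name, mean(w, na.rm = TRUE))
      }
    },
    AHP_depth = {
      chk <- need(1); if (!is.null(chk)) chk
      else if (all(is.na(spikes$ahp_min))) invalid_feature(name, "no AHP window")
      else valid_feature(name, vb() - mean(spikes$ahp_min, na.rm = TRUE))
    },
    AHP_depth_abs = {
      chk <- need(1); if (!is.null(chk)) chk
      else if (all(is.na(spikes$ahp_min))) invalid_feature(name, "no AHP window")
      else valid_feature(name, mean(spikes$ahp_min, na.rm = TRUE))
    },
    voltage_base = valid_feature(name, vb()),
    voltage_after_stim = valid_feature(name, window_mean(t, v, off + 25, off + 75)),
    voltage_deflection = valid_feature(name, ssse() - vb()),
    voltage_deflection_begin = {
      L <- off - on
      valid_feature(name, window_mean(t, v, on + 0.05 * L, on + 0.15 * L) - vb())
    },
    ohmic_input_resistance_vb_ssse = {
      if (is.na(amp) || amp == 0) invalid_feature(name, "zero stimulus amplitude")
      else valid_feature(name, (ssse() - vb()) / amp)
    },
    inv_time_to_first_spike = {
      chk <- need(1); if (!is.null(chk)) chk
      else {
        lat <- spikes$onset_time[1] - on
        if (lat <= 0) invalid_feature(name, "non-positive latency")
        else valid_feature(name, 1000 / lat)
      }
    },
    time_to_last_spike = { chk <- need(1); if (!is.null(chk)) chk
      else valid_feature(name, spikes$onset_time[nsp] - on) },
    inv_first_ISI = inv_isi(1),
    inv_second_ISI = inv_isi(2),
    inv_third_ISI = inv_isi(3),
    inv_fourth_ISI = inv_isi(4),
    inv_fifth_ISI = inv_isi(5),
    inv_last_ISI = { chk <- need(2); if (!is.null(chk)) chk
      else valid_feature(name, 1000 / isis[length(isis)]) },
    ISI_values = { chk <- need(2); if (!is.null(chk)) chk
      else valid_feature(name, mean(isis)) },
    ISI_CV = { chk <- need(3); if (!is.null(chk)) chk
      else valid_feature(name, stats::sd(isis) / mean(isis)) },
    ISI_log_slope = {
      chk <- need(3); if (!is.null(chk)) chk
      else {
        k <- seq_along(isis); y <- log(isis)
        valid_feature(name, sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2))
      }
    },
    burst_number = {
      chk <- need(3); if (!is.null(chk)) chk
      else {
        thr <- 0.5 * stats::median(isis)
        r <- rle(isis < thr)
        valid_feature(name, sum(r$values))
      }
    },
    minimum_voltage = valid_feature(name, min(v[stim_sel])),
    steady_state_voltage = valid_feature(name, mean(v[stim_sel])),
    steady_state_voltage_stimend = valid_feature(name, ssse()),
    sag_amplitude = valid_feature(name, ssse() - min(v[stim_sel])),
    sag_ratio = {
      den <- vb() - min(v[stim_sel])
      if (!is.finite(den) || den <= 0) invalid_feature(name, "no hyperpolarizing deflection")
      else valid_feature(name, (ssse() - min(v[stim_sel])) / den)
    },
    maximum_voltage_from_voltagebase = valid_feature(name, max(v[stim_sel]) - vb()),
    maximum_ca = {
      if (trace$kind != "calcium") invalid_feature(name, "requires a calcium trace")
      else valid_feature(name, max(v[stim_sel]) - window_mean(t, v, on - 100, on))
    },
    decay_time_constant_after_stim = decay_tau_feature(name, t, v, off)
  )
}

# deterministic log-linear estimate of the relaxation time constant over
# [offset, offset + 100] ms: the steady level is the mean of the last 10 ms
# of the window; samples with |V - Vss| >= 1% of the initial deviation and
# at least 10 ms before the window end enter an OLS fit of log|V - Vss| vs t
decay_tau_feature <- function(name, t, v, off) {
  sel <- t >= off & t <= off + 100
  if (sum(sel) < 10) return(invalid_feature(name, "post-stimulus window too short"))
  tt <- t[sel]; vv <- v[sel]
  vss <- mean(vv[tt >= off + 90])
  y <- vv - vss
  if (abs(y[1]) < 1e-9) return(invalid_feature(name, "no deflection to relax"))
  use <- abs(y) >= 0.01 * abs(y[1]) & tt <= off + 90 & sign(y) == sign(y[1])
  if (sum(use) < 5) return(invalid_feature(name, "too few points for fit"))
  x <- tt[use]; ly <- log(abs(y[use]))
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sum((x - mean(x))^2)
  if (slope >= 0) return(invalid_feature(name, "non-decaying relaxation"))
  valid_feature(name, -1 / slope)
}

#' Compute several features at once
#'
#' @param trace an `emf_trace`
#' @param names character vector of registered feature names
#' @param threshold spike detection threshold, mV
#' @return tibble: name, value, valid, reason
#' @export
compute_features <- function(trace, names, threshold = -30) {
  spikes <- if (trace$kind == "voltage") detect_spikes(trace, threshold) else NULL
  purrr::map_dfr(names, function(nm)
    tibble::as_tibble(compute_feature(trace, nm, spikes, threshold)))
}
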