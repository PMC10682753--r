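# Independent brute-force oracles for the e-feature registry: plain loops
# re-deriving every definition directly from the raw samples. Kept free of
# any package internals so they can disagree with the implementation.

oracle_spikes <- function(t, v, on, off, thr = -30) {
  onsets <- integer(0)
  for (i in 2:length(v))
    if (v[i - 1] < thr && v[i] >= thr && t[i] >= on && t[i] <= off)
      onsets <- c(onsets, i)
  if (!length(onsets))
    return(list(n = 0L, onset_i = integer(0), peak_i = integer(0),
                ahp = numeric(0)))
  peak_i <- integer(length(onsets)); ahp <- numeric(length(onsets))
  last_in_stim <- 0L
  for (i in seq_along(t)) if (t[i] <= off) last_in_stim <- i
  if (last_in_stim == 0L) last_in_stim <- length(t)
  for (k in seq_along(onsets)) {
    i <- onsets[k]
    j <- i
    while (j < length(v) && !(v[j + 1] < thr && v[j] >= thr)) j <- j + 1
    j <- min(j + 1, length(v))
    best <- i
    for (q in i:j) if (v[q] > v[best]) best <- q
    peak_i[k] <- best
    nxt <- if (k < length(onsets)) onsets[k + 1] else last_in_stim
    if (nxt > best) {
      mn <- v[best]
      for (q in best:nxt) if (v[q] < mn) mn <- v[q]
      ahp[k] <- mn
    } else ahp[k] <- NA_real_
  }
  list(n = length(onsets), onset_i = onsets, peak_i = peak_i, ahp = ahp)
}

oracle_mean_window <- function(t, v, a, b) {
  s <- 0; n <- 0L
  for (i in seq_along(t)) if (t[i] >= a && t[i] < b) { s <- s + v[i]; n <- n + 1L }
  if (n == 0L) NA_real_ else s / n
}

oracle_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    den <- den + (x[i] - mx)^2
  }
  num / den
}

# returns list(value, valid); mirrors the registry definitions naively
oracle_feature <- function(name, t, v, on, off, amp, thr = -30) {
  sp <- oracle_spikes(t, v, on, off, thr)
  nsp <- sp$n
  vb <- oracle_mean_window(t, v, on - 100, on)
  ssse <- oracle_mean_window(t, v, off - 0.1 * (off - on), off)
  stim_v <- v[t >= on & t <= off]
  isis <- if (nsp >= 2) diff(t[sp$onset_i]) else numeric(0)
  amp_k <- function(k) v[sp$peak_i[k]] - v[sp$onset_i[k]]
  ok <- function(x) list(value = x, valid = is.finite(x))
  bad <- function() list(value = NA_real_, valid = FALSE)

  switch(name,
    Spikecount = ok(nsp),
    mean_frequency = ok(nsp / ((off - on) / 1000)),
    AP_amplitude = if (nsp < 1) bad() else ok(mean(sapply(seq_len(nsp), amp_k))),
    AP1_amp = if (nsp < 1) bad() else ok(amp_k(1)),
    AP2_amp = if (nsp < 2) bad() else ok(amp_k(2)),
    APlast_amp = if (nsp < 1) bad() else ok(amp_k(nsp)),
    AP_duration_half_width = {
      if (nsp < 1) bad()
      else {
        w <- rep(NA_real_, nsp)
        for (k in seq_len(nsp)) {
          half <- v[sp$onset_i[k]] + (v[sp$peak_i[k]] - v[sp$onset_i[k]]) / 2
          r1 <- NA
          for (q in sp$onset_i[k]:sp$peak_i[k]) if (v[q] >= half) { r1 <- q; break }
          r2 <- NA
          if (sp$peak_i[k] < length(v))
            for (q in (sp$peak_i[k] + 1):length(v)) if (v[q] < half) { r2 <- q; break }
          if (!is.na(r1) && !is.na(r2)) {
            t1 <- t[r1]
            if (r1 > 1 && v[r1] != v[r1 - 1])
              t1 <- t[r1 - 1] + (half - v[r1 - 1]) / (v[r1] - v[r1 - 1]) *
                (t[r1] - t[r1 - 1])
            t2 <- t[r2]
            if (v[r2] != v[r2 - 1])
              t2 <- t[r2 - 1] + (half - v[r2 - 1]) / (v[r2] - v[r2 - 1]) *
                (t[r2] - t[r2 - 1])
            w[k] <- t2 - t1
          }
        }
        if (all(is.na(w))) bad() else ok(mean(w, na.rm = TRUE))
      }
    },
    AHP_depth = if (nsp < 1 || all(is.na(sp$ahp))) bad()
                else ok(vb - mean(sp$ahp, na.rm = TRUE)),
    AHP_depth_abs = if (nsp < 1 || all(is.na(sp$ahp))) bad()
                    else ok(mean(sp$ahp, na.rm = TRUE)),
    voltage_base = ok(vb),
    voltage_after_stim = ok(oracle_mean_window(t, v, off + 25, off + 75)),
    voltage_deflection = ok(ssse - vb),
    voltage_deflection_begin =
      ok(oracle_mean_window(t, v, on + 0.05 * (off - on),
                            on + 0.15 * (off - on)) - vb),
    ohmic_input_resistance_vb_ssse =
      if (is.na(amp) || amp == 0) bad() else ok((ssse - vb) / amp),
    inv_time_to_first_spike = {
      if (nsp < 1) bad()
      else {
        lat <- t[sp$onset_i[1]] - on
        if (lat <= 0) bad() else ok(1000 / lat)
      }
    },
    time_to_last_spike = if (nsp < 1) bad() else ok(t[sp$onset_i[nsp]] - on),
    inv_first_ISI = if (nsp < 2) bad() else ok(1000 / isis[1]),
    inv_second_ISI = if (nsp < 3) bad() else ok(1000 / isis[2]),
    inv_third_ISI = if (nsp < 4) bad() else ok(1000 / isis[3]),
    inv_fourth_ISI = if (nsp < 5) bad() else ok(1000 / isis[4]),
    inv_fifth_ISI = if (nsp < 6) bad() else ok(1000 / isis[5]),
    inv_last_ISI = if (nsp < 2) bad() else ok(1000 / isis[length(isis)]),
    ISI_values = if (nsp < 2) bad() else ok(mean(isis)),
    ISI_CV = if (nsp < 3) bad() else ok(stats::sd(isis) / mean(isis)),
    ISI_log_slope = if (nsp < 3) bad()
                    else ok(oracle_slope(seq_along(isis), log(isis))),
    burst_number = {
      if (nsp < 3) bad()
      else {
        thr_isi <- 0.5 * stats::median(isis)
        nb <- 0L; inb <- FALSE
        for (x in isis) {
          if (x < thr_isi && !inb) { nb <- nb + 1L; inb <- TRUE }
          if (x >= thr_isi) inb <- FALSE
        }
        ok(nb)
      }
    },
    minimum_voltage = ok(min(stim_v)),
    steady_state_voltage = ok(mean(stim_v)),
    steady_state_voltage_stimend = ok(ssse),
    sag_amplitude = ok(ssse - min(stim_v)),
    sag_ratio = {
      den <- vb - min(stim_v)
      if (!is.finite(den) || den <= 0) bad()
      else ok((ssse - min(stim_v)) / den)
    },
    maximum_voltage_from_voltagebase = ok(max(stim_v) - vb),
    decay_time_constant_after_stim = {
      sel <- which(t >= off & t <= off + 100)
      if (length(sel) < 10) return(bad())
      tt <- t[sel]; vv <- v[sel]
      vss <- mean(vv[tt >= off + 90])
      y <- vv - vss
      if (abs(y[1]) < 1e-9) return(bad())
      use <- which(abs(y) >= 0.01 * abs(y[1]) & tt <= off + 90 &
                   sign(y) == sign(y[1]))
      if (length(use) < 5) return(bad())
      sl <- oracle_slope(tt[use], log(abs(y[use])))
      if (sl >= 0) bad() else ok(-1 / sl)
    },
    stop(sprintf("oracle has no feature '%s'", name))
  )
}

# randomized synthetic voltage trace generator for the oracle-equivalence
# property (deterministic per id)
random_feature_trace <- function(id) {
  set.seed(7000 + id)
  dt <- 0.2
  on <- 100; off <- 900
  t <- seq(0, 1100, by = dt)
  base <- runif(1, -80, -65)
  defl <- runif(1, -25, 25)
  tau <- runif(1, 5, 40)
  v <- base + defl * (1 - exp(-pmax(t - on, 0) / tau)) *
    (t >= on & t <= off)
  # relaxation after offset
  post <- t > off
  v[post] <- base + defl * exp(-(t[post] - off) / tau)
  nspk <- sample(0:8, 1)
  if (nspk > 0 && defl > -10) {
    st <- sort(runif(nspk, on + 20, off - 20))
    peak <- runif(1, -10, 25)
    for (s in st) {
      tri <- pmax(0, 1 - abs(t - s) / 1.5)
      v <- pmax(v, base + (peak - base) * tri)
    }
  }
  if (runif(1) < 0.3) {       # excursion outside the stimulus: must not count
    tri <- pmax(0, 1 - abs(t - 50) / 1.5)
    v <- pmax(v, base + (10 - base) * tri)
  }
  v <- v + 0.02 * sin(t / 7)  # mild deterministic ripple
  make_trace(t, v, on, off, amp = round(runif(1, -0.2, 0.3), 3))
}

oracle_feature_names <- function() {
  setdiff(feature_registry()$name,
          c("bpo_holding_current", "bpo_threshold_current", "maximum_ca"))
}
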