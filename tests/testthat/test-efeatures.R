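test_that("spike detection honors the threshold and the stimulus window", {
  # two excursions to 0 mV during the stimulus -> 2 spikes
  tr <- spiky_trace(c(300, 500))
  expect_equal(nrow(detect_spikes(tr)), 2)
  # the same excursion before stimulus onset is ignored
  tr2 <- spiky_trace(c(50, 300))
  expect_equal(nrow(detect_spikes(tr2)), 1)
  # flat trace at -70: no spikes
  tr3 <- spiky_trace(numeric(0))
  expect_equal(nrow(detect_spikes(tr3)), 0)
  # excursion peaking below the threshold is not a spike
  tr4 <- spiky_trace(400, peak = -31)
  expect_equal(nrow(detect_spikes(tr4)), 0)
  tr5 <- spiky_trace(400, peak = -29.5)
  expect_equal(nrow(detect_spikes(tr5)), 1)
})

test_that("raising the detection threshold never increases the spike count", {
  for (id in 1:20) {
    tr <- random_feature_trace(id)
    counts <- vapply(c(-40, -30, -20, -10), function(th)
      nrow(detect_spikes(tr, th)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("worked registry examples: counts, input resistance, sag ratio", {
  tr <- spiky_trace(c(300, 400, 500))
  expect_equal(compute_feature(tr, "Spikecount")$value, 3)

  # passive deflection of -4 mV for -0.04 nA -> 100 MOhm
  t <- seq(0, 1000, by = 0.5)
  v <- -70 + ifelse(t >= 100 & t <= 900, -4, 0)
  rin <- compute_feature(make_trace(t, v, 100, 900, -0.04),
                         "ohmic_input_resistance_vb_ssse")
  expect_equal(rin$value, 100)

  # base -70, minimum -90, steady -80 -> sag ratio 0.5
  v2 <- rep(-70, length(t))
  stim <- t >= 100 & t <= 900
  v2[stim] <- -80
  v2[t >= 100 & t <= 200] <- -90
  sr <- compute_feature(make_trace(t, v2, 100, 900, -0.1), "sag_ratio")
  expect_equal(sr$value, 0.5)
  expect_equal(compute_feature(make_trace(t, v2, 100, 900, -0.1),
                               "sag_amplitude")$value, 10)
})

test_that("every registry feature matches its brute-force oracle on randomized traces", {
  feats <- oracle_feature_names()
  for (id in 1:100) {
    tr <- random_feature_trace(id)
    got <- compute_features(tr, feats)
    for (k in seq_along(feats)) {
      want <- oracle_feature(feats[k], tr$times, tr$values, tr$stim_onset,
                             tr$stim_offset, tr$stim_amp)
      expect_equal(got$valid[k], want$valid,
                   info = sprintf("trace %d feature %s validity", id, feats[k]))
      if (want$valid)
        expect_equal(got$value[k], want$value, tolerance = 1e-9,
                     info = sprintf("trace %d feature %s", id, feats[k]))
    }
  }
})

test_that("AP amplitude is non-negative and inverse ISIs invert the ISIs", {
  for (id in 1:30) {
    tr <- random_feature_trace(id)
    sp <- detect_spikes(tr)
    ap <- compute_feature(tr, "AP_amplitude", sp)
    if (ap$valid) expect_gte(ap$value, 0)
    if (nrow(sp) >= 3) {
      isis <- diff(sp$onset_time)
      i1 <- compute_feature(tr, "inv_first_ISI", sp)
      i2 <- compute_feature(tr, "inv_second_ISI", sp)
      expect_equal(i1$value, 1000 / isis[1])
      expect_equal(i2$value, 1000 / isis[2])
      last <- compute_feature(tr, "inv_last_ISI", sp)
      expect_equal(last$value, 1000 / isis[length(isis)])
    }
  }
})

test_that("invalid features carry reasons and unknown names error", {
  tr <- spiky_trace(numeric(0))
  f <- compute_feature(tr, "AP_amplitude")
  expect_false(f$valid)
  expect_match(f$reason, "spikes")
  f2 <- compute_feature(spiky_trace(c(300, 400)), "inv_second_ISI")
  expect_false(f2$valid)
  expect_error(compute_feature(tr, "not_a_feature"), "unknown feature")
  # calcium features demand a calcium trace
  expect_false(compute_feature(tr, "maximum_ca_prox_soma")$valid)
  ca <- make_trace(tr$times, 5e-5 + 1e-4 * (tr$times > 100 & tr$times < 900),
                   100, 900, 0.1, kind = "calcium")
  ca$kind <- "calcium"
  expect_equal(compute_feature(ca, "maximum_ca")$value, 1e-4)
})

test_that("decay time constant recovers a generated exponential", {
  t <- seq(0, 1100, by = 0.2)
  v <- -70 + ifelse(t <= 900, ifelse(t >= 100, -8, 0),
                    -8 * exp(-(t[t > 900] - 900) / 15)[1])
  v <- rep(-70, length(t))
  v[t >= 100 & t <= 900] <- -78
  post <- t > 900
  v[post] <- -70 - 8 * exp(-(t[post] - 900) / 15)
  f <- compute_feature(make_trace(t, v, 100, 900, -0.08),
                       "decay_time_constant_after_stim")
  expect_true(f$valid)
  expect_equal(f$value, 15, tolerance = 0.05)
})
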