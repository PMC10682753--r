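test_that("compartmentalization follows the ceiling rule", {
  cell <- passive_dendritic_cell()
  geom <- build_compartments(cell, max_seg_length = 50)
  seg <- geom$seg
  # the 400-um apical trunk splits into ceil(400/50) = 8 segments
  expect_equal(sum(seg$section_id == 2), 8)
  # a single-point soma is exactly one segment
  expect_equal(sum(seg$type == "soma"), 1)
  # parent indices form a tree rooted at the soma
  expect_equal(sum(geom$sys$parent == -1L), 1)
  expect_true(all(geom$sys$parent < seq_along(geom$sys$parent) - 1L + 1L))
})

test_that("passive step response matches the RC closed form across an (R, tau) grid", {
  for (R in c(50, 100, 200)) for (tau in c(10, 20)) {
    cell <- passive_cell(R, tau)
    I <- 0.1
    tr <- simulate(cell, list(stimulus("step", amplitude = I, onset = 0,
                                       offset = 200)),
                   duration = 200, rec_every = 4L)[[1]]
    expected <- -70 + I * R * (1 - exp(-tr$times / tau))
    expect_lt(max(abs(tr$values - expected)), 0.05)
  }
})

test_that("a passive cell without stimulus stays at e_pas", {
  tr <- simulate(passive_cell(100, 20), list(), duration = 300)[[1]]
  expect_lt(max(abs(tr$values + 70)), 1e-6)
})

test_that("per-segment charge bookkeeping closes to 1e-6 nA", {
  cell <- dendritic_ground_truth_cell()
  recs <- list(recording(loc("soma"), "mech_currents"),
               recording(loc("soma"), "capacitive"),
               recording(loc("soma"), "axial"),
               recording(loc("soma"), "injected"),
               recording(loc("apical"), "mech_currents"),
               recording(loc("apical"), "capacitive"),
               recording(loc("apical"), "axial"),
               recording(loc("apical"), "injected"))
  trs <- simulate(cell, list(stimulus("step", amplitude = 0.5, onset = 20,
                                      offset = 120)),
                  recs, duration = 150, rec_every = 1L)
  for (base in c(0, 4)) {
    imech <- rowSums(trs[[base + 1]]$values)
    resid <- trs[[base + 2]]$values + imech + trs[[base + 3]]$values -
      trs[[base + 4]]$values
    expect_lt(max(abs(resid[-1])), 1e-6)
  }
})

test_that("stochastic channels in deterministic mode reproduce the plain channel exactly", {
  lib <- default_channel_library("soma")
  mk <- function(mechs) {
    cell_model(point_morphology(),
               mechanisms = mechs,
               passive = list(g_pas = 1e-4, e_pas = -75, cm = 1, Ra = 100),
               parameters = cell_parameters(c("gbar_StochKv", "gbar_NaT"),
                                            c(0.01, 0.05)))
  }
  plain <- lib$StochKv; class(plain) <- "emf_channel"; plain$gamma_pS <- 0
  stim <- list(stimulus("step", amplitude = 0.1, onset = 50, offset = 450))
  a <- simulate(mk(list(lib$StochKv, lib$NaT)), stim, duration = 500,
                mode = "deterministic")[[1]]
  b <- simulate(mk(list(plain, lib$NaT)), stim, duration = 500)[[1]]
  expect_identical(a$values, b$values)
})

test_that("stochastic-mode mean converges to the deterministic trace", {
  lib <- default_channel_library("soma")
  cell <- cell_model(point_morphology(40),
                     mechanisms = list(lib$StochKv),
                     passive = list(g_pas = 1e-4, e_pas = -75, cm = 1, Ra = 100),
                     parameters = cell_parameters("gbar_StochKv", 0.02))
  stim <- list(stimulus("step", amplitude = 0.15, onset = 20, offset = 180))
  det <- simulate(cell, stim, duration = 200, rec_every = 8L)[[1]]$values
  acc <- 0
  nseed <- 200
  for (s in seq_len(nseed))
    acc <- acc + simulate(cell, stim, duration = 200, rec_every = 8L,
                          seed = s, mode = "stochastic")[[1]]$values
  mean_tr <- acc / nseed
  # large channel count: Monte-Carlo error on the mean is well below 1 mV
  expect_lt(max(abs(mean_tr - det)), 1)
  expect_gt(max(abs(
    simulate(cell, stim, duration = 200, rec_every = 8L, seed = 1,
             mode = "stochastic")[[1]]$values - det)), 1e-4)
})

test_that("halving the segment length moves a passive RMP by < 0.01 mV", {
  cell <- passive_dendritic_cell()
  rmp <- function(msl) {
    c2 <- cell; c2$geometry <- build_compartments(cell, msl)
    tr <- simulate(c2, list(stimulus("step", amplitude = -0.05, onset = 100,
                                     offset = 600)),
                   duration = 600, rec_every = 8L)[[1]]
    mean(tr$values[tr$times >= 540])
  }
  expect_lt(abs(rmp(20) - rmp(10)), 0.01)
})

test_that("spike count is robust to halving dt at the default resolution", {
  cell <- ground_truth_cell()
  n_at <- function(dt) {
    tr <- simulate(cell, list(stimulus("step", amplitude = 0.15, onset = 100,
                                       offset = 1100)),
                   duration = 1200, dt = dt, rec_every = 1L)[[1]]
    nrow(detect_spikes(tr))
  }
  expect_equal(n_at(0.025), n_at(0.0125))
})

test_that("EPSP machinery: zero conductance is the baseline, peak conductance is g_max", {
  cell <- passive_dendritic_cell()
  syn0 <- synapse_spec(0, location = loc("apical", 0.5))
  trs0 <- simulate_epsp(cell, syn0, duration = 200)
  expect_lt(max(abs(trs0[[2]]$values + 70)), 1e-6)

  syn <- synapse_spec(1.5, location = loc("apical", 0.5))
  trs <- simulate_epsp(cell, syn, duration = 200, record_current = TRUE)
  g_uS <- trs$syn_current / trs[[1]]$values    # I = g (V - E), E = 0 mV
  expect_equal(max(g_uS) * 1e3, 1.5, tolerance = 0.01)

  # a divergent synapse location errors cleanly
  expect_error(simulate_epsp(cell, synapse_spec(1, location = loc("nope"))),
               "no section")
})

test_that("mechanism JSON round-trips the channel library", {
  lib <- default_channel_library()
  f <- withr::local_tempfile(fileext = ".json")
  write_mechanisms_json(lib, f)
  back <- read_mechanisms_json(f)
  expect_equal(length(back), length(lib))
  expect_equal(back[["NaT"]]$gates[[1]]$vhalf, lib$NaT$gates[[1]]$vhalf)
  expect_equal(back[["StochKv"]]$gamma_pS, lib$StochKv$gamma_pS)
  expect_s3_class(back[["StochKv"]], "emf_stoch_channel")
})

test_that("calcium dynamics: influx under depolarization, floored at rest", {
  lib <- default_channel_library("soma")
  cell <- cell_model(point_morphology(),
                     mechanisms = c(lib[c("NaT", "Kdr", "CaHVA", "SK")],
                                    list(calcium_dynamics_spec(decay_tau = 80,
                                                               regions = "soma"))),
                     passive = list(g_pas = 1e-4, e_pas = -75, cm = 1, Ra = 100),
                     parameters = cell_parameters(
                       c("gbar_NaT", "gbar_Kdr", "gbar_CaHVA", "gbar_SK"),
                       c(0.05, 0.02, 5e-4, 1e-4)))
  trs <- simulate(cell,
                  list(stimulus("step", amplitude = 0.2, onset = 100,
                                offset = 600)),
                  list(recording(loc("soma"), "voltage"),
                       recording(loc("soma"), "calcium")),
                  duration = 800, rec_every = 4L)
  ca <- trs[[2]]
  expect_true(all(ca$values >= 5e-5 - 1e-12))       # never below ca_min
  expect_gt(max(ca$values), 2 * 5e-5)               # spiking drives influx
  fv <- compute_feature(ca, "maximum_ca")
  expect_true(fv$valid)
  expect_gt(fv$value, 0)
  # after the stimulus the concentration decays back toward the floor
  tail_ca <- ca$values[ca$times > 750]
  expect_lt(tail_ca[length(tail_ca)], max(ca$values) / 2)
})
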