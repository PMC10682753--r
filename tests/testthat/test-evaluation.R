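test_that("the Z score is |model - mean| / sd with clipping for failures", {
  expect_equal(z_score(10, 8, 1), 2)
  expect_equal(z_score(8, 8, 1), 0)
  expect_equal(z_score(NA_real_, 8, 1), 250)
  expect_equal(z_score(1e9, 8, 1), 250)
  expect_equal(z_score(NA_real_, 8, 1, clip = 100), 100)
  expect_error(z_score(1, 1, 0), "sd")
})

test_that("RMP of a passive cell is its leak reversal", {
  expect_equal(compute_rmp(passive_cell(100, 20, e_pas = -70)), -70,
               tolerance = 0.05)
  # a tonic depolarizing conductance pulls the RMP above e_pas
  lib <- default_channel_library("soma")
  cell <- cell_model(point_morphology(),
                     mechanisms = lib["Ih"],
                     passive = list(g_pas = 1e-4, e_pas = -80, cm = 1, Ra = 100),
                     parameters = cell_parameters("gbar_Ih", 2e-4))
  expect_gt(compute_rmp(cell), -80)
})

test_that("holding-current search matches the Ohmic closed form on passive cells", {
  cell <- passive_cell(100, 20, e_pas = -70)
  i <- search_holding_current(cell, target_potential = -80)
  expect_lt(abs(i - (-0.1)), 0.1 / 100 + 1e-3)  # tol(mV) / R(MOhm)
  i0 <- search_holding_current(cell, target_potential = -70 + 0.01)
  expect_lt(abs(i0), 2e-3)
  expect_error(search_holding_current(cell, target_potential = -200),
               "bracket")
})

test_that("threshold-current bisection agrees with an exhaustive grid scan", {
  variants <- list(
    ground_truth_cell(),
    set_parameters(ground_truth_cell(), c(gbar_NaT = 0.03)),
    set_parameters(ground_truth_cell(), c(gbar_Kdr = 0.04)))
  for (cell in variants) {
    found <- search_threshold_current(cell, holding = 0, precision = 0.001)
    # independent oracle: ascending scan in 0.001 nA steps without the
    # early-exit fast path
    grid <- NA_real_
    for (amp in seq(0.001, 0.6, by = 0.001)) {
      if (emforge:::spikes_at(cell, amp, 0, 100, 2000, 0.025, fast = FALSE) >= 1) {
        grid <- amp; break
      }
    }
    expect_false(is.na(grid))
    expect_lt(abs(found - grid), 0.001 + 1e-12)
  }
})

test_that("the spiking predicate is monotone in the stimulus amplitude", {
  cell <- ground_truth_cell()
  spk <- vapply(seq(0.02, 0.3, by = 0.02), function(a)
    emforge:::spikes_at(cell, a, 0, 100, 2000, 0.025, fast = FALSE) >= 1,
    logical(1))
  expect_true(all(diff(spk) >= 0))
})

test_that("a purely passive cell is reported subthreshold", {
  expect_error(search_threshold_current(passive_cell(50, 20)),
               "subthreshold")
})

test_that("self-evaluation of the ground truth scores zero; totals add up", {
  rep_ <- evaluate_emodel(ground_truth_cell(), default_protocol_suite(),
                          optimization_targets())
  expect_false(rep_$early_stop)
  expect_lt(rep_$total, 0.5)
  expect_equal(rep_$total, sum(rep_$scores$score))
  g <- glance(rep_)
  expect_equal(g$total_cost, rep_$total)
  expect_equal(g$holding_current_nA, rep_$holding_current)
})

test_that("models failing the RMP/Rin gate stop early with clipped scores", {
  cell <- ground_truth_cell()
  bad <- set_parameters(cell, c(gbar_Ih = 1e-3))   # strongly depolarized RMP
  rep_ <- evaluate_emodel(bad, default_protocol_suite(),
                          optimization_targets())
  expect_true(rep_$early_stop)
  rest <- rep_$scores[!rep_$scores$protocol %in% c("RMP", "Rin"), ]
  expect_true(all(rest$score == 250))
  good <- evaluate_emodel(cell, default_protocol_suite(),
                          optimization_targets())
  expect_gt(rep_$total, good$total)
})

test_that("changing one protocol's feature list only changes those entries", {
  suite <- default_protocol_suite()
  targets <- optimization_targets()
  base <- evaluate_emodel(ground_truth_cell(), suite, targets)
  suite2 <- suite
  i <- which(suite2$protocol == "APWaveform")
  suite2$features[[i]] <- "AP_amplitude"
  mod <- evaluate_emodel(ground_truth_cell(), suite2, targets)
  other <- function(r) r$scores[r$scores$protocol != "APWaveform", ]
  expect_equal(other(mod), other(base))
  expect_equal(nrow(mod$scores[mod$scores$protocol == "APWaveform", ]), 1)
})

test_that("evaluation is deterministic", {
  a <- evaluate_emodel(ground_truth_cell(), default_protocol_suite(),
                       optimization_targets())
  b <- evaluate_emodel(ground_truth_cell(), default_protocol_suite(),
                       optimization_targets())
  expect_identical(a$scores$score, b$scores$score)
  expect_identical(a$threshold_current, b$threshold_current)
})
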