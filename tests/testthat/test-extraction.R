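# helpers building tiny synthetic recording sets ----------------------------

sweep_at <- function(amp, spiking, vb = -70, protocol = "IDrest") {
  if (spiking) {
    tr <- spiky_trace(c(300, 500), base = vb, amp = amp, protocol = protocol)
  } else {
    t <- seq(0, 1000, by = 0.5)
    tr <- make_trace(t, rep(vb, length(t)), 100, 900, amp, protocol)
  }
  tr
}

test_that("rheobase is the lowest spiking IDrest/IDthresh amplitude", {
  cell <- cell_recording_set("c1", traces = list(
    sweep_at(0.05, FALSE), sweep_at(0.10, TRUE), sweep_at(0.15, TRUE)))
  expect_equal(compute_cell_rheobase(cell), 0.10)
  # ties at the lowest spiking amplitude are irrelevant
  cell2 <- cell_recording_set("c2", traces = list(
    sweep_at(0.10, TRUE), sweep_at(0.10, TRUE), sweep_at(0.2, TRUE)))
  expect_equal(compute_cell_rheobase(cell2), 0.10)
  # only hyperpolarizing (non-spiking) recordings: an error
  cell3 <- cell_recording_set("c3", traces = list(
    sweep_at(-0.05, FALSE), sweep_at(-0.1, FALSE)))
  expect_error(compute_cell_rheobase(cell3), "no spiking")
  # other protocols are excluded from the search
  cell4 <- cell_recording_set("c4", traces = list(
    sweep_at(0.02, TRUE, protocol = "Ramp"), sweep_at(0.10, TRUE)))
  expect_equal(compute_cell_rheobase(cell4), 0.10)
})

test_that("the 150% / 10% binning window is exactly [140, 160]%", {
  # rheobase 0.1; sweeps at 139.9, 140, 160, 160.1 % with distinct bases
  mk <- function(pct, vb) sweep_at(pct / 100 * 0.1, FALSE, vb = vb)
  cell <- cell_recording_set("c1", traces = list(
    sweep_at(0.1, TRUE, vb = -60),
    mk(139.9, -71), mk(140, -72), mk(160, -74), mk(160.1, -75)))
  res <- bin_and_average(list(cell),
                         target_spec("IDrest", 150, 10, "voltage_base"))
  vb <- res[res$feature == "voltage_base", ]
  # the spiking 100% sweep and the two edge sweeps are included; the
  # outside sweeps are not: mean of (-72, -74) would be -73, but 100% sweep
  # is outside [140, 160] so only the closed-window sweeps count
  expect_equal(vb$mean, -73)
})

test_that("within-cell averaging precedes equal-weight cross-cell averaging", {
  # cell A has two in-window sweeps (bases -10, -14), cell B one (-12):
  # equal cell weights give ((-12) + (-12)) / 2, not the sweep mean
  mk_cell <- function(id, bases) cell_recording_set(id, traces = c(
    list(sweep_at(0.1, TRUE, vb = -70)),
    lapply(bases, function(b) sweep_at(0.15, FALSE, vb = b))))
  res <- bin_and_average(list(mk_cell("a", c(-10, -14)), mk_cell("b", -12)),
                         target_spec("IDrest", 150, 10, "voltage_base"))
  vb <- res[res$feature == "voltage_base", ]
  expect_equal(vb$mean, -12)
  expect_equal(vb$n_cells, 2)
  # two cells contributing 10 and 12 -> mean 11
  res2 <- bin_and_average(list(mk_cell("a", 10), mk_cell("b", 12)),
                          target_spec("IDrest", 150, 10, "voltage_base"))
  expect_equal(res2$mean[res2$feature == "voltage_base"], 11)
  expect_gt(res2$sd[res2$feature == "voltage_base"], 0)
})

test_that("single-cell targets get sd 0, flagged and floored", {
  cell <- cell_recording_set("only", traces = list(
    sweep_at(0.1, TRUE), sweep_at(0.15, FALSE, vb = -71)))
  res <- bin_and_average(list(cell),
                         target_spec("IDrest", 150, 10, "voltage_base"))
  row <- res[res$feature == "voltage_base", ]
  expect_equal(row$sd, 0)
  expect_equal(row$n_cells, 1)
  expect_true(row$sd_floored)
  expect_gt(row$sd_eff, 0)
})

test_that("rheobase normalization is invariant to a common amplitude scale", {
  mk_cell <- function(id, fac) cell_recording_set(id, traces = list(
    sweep_at(0.1 * fac, TRUE),
    sweep_at(0.15 * fac, FALSE, vb = -71),
    sweep_at(0.2 * fac, FALSE, vb = -73)))
  tg <- target_spec("IDrest", 150, 10, "voltage_base")
  a <- bin_and_average(list(mk_cell("a", 1)), tg)
  b <- bin_and_average(list(mk_cell("b", 3)), tg)
  expect_equal(a$mean[a$feature == "voltage_base"],
               b$mean[b$feature == "voltage_base"])
})

test_that("widening the tolerance never reduces the cell count", {
  mk_cell <- function(id, pcts) cell_recording_set(id, traces = c(
    list(sweep_at(0.1, TRUE)),
    lapply(pcts, function(p) sweep_at(p / 100 * 0.1, FALSE, vb = -71))))
  cells <- list(mk_cell("a", c(155, 175)), mk_cell("b", 135), mk_cell("c", 162))
  n_at <- function(tol) {
    res <- bin_and_average(cells, target_spec("IDrest", 150, tol, "voltage_base"))
    res$n_cells[res$feature == "voltage_base"]
  }
  expect_true(all(diff(vapply(c(5, 10, 15, 25), n_at, numeric(1))) >= 0))
})

test_that("noiseless zero-jitter fixtures give sd 0 targets (self-consistency)", {
  tg <- noiseless_targets()
  expect_true(all(tg$sd < 1e-9))
  expect_true(all(tg$sd_eff > 0))
  expect_true(all(tg$n_cells == 2))
  # search-based targets present with sensible magnitudes
  expect_equal(tg$mean[tg$feature == "bpo_holding_current"], 0)
  expect_gt(tg$mean[tg$feature == "bpo_threshold_current"], 0)
})

test_that("targets and trace bundles round-trip through JSON", {
  tg <- noiseless_targets()
  f <- withr::local_tempfile(fileext = ".json")
  write_targets_json(tg, f)
  back <- read_targets_json(f)
  expect_equal(as.data.frame(back), as.data.frame(tg), tolerance = 1e-12)

  cells <- noiseless_cells()
  f2 <- withr::local_tempfile(fileext = ".json")
  write_trace_bundle(cells[1], f2)
  back2 <- read_trace_bundle(f2)
  expect_equal(length(back2[[1]]$traces), length(cells[[1]]$traces))
  expect_equal(back2[[1]]$traces[[3]]$values, cells[[1]]$traces[[3]]$values)
  expect_equal(compute_cell_rheobase(back2[[1]]),
               compute_cell_rheobase(cells[[1]]))
})
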