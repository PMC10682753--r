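test_that("SWC reading maps types, doubles radii and validates structure", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# a 3-point soma",
               "1 1 0 0 0 5 -1",
               "2 1 0 5 0 5 1",
               "3 1 0 10 0 5 2"), f)
  m <- read_swc(f)
  expect_length(m$sections, 1)
  expect_equal(m$sections[[1]]$type, "soma")
  expect_equal(m$sections[[1]]$diam, rep(10, 3))

  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1 7"), f)
  expect_error(read_swc(f), "parent")
  writeLines(c("1 1 0 0 0 5 -1", "2 9 0 5 0 1 1"), f)
  expect_error(read_swc(f), "type code")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1"), f)
  expect_error(read_swc(f), "7 columns")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 0 5 0 5 -1"), f)
  expect_error(read_swc(f), "one root")
})

test_that("SWC write/read round-trips types and geometry to 1e-6 um", {
  # SWC canonicalizes unbranched same-type section chains into single runs,
  # so compare the per-type point geometry and total cable lengths
  m <- replace_axon(fixture_morphology())
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(total_length(m2), total_length(m), tolerance = 1e-9)
  key <- function(x) {
    tb <- as_tibble(x)
    tb <- unique(tb[c("type", "x", "y", "z", "diam")])
    tb[order(tb$type, tb$x, tb$y, tb$z), ]
  }
  expect_equal(key(m2), key(m), tolerance = 1e-6)
  expect_equal(surface_area(m2, "all"), surface_area(m, "all"),
               tolerance = 1e-9)
  # a second write/read cycle is exact: the SWC form is a fixed point
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(m2, f2)
  m3 <- read_swc(f2)
  expect_equal(as_tibble(m3), as_tibble(m2), tolerance = 1e-9)
  f3 <- withr::local_tempfile(fileext = ".swc")
  write_swc(m3, f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("axon replacement yields one AIS and one myelin section of the stated lengths", {
  m <- fixture_morphology()
  r <- replace_axon(m)
  types <- vapply(r$sections, `[[`, character(1), "type")
  expect_equal(sum(types == "AIS"), 1)
  expect_equal(sum(types == "myelin"), 1)
  expect_equal(sum(types == "axon"), 0)
  ais <- r$sections[[which(types == "AIS")]]
  mye <- r$sections[[which(types == "myelin")]]
  expect_equal(section_length(ais), 60)
  expect_equal(section_length(mye), 1000)
  # AIS diameter inherited from the original axon's first point
  expect_equal(unique(ais$diam), m$sections[[6]]$diam[1])
  # dendrites untouched
  dl <- function(x) sum(total_length(x)[c("basal", "apical")])
  expect_equal(dl(r), dl(m))
  # custom lengths respected
  r2 <- replace_axon(m, ais_length = 45, myelin_length = 500)
  types2 <- vapply(r2$sections, `[[`, character(1), "type")
  expect_equal(section_length(r2$sections[[which(types2 == "AIS")]]), 45)
})

test_that("axon replacement is idempotent and handles axon-less morphologies", {
  m <- fixture_morphology()
  once <- replace_axon(m)
  twice <- replace_axon(once)
  expect_equal(as_tibble(twice), as_tibble(once))
  no_axon <- morphology(m$sections[1:5], name = "no_axon")
  r <- replace_axon(no_axon)
  types <- vapply(r$sections, `[[`, character(1), "type")
  expect_true(all(c("AIS", "myelin") %in% types))
  expect_equal(unique(r$sections[[which(types == "AIS")]]$diam), 1)
})

test_that("cloning: identity, pure rescale, and seed determinism", {
  m <- fixture_morphology()
  id <- clone_morphology(m, scale = 1, length_jitter_sd = 0,
                         angle_jitter_sd = 0, seed = 3)
  expect_equal(as_tibble(id)[c("x", "y", "z", "diam")],
               as_tibble(m)[c("x", "y", "z", "diam")])
  up <- clone_morphology(m, scale = 1.1, length_jitter_sd = 0,
                         angle_jitter_sd = 0, seed = 3)
  for (i in seq_along(m$sections))
    if (m$sections[[i]]$type != "soma")
      expect_equal(section_length(up$sections[[i]]),
                   1.1 * section_length(m$sections[[i]]), tolerance = 1e-9)
  a <- clone_morphology(m, length_jitter_sd = 0.1, angle_jitter_sd = 0.2, seed = 11)
  b <- clone_morphology(m, length_jitter_sd = 0.1, angle_jitter_sd = 0.2, seed = 11)
  c_ <- clone_morphology(m, length_jitter_sd = 0.1, angle_jitter_sd = 0.2, seed = 12)
  expect_equal(as_tibble(a), as_tibble(b))
  expect_false(isTRUE(all.equal(as_tibble(a)$x, as_tibble(c_)$x)))
  # topology and types preserved under jitter
  expect_equal(vapply(a$sections, `[[`, character(1), "type"),
               vapply(m$sections, `[[`, character(1), "type"))
  expect_equal(vapply(a$sections, `[[`, integer(1), "parent"),
               vapply(m$sections, `[[`, integer(1), "parent"))
})

test_that("surface areas: analytic cylinder, AIS cutoff, empty region, partition", {
  cyl <- morphology(list(
    new_s <- emforge:::new_section(1, "soma", matrix(c(0, 0, 0), 1, 3), 10, NA),
    emforge:::new_section(2, "axon", rbind(c(0, 0, 0), c(100, 0, 0)),
                          c(2, 2), 1)), name = "cyl")
  expect_equal(surface_area(cyl, "AIS_proxy", ais_cutoff = 1e9), 200 * pi)
  # only the first 40 um of a 100 um axon count
  expect_equal(surface_area(cyl, "AIS_proxy", ais_cutoff = 40), 80 * pi)
  # dendrite entirely beyond the proximal cutoff contributes nothing
  far <- morphology(list(
    emforge:::new_section(1, "soma", matrix(c(0, 0, 0), 1, 3), 10, NA),
    emforge:::new_section(2, "basal", rbind(c(0, 0, 0), c(600, 0, 0)),
                          c(1, 1), 1),
    emforge:::new_section(3, "basal", rbind(c(600, 0, 0), c(700, 0, 0)),
                          c(1, 1), 2)), name = "far")
  expect_equal(surface_area(far, "proximal_dendrites", dendrite_cutoff = 500),
               pi * 1 * 500)
  m <- replace_axon(fixture_morphology())
  # disjoint regions partition the total area
  expect_equal(surface_area(m, "soma") +
                 surface_area(m, "AIS_proxy", ais_cutoff = 1e9) +
                 surface_area(m, "proximal_dendrites", dendrite_cutoff = 1e9),
               surface_area(m, "all"), tolerance = 1e-9)
})

test_that("morphology invariants are enforced", {
  s1 <- emforge:::new_section(1, "soma", matrix(c(0, 0, 0), 1, 3), 10, NA)
  s2 <- emforge:::new_section(2, "basal", rbind(c(0, 0, 0), c(10, 0, 0)),
                              c(1, 1), 5)
  expect_error(morphology(list(s1, s2)), "missing parent")
  bad_diam <- emforge:::new_section(2, "basal", rbind(c(0, 0, 0), c(10, 0, 0)),
                                    c(1, -1), 1)
  expect_error(morphology(list(s1, bad_diam)), "positive")
  expect_error(morphology(list(s1, s1)), "duplicate")
})
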