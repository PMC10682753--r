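test_that("the acceptance threshold is max(5, 5 * exemplar score)", {
  expect_equal(acceptance_threshold(0.3), 5)
  expect_equal(acceptance_threshold(2), 10)
  expect_equal(acceptance_threshold(1), 5)
  expect_equal(acceptance_threshold(0), 5)
  # branch-free reformulation 5 * max(1, s) on random scores
  s <- c(0, runif(200, 0, 10))
  expect_equal(acceptance_threshold(s), 5 * pmax(1, s))
  expect_error(acceptance_threshold(-1))
})

test_that("acceptance is monotone: lowering a combo score never rejects", {
  set.seed(12)
  for (i in 1:50) {
    se <- runif(6, 0, 4)
    sc <- runif(6, 0, 25)
    thr <- acceptance_threshold(se)
    acc1 <- all(sc < thr)
    sc2 <- sc * runif(6, 0, 1)      # lower every score
    acc2 <- all(sc2 < thr)
    expect_true(!acc1 || acc2)
  }
})

test_that("generalization reports count acceptance fractions correctly", {
  mk <- function(m_type, e_type, accepted, id) {
    structure(list(morphology_id = id, m_type = m_type, emodel_id = "em",
                   e_type = e_type, scores = tibble::tibble(),
                   accepted = accepted, failing_features = character(0),
                   reason = if (accepted) NA_character_ else "feature_scores",
                   total_combo = 1, total_exemplar = 1,
                   ais_surface_um2 = 10, dendrite_surface_um2 = 100),
              class = "emf_combo_result")
  }
  res <- list(mk("A", "e1", TRUE, "m1"), mk("A", "e1", TRUE, "m2"),
              mk("A", "e1", TRUE, "m3"), mk("A", "e1", FALSE, "m4"),
              mk("B", "e1", TRUE, "m5"))
  rep_ <- generalization_report(res)
  a <- rep_$matrix[rep_$matrix$m_type == "A", ]
  expect_equal(a$fraction_accepted, 0.75)
  expect_equal(a$n, 4)
  # absent combinations are absent, not zero
  expect_equal(nrow(rep_$matrix), 2)
  expect_equal(nrow(rep_$scatter), 5)
  expect_true(all(c("ais_surface_um2", "dendrite_surface_um2") %in%
                  names(rep_$scatter)))
})

gen_suite <- function() default_protocol_suite(idrest_pcts = 150)

gen_targets <- function() {
  tg <- noiseless_targets()
  tg[(tg$protocol %in% c("RMP", "Rin", "RinHoldCurrent", "Threshold", "IV")) |
     (tg$protocol == "IDrest" & tg$target_pct == 150), ]
}

test_that("an identity clone reproduces the exemplar scores and is accepted", {
  cell <- ground_truth_cell()
  suite <- gen_suite(); targets <- gen_targets()
  exemplar <- evaluate_emodel(cell, suite, targets)
  clone <- clone_morphology(cell$morphology, seed = 4)   # zero jitter
  combo <- evaluate_combo(clone, cell, suite, targets, exemplar)
  expect_true(combo$accepted)
  expect_equal(combo$scores$score_combo, combo$scores$score_exemplar)
  expect_length(combo$failing_features, 0)
})

test_that("clones whose AIS cannot sustain spiking are rejected as subthreshold", {
  cell <- dendritic_ground_truth_cell()
  suite <- gen_suite(); targets <- dendritic_targets()
  exemplar <- evaluate_emodel(cell, suite, targets)
  expect_false(exemplar$early_stop)
  expect_false(exemplar$subthreshold)
  shrunken <- clone_morphology(cell$morphology, ais_diam_scale = 0.05, seed = 2)
  combo <- evaluate_combo(shrunken, cell, suite, targets, exemplar)
  expect_false(combo$accepted)
  expect_equal(combo$reason, "subthreshold")
})

test_that("morphology banks are deterministic and span the requested grid", {
  base <- replace_axon(fixture_morphology())
  dir <- withr::local_tempdir()
  a <- generate_morphology_bank(base, 4, seed = 3, dir = dir)
  b <- generate_morphology_bank(base, 4, seed = 3)
  expect_equal(as_tibble(a[[2]]), as_tibble(b[[2]]))
  files <- attr(a, "files")
  expect_length(files, 4)
  expect_identical(readLines(files[1]), readLines(files[1]))
  # single clone with zero jitter equals the base
  c1 <- generate_morphology_bank(base, 1, length_jitter_sd = 0,
                                 angle_jitter_sd = 0, seed = 1)
  expect_equal(as_tibble(c1[[1]])[c("x", "y", "z", "diam")],
               as_tibble(base)[c("x", "y", "z", "diam")])
})

test_that("the me-combination map validates and answers lookups", {
  cm <- combo_map(c("TPC", "POINT"), list(c("cADfix", "bACfix"), "cADfix"))
  expect_setequal(allowed_etypes(cm, "TPC"), c("cADfix", "bACfix"))
  expect_equal(allowed_etypes(cm, "POINT"), "cADfix")
  expect_length(allowed_etypes(cm, "unknown"), 0)
  expect_error(combo_map("TPC", list(character(0))), "at least one")
})
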