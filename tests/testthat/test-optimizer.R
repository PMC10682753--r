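sphere_eval <- function(p) c(o1 = abs(p[[1]] - 0.3), o2 = abs(p[[2]] - 0.7))
sphere_bounds <- tibble::tibble(name = c("x", "y"), lower = 0, upper = 1)

test_that("IBEA solves a two-objective sphere problem", {
  fit <- ibea_run(sphere_eval, sphere_bounds,
                  optimization_config(offspring = 32, generations = 30,
                                      seed = 5))
  expect_lt(abs(fit$best[["x"]] - 0.3), 1e-2)
  expect_lt(abs(fit$best[["y"]] - 0.7), 1e-2)
  expect_lt(fit$best_total, 2e-2)
})

test_that("optimization is bit-reproducible for a fixed seed", {
  cfg <- optimization_config(offspring = 16, generations = 5, seed = 9)
  a <- ibea_run(sphere_eval, sphere_bounds, cfg)
  b <- ibea_run(sphere_eval, sphere_bounds, cfg)
  expect_identical(a$best, b$best)
  expect_identical(a$population, b$population)
  c_ <- ibea_run(sphere_eval, sphere_bounds,
                 optimization_config(offspring = 16, generations = 5, seed = 10))
  expect_false(identical(a$best, c_$best))
})

test_that("the all-time best total is non-increasing over generations", {
  fit <- ibea_run(sphere_eval, sphere_bounds,
                  optimization_config(offspring = 16, generations = 20, seed = 2))
  expect_true(all(diff(fit$convergence$best_total) <= 0))
})

test_that("environmental selection matches a from-scratch reimplementation", {
  # independent reference: recompute survivor fitness from the initial-pool
  # indicator matrix after each removal, removing the worst each time
  brute_select <- function(obj, mu, kappa = 0.05) {
    o <- pmin(obj, 250)
    lo <- apply(o, 2, min)
    hi <- apply(o, 2, quantile, probs = 0.75, names = FALSE)
    span <- ifelse(hi - lo == 0, 1, hi - lo)
    no <- pmin(sweep(sweep(o, 2, lo), 2, span, "/"), 2)
    n <- nrow(no)
    I <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      I[i, j] <- max(no[i, ] - no[j, ])
    cc <- max(abs(I)); if (cc == 0) cc <- 1
    alive <- seq_len(n)
    while (length(alive) > mu) {
      fit <- vapply(alive, function(x)
        sum(vapply(setdiff(alive, x), function(y)
          -exp(-I[y, x] / (cc * kappa)), numeric(1))), numeric(1))
      alive <- alive[-which.min(fit)]
    }
    alive
  }
  set.seed(42)
  for (rep in 1:20) {
    obj <- matrix(runif(50, 0, 10), nrow = 10, ncol = 5)
    expect_equal(emforge:::ibea_select(obj, 5), brute_select(obj, 5),
                 info = sprintf("table %d", rep))
  }
})

test_that("selection never removes the fittest individual at any step", {
  set.seed(7)
  for (rep in 1:10) {
    obj <- matrix(runif(60, 0, 10), nrow = 12, ncol = 5)
    ft <- emforge:::ibea_fitness(obj, 0.05)
    keep <- emforge:::ibea_select(obj, 6)
    expect_true(which.max(ft$fitness) %in% keep)
  }
})

test_that("variation operators respect bounds", {
  set.seed(1)
  lower <- c(0, -1); upper <- c(1, 1)
  for (i in 1:200) {
    off <- emforge:::sbx_crossover(runif(2, lower, upper),
                                   runif(2, lower, upper),
                                   lower, upper, eta = 10, prob = 1)
    m <- emforge:::poly_mutation(off[[1]], lower, upper, eta = 20, prob = 1)
    expect_true(all(m >= lower & m <= upper))
    expect_true(all(off[[2]] >= lower & off[[2]] <= upper))
  }
})

test_that("the two-stage plan frees only stochastic conductances in stage 2", {
  lib <- default_channel_library("soma")
  cell <- cell_model(point_morphology(),
                     mechanisms = c(lib[c("NaT", "Kdr", "Ih")],
                                    lib["StochKv"]),
                     passive = list(g_pas = 1e-4, e_pas = -80, cm = 1, Ra = 100),
                     parameters = cell_parameters(
                       c("gbar_NaT", "gbar_Kdr", "gbar_Ih", "gbar_StochKv"),
                       c(0.05, 0.02, 2e-4, 0.005),
                       lower = c(0.01, 0.004, 4e-5, 1e-4),
                       upper = c(0.25, 0.1, 1e-3, 0.05)))
  expect_equal(emforge:::stochastic_gbar_params(cell), "gbar_StochKv")
  suite <- default_protocol_suite(idrest_pcts = 150)
  s1 <- emforge:::drop_suite_features(suite, "burst_number")
  expect_false(any(vapply(s1$features, function(f) "burst_number" %in% f,
                          logical(1))))
  # a model without stochastic channels is a configuration error
  expect_error(run_two_stage(ground_truth_cell(), suite, noiseless_targets()),
               "stochastic")
})

test_that("a miniature two-stage run returns merged parameters", {
  lib <- default_channel_library("soma")
  cell <- cell_model(point_morphology(),
                     mechanisms = c(lib[c("NaT", "Kdr", "Kslow", "Ih")],
                                    lib["StochKv"]),
                     passive = list(g_pas = 1e-4, e_pas = -80, cm = 1, Ra = 100),
                     parameters = cell_parameters(
                       c("gbar_NaT", "gbar_Kdr", "gbar_Kslow", "gbar_Ih",
                         "gbar_StochKv"),
                       c(0.05, 0.02, 0.003, 2e-4, 0.002),
                       lower = c(0.01, 0.004, 6e-4, 4e-5, 1e-4),
                       upper = c(0.25, 0.1, 0.015, 1e-3, 0.02)))
  out <- run_two_stage(
    cell, default_protocol_suite(idrest_pcts = 150), noiseless_targets(),
    stage1_config = optimization_config(offspring = 6, generations = 1, seed = 1),
    stage2_config = optimization_config(offspring = 4, generations = 1, seed = 1))
  expect_equal(out$stage2_free, "gbar_StochKv")
  expect_setequal(names(out$parameters),
                  c("gbar_NaT", "gbar_Kdr", "gbar_Kslow", "gbar_Ih",
                    "gbar_StochKv"))
  expect_equal(names(out$stage2$best), "gbar_StochKv")
})
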