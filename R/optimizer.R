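# Indicator-based evolutionary algorithm (IBEA) for multi-objective model
# fitting, plus the two-stage procedure for e-types with stochastic channels.
#
# Fitness follows the additive-epsilon-indicator scheme: objectives are
# normalized to [0, 1] over the current pool, I(x, y) is the smallest shift
# by which x weakly dominates y, and F(x) = sum_{y != x} -exp(-I(y, x) /
# (c * kappa)) with c the largest |I|. Environmental selection removes the
# worst individual and adds its indicator contribution back to the
# survivors, mu times. Variation is simulated-binary crossover plus bounded
# polynomial mutation on the native (un-normalized) parameter scale.

#' Optimizer configuration
#'
#' @param offspring offspring (and parent) population size, default 256
#' @param generations number of generations, default 100
#' @param seed integer RNG seed
#' @param kappa indicator scaling factor
#' @param cx_prob crossover probability per pair
#' @param cx_eta simulated-binary crossover distribution index
#' @param mut_eta polynomial-mutation distribution index
#' @param mut_prob per-gene mutation probability
#' @export
optimization_config <- function(offspring = 256, generations = 100, seed = 1L,
                                kappa = 0.01, cx_prob = 1, cx_eta = 10,
                                mut_eta = 20, mut_prob = 0.5) {
  stopifnot(offspring >= 2, generations >= 1)
  list(offspring = as.integer(offspring), generations = as.integer(generations),
       seed = as.integer(seed), kappa = kappa, cx_prob = cx_prob,
       cx_eta = cx_eta, mut_eta = mut_eta, mut_prob = mut_prob)
}

# pairwise additive-epsilon indicator on a normalized objective matrix:
# I[i, j] = max_k (obj[i, k] - obj[j, k])
eps_indicator <- function(norm_obj) {
  n <- nrow(norm_obj)
  I <- matrix(0, n, n)
  for (i in seq_len(n))
    I[i, ] <- apply(norm_obj[rep(i, n), , drop = FALSE] - norm_obj, 1, max)
  I
}

# Objectives are clipped at `clip`, then normalized per objective by a
# robust range [min, 75th percentile] and capped at 2. A failed individual
# carrying a clipped score would otherwise define the whole scale and
# compress every viable individual onto a sliver of it, erasing the
# indicator's resolution exactly where selection matters; with the robust
# range, failures saturate instead of dominating the normalization.
normalize_objectives <- function(obj, clip = 250) {
  obj <- pmin(obj, clip)
  lo <- apply(obj, 2, min)
  hi <- apply(obj, 2, stats::quantile, probs = 0.75, names = FALSE)
  span <- hi - lo
  span[span == 0] <- 1
  out <- sweep(sweep(obj, 2, lo), 2, span, "/")
  pmin(out, 2)
}

ibea_fitness <- function(obj, kappa = 0.05, clip = 250) {
  I <- eps_indicator(normalize_objectives(obj, clip))
  c_ <- max(abs(I)); if (c_ == 0) c_ <- 1
  E <- exp(-I / (c_ * kappa))
  diag(E) <- 0
  list(fitness = -colSums(E), E = E)
}

# environmental selection: repeatedly drop the worst-fitness individual,
# updating survivors' fitness by adding its column contribution back
ibea_select <- function(obj, mu, kappa = 0.05, clip = 250) {
  ft <- ibea_fitness(obj, kappa, clip)
  alive <- rep(TRUE, nrow(obj))
  fit <- ft$fitness
  while (sum(alive) > mu) {
    worst <- which(alive)[which.min(fit[alive])]
    alive[worst] <- FALSE
    fit <- fit + ft$E[worst, ]
  }
  which(alive)
}

sbx_crossover <- function(p1, p2, lower, upper, eta, prob) {
  if (stats::runif(1) > prob) return(list(p1, p2))
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(p, lower, upper, eta, prob) {
  do_mut <- stats::runif(length(p)) < prob
  if (!any(do_mut)) return(p)
  u <- stats::runif(sum(do_mut))
  span <- (upper - lower)[do_mut]
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  p[do_mut] <- p[do_mut] + delta * span
  pmin(pmax(p, lower), upper)
}

tournament <- function(fit) {
  i <- sample.int(length(fit), 2)
  if (fit[i[1]] >= fit[i[2]]) i[1] else i[2]
}

#' Run an IBEA optimization
#'
#' @param evaluate function mapping a named parameter vector to a numeric
#'   vector of non-negative objective scores; it must be total (failures
#'   return clipped scores, never throw)
#' @param bounds tibble with columns name, lower, upper for the free
#'   parameters (native units; the genome is not rescaled)
#' @param config an [optimization_config()]
#' @param clip objective clipping value applied before normalization
#' @param progress optional function(generation, best_total) for logging
#' @return an `emf_optim_fit`: best individual (all-time minimum total
#'   score), final population, per-generation convergence log
#' @export
ibea_run <- function(evaluate, bounds, config = optimization_config(),
                     clip = 250, progress = NULL) {
  n <- nrow(bounds)
  lower <- bounds$lower; upper <- bounds$upper
  mut_prob <- config$mut_prob %||% 0.5
  mu <- config$offspring

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # Latin-hypercube initial population: one sample per stratum and
  # dimension, independently permuted, for even coverage at small mu
  pop <- vapply(seq_len(n), function(j) {
    u <- (sample.int(mu) - stats::runif(mu)) / mu
    lower[j] + u * (upper[j] - lower[j])
  }, numeric(mu))
  pop <- matrix(pop, nrow = mu, dimnames = list(NULL, bounds$name))
  eval_pop <- function(P) {
    rows <- lapply(seq_len(nrow(P)), function(i)
      evaluate(stats::setNames(P[i, ], bounds$name)))
    matrix(unlist(rows), nrow = nrow(P), byrow = TRUE)
  }
  obj <- pmin(eval_pop(pop), clip)

  best_par <- NULL; best_total <- Inf
  note_best <- function(P, O) {
    tot <- rowSums(O)
    i <- which.min(tot)
    if (tot[i] < best_total) {
      best_total <<- tot[i]; best_par <<- P[i, ]
    }
  }
  note_best(pop, obj)
  log <- list(tibble(generation = 0L, best_total = best_total,
                     pop_best_total = min(rowSums(obj))))

  for (gen in seq_len(config$generations)) {
    ft <- ibea_fitness(obj, config$kappa, clip)$fitness
    children <- matrix(NA_real_, mu, n)
    i <- 1L
    while (i <= mu) {
      a <- pop[tournament(ft), ]; b <- pop[tournament(ft), ]
      off <- sbx_crossover(a, b, lower, upper, config$cx_eta, config$cx_prob)
      children[i, ] <- poly_mutation(off[[1]], lower, upper, config$mut_eta, mut_prob)
      if (i + 1L <= mu)
        children[i + 1L, ] <- poly_mutation(off[[2]], lower, upper,
                                            config$mut_eta, mut_prob)
      i <- i + 2L
    }
    cobj <- pmin(eval_pop(children), clip)
    note_best(children, cobj)
    pool <- rbind(pop, children)
    pobj <- rbind(obj, cobj)
    keep <- ibea_select(pobj, mu, config$kappa, clip)
    pop <- pool[keep, , drop = FALSE]
    obj <- pobj[keep, , drop = FALSE]
    log[[gen + 1L]] <- tibble(generation = gen, best_total = best_total,
                              pop_best_total = min(rowSums(obj)))
    if (!is.null(progress)) progress(gen, best_total)
  }

  structure(list(best = stats::setNames(best_par, bounds$name),
                 best_total = best_total, population = pop, objectives = obj,
                 convergence = dplyr::bind_rows(log), bounds = bounds,
                 config = config),
            class = "emf_optim_fit")
}

#' @export
print.emf_optim_fit <- function(x, ...) {
  cat(sprintf("<IBEA fit: %d params, offspring %d x %d generations, best total %.3f>\n",
              nrow(x$bounds), x$config$offspring, x$config$generations,
              x$best_total))
  invisible(x)
}

#' Tidy the best parameter vector of an optimization
#' @param x an `emf_optim_fit`
#' @param ... unused
#' @export
tidy.emf_optim_fit <- function(x, ...) {
  tibble(parameter = names(x$best), estimate = unname(x$best),
         lower = x$bounds$lower, upper = x$bounds$upper)
}

#' One-row optimization summary
#' @param x an `emf_optim_fit`
#' @param ... unused
#' @export
glance.emf_optim_fit <- function(x, ...) {
  tibble(best_total = x$best_total, offspring = x$config$offspring,
         generations = x$config$generations, n_params = nrow(x$bounds),
         seed = x$config$seed)
}

#' Build an evaluator closure for a cell model
#'
#' Returns a total function mapping a named vector of free parameter values
#' to the per-target score vector of [evaluate_emodel()].
#'
#' @param cell a cell model
#' @param suite protocol suite
#' @param targets extraction result
#' @param mode gating mode for stochastic channels
#' @param ... passed to [evaluate_emodel()]
#' @export
make_evaluator <- function(cell, suite, targets, mode = "deterministic", ...) {
  cell <- ensure_geometry(cell)
  template <- NULL
  function(params) {
    rep_ <- tryCatch(
      evaluate_emodel(set_parameters(cell, params), suite, targets,
                      mode = mode, ...),
      error = function(e) NULL)
    if (is.null(rep_)) {
      if (is.null(template)) abort("evaluator failed on first call")
      return(rep(250, length(template)))
    }
    if (is.null(template)) template <<- rep_$scores$feature
    stats::setNames(rep_$scores$score,
                    paste(rep_$scores$protocol, rep_$scores$feature, sep = "."))
  }
}

#' Optimize a cell model against targets
#'
#' Convenience wrapper: builds the evaluator over the model's free
#' parameters and runs IBEA.
#'
#' @inheritParams make_evaluator
#' @param config an [optimization_config()]
#' @return an `emf_optim_fit`
#' @export
optimize_emodel <- function(cell, suite, targets,
                            config = optimization_config(),
                            mode = "deterministic", ...) {
  free <- cell$parameters[!cell$parameters$frozen, ]
  bounds <- tibble(name = free$name, lower = free$lower, upper = free$upper)
  ev <- make_evaluator(cell, suite, targets, mode = mode, ...)
  ibea_run(ev, bounds, config)
}

#' Two-stage optimization for stochastic-channel e-types
#'
#' Stage 1 optimizes all free parameters with stochastic channels forced to
#' deterministic mode, on a feature set excluding the burst number. Stage 2
#' starts from the stage-1 optimum, freezes every parameter except the
#' stochastic channel maximal conductances, re-enables stochasticity and
#' optimizes against burst-number and ISI targets only. Returns the merged
#' parameter vector with both stage fits.
#'
#' @param cell a cell model containing at least one stochastic channel
#' @param suite optimization protocol suite
#' @param targets extraction result
#' @param stage1_config,stage2_config [optimization_config()]s
#' @param stage2_features feature names scored in stage 2
#' @export
run_two_stage <- function(cell, suite, targets,
                          stage1_config = optimization_config(),
                          stage2_config = optimization_config(generations = 20),
                          stage2_features = c("burst_number", "ISI_CV",
                                              "inv_first_ISI", "inv_second_ISI",
                                              "inv_last_ISI", "ISI_values")) {
  stoch_params <- stochastic_gbar_params(cell)
  if (!length(stoch_params))
    abort("two-stage plan requires a model with stochastic channels")

  s1_suite <- drop_suite_features(suite, "burst_number")
  s1_targets <- targets[targets$feature != "burst_number", ]
  fit1 <- optimize_emodel(cell, s1_suite, s1_targets, stage1_config,
                          mode = "deterministic")

  cell2 <- set_parameters(cell, fit1$best)
  cell2$parameters$frozen <- !(cell2$parameters$name %in% stoch_params)
  s2_suite <- keep_suite_features(suite, stage2_features)
  s2_targets <- targets[targets$feature %in% stage2_features, ]
  fit2 <- optimize_emodel(cell2, s2_suite, s2_targets, stage2_config,
                          mode = "stochastic")

  merged <- fit1$best
  merged[names(fit2$best)] <- fit2$best
  list(parameters = merged, stage1 = fit1, stage2 = fit2,
       stage2_free = stoch_params)
}

stochastic_gbar_params <- function(cell) {
  unname(unlist(lapply(cell$mechanisms, function(m)
    if (inherits(m, "emf_stoch_channel")) m$gbar_param)))
}

drop_suite_features <- function(suite, drop) {
  suite$features <- lapply(suite$features, setdiff, y = drop)
  suite[lengths(suite$features) > 0, ]
}

keep_suite_features <- function(suite, keep) {
  suite$features <- lapply(suite$features, intersect, y = keep)
  special <- suite$protocol %in% c("RMP", "Rin", "RinHoldCurrent", "Threshold")
  suite[lengths(suite$features) > 0 | special, ]
}

#' Write an optimization checkpoint as JSON
#' @param fit an `emf_optim_fit`
#' @param path JSON path
#' @export
write_checkpoint_json <- function(fit, path) {
  jsonlite::write_json(list(best = as.list(fit$best),
                            best_total = fit$best_total,
                            population = fit$population,
                            objectives = fit$objectives,
                            convergence = as.data.frame(fit$convergence),
                            config = fit$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
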