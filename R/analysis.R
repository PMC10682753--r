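# Post-hoc model analysis: one-at-a-time parameter sensitivity slopes and
# currentscape-style decomposition of the somatic membrane currents.

#' Parameter sensitivity analysis
#'
#' Each free parameter is decreased one at a time by the given percentages
#' (default 10, 50 and 90%) while all others stay at their control values.
#' For every feature, the absolute score difference to the control model is
#' regressed against the perturbation percentage (ordinary least squares
#' through the points, with the control (0, 0) included); the slope is the
#' sensitivity. Perturbations that break the evaluation enter the regression
#' at the clipped maximum score. Slopes above `sensitive_above` are flagged
#' sensitive.
#'
#' @param cell a cell model that evaluates without early stop at control
#' @param suite protocol suite
#' @param targets extraction result
#' @param percentages perturbation sizes, % decrease
#' @param parameters parameter names to perturb (default: all free)
#' @param sensitive_above flag threshold on the slope
#' @param ... passed to [evaluate_emodel()]
#' @return an `emf_sensitivity` tibble: parameter, protocol, feature, slope,
#'   sensitive
#' @export
sensitivity_analysis <- function(cell, suite, targets,
                                 percentages = c(10, 50, 90),
                                 parameters = NULL, sensitive_above = 1, ...) {
  cell <- ensure_geometry(cell)
  control <- evaluate_emodel(cell, suite, targets, ...)
  if (control$early_stop)
    abort("control model early-stops; sensitivity analysis needs a viable model")
  if (is.null(parameters))
    parameters <- cell$parameters$name[!cell$parameters$frozen]

  ctrl <- control$scores
  rows <- purrr::map_dfr(parameters, function(pname) {
    v0 <- cell$parameters$value[cell$parameters$name == pname]
    per_pct <- purrr::map_dfr(percentages, function(pct) {
      pert <- set_parameters(cell, stats::setNames(v0 * (1 - pct / 100), pname))
      rep_ <- evaluate_emodel(pert, suite, targets, ...)
      dplyr::tibble(protocol = ctrl$protocol, target_pct = ctrl$target_pct,
                    feature = ctrl$feature, pct = pct,
                    d = abs(rep_$scores$score - ctrl$score))
    })
    per_pct |>
      dplyr::bind_rows(dplyr::tibble(protocol = ctrl$protocol,
                                     target_pct = ctrl$target_pct,
                                     feature = ctrl$feature, pct = 0, d = 0)) |>
      dplyr::group_by(.data$protocol, .data$target_pct, .data$feature) |>
      dplyr::summarise(slope = ols_slope(.data$pct, .data$d), .groups = "drop") |>
      dplyr::mutate(parameter = pname)
  })
  out <- rows |>
    dplyr::mutate(sensitive = .data$slope > sensitive_above) |>
    dplyr::select("parameter", "protocol", "target_pct", "feature", "slope",
                  "sensitive")
  structure(out, class = c("emf_sensitivity", class(out)))
}

# closed-form least-squares slope through (x, d)
ols_slope <- function(x, d) {
  sum((x - mean(x)) * (d - mean(d))) / sum((x - mean(x))^2)
}

#' Export a sensitivity matrix as CSV (parameters x features)
#' @param sens an `emf_sensitivity`
#' @param path CSV path
#' @export
write_sensitivity_csv <- function(sens, path) {
  wide <- sens |>
    dplyr::mutate(key = paste(.data$protocol,
                              ifelse(is.na(.data$target_pct), "",
                                     .data$target_pct),
                              .data$feature, sep = ".")) |>
    dplyr::select("parameter", "key", "slope") |>
    tidyr::pivot_wider(names_from = "key", values_from = "slope")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Currentscape decomposition of the somatic membrane currents
#'
#' Simulates a depolarizing step (by default 150% of the model's rheobase,
#' searched on the fly) while recording every mechanism's somatic membrane
#' current, splits them by sign at each time step (inward negative, outward
#' positive) and computes each mechanism's fractional contribution within
#' its sign class.
#'
#' @param cell a cell model
#' @param stimulus optional [stimulus()]; when NULL a 150%-rheobase step of
#'   `duration` ms is used
#' @param pct_rheobase step amplitude when `stimulus` is NULL, % of rheobase
#' @param duration step duration, ms
#' @param holding holding current, nA
#' @param dt time step, ms
#' @return an `emf_currentscape`: times, per-mechanism current matrix (nA),
#'   inward/outward fraction matrices and total envelopes
#' @export
currentscape <- function(cell, stimulus = NULL, pct_rheobase = 150,
                         duration = 1000, holding = 0, dt = 0.025) {
  cell <- ensure_geometry(cell)
  pre <- 100
  if (is.null(stimulus)) {
    thr <- search_threshold_current(cell, holding = holding)
    stimulus <- stimulus("step", amplitude = pct_rheobase / 100 * thr,
                         onset = pre, offset = pre + duration)
  }
  stims <- list(stimulus)
  if (holding != 0) stims <- c(list(stimulus("holding", amplitude = holding)), stims)
  trs <- simulate(cell, stims,
                  list(recording(loc("soma"), "mech_currents"),
                       recording(loc("soma"), "voltage")),
                  duration = stimulus$offset + 100, dt = dt, rec_every = 4L,
                  protocol = "currentscape")
  if (attr(trs, "diverged")) abort("model diverged under the currentscape stimulus")
  cur <- trs[[1]]$values
  colnames(cur) <- trs[[1]]$mech_names
  cur <- cur[, colSums(abs(cur)) > 0, drop = FALSE]   # drop absent mechanisms

  inw <- pmin(cur, 0); outw <- pmax(cur, 0)
  tot_in <- rowSums(inw); tot_out <- rowSums(outw)
  frac_in <- sweep(inw, 1, ifelse(tot_in == 0, 1, tot_in), "/")
  frac_out <- sweep(outw, 1, ifelse(tot_out == 0, 1, tot_out), "/")
  frac_in[tot_in == 0, ] <- NA
  frac_out[tot_out == 0, ] <- NA

  structure(list(times = trs[[1]]$times, currents = cur,
                 fraction_inward = frac_in, fraction_outward = frac_out,
                 total_inward = tot_in, total_outward = tot_out,
                 voltage = trs[[2]]$values),
            class = "emf_currentscape")
}

#' @export
print.emf_currentscape <- function(x, ...) {
  cat(sprintf("<currentscape: %d mechanisms x %d samples>\n",
              ncol(x$currents), length(x$times)))
  invisible(x)
}

#' Long-format table of a currentscape
#' @param x an `emf_currentscape`
#' @param ... unused
#' @export
as_tibble.emf_currentscape <- function(x, ...) {
  purrr::map_dfr(colnames(x$currents), function(m)
    tibble(time_ms = x$times, mechanism = m,
           current_nA = x$currents[, m],
           fraction_inward = x$fraction_inward[, m],
           fraction_outward = x$fraction_outward[, m]))
}

#' Export currentscape data as CSV
#' @param cs an `emf_currentscape`
#' @param path CSV path
#' @export
write_currentscape_csv <- function(cs, path) {
  utils::write.csv(as_tibble(cs), path, row.names = FALSE)
  invisible(path)
}
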