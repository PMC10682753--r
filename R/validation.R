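# Held-out validation: back-propagating AP and EPSP attenuation along the
# dendrites with exponential fits, and somatic validation on protocols never
# used during optimization.

#' Back-propagating action potential attenuation profile
#'
#' Injects a brief strong somatic step (defaults 5 ms, 2 nA), detects the
#' somatic spike and measures the bAP amplitude (local peak minus local
#' pre-stimulus baseline) at every dendritic segment midpoint up to
#' `max_apical` / `max_basal` um of path distance. The reported diameter is
#' the dendritic diameter at the midpoint of the path from the soma to the
#' recording site.
#'
#' @param cell a cell model
#' @param amplitude,duration somatic step, nA / ms
#' @param max_apical,max_basal maximum sampled path distances, um
#' @param dt time step, ms
#' @return an `emf_attenuation` tibble: distance_um, amplitude, kind,
#'   midpoint_diam_um (soma row at distance 0 included)
#' @export
run_bap <- function(cell, amplitude = 2, duration = 5, max_apical = 900,
                    max_basal = 150, dt = 0.025) {
  cell <- ensure_geometry(cell)
  seg <- cell$geometry$seg
  dend <- seg[(seg$type == "apical" & seg$path_mid_um <= max_apical) |
              (seg$type == "basal" & seg$path_mid_um <= max_basal), ]
  pre <- 50
  locs <- c(list(loc("soma", 0.5)),
            purrr::map(seq_len(nrow(dend)), function(i)
              loc(dend$section_id[i], dend$pos_mid[i])))
  recs <- purrr::map(locs, recording)
  trs <- simulate(cell,
                  list(stimulus("step", amplitude = amplitude, onset = pre,
                                offset = pre + duration)),
                  recs, duration = pre + duration + 45, dt = dt,
                  protocol = "bAP")
  if (attr(trs, "diverged")) abort("model diverged under the bAP stimulus")
  soma_spikes <- detect_spikes(trs[[1]])
  if (nrow(soma_spikes) == 0) abort("no somatic spike under the bAP stimulus")

  amp_of <- function(tr) {
    t <- tr$times; v <- tr$values
    base <- mean(v[t >= pre - 10 & t < pre])
    max(v[t >= pre & t <= pre + duration + 20]) - base
  }
  amps <- vapply(trs, amp_of, numeric(1))
  out <- tibble(
    distance_um = c(0, dend$path_mid_um),
    amplitude = amps,
    kind = c("soma", dend$type),
    midpoint_diam_um = c(seg$diam_um[seg$type == "soma"][1],
                         vapply(seq_len(nrow(dend)), function(i)
                           diam_at_distance(seg, dend$type[i],
                                            dend$path_mid_um[i] / 2),
                           numeric(1))))
  new_attenuation(out, "bAP")
}

diam_at_distance <- function(seg, type, d) {
  cand <- seg[seg$type == type, ]
  if (!nrow(cand)) return(NA_real_)
  cand$diam_um[which.min(abs(cand$path_mid_um - d))]
}

new_attenuation <- function(tab, what) {
  structure(tab, class = c("emf_attenuation", class(tab)), what = what)
}

#' EPSP attenuation profile
#'
#' Activates a double-exponential synaptic conductance at each dendritic
#' segment midpoint (default peaks 1.5 nS on apical, 0.2 nS on basal
#' dendrites) and reports the somatic-to-dendritic amplitude ratio, both
#' amplitudes measured from the resting potential to the EPSP maximum.
#'
#' @param cell a cell model
#' @param g_apical,g_basal synaptic peak conductances, nS
#' @param tau_rise,tau_decay synaptic kinetics, ms
#' @param dt time step, ms
#' @return an `emf_attenuation` tibble: distance_um, amplitude (the ratio,
#'   in (0, 1] for passive dendrites), kind, midpoint_diam_um
#' @export
run_epsp_attenuation <- function(cell, g_apical = 1.5, g_basal = 0.2,
                                 tau_rise = 0.5, tau_decay = 5, dt = 0.025) {
  cell <- ensure_geometry(cell)
  seg <- cell$geometry$seg
  dend <- seg[seg$type %in% c("apical", "basal"), ]
  onset <- 50
  rows <- purrr::map_dfr(seq_len(nrow(dend)), function(i) {
    g <- if (dend$type[i] == "apical") g_apical else g_basal
    syn <- synapse_spec(g, tau_rise, tau_decay,
                        location = loc(dend$section_id[i], dend$pos_mid[i]))
    trs <- simulate_epsp(cell, syn, onset = onset, duration = 250, dt = dt)
    if (attr(trs, "diverged")) return(tibble())
    amp <- function(tr) {
      t <- tr$times; v <- tr$values
      max(v[t >= onset]) - mean(v[t >= onset - 10 & t < onset])
    }
    local <- amp(trs[[1]]); soma <- amp(trs[[2]])
    tibble(distance_um = dend$path_mid_um[i],
           amplitude = if (local > 0) soma / local else NA_real_,
           kind = dend$type[i],
           midpoint_diam_um = diam_at_distance(seg, dend$type[i],
                                               dend$path_mid_um[i] / 2))
  })
  new_attenuation(rows, "EPSP")
}

#' Fit an exponential attenuation profile
#'
#' Least-squares fit of `y = A * exp(-x / lambda)` by Levenberg-Marquardt.
#' A profile that does not decay (constant, or fitted length constant far
#' beyond the sampled range) is flagged ill-conditioned rather than erroring.
#'
#' @param profile an `emf_attenuation` (or any data frame with distance_um
#'   and amplitude), typically filtered to one dendrite kind
#' @param kind optional filter on the `kind` column
#' @return an `emf_exp_fit`: amplitude `A`, length constant `lambda` (um)
#'   with standard error, residual norm, convergence and conditioning flags
#' @export
fit_attenuation <- function(profile, kind = NULL) {
  df <- as.data.frame(profile)
  if (!is.null(kind)) df <- df[df$kind %in% kind, ]
  df <- df[is.finite(df$amplitude) & is.finite(df$distance_um), ]
  if (nrow(df) < 3) abort("need at least 3 points to fit an exponential")
  span <- max(df$distance_um) - min(df$distance_um)
  fit <- tryCatch(
    minpack.lm::nlsLM(amplitude ~ A * exp(-distance_um / lambda), data = df,
                      start = list(A = max(df$amplitude),
                                   lambda = max(span / 2, 1)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, lambda = NA_real_,
                          lambda_se = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, ill_conditioned = TRUE,
                          n = nrow(df)), class = "emf_exp_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["lambda", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(A = unname(co["A"]), lambda = unname(co["lambda"]),
                 lambda_se = se,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 ill_conditioned = unname(co["lambda"]) > 50 * max(df$distance_um),
                 n = nrow(df)),
            class = "emf_exp_fit")
}

#' @export
print.emf_exp_fit <- function(x, ...) {
  cat(sprintf("<exponential fit: A = %.2f, lambda = %.1f um (se %.2g), n = %d%s>\n",
              x$A, x$lambda, x$lambda_se, x$n,
              if (x$ill_conditioned) ", ILL-CONDITIONED" else ""))
  invisible(x)
}

#' @export
tidy.emf_exp_fit <- function(x, ...) {
  tibble(term = c("A", "lambda"), estimate = c(x$A, x$lambda),
         std.error = c(NA_real_, x$lambda_se))
}

#' @export
glance.emf_exp_fit <- function(x, ...) {
  tibble(A = x$A, lambda_um = x$lambda, lambda_se = x$lambda_se,
         residual_norm = x$residual_norm, n = x$n,
         converged = x$converged, ill_conditioned = x$ill_conditioned)
}

#' Somatic validation on held-out protocols
#'
#' Scores the model on Ramp / sAHP / IDHyperpol targets (never used during
#' optimization) with the documented feature-window routing, and summarizes
#' a pass/fail per feature at `sd_threshold` standard deviations.
#'
#' @param cell a cell model
#' @param suite a [validation_protocol_suite()]
#' @param targets extraction result built from held-out recordings
#' @param sd_threshold pass/fail limit in SD units (default 5)
#' @param ... passed to [evaluate_emodel()]
#' @return list with the full `emf_score_report` and a `summary` tibble
#'   (feature, score, pass)
#' @export
somatic_validation <- function(cell, suite = validation_protocol_suite(),
                               targets, sd_threshold = 5, ...) {
  report <- evaluate_emodel(cell, suite, targets, ...)
  summary <- report$scores |>
    dplyr::mutate(pass = .data$score < sd_threshold) |>
    dplyr::select("protocol", "target_pct", "feature", "score", "pass")
  list(report = report, summary = summary,
       n_pass = sum(summary$pass), n_total = nrow(summary))
}

#' Export a validation result as JSON
#' @param validation result of [somatic_validation()]
#' @param path JSON path
#' @export
write_validation_json <- function(validation, path) {
  jsonlite::write_json(list(summary = as.data.frame(validation$summary),
                            total = validation$report$total,
                            n_pass = validation$n_pass,
                            n_total = validation$n_total),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
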