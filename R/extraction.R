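# Turn per-cell recordings into e-type feature targets: rheobase
# normalization, tolerance binning around relative targets, within-cell then
# cross-cell averaging.

#' Bundle the recordings of one cell
#'
#' @param cell_id cell identifier
#' @param e_type electrical-type label
#' @param traces list of voltage `emf_trace`s, each carrying a protocol name
#'   and absolute stimulus amplitude (nA)
#' @param holding_current holding current applied during the session, nA
#' @export
cell_recording_set <- function(cell_id, e_type = "generic", traces = list(),
                               holding_current = 0) {
  for (tr in traces)
    if (is.na(tr$stim_onset) || is.na(tr$stim_offset))
      abort("every recording needs stimulus onset/offset metadata")
  structure(list(cell_id = cell_id, e_type = e_type, traces = traces,
                 holding_current = holding_current),
            class = "emf_cell_recordings")
}

#' @export
print.emf_cell_recordings <- function(x, ...) {
  cat(sprintf("<recordings '%s' (%s): %d sweeps [%s]>\n", x$cell_id, x$e_type,
              length(x$traces),
              paste(unique(vapply(x$traces, `[[`, character(1), "protocol")),
                    collapse = ", ")))
  invisible(x)
}

#' Rheobase of a recorded cell
#'
#' The lowest absolute stimulus amplitude among the cell's IDrest/IDthresh
#' sweeps that elicits at least one spike. Holding sweeps and other
#' protocols are ignored.
#'
#' @param cell a [cell_recording_set()]
#' @param threshold spike detection threshold, mV
#' @return rheobase in nA
#' @export
compute_cell_rheobase <- function(cell, threshold = -30) {
  protos <- vapply(cell$traces, `[[`, character(1), "protocol")
  cand <- cell$traces[protos %in% c("IDrest", "IDthresh")]
  if (!length(cand)) abort(sprintf("cell '%s' has no IDrest/IDthresh recording",
                                   cell$cell_id))
  amps <- vapply(cand, `[[`, numeric(1), "stim_amp")
  spiking <- vapply(cand, function(tr) nrow(detect_spikes(tr, threshold)) > 0,
                    logical(1))
  if (!any(spiking)) abort(sprintf("cell '%s': no spiking recording", cell$cell_id))
  min(amps[spiking])
}

#' Target specification for extraction
#'
#' @param protocol protocol name; `"IDrest"` also matches `"IDthresh"` sweeps
#' @param target_pct target amplitude as % of rheobase; `NA` matches every
#'   sweep of the protocol regardless of amplitude (used for fixed-amplitude
#'   protocols such as the Rin step)
#' @param tolerance binning half-width, % of rheobase (default 10, giving
#'   e.g. an inclusion window of exactly `[140, 160]`% for a 150% target)
#' @param features feature names to extract
#' @export
target_spec <- function(protocol, target_pct, tolerance = 10, features,
                        route = list()) {
  stopifnot(tolerance > 0)
  tibble(protocol = protocol, target_pct = target_pct, tolerance = tolerance,
         features = list(features), route = list(route))
}

#' Bin recordings at relative targets and average features across cells
#'
#' Each sweep's amplitude is expressed as % of its own cell's rheobase; for a
#' target T with tolerance tol, sweeps with relative amplitude in the closed
#' window `[T - tol, T + tol]` contribute. Features are computed per sweep,
#' averaged within each cell, then averaged with equal weight across cells
#' (so cells with many sweeps do not dominate). Invalid feature values are
#' dropped before averaging. Two search-based targets are added from session
#' metadata: `bpo_threshold_current` (the per-cell rheobase, protocol
#' `"Threshold"`) and `bpo_holding_current` (the per-cell holding current,
#' protocol `"RinHoldCurrent"`).
#'
#' @param cells list of [cell_recording_set()]s
#' @param targets tibble of [target_spec()] rows
#' @param threshold spike detection threshold, mV
#' @param sd_floor_rel,sd_floor_abs the sd floor used for scoring:
#'   `max(sd, sd_floor_rel * |mean| + sd_floor_abs)` keeps Z scores finite
#'   when all cells agree and represents a minimal biological coefficient of
#'   variation (default 5%) so the cost landscape stays informative when a
#'   target comes from a single cell; floored entries are flagged
#' @return an `emf_extraction_result` tibble: protocol, target_pct, feature,
#'   mean, sd, sd_eff, n_cells, sd_floored
#' @export
bin_and_average <- function(cells, targets, threshold = -30,
                            sd_floor_rel = 0.05, sd_floor_abs = 1e-6) {
  rheo <- vapply(cells, compute_cell_rheobase, numeric(1), threshold = threshold)

  rows <- list()
  for (ti in seq_len(nrow(targets))) {
    tg <- targets[ti, ]
    feats <- tg$features[[1]]
    match_protos <- if (tg$protocol == "IDrest") c("IDrest", "IDthresh") else tg$protocol
    per_cell <- purrr::map_dfr(seq_along(cells), function(ci) {
      cell <- cells[[ci]]
      protos <- vapply(cell$traces, `[[`, character(1), "protocol")
      trs <- cell$traces[protos %in% match_protos]
      if (!is.na(tg$target_pct)) {
        rel <- vapply(trs, `[[`, numeric(1), "stim_amp") / rheo[ci] * 100
        # closed window on both sides, with a rounding guard at the edges
        trs <- trs[rel >= tg$target_pct - tg$tolerance - 1e-9 &
                   rel <= tg$target_pct + tg$tolerance + 1e-9]
      }
      if (!length(trs)) return(tibble())
      route <- tg$route[[1]]
      sweep_vals <- purrr::map_dfr(trs, function(tr)
        purrr::map_dfr(feats, function(f) {
          fv <- compute_feature(apply_route(tr, route[[f]] %||% "stim"), f,
                                threshold = threshold)
          tibble(name = f, value = fv$value, valid = fv$valid)
        }))
      sweep_vals |>
        dplyr::filter(.data$valid) |>
        dplyr::group_by(.data$name) |>
        dplyr::summarise(cell_value = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(cell_id = cell$cell_id)
    })
    if (!nrow(per_cell)) next
    rows[[length(rows) + 1]] <- per_cell |>
      dplyr::group_by(feature = .data$name) |>
      dplyr::summarise(mean = mean(.data$cell_value),
                       sd = if (dplyr::n() > 1) stats::sd(.data$cell_value) else 0,
                       n_cells = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(protocol = tg$protocol, target_pct = tg$target_pct)
  }

  # search-based targets from session metadata
  hold <- vapply(cells, `[[`, numeric(1), "holding_current")
  rows[[length(rows) + 1]] <- tibble(
    feature = c("bpo_threshold_current", "bpo_holding_current"),
    mean = c(mean(rheo), mean(hold)),
    sd = c(if (length(rheo) > 1) stats::sd(rheo) else 0,
           if (length(hold) > 1) stats::sd(hold) else 0),
    n_cells = length(cells),
    protocol = c("Threshold", "RinHoldCurrent"), target_pct = NA_real_)

  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      sd_eff = pmax(.data$sd, sd_floor_rel * abs(.data$mean) + sd_floor_abs),
      sd_floored = .data$sd_eff > .data$sd) |>
    dplyr::select("protocol", "target_pct", "feature", "mean", "sd", "sd_eff",
                  "n_cells", "sd_floored")
  class(out) <- c("emf_extraction_result", class(out))
  out
}

#' Write / read extraction targets as JSON
#' @param result an extraction result
#' @param path JSON path
#' @export
write_targets_json <- function(result, path) {
  jsonlite::write_json(as.data.frame(result), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_targets_json
#' @export
read_targets_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(df)
  out$target_pct <- as.numeric(out$target_pct)
  class(out) <- c("emf_extraction_result", class(out))
  out
}

#' Write a set of recordings as a JSON trace bundle (with per-sweep CSV
#' alternative via [write_trace_csv()])
#' @param cells list of [cell_recording_set()]s
#' @param path JSON path
#' @export
write_trace_bundle <- function(cells, path) {
  ser <- lapply(cells, function(cell) list(
    cell_id = cell$cell_id, e_type = cell$e_type,
    holding_current = cell$holding_current,
    traces = lapply(cell$traces, function(tr) list(
      times = tr$times, values = tr$values, kind = tr$kind,
      location = tr$location, protocol = tr$protocol,
      stim_onset = tr$stim_onset, stim_offset = tr$stim_offset,
      stim_amp = tr$stim_amp, phases = tr$phases))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_bundle
#' @export
read_trace_bundle <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(cell) cell_recording_set(
    cell$cell_id, cell$e_type,
    traces = lapply(cell$traces, function(tr)
      new_trace(unlist(tr$times), unlist(tr$values), tr$kind, tr$location,
                tr$protocol, tr$stim_onset, tr$stim_offset, tr$stim_amp,
                phases = lapply(tr$phases, unlist))),
    holding_current = cell$holding_current))
}

#' Export a single trace as CSV (time_ms, value)
#' @param trace an `emf_trace`
#' @param path CSV path
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as_tibble(trace), path, row.names = FALSE)
  invisible(path)
}
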