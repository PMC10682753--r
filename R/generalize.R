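# Generalization of an optimized e-model across a morphology population:
# per-feature acceptance gating against the exemplar scores, and the
# m-type x e-type acceptance matrix.

#' Allowed e-types per morphological type
#'
#' The me-combination rule: each m-type maps to the list of e-model types
#' that may be paired with it during generalization.
#'
#' @param m_type character vector of m-type labels
#' @param e_types list of character vectors, one per m-type (each non-empty)
#' @return an `emf_combo_map` tibble
#' @export
combo_map <- function(m_type, e_types) {
  if (!is.list(e_types)) e_types <- list(e_types)
  if (any(lengths(e_types) == 0))
    abort("every m-type must map to at least one e-type")
  structure(tibble(m_type = m_type, e_types = e_types),
            class = c("emf_combo_map", class(tibble())))
}

#' @param map an `emf_combo_map`
#' @rdname combo_map
#' @export
allowed_etypes <- function(map, m_type) {
  hit <- which(map$m_type == m_type)
  if (!length(hit)) character(0) else map$e_types[[hit[1]]]
}

#' Acceptance threshold for a feature score
#'
#' A morphology-model combination is accepted when every feature score on
#' the new morphology stays strictly below `max(5, 5 * s_e)` where `s_e` is
#' the exemplar morphology's score for the same feature: perfect exemplar
#' features still tolerate scores up to 5, and poorly-fit exemplar features
#' scale the allowance proportionally.
#'
#' @param exemplar_score exemplar score(s), >= 0 (vectorized)
#' @return the threshold(s)
#' @export
acceptance_threshold <- function(exemplar_score) {
  stopifnot(all(exemplar_score >= 0))
  pmax(5, 5 * exemplar_score)
}

#' Evaluate an e-model on a swapped-in morphology
#'
#' Runs the full four-step evaluation (including a fresh holding/threshold
#' search on the new morphology), compares every feature score with the
#' exemplar's and applies the strict-inequality acceptance rule. Non-firing
#' morphologies are rejected with reason "subthreshold".
#'
#' @param morph the candidate morphology
#' @param cell the optimized e-model (on its exemplar morphology)
#' @param suite protocol suite used for the optimization
#' @param targets extraction result
#' @param exemplar_report the e-model's [evaluate_emodel()] report on its own
#'   exemplar morphology with the same suite
#' @param ... passed to [evaluate_emodel()]
#' @return an `emf_combo_result`
#' @export
evaluate_combo <- function(morph, cell, suite, targets, exemplar_report, ...) {
  cell2 <- cell
  cell2$morphology <- morph
  cell2$geometry <- NULL
  report <- evaluate_emodel(cell2, suite, targets, ...)

  cmp <- dplyr::inner_join(
    report$scores |> dplyr::rename(score_combo = "score") |>
      dplyr::select(-"model_value"),
    exemplar_report$scores |> dplyr::rename(score_exemplar = "score") |>
      dplyr::select(-"model_value"),
    by = c("protocol", "target_pct", "feature")) |>
    dplyr::mutate(threshold = acceptance_threshold(.data$score_exemplar),
                  pass = .data$score_combo < .data$threshold)

  accepted <- all(cmp$pass)
  reason <- if (report$subthreshold) "subthreshold"
            else if (report$early_stop) "early_stop"
            else if (!accepted) "feature_scores" else NA_character_
  structure(list(
    morphology_id = morph$name, m_type = morph$m_type,
    emodel_id = cell$name, e_type = cell$e_type,
    scores = cmp, accepted = accepted,
    failing_features = cmp$feature[!cmp$pass], reason = reason,
    total_combo = report$total, total_exemplar = exemplar_report$total,
    ais_surface_um2 = surface_area(morph, "AIS_proxy"),
    dendrite_surface_um2 = surface_area(morph, "proximal_dendrites")),
    class = "emf_combo_result")
}

#' @export
print.emf_combo_result <- function(x, ...) {
  cat(sprintf("<me-combo %s x %s: %s%s>\n", x$morphology_id, x$emodel_id,
              if (x$accepted) "ACCEPTED" else "rejected",
              if (!x$accepted) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Acceptance structure of a generalization run
#'
#' @param results list of [evaluate_combo()] results
#' @return an `emf_generalization` list: `matrix` (fraction accepted per
#'   m-type x e-type, with counts), `by_etype` marginals, and `scatter` (one
#'   row per combo: AIS and proximal dendritic surface areas vs acceptance,
#'   the surface-analysis table)
#' @export
generalization_report <- function(results) {
  stopifnot(length(results) > 0)
  tab <- purrr::map_dfr(results, function(r)
    tibble(morphology_id = r$morphology_id, m_type = r$m_type,
           emodel_id = r$emodel_id, e_type = r$e_type,
           accepted = r$accepted, reason = r$reason,
           total_combo = r$total_combo,
           ais_surface_um2 = r$ais_surface_um2,
           dendrite_surface_um2 = r$dendrite_surface_um2))
  mat <- tab |>
    dplyr::group_by(.data$m_type, .data$e_type) |>
    dplyr::summarise(n = dplyr::n(), n_accepted = sum(.data$accepted),
                     fraction_accepted = mean(.data$accepted),
                     .groups = "drop")
  by_etype <- tab |>
    dplyr::group_by(.data$e_type) |>
    dplyr::summarise(n = dplyr::n(), fraction_accepted = mean(.data$accepted),
                     .groups = "drop")
  structure(list(matrix = mat, by_etype = by_etype, scatter = tab),
            class = "emf_generalization")
}

#' @export
print.emf_generalization <- function(x, ...) {
  cat(sprintf("<generalization: %d combos, %.0f%% accepted>\n",
              nrow(x$scatter), 100 * mean(x$scatter$accepted)))
  print(x$matrix)
  invisible(x)
}

#' Export the acceptance matrix as CSV
#' @param report an `emf_generalization`
#' @param path CSV path
#' @export
write_generalization_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report$matrix), path, row.names = FALSE)
  invisible(path)
}
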