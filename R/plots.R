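# ggplot2 presentations of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_area labs theme_minimal scale_fill_viridis_c facet_wrap
NULL

#' Plot a trace
#' @param object an `emf_trace`
#' @param ... unused
#' @export
autoplot.emf_trace <- function(object, ...) {
  df <- as_tibble(object)
  if (!"value" %in% names(df))
    df <- tidyr::pivot_longer(df, -"time_ms", names_to = "mechanism",
                              values_to = "value")
  p <- ggplot(df, aes(x = .data$time_ms, y = .data$value)) +
    labs(x = "time (ms)",
         y = switch(object$kind, voltage = "V (mV)", calcium = "[Ca] (mM)",
                    "I (nA)"),
         title = sprintf("%s @ %s (%s)", object$kind, object$location,
                         object$protocol)) +
    theme_minimal()
  if ("mechanism" %in% names(df))
    p + geom_line(aes(color = .data$mechanism))
  else p + geom_line()
}

#' Plot an attenuation profile with its exponential fit
#' @param object an `emf_attenuation`
#' @param fit optional [fit_attenuation()] result overlay
#' @param ... unused
#' @export
autoplot.emf_attenuation <- function(object, fit = NULL, ...) {
  df <- as.data.frame(object)
  p <- ggplot(df, aes(x = .data$distance_um, y = .data$amplitude,
                      color = .data$kind)) +
    geom_point() +
    labs(x = "path distance from soma (um)",
         y = if (attr(object, "what") == "bAP") "bAP amplitude (mV)"
             else "soma / dendrite EPSP ratio",
         title = paste(attr(object, "what"), "attenuation")) +
    theme_minimal()
  if (!is.null(fit) && is.finite(fit$lambda)) {
    xs <- seq(0, max(df$distance_um), length.out = 100)
    p <- p + geom_line(data = data.frame(distance_um = xs,
                                         amplitude = fit$A * exp(-xs / fit$lambda),
                                         kind = "fit"),
                       linetype = 2)
  }
  p
}

#' Stacked-fraction currentscape plot
#' @param object an `emf_currentscape`
#' @param ... unused
#' @export
autoplot.emf_currentscape <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("fraction_inward", "fraction_outward"),
                        names_to = "side", values_to = "fraction") |>
    dplyr::mutate(fraction = abs(.data$fraction),
                  side = sub("fraction_", "", .data$side))
  ggplot(df, aes(x = .data$time_ms, y = .data$fraction,
                 fill = .data$mechanism)) +
    geom_area(position = "stack", na.rm = TRUE) +
    facet_wrap(~side, ncol = 1) +
    labs(x = "time (ms)", y = "fraction of total current",
         title = "currentscape") +
    theme_minimal()
}

#' Sensitivity heatmap (parameters x features)
#' @param object an `emf_sensitivity`
#' @param ... unused
#' @export
autoplot.emf_sensitivity <- function(object, ...) {
  df <- as.data.frame(object)
  df$key <- paste(df$protocol,
                  ifelse(is.na(df$target_pct), "", df$target_pct),
                  df$feature)
  ggplot(df, aes(x = .data$key, y = .data$parameter, fill = .data$slope)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "sensitivity",
         title = "parameter sensitivity (slope of score vs perturbation)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Acceptance-matrix heatmap
#' @param object an `emf_generalization`
#' @param ... unused
#' @export
autoplot.emf_generalization <- function(object, ...) {
  ggplot(object$matrix, aes(x = .data$e_type, y = .data$m_type,
                            fill = .data$fraction_accepted)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "e-type", y = "m-type", fill = "accepted",
         title = "generalization acceptance") +
    theme_minimal()
}

#' Convergence plot of an optimization
#' @param object an `emf_optim_fit`
#' @param ... unused
#' @export
autoplot.emf_optim_fit <- function(object, ...) {
  ggplot(object$convergence, aes(x = .data$generation, y = .data$best_total)) +
    geom_line() +
    labs(x = "generation", y = "best total score (all-time)",
         title = "IBEA convergence") +
    theme_minimal()
}
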