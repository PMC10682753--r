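# Synthetic-data generators: ground-truth cell models, pseudo-experimental
# recording sessions (parameter jitter across cells, additive recording
# noise) and toy morphology banks. These stand in for patch-clamp datasets
# and reconstructed morphology populations so the whole workflow can be
# exercised and tested at desk scale.

#' Toy multi-section morphology
#'
#' A synthetic reconstruction with a spherical soma, an apical trunk and
#' extension, two basal dendrites and an axon stub (meant to be replaced by
#' [replace_axon()]). Dimensions are fixed so tests are reproducible.
#'
#' @param name morphology label
#' @param m_type morphological-type label
#' @export
fixture_morphology <- function(name = "toy_pyramidal", m_type = "TPC") {
  along <- function(dir, from, lengths) {
    dir <- dir / sqrt(sum(dir^2))
    t(vapply(c(0, cumsum(lengths)), function(d) from + dir * d, numeric(3)))
  }
  o <- c(0, 0, 0)
  soma <- new_section(1, "soma", matrix(o, 1, 3), 15, NA)
  ap1 <- new_section(2, "apical", along(c(0, 1, 0), o, rep(40, 10)),
                     seq(2.2, 1.6, length.out = 11), 1)
  ap1_end <- ap1$points[nrow(ap1$points), ]
  ap2 <- new_section(3, "apical", along(c(0.15, 1, 0), ap1_end, rep(40, 10)),
                     seq(1.6, 1.0, length.out = 11), 2)
  ba1 <- new_section(4, "basal", along(c(0.6, -1, 0), o, rep(30, 4)),
                     seq(1.4, 0.8, length.out = 5), 1)
  ba2 <- new_section(5, "basal", along(c(-0.6, -1, 0), o, rep(30, 4)),
                     seq(1.4, 0.8, length.out = 5), 1)
  axon <- new_section(6, "axon", along(c(0, -1, 0.1), o, rep(25, 8)),
                      seq(1.2, 0.8, length.out = 9), 1)
  morphology(list(soma, ap1, ap2, ba1, ba2, axon), name = name, m_type = m_type)
}

#' Single-compartment morphology (spherical soma)
#' @param diam_um soma diameter, um
#' @param name label
#' @export
point_morphology <- function(diam_um = 30, name = "point_soma") {
  morphology(list(new_section(1, "soma", matrix(c(0, 0, 0), 1, 3),
                              diam_um, NA)),
             name = name, m_type = "POINT")
}

GT_POINT_PARAMS <- c(gbar_NaT = 0.05, gbar_Kdr = 0.02, gbar_Kslow = 2e-4,
                     gbar_Ih = 2e-4)

#' Ground-truth single-compartment cell model
#'
#' The default desk-scale fixture: a spherical soma carrying transient Na,
#' delayed-rectifier K, slow K and Ih with four free maximal conductances
#' (bounds a factor 2.5 around the ground truth). Spiking with
#' adaptation, afterhyperpolarization and an Ih sag.
#'
#' @param params named conductance overrides (S/cm^2)
#' @param name,e_type labels
#' @export
ground_truth_cell <- function(params = GT_POINT_PARAMS,
                              name = "gt_point", e_type = "cADfix") {
  lib <- default_channel_library("soma")
  pars <- cell_parameters(
    name = names(GT_POINT_PARAMS),
    value = unname(params[names(GT_POINT_PARAMS)]),
    lower = unname(GT_POINT_PARAMS) / 2.5,
    upper = unname(GT_POINT_PARAMS) * 2.5,
    frozen = FALSE)
  cell_model(point_morphology(),
             mechanisms = lib[c("NaT", "Kdr", "Kslow", "Ih")],
             passive = list(g_pas = 1e-4, e_pas = -80, cm = 1, Ra = 100),
             parameters = pars, name = name, e_type = e_type)
}

GT_DEND_PARAMS <- c(gbar_NaT_somatic = 0.005, gbar_NaT_ais = 2,
                    gbar_Kdr_somatic = 0.02, gbar_Kslow_somatic = 2e-4,
                    gbar_Ih_somatic = 3e-4)

#' Ground-truth dendritic cell model
#'
#' The toy morphology of [fixture_morphology()] with the axon replaced by
#' the synthetic AIS + myelin, active soma and AIS (spike initiation
#' dominated by the AIS sodium conductance, so clones with a shrunken AIS
#' lose firing), and passive dendrites with a small Ih.
#'
#' @param params named conductance overrides (S/cm^2)
#' @param morph optional replacement morphology (same section types)
#' @param name,e_type labels
#' @export
dendritic_ground_truth_cell <- function(params = GT_DEND_PARAMS,
                                        morph = NULL,
                                        name = "gt_dendritic",
                                        e_type = "cADfix") {
  if (is.null(morph)) morph <- replace_axon(fixture_morphology())
  lib <- default_channel_library()
  nat_soma <- lib$NaT; nat_soma$regions <- "soma"
  nat_soma$gbar_param <- "gbar_NaT_somatic"
  nat_ais <- lib$NaT; nat_ais$name <- "NaT_ais"; nat_ais$regions <- "AIS"
  nat_ais$gbar_param <- "gbar_NaT_ais"
  kdr <- lib$Kdr; kdr$regions <- c("soma", "AIS")
  kdr$gbar_param <- "gbar_Kdr_somatic"
  kslow <- lib$Kslow; kslow$regions <- "soma"
  kslow$gbar_param <- "gbar_Kslow_somatic"
  ih <- lib$Ih; ih$regions <- c("soma", "apical", "basal")
  ih$gbar_param <- "gbar_Ih_somatic"
  pars <- cell_parameters(
    name = names(GT_DEND_PARAMS),
    value = unname(params[names(GT_DEND_PARAMS)]),
    lower = unname(GT_DEND_PARAMS) / 2.5,
    upper = unname(GT_DEND_PARAMS) * 2.5,
    frozen = FALSE)
  cell_model(morph, mechanisms = list(nat_soma, nat_ais, kdr, kslow, ih),
             passive = list(g_pas = 4e-4, e_pas = -75, cm = 1, Ra = 100),
             parameters = pars, name = name, e_type = e_type)
}

#' Fixture configuration for pseudo-experimental recordings
#'
#' The generator emulates a patch-clamp session on `n_cells` pseudo-cells:
#' each cell is the ground-truth model with conductances jittered by a
#' fractional Gaussian (`param_jitter_sd`), its own rheobase found by
#' threshold search, protocols delivered at amplitudes relative to that
#' rheobase (matching the canonical session structure: 2 s IDrest/IDthresh
#' steps at 10 kHz, 50 ms APWaveform at 50 kHz, 3 s IV steps, plus Ramp /
#' sAHP / IDHyperpol validation protocols), and Gaussian recording noise
#' added (`noise_sd_mV`).
#'
#' @param n_cells number of pseudo-cells
#' @param param_jitter_sd fractional SD of per-cell conductance jitter
#' @param noise_sd_mV additive recording noise SD, mV
#' @param idrest_pcts,idthresh_pcts step amplitudes, % of rheobase
#' @param apwaveform_pct,iv_pct,rin_amp as in [default_protocol_suite()]
#' @param ramp_pct,sahp_pcts,idhyperpol_pct validation amplitudes
#' @param include_validation generate the held-out protocols too
#' @param seed integer seed
#' @export
fixture_config <- function(n_cells = 5, param_jitter_sd = 0.05,
                           noise_sd_mV = 0.25,
                           idrest_pcts = c(150, 200, 250),
                           idthresh_pcts = c(60, 80, 95, 100, 110, 125),
                           apwaveform_pct = 300, iv_pct = -100,
                           rin_amp = -0.04, ramp_pct = 150,
                           sahp_pcts = c(150, 350), idhyperpol_pct = 250,
                           include_validation = TRUE, seed = 1L) {
  stopifnot(param_jitter_sd >= 0, noise_sd_mV >= 0, n_cells >= 1)
  as.list(environment())
}

# suite of generator sweeps (protocol rows reused from evaluation so data
# and model are measured identically)
fixture_sweep_suite <- function(cfg) {
  opt <- default_protocol_suite(cfg$idrest_pcts, cfg$apwaveform_pct,
                                cfg$iv_pct, cfg$rin_amp)
  idthresh <- purrr::map_dfr(cfg$idthresh_pcts, function(p)
    proto_row("IDthresh", p, "Spikecount", dur = 2000))
  rows <- dplyr::bind_rows(opt[!opt$protocol %in%
                               c("RinHoldCurrent", "Threshold"), ], idthresh)
  if (cfg$include_validation)
    rows <- dplyr::bind_rows(rows, validation_protocol_suite(
      cfg$ramp_pct, cfg$sahp_pcts, cfg$idhyperpol_pct))
  rows
}

#' Generate pseudo-experimental recordings
#'
#' @param cfg a [fixture_config()]
#' @param cell_factory function returning the ground-truth cell (default
#'   [ground_truth_cell()])
#' @return list of [cell_recording_set()]s, with the per-cell true
#'   parameters and rheobase attached as attributes `true_params` and
#'   `true_rheobase`
#' @export
generate_recordings <- function(cfg = fixture_config(),
                                cell_factory = ground_truth_cell) {
  base <- ensure_geometry(cell_factory())
  free <- base$parameters$name[!base$parameters$frozen]
  suite <- fixture_sweep_suite(cfg)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  cells <- list(); truths <- list(); rheos <- numeric(0)
  ci <- 0L
  while (length(cells) < cfg$n_cells) {
    ci <- ci + 1L
    v0 <- stats::setNames(base$parameters$value[match(free, base$parameters$name)],
                          free)
    vals <- v0 * (1 + stats::rnorm(length(free), 0, cfg$param_jitter_sd))
    lo <- base$parameters$lower[match(free, base$parameters$name)]
    hi <- base$parameters$upper[match(free, base$parameters$name)]
    vals <- pmin(pmax(vals, lo), hi)
    cell <- set_parameters(base, vals)
    # the search mirrors the evaluation-time conditions (same pre-stimulus
    # delay as the sweeps, same fine precision) so that the 100% IDthresh
    # sweep is the lowest spiking one and rheobase-rescaled protocols are
    # exactly reproducible
    rheo <- tryCatch(search_threshold_current(cell, holding = 0, pre = 250,
                                              precision = 2.5e-4),
                     error = function(e) NA_real_)
    if (is.na(rheo)) next  # jitter broke spiking; resample
    noise_seed <- cfg$seed * 1000L + ci
    traces <- list()
    for (ri in seq_len(nrow(suite))) {
      proto <- suite[ri, ]
      res <- run_protocol(cell, proto, holding = 0, rheobase = rheo,
                          seed = noise_seed)
      tr <- res$traces[[1]]
      if (cfg$noise_sd_mV > 0)
        tr$values <- tr$values + stats::rnorm(length(tr$values), 0,
                                              cfg$noise_sd_mV)
      traces[[length(traces) + 1]] <- tr
    }
    cells[[length(cells) + 1]] <- cell_recording_set(
      sprintf("cell%03d", length(cells) + 1L), base$e_type, traces,
      holding_current = 0)
    truths[[length(truths) + 1]] <- vals
    rheos <- c(rheos, rheo)
  }
  attr(cells, "true_params") <- truths
  attr(cells, "true_rheobase") <- rheos
  cells
}

#' Default extraction target specs matching the generator's sweeps
#'
#' @param cfg a [fixture_config()]
#' @param tolerance binning tolerance, % of rheobase
#' @export
default_target_specs <- function(cfg = fixture_config(), tolerance = 10) {
  opt <- default_protocol_suite(cfg$idrest_pcts, cfg$apwaveform_pct,
                                cfg$iv_pct, cfg$rin_amp)
  rows <- purrr::map_dfr(
    seq_len(nrow(opt)), function(i) {
      p <- opt[i, ]
      if (p$protocol %in% c("RinHoldCurrent", "Threshold")) return(tibble())
      target_spec(p$protocol, p$target_pct, tolerance, p$features[[1]],
                  route = p$route[[1]])
    })
  if (cfg$include_validation) {
    val <- validation_protocol_suite(cfg$ramp_pct, cfg$sahp_pcts,
                                     cfg$idhyperpol_pct)
    rows <- dplyr::bind_rows(rows, purrr::map_dfr(
      seq_len(nrow(val)), function(i) {
        p <- val[i, ]
        target_spec(p$protocol, p$target_pct, tolerance, p$features[[1]],
                    route = p$route[[1]])
      }))
  }
  rows
}

#' Generate a bank of cloned morphologies
#'
#' Clones the base morphology `n` times over a jitter grid, optionally
#' scaling the AIS diameter to span firing and non-firing regimes, and
#' optionally writes SWC files (filenames encode the clone parameters).
#' Deterministic per seed.
#'
#' @param base base morphology
#' @param n number of clones
#' @param scale global length scale applied to every clone
#' @param length_jitter_sd,angle_jitter_sd jitter SDs (see
#'   [clone_morphology()])
#' @param ais_diam_scales optional vector recycled over clones
#' @param seed integer seed
#' @param dir optional output directory for SWC files
#' @return list of morphologies (attribute `files` when written)
#' @export
generate_morphology_bank <- function(base, n, scale = 1,
                                     length_jitter_sd = 0.05,
                                     angle_jitter_sd = 0.1,
                                     ais_diam_scales = 1, seed = 1L,
                                     dir = NULL) {
  stopifnot(n >= 1)
  ais <- rep_len(ais_diam_scales, n)
  bank <- purrr::map(seq_len(n), function(i) {
    m <- clone_morphology(base, scale = scale,
                          length_jitter_sd = length_jitter_sd,
                          angle_jitter_sd = angle_jitter_sd,
                          seed = seed * 10000L + i,
                          ais_diam_scale = ais[i])
    m$name <- sprintf("%s_clone%03d_s%.2f_j%.2f_a%.2f", base$name, i, scale,
                      length_jitter_sd, ais[i])
    m
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(bank, function(m)
      write_swc(m, file.path(dir, paste0(m$name, ".swc"))), character(1))
    attr(bank, "files") <- files
  }
  bank
}
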