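#' @useDynLib emforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data abort
NULL

SWC_TYPE_CODES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L,
                    AIS = 5L, myelin = 6L)
SECTION_TYPES <- names(SWC_TYPE_CODES)

new_section <- function(id, type, points, diam, parent = NA_integer_) {
  points <- matrix(as.numeric(points), ncol = 3)
  list(id = as.integer(id), type = type, points = points,
       diam = as.numeric(diam), parent = as.integer(parent))
}

#' Construct a neuronal morphology
#'
#' A morphology is a rooted tree of typed sections (soma, axon, AIS, myelin,
#' basal and apical dendrites). Each section is a 3D polyline with per-point
#' diameters; a single-point soma is treated as a sphere. Children are
#' assumed to attach at the end point of their parent section.
#'
#' @param sections list of sections as built by the SWC reader or the
#'   synthetic generators; each has `id`, `type`, `points` (n x 3 matrix,
#'   um), `diam` (per-point, um) and `parent` (section id or `NA` for the
#'   root).
#' @param name morphology label.
#' @param m_type morphological-type label (used by the generalization
#'   report).
#' @return an object of class `emf_morphology`.
#' @export
morphology <- function(sections, name = "morphology", m_type = "generic") {
  m <- structure(list(sections = sections, name = name, m_type = m_type),
                 class = "emf_morphology")
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  secs <- m$sections
  if (length(secs) == 0) abort("morphology has no sections")
  ids <- vapply(secs, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) abort("duplicate section ids")
  parents <- vapply(secs, `[[`, integer(1), "parent")
  roots <- sum(is.na(parents))
  if (roots != 1L) abort(sprintf("morphology must have exactly 1 root, found %d", roots))
  for (s in secs) {
    if (!s$type %in% SECTION_TYPES)
      abort(sprintf("unknown section type '%s'", s$type))
    if (!is.na(s$parent) && !s$parent %in% ids)
      abort(sprintf("section %d refers to missing parent %d", s$id, s$parent))
    if (nrow(s$points) != length(s$diam))
      abort("points and diameters differ in length")
    if (nrow(s$points) < 2 && s$type != "soma")
      abort("non-soma sections need at least 2 points")
    if (any(!is.finite(s$points))) abort("non-finite coordinates")
    if (any(s$diam <= 0)) abort("diameters must be positive")
  }
  invisible(m)
}

section_by_id <- function(m, id) {
  for (s in m$sections) if (s$id == id) return(s)
  NULL
}

seg_lengths <- function(points) {
  if (nrow(points) < 2) return(numeric(0))
  sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
}

#' @export
section_length <- function(section) sum(seg_lengths(section$points))

#' Total polyline length per section type
#' @param m a morphology
#' @return named numeric vector (um) over the types present
#' @export
total_length <- function(m) {
  out <- vapply(m$sections, section_length, numeric(1))
  tapply(out, vapply(m$sections, `[[`, character(1), "type"), sum)
}

#' @export
print.emf_morphology <- function(x, ...) {
  types <- vapply(x$sections, `[[`, character(1), "type")
  cat(sprintf("<morphology '%s' (%s): %d sections [%s]>\n", x$name, x$m_type,
              length(x$sections),
              paste(sprintf("%s:%d", names(table(types)), table(types)),
                    collapse = ", ")))
  invisible(x)
}

#' Points table of a morphology
#'
#' @param x a morphology
#' @param ... unused
#' @return a tibble with one row per point: section id, type, x/y/z (um),
#'   diameter (um) and the section's parent id.
#' @export
as_tibble.emf_morphology <- function(x, ...) {
  purrr::map_dfr(x$sections, function(s) {
    tibble(section = s$id, type = s$type,
           x = s$points[, 1], y = s$points[, 2], z = s$points[, 3],
           diam = s$diam, parent = s$parent)
  })
}

# ---- SWC I/O ---------------------------------------------------------------

#' Read a morphology from an SWC file
#'
#' Strict 7-column SWC dialect: whitespace-separated `id type x y z radius
#' parent`, `#` comments, 1-based ids, parents defined before use, exactly
#' one root. Type codes: 1 soma, 2 axon, 3 basal, 4 apical, plus the
#' extended codes 5 (AIS) and 6 (myelin) used when writing replaced axons;
#' any other code is rejected. Radii are doubled into diameters. Samples are
#' grouped into unbranched runs of a single type; each non-root section is
#' prepended with its parent sample so that polylines are contiguous.
#'
#' @param path SWC file path
#' @return an `emf_morphology`
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty SWC file")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) abort(sprintf("malformed SWC row %d: expected 7 columns", bad[1]))
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(tab)) abort("malformed SWC row: non-numeric field")
  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2]); par <- as.integer(tab[, 7])
  if (any(!type %in% SWC_TYPE_CODES))
    abort(sprintf("unknown SWC type code %d", setdiff(type, SWC_TYPE_CODES)[1]))
  idx <- match(par, id)            # row index of each sample's parent
  if (any(par != -1L & is.na(idx))) abort("structural error: parent id not defined")
  child_rows <- which(par != -1L)
  if (any(child_rows <= idx[child_rows]))
    abort("structural error: parent defined after child")
  if (sum(par == -1L) != 1L) abort("structural error: SWC must have exactly one root")

  nchild <- tabulate(idx[!is.na(idx)], nbins = length(id))
  # a sample starts a new section at the root, at a type change, or below
  # a branch point; otherwise it continues its parent's section (runs need
  # not be contiguous in file order)
  starts <- par == -1L | type[pmax(idx, 1L)] != type | nchild[pmax(idx, 1L)] > 1L
  starts[is.na(starts)] <- TRUE
  run <- integer(length(id)); nrun <- 0L
  for (i in seq_along(id)) {
    if (starts[i]) { nrun <- nrun + 1L; run[i] <- nrun }
    else run[i] <- run[idx[i]]
  }
  sec_of_sample <- run

  secs <- list()
  for (r in seq_len(max(run))) {
    rows <- which(run == r)
    prow <- idx[rows[1]]
    pts <- tab[rows, 3:5, drop = FALSE]
    dm <- 2 * tab[rows, 6]
    parent_sec <- NA_integer_
    if (!is.na(prow)) {
      parent_sec <- sec_of_sample[prow]
      # prepend the attachment sample unless the child re-states it (a child
      # whose first sample sits on the parent keeps its own diameter there)
      if (any(abs(tab[prow, 3:5] - pts[1, ]) > 1e-9)) {
        pts <- rbind(tab[prow, 3:5], pts)
        dm <- c(2 * tab[prow, 6], dm)
      }
    }
    tname <- names(SWC_TYPE_CODES)[match(type[rows[1]], SWC_TYPE_CODES)]
    secs[[r]] <- new_section(r, tname, pts, dm, parent_sec)
  }
  morphology(secs, name = sub("\\.swc$", "", basename(path)))
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: duplicated attachment samples (a child section's
#' first point equal to its parent's last point) are emitted once.
#'
#' @param m a morphology
#' @param path output path
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path) {
  rows <- list(); next_id <- 1L
  last_sample <- integer(0)  # per section id: SWC id of its last sample
  ord <- tree_order(m)
  for (s in m$sections[ord]) {
    pts <- s$points; dm <- s$diam
    par_swc <- -1L
    from <- 1L
    if (!is.na(s$parent)) {
      par_swc <- last_sample[[as.character(s$parent)]]
      psec <- section_by_id(m, s$parent)
      np <- nrow(psec$points)
      # drop the duplicated attachment sample only when the parent already
      # carries both its coordinates and its diameter
      if (nrow(pts) >= 2 &&
          isTRUE(all(abs(pts[1, ] - psec$points[np, ]) < 1e-9)) &&
          isTRUE(abs(dm[1] - psec$diam[np]) < 1e-9))
        from <- 2L
    }
    code <- SWC_TYPE_CODES[[s$type]]
    prev <- par_swc
    for (i in seq(from, nrow(pts))) {
      rows[[length(rows) + 1L]] <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                                           next_id, code, pts[i, 1], pts[i, 2],
                                           pts[i, 3], dm[i] / 2, prev)
      prev <- next_id; next_id <- next_id + 1L
    }
    last_sample[[as.character(s$id)]] <- prev
  }
  writeLines(c("# generated by emforge", unlist(rows)), path)
  invisible(path)
}

# sections ordered so parents precede children
tree_order <- function(m) {
  ids <- vapply(m$sections, `[[`, integer(1), "id")
  parents <- vapply(m$sections, `[[`, integer(1), "parent")
  ord <- integer(0); placed <- rep(FALSE, length(ids))
  repeat {
    ready <- which(!placed & (is.na(parents) | parents %in% ids[placed]))
    if (!length(ready)) break
    ord <- c(ord, ready); placed[ready] <- TRUE
  }
  if (!all(placed)) abort("cyclic or disconnected morphology")
  ord
}

# ---- axon replacement ------------------------------------------------------

#' Replace the reconstructed axon by a synthetic AIS plus myelinated segment
#'
#' All axonal sections (types axon, AIS, myelin) are removed and replaced by
#' one straight axon initial segment of `ais_length` attached to the soma,
#' followed by one myelinated section of `myelin_length`. The AIS diameter is
#' taken from the first point of the original axon (falling back to 1 um when
#' the morphology has no axon); the myelin diameter is fixed at 1 um.
#' Dendrites are untouched and the operation is idempotent.
#'
#' @param m a morphology
#' @param ais_length AIS length, um (default 60)
#' @param myelin_length myelinated segment length, um (default 1000)
#' @return a morphology with exactly one AIS and one myelin section
#' @export
replace_axon <- function(m, ais_length = 60, myelin_length = 1000) {
  stopifnot(ais_length > 0, myelin_length > 0)
  axonal <- c("axon", "AIS", "myelin")
  types <- vapply(m$sections, `[[`, character(1), "type")
  old_axon <- m$sections[types %in% c("axon", "AIS")]
  ais_diam <- if (length(old_axon)) old_axon[[1]]$diam[1] else 1
  keep <- m$sections[!types %in% axonal]

  soma_id <- keep[[which(vapply(keep, `[[`, character(1), "type") == "soma")[1]]]$id
  soma <- section_by_id(m, soma_id)
  p0 <- soma$points[nrow(soma$points), ]
  max_id <- max(vapply(keep, `[[`, integer(1), "id"))
  dirv <- c(0, -1, 0)
  ais_pts <- rbind(p0, p0 + dirv * ais_length)
  mye_pts <- rbind(p0 + dirv * ais_length, p0 + dirv * (ais_length + myelin_length))
  ais <- new_section(max_id + 1L, "AIS", ais_pts, rep(ais_diam, 2), soma_id)
  mye <- new_section(max_id + 2L, "myelin", mye_pts, rep(1, 2), max_id + 1L)
  morphology(c(keep, list(ais, mye)), name = m$name, m_type = m$m_type)
}

# ---- cloning ---------------------------------------------------------------

#' Clone a morphology by rescaling and jitter
#'
#' Produces a morphological "clone": every section's length is multiplied by
#' `scale * (1 + eps)` with `eps ~ Normal(0, length_jitter_sd)` truncated so
#' lengths stay positive, and each non-soma section's direction is rotated by
#' a random small rotation with angle `~ Normal(0, angle_jitter_sd)` about a
#' random axis through its attachment point. Topology, section types and
#' diameters are preserved (optionally scaled for the AIS via `ais_diam_scale`
#' to emulate clones whose AIS no longer supports spiking). Deterministic
#' given `seed`.
#'
#' @param m a morphology
#' @param scale global length scale (> 0)
#' @param length_jitter_sd fractional SD of per-section length jitter
#' @param angle_jitter_sd SD of branch rotation angles, radians
#' @param seed integer seed
#' @param ais_diam_scale multiplier on AIS diameters (default 1)
#' @return a morphology
#' @export
clone_morphology <- function(m, scale = 1, length_jitter_sd = 0,
                             angle_jitter_sd = 0, seed = 1L,
                             ais_diam_scale = 1) {
  stopifnot(scale > 0, length_jitter_sd >= 0, angle_jitter_sd >= 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  ord <- tree_order(m)
  new_secs <- m$sections
  names(new_secs) <- vapply(m$sections, function(s) as.character(s$id), character(1))
  new_end <- list()

  for (i in ord) {
    s <- m$sections[[i]]
    f <- scale * (1 + rnorm(1, 0, length_jitter_sd))
    tries <- 0
    while (f <= 0 && tries < 100) { f <- scale * (1 + rnorm(1, 0, length_jitter_sd)); tries <- tries + 1 }
    f <- max(f, 1e-6)
    pts <- s$points
    vecs <- if (nrow(pts) >= 2) (pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]) * f
            else matrix(numeric(0), ncol = 3)
    if (s$type != "soma" && nrow(vecs) > 0) {
      ang <- rnorm(1, 0, angle_jitter_sd)
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      if (abs(ang) > 0) vecs <- vecs %*% t(rotation_matrix(axis, ang))
    }
    start <- if (is.na(s$parent)) pts[1, ] else new_end[[as.character(s$parent)]]
    npts <- matrix(0, nrow(pts), 3)
    npts[1, ] <- start
    if (nrow(pts) >= 2) {
      cs <- apply(vecs, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
      npts[2:nrow(pts), ] <- sweep(cs, 2, start, "+")
    }
    dm <- s$diam
    if (s$type == "AIS") dm <- dm * ais_diam_scale
    # a single-point (spherical) soma has no length to scale; its size is
    # its diameter, so the rescale acts there instead
    if (s$type == "soma" && nrow(pts) < 2) dm <- dm * f
    new_secs[[as.character(s$id)]] <- new_section(s$id, s$type, npts, dm, s$parent)
    new_end[[as.character(s$id)]] <- npts[nrow(npts), ]
  }
  morphology(unname(new_secs), name = paste0(m$name, "_clone", seed),
             m_type = m$m_type)
}

rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle); t_ <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t_*x*x + c_,   t_*x*y - s_*z, t_*x*z + s_*y,
           t_*x*y + s_*z, t_*y*y + c_,   t_*y*z - s_*x,
           t_*x*z - s_*y, t_*y*z + s_*x, t_*z*z + c_), 3, 3, byrow = TRUE)
}

# ---- surface areas and path distances --------------------------------------

# start path distance (um, from soma) per section; soma sections are 0
section_start_distance <- function(m) {
  ord <- tree_order(m)
  start <- stats::setNames(numeric(length(m$sections)),
                           vapply(m$sections, function(s) as.character(s$id), character(1)))
  endd <- start
  for (i in ord) {
    s <- m$sections[[i]]
    if (s$type == "soma") { start[as.character(s$id)] <- 0; endd[as.character(s$id)] <- 0; next }
    d0 <- if (is.na(s$parent)) 0 else endd[[as.character(s$parent)]]
    start[as.character(s$id)] <- d0
    endd[as.character(s$id)] <- d0 + section_length(s)
  }
  list(start = start, end = endd)
}

#' Membrane surface area of a morphological region
#'
#' Areas are sums of open frustum lateral areas `pi * mean(d) * L` over the
#' polyline segments inside the region; a single-point soma contributes its
#' sphere area `pi * d^2`. Regions: `AIS_proxy` is the axonal arbor within
#' `ais_cutoff` um of path distance from the soma (default the first 40 um of
#' axon), `proximal_dendrites` the basal + apical arbor within
#' `dendrite_cutoff` um (default 500), `soma` and `all` as named. Segments
#' straddling a cutoff contribute their included fraction.
#'
#' @param m a morphology
#' @param region one of `"all"`, `"AIS_proxy"`, `"proximal_dendrites"`, `"soma"`
#' @param ais_cutoff,dendrite_cutoff path-length cutoffs, um
#' @return area in um^2 (0 for an empty region)
#' @export
surface_area <- function(m, region = c("all", "AIS_proxy", "proximal_dendrites", "soma"),
                         ais_cutoff = 40, dendrite_cutoff = 500) {
  region <- match.arg(region)
  stopifnot(ais_cutoff > 0, dendrite_cutoff > 0)
  sd_ <- section_start_distance(m)
  types <- switch(region,
                  all = SECTION_TYPES,
                  AIS_proxy = c("axon", "AIS", "myelin"),
                  proximal_dendrites = c("basal", "apical"),
                  soma = "soma")
  cutoff <- switch(region, AIS_proxy = ais_cutoff,
                   proximal_dendrites = dendrite_cutoff, Inf)
  total <- 0
  for (s in m$sections) {
    if (!s$type %in% types) next
    if (nrow(s$points) < 2) {        # spherical soma
      total <- total + pi * s$diam[1]^2
      next
    }
    L <- seg_lengths(s$points)
    d0 <- if (s$type == "soma") 0 else sd_$start[[as.character(s$id)]]
    cum <- d0 + c(0, cumsum(L))
    for (k in seq_along(L)) {
      if (L[k] <= 0) next
      a <- cum[k]; b <- cum[k + 1]
      if (a >= cutoff) next
      frac <- min(1, (cutoff - a) / L[k])
      d1 <- s$diam[k]; d2 <- s$diam[k + 1]
      dmid2 <- d1 + (d2 - d1) * frac
      total <- total + pi * (d1 + dmid2) / 2 * L[k] * frac
    }
  }
  total
}

#' Per-region length/area summary of a morphology
#'
#' @param m a morphology
#' @return a tibble with columns region, length_um, area_um2
#' @export
morphology_summary <- function(m) {
  types <- vapply(m$sections, `[[`, character(1), "type")
  purrr::map_dfr(unique(types), function(tp) {
    secs <- m$sections[types == tp]
    len <- sum(vapply(secs, section_length, numeric(1)))
    area <- sum(vapply(secs, function(s) {
      if (nrow(s$points) < 2) return(pi * s$diam[1]^2)
      L <- seg_lengths(s$points)
      sum(pi * (s$diam[-length(s$diam)] + s$diam[-1]) / 2 * L)
    }, numeric(1)))
    tibble(region = tp, length_um = len, area_um2 = area)
  })
}
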