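#' Skin-surface temperature profile
#'
#' Samples the solved temperature on the outer skin arc at equal arc-length
#' steps. Position 0 is the left end of the section (x = -outer_radius on the
#' chord) and the last position is [skin_arc_length()].
#'
#' @param field a [solve_steady()] result.
#' @param geometry the geometry the field was solved on (consistency checked).
#' @param n_samples number of equally spaced arc positions; default 512.
#' @return object of class `thermal_profile`: a data frame with `position`
#'   (cm along the arc) and `temperature` (degC), with provenance attributes.
#' @export
skin_profile <- function(field, geometry, n_samples = 512) {
  stopifnot(inherits(field, "temperature_field"))
  .check_field_geometry(field, geometry)
  R <- geometry$outer_radius
  s <- seq(0, pi * R, length.out = n_samples)
  th <- pi - s / R                      # arc position 0 at the left end
  # interpolate the Robin-extrapolated surface temperature in theta
  dom <- field$domain
  fj <- pmin(pmax(th / dom$dth + 0.5, 1), dom$nt)
  j0 <- pmin(floor(fj), dom$nt - 1L)
  w <- fj - j0
  Ts <- field$T_surface
  temp <- (1 - w) * Ts[j0] + w * Ts[j0 + 1]
  structure(data.frame(position = s, temperature = temp),
            class = c("thermal_profile", "data.frame"),
            kind = "skin", geometry = geometry,
            resolution = field$resolution)
}

.check_field_geometry <- function(field, geometry) {
  stopifnot(inherits(geometry, "neck_geometry"))
  gf <- field$problem$geometry
  if (abs(gf$outer_radius - geometry$outer_radius) > 1e-9 ||
      abs(gf$fat_thickness - geometry$fat_thickness) > 1e-9)
    stop("field was not solved on this geometry")
  invisible(TRUE)
}

#' Temperature profile along a line segment
#'
#' Bilinear sampling of the field along the segment from `p_start` to
#' `p_end`. With both `p_start` and `p_end` `NULL`, the segment runs from the
#' section centre through the nodule centre to the skin surface (the radial
#' line of the reported interior profile).
#'
#' @param field a [solve_steady()] result on a neck geometry.
#' @param p_start,p_end segment endpoints (x, y) in cm, or `NULL` for the
#'   default radial line through the nodule.
#' @param n_samples number of samples; default 512.
#' @return a `thermal_profile` data frame: `position` (cm from `p_start`),
#'   `temperature` (degC), plus a `tissue` column with the tissue label at
#'   each sample.
#' @export
line_profile <- function(field, p_start = NULL, p_end = NULL,
                         n_samples = 512) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$problem$geometry
  if (is.null(p_start) && is.null(p_end)) {
    if (is.null(g$nodule))
      stop("no nodule: give explicit endpoints for the line profile")
    u <- g$nodule$center / sqrt(sum(g$nodule$center^2))
    # the ray from the section centre crosses the (insulated, unsolved)
    # trachea hole first; start at its wall
    r0 <- 2 * u[2] * g$trachea_radius + 1e-6
    p_start <- u * r0
    p_end <- u * g$outer_radius
  }
  if (is.null(p_start) || is.null(p_end))
    stop("give both endpoints or neither")
  L <- sqrt(sum((p_end - p_start)^2))
  if (L <= 0) stop("degenerate segment")
  t <- seq(0, 1, length.out = n_samples)
  x <- p_start[1] + t * (p_end[1] - p_start[1])
  y <- p_start[2] + t * (p_end[2] - p_start[2])
  r <- sqrt(x^2 + y^2)
  if (any(y < -1e-9 | r > g$outer_radius + 1e-9))
    stop("line endpoint outside the half-disc domain")
  # clamp the outer endpoint onto the last cell centre ring
  temp <- sample_field(field, x, y)
  tis <- tissue_at(g, x, y, on_outside = "na")
  structure(data.frame(position = t * L, temperature = temp, tissue = tis),
            class = c("thermal_profile", "data.frame"),
            kind = "line", geometry = g, p_start = p_start, p_end = p_end,
            resolution = field$resolution)
}

#' Temperature drop across a tissue layer along a profile
#'
#' Temperature at the layer's inner boundary minus temperature at its outer
#' boundary, taken over the contiguous run of samples labelled with the layer
#' along a [line_profile()].
#'
#' @param profile a [line_profile()] with a `tissue` column.
#' @param geometry the neck geometry (consistency only).
#' @param layer tissue label, e.g. `"fat"` or `"muscle"`.
#' @return drop in degC (positive when the layer insulates outward heat flow).
#' @export
layer_drop <- function(profile, geometry, layer) {
  stopifnot(inherits(profile, "thermal_profile"),
            "tissue" %in% names(profile))
  idx <- which(profile$tissue == layer)
  if (!length(idx)) stop("profile does not cross layer: ", layer)
  # last contiguous run (the outward crossing for layered shells)
  brk <- which(diff(idx) > 1)
  if (length(brk)) idx <- idx[(max(brk) + 1):length(idx)]
  profile$temperature[idx[1]] - profile$temperature[idx[length(idx)]]
}

#' Contralateral skin-surface contrast in front of the nodule
#'
#' Temperature at the arc point radially in front of the nodule minus the
#' temperature at its mirror point on the contralateral side.
#'
#' @param profile a [skin_profile()].
#' @param geometry the neck geometry the profile was taken on.
#' @param nodule the [nodule_spec()] (or `NULL`: returns 0 with attribute
#'   `no_nodule = TRUE`).
#' @return contrast in degC; attribute `perceptible` flags values above the
#'   0.05 degC camera-sensitivity threshold.
#' @export
surface_contrast <- function(profile, geometry, nodule = geometry$nodule) {
  stopifnot(inherits(profile, "thermal_profile"),
            identical(attr(profile, "kind"), "skin"))
  if (is.null(nodule)) return(structure(0, no_nodule = TRUE))
  R <- geometry$outer_radius
  th <- atan2(nodule$center[2], nodule$center[1])
  s_nod <- (pi - th) * R
  s_mir <- pi * R - s_nod
  f <- stats::approxfun(profile$position, profile$temperature)
  ct <- f(s_nod) - f(s_mir)
  structure(ct, perceptible = abs(ct) > 0.05)
}

#' Nodule-size by fat-thickness simulation sweep
#'
#' Solves the steady bioheat problem for every combination of nodule size and
#' fat thickness (duplicates removed) and tabulates the contralateral skin
#' contrast, nodule-centre temperature and contralateral (mirror-point) lobe
#' temperature. The published grid is the four sizes of
#' [standard_nodule_sizes()] against fat thicknesses 0.1, 0.6 and 1.2 cm.
#'
#' @param sizes list of [nodule_spec()]s.
#' @param fats numeric vector of fat thicknesses, cm.
#' @param resolution solver grid spacing, cm; default 0.05 (sweeps trade a
#'   little accuracy for 12 solves).
#' @param properties tissue table; default the calibrated perfusion reading,
#'   which is the configuration under which contrasts are physically
#'   meaningful.
#' @param n_samples skin-profile sampling density.
#' @return data frame (class `sweep_result`) with one row per combination:
#'   `size_minor`, `size_major`, `fat`, `contrast`, `nodule_T`, `lobe_T`,
#'   `perceptible`.
#' @export
run_sweep <- function(sizes, fats, resolution = 0.05,
                      properties = tissue_properties("calibrated"),
                      n_samples = 1024) {
  stopifnot(length(sizes) >= 1, length(fats) >= 1)
  if (inherits(sizes, "nodule_spec")) sizes <- list(sizes)
  key <- paste(vapply(sizes, function(s) paste(s$diameter_minor,
                                               s$diameter_major), ""),
               sep = "")
  sizes <- sizes[!duplicated(key)]
  fats <- unique(fats)
  rows <- list()
  for (nod in sizes) for (fat in fats) {
    tag <- sprintf("size %gx%g, fat %g", nod$diameter_minor,
                   nod$diameter_major, fat)
    row <- tryCatch({
      g <- build_neck_section(fat, nod)
      fld <- solve_steady(pennes_problem(g, properties), resolution)
      prof <- skin_profile(fld, g, n_samples)
      ct <- surface_contrast(prof, g)
      ctr <- g$nodule$center
      data.frame(size_minor = nod$diameter_minor,
                 size_major = nod$diameter_major, fat = fat,
                 contrast = as.numeric(ct),
                 nodule_T = sample_field(fld, ctr[1], ctr[2]),
                 lobe_T = sample_field(fld, -ctr[1], ctr[2]),
                 perceptible = isTRUE(attr(ct, "perceptible")))
    }, error = function(e) stop("sweep failed at ", tag, ": ",
                                conditionMessage(e)))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write a profile or sweep table as CSV with a JSON sidecar
#'
#' @param x a `thermal_profile` or `sweep_result`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  meta <- list(kind = attr(x, "kind") %||% "sweep",
               resolution = attr(x, "resolution"),
               units = list(position = "cm", temperature = "degC"))
  g <- attr(x, "geometry")
  if (!is.null(g)) {
    meta$geometry <- unclass(g)
    if (!is.null(meta$geometry$nodule))
      meta$geometry$nodule <- unclass(meta$geometry$nodule)
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
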