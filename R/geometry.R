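#' Elliptic nodule specification
#'
#' Describes a malignant nodule as an ellipse in the cross-section plane. The
#' four sizes studied in the sweep are 0.5x0.78, 1.0x1.57, 1.5x2.36 and
#' 2.0x3.14 cm (minor x major diameter).
#'
#' @param diameter_minor minor-axis diameter, cm.
#' @param diameter_major major-axis diameter, cm.
#' @param center optional 2-vector (x, y) cm; if `NULL`, [build_neck_section()]
#'   anchors the nodule on the anterior face of the left thyroid lobe.
#' @param orientation optional major-axis direction, radians from +x; if
#'   `NULL`, the major axis is placed tangentially to the gland band.
#' @return object of class `nodule_spec`.
#' @examples
#' nodule_spec(1.0, 1.57)
#' @export
nodule_spec <- function(diameter_minor, diameter_major,
                        center = NULL, orientation = NULL) {
  if (diameter_minor <= 0 || diameter_major <= 0)
    stop("nodule diameters must be positive")
  structure(list(diameter_minor = diameter_minor,
                 diameter_major = diameter_major,
                 center = center, orientation = orientation),
            class = "nodule_spec")
}

#' The four published nodule sizes
#'
#' @return list of [nodule_spec()] objects, smallest first.
#' @export
standard_nodule_sizes <- function() {
  list(nodule_spec(0.5, 0.78), nodule_spec(1.0, 1.57),
       nodule_spec(1.5, 2.36), nodule_spec(2.0, 3.14))
}

#' Build the layered neck cross-section
#'
#' The neck is modelled as a half disc sitting on a flat chord (the posterior
#' cut, held at core temperature by the solver). From the inside out:
#' a muscle-tissue core of radius `core_radius`, a muscle layer, a fat layer
#' of variable thickness and a 0.2 cm skin layer. The trachea is a circular
#' hole tangent to the chord on the midline whose boundary is insulated; the
#' thyroid gland is a crescent band hugging the trachea anteriorly. An
#' elliptic nodule may be embedded in one lobe of the gland; nodular
#' overgrowth locally enlarges the gland, so the gland region is the band
#' united with the nodule ellipse, and the nodule centre must lie inside the
#' band.
#'
#' The core radius default (3.87 cm) is a documented calibration: it is not
#' printed in the source geometry, but with skin 0.2 + muscle 1.0 + fat 1.2 cm
#' it makes the semicircular skin arc pi * 6.27 = 19.7 cm, the reported arc
#' length of the fattest configuration.
#'
#' @param fat_thickness fat-layer thickness, cm (the study varies 0.1, 0.6,
#'   1.2).
#' @param nodule a [nodule_spec()] or `NULL` for a nodule-free neck.
#' @param overrides named list overriding geometric defaults: `core_radius`,
#'   `muscle_thickness`, `skin_thickness`, `trachea_radius`,
#'   `thyroid_inner` / `thyroid_outer` (radii from the trachea centre, cm),
#'   `thyroid_half_angle` (radians about the anterior midline).
#' @return object of class `neck_geometry` with fields `core_radius`,
#'   `muscle_thickness`, `fat_thickness`, `skin_thickness`, `outer_radius`,
#'   `trachea_center`, `trachea_radius`, thyroid band parameters and the
#'   resolved `nodule` (with concrete centre and orientation).
#' @examples
#' g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
#' g$outer_radius    # 6.27
#' @export
build_neck_section <- function(fat_thickness, nodule = NULL, overrides = NULL) {
  p <- list(core_radius = 3.87, muscle_thickness = 1.0, skin_thickness = 0.2,
            trachea_radius = 1.0, thyroid_inner = 1.0, thyroid_outer = NULL,
            thyroid_half_angle = 70 * pi / 180)
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) stop("unknown geometry overrides: ",
                              paste(unknown, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  if (fat_thickness <= 0 || p$core_radius <= 0 || p$muscle_thickness <= 0 ||
      p$skin_thickness <= 0 || p$trachea_radius <= 0)
    stop("all thicknesses and radii must be positive")
  # the gland is superficial: by default its anterior face reaches the deep
  # side of the muscle layer (band outer radius touches the core boundary on
  # the midline)
  if (is.null(p$thyroid_outer))
    p$thyroid_outer <- p$core_radius - p$trachea_radius
  if (p$thyroid_inner < p$trachea_radius)
    stop("thyroid band must start at or outside the trachea wall")

  g <- list(
    core_radius = p$core_radius,
    muscle_thickness = p$muscle_thickness,
    fat_thickness = fat_thickness,
    skin_thickness = p$skin_thickness,
    outer_radius = p$core_radius + p$muscle_thickness + fat_thickness +
      p$skin_thickness,
    trachea_center = c(0, p$trachea_radius),  # tangent to the chord
    trachea_radius = p$trachea_radius,
    thyroid_inner = p$thyroid_inner,
    thyroid_outer = p$thyroid_outer,
    thyroid_half_angle = p$thyroid_half_angle,
    nodule = NULL
  )
  class(g) <- "neck_geometry"
  if (p$thyroid_outer > p$core_radius - p$trachea_radius + 1e-9 &&
      p$trachea_radius + p$thyroid_outer > p$core_radius)
    stop("thyroid band extends beyond the interior core")

  if (!is.null(nodule)) {
    stopifnot(inherits(nodule, "nodule_spec"))
    half_ang <- g$thyroid_half_angle / 2
    if (is.null(nodule$center)) {
      # left-lobe anterior-face anchor: half the band's angular extent to the
      # left of the midline, centre on the gland's superficial face, so the
      # overgrowth bulges anteriorly into the strap-muscle plane (a palpable
      # anterior nodule)
      nodule$center <- g$trachea_center +
        g$thyroid_outer * c(-sin(half_ang), cos(half_ang))
    }
    if (is.null(nodule$orientation)) {
      # major axis tangential to the band (perpendicular to the trachea radial)
      d <- nodule$center - g$trachea_center
      nodule$orientation <- atan2(d[2], d[1]) + pi / 2
    }
    g$nodule <- nodule
    .check_nodule_containment(g)
  }
  g
}

# nodule centre must sit in the gland band; the ellipse (the gland locally
# enlarged by the nodular overgrowth) may bulge into the deep muscle but must
# stay inside the fat layer's inner boundary, off the trachea hole and above
# the chord
.check_nodule_containment <- function(g) {
  n <- g$nodule
  ctr <- n$center
  d <- sqrt(sum((ctr - g$trachea_center)^2))
  ang <- abs(atan2(-(ctr[1] - g$trachea_center[1]),
                   ctr[2] - g$trachea_center[2]))
  if (d <= g$thyroid_inner - 1e-9 || d > g$thyroid_outer + 1e-9 ||
      ang > g$thyroid_half_angle + 1e-9)
    stop("nodule containment error: centre (", signif(ctr[1], 4), ", ",
         signif(ctr[2], 4), ") is outside the thyroid band")
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  a <- n$diameter_major / 2; b <- n$diameter_minor / 2
  ca <- cos(n$orientation); sa <- sin(n$orientation)
  bx <- ctr[1] + a * cos(th) * ca - b * sin(th) * sa
  by <- ctr[2] + a * cos(th) * sa + b * sin(th) * ca
  r <- sqrt(bx^2 + by^2)
  dtr <- sqrt((bx - g$trachea_center[1])^2 + (by - g$trachea_center[2])^2)
  tol <- 1e-9
  if (any(r > g$core_radius + g$muscle_thickness + tol) || any(by < -tol) ||
      any(dtr < g$trachea_radius - tol))
    stop("nodule containment error: ellipse reaches the fat layer, ",
         "crosses the chord or intersects the trachea")
  invisible(TRUE)
}

#' Semicircular skin arc length
#'
#' `pi * outer_radius`: the length of the skin surface of the half-disc
#' section. 19.7 cm for the 1.2 cm fat layer with the default core radius.
#'
#' @param geometry a [build_neck_section()] object.
#' @return arc length, cm.
#' @export
skin_arc_length <- function(geometry) {
  stopifnot(inherits(geometry, "neck_geometry"))
  pi * geometry$outer_radius
}

# squared normalized elliptic distance of points to the nodule (<= 1 inside)
.nodule_dist2 <- function(nodule, x, y) {
  a <- nodule$diameter_major / 2; b <- nodule$diameter_minor / 2
  ca <- cos(nodule$orientation); sa <- sin(nodule$orientation)
  dx <- x - nodule$center[1]; dy <- y - nodule$center[2]
  u <- dx * ca + dy * sa    # along major axis
  v <- -dx * sa + dy * ca   # along minor axis
  (u / a)^2 + (v / b)^2
}

#' Tissue label at points of the cross-section
#'
#' Classifies points into `skin`, `fat`, `muscle`, `thyroid` or `nodule`.
#' Regions are tested innermost-first (nodule before thyroid before muscle);
#' layer boundaries follow a half-open convention in which the outer layer
#' owns the shared boundary. The interior core outside gland/nodule/trachea is
#' muscle tissue.
#'
#' @param geometry a [build_neck_section()] object.
#' @param x,y point coordinates, cm (vectorised; the chord is y = 0, the
#'   midline x = 0).
#' @param on_outside what to do with points outside the half-disc domain or
#'   inside the trachea hole: `"error"` (default) or `"na"`.
#' @return character vector of tissue labels.
#' @examples
#' g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
#' tissue_at(g, g$nodule$center[1], g$nodule$center[2])  # "nodule"
#' @export
tissue_at <- function(geometry, x, y, on_outside = c("error", "na")) {
  g <- geometry
  stopifnot(inherits(g, "neck_geometry"), length(x) == length(y))
  on_outside <- match.arg(on_outside)
  r <- sqrt(x^2 + y^2)
  dtr <- sqrt((x - g$trachea_center[1])^2 + (y - g$trachea_center[2])^2)
  out <- y < 0 | r > g$outer_radius | dtr < g$trachea_radius
  if (any(out) && on_outside == "error")
    stop("point outside the neck domain (or inside the trachea hole)")
  lab <- rep(NA_character_, length(x))
  r_core <- g$core_radius
  r_musc <- r_core + g$muscle_thickness
  r_fat <- r_musc + g$fat_thickness
  # half-open layers: the outer layer owns the shared (its inner) boundary
  lab[!out & r >= r_fat] <- "skin"
  lab[!out & r >= r_musc & r < r_fat] <- "fat"
  lab[!out & r >= r_core & r < r_musc] <- "muscle"
  core <- !out & r < r_core
  lab[core] <- "muscle"
  ang <- abs(atan2(-(x - g$trachea_center[1]), y - g$trachea_center[2]))
  in_band <- core & dtr > g$thyroid_inner & dtr <= g$thyroid_outer &
    ang <= g$thyroid_half_angle
  lab[in_band] <- "thyroid"
  if (!is.null(g$nodule)) {
    # the nodular overgrowth may bulge out of the core into the deep muscle
    in_nod <- !out & r < r_musc & .nodule_dist2(g$nodule, x, y) <= 1
    lab[in_nod] <- "nodule"
  }
  lab
}

#' Rasterise the cross-section to a labelled tissue mask
#'
#' @param geometry a [build_neck_section()] object.
#' @param resolution pixel size, cm.
#' @param file optional PNG path; if given, a colour-coded map is written for
#'   visual inspection.
#' @return integer matrix (rows = y, from the chord upward) with levels
#'   `0` outside/trachea, then `skin`=1, `fat`=2, `muscle`=3, `thyroid`=4,
#'   `nodule`=5; the level key is in the `levels` attribute.
#' @export
rasterize_geometry <- function(geometry, resolution = 0.05, file = NULL) {
  g <- geometry
  xs <- seq(-g$outer_radius + resolution / 2, g$outer_radius, by = resolution)
  ys <- seq(resolution / 2, g$outer_radius, by = resolution)
  pts <- expand.grid(x = xs, y = ys)
  lab <- tissue_at(g, pts$x, pts$y, on_outside = "na")
  lev <- c("skin", "fat", "muscle", "thyroid", "nodule")
  m <- matrix(match(lab, lev), nrow = length(ys), byrow = TRUE)
  m[is.na(m)] <- 0L
  attr(m, "levels") <- lev
  attr(m, "resolution") <- resolution
  if (!is.null(file)) {
    cols <- c("#000000", "#f4c7a1", "#ffe9a8", "#c45850", "#7f3fbf", "#2ca02c")
    img <- array(0, dim = c(dim(m), 3))
    for (i in 0:5) {
      rgbv <- grDevices::col2rgb(cols[i + 1]) / 255
      for (ch in 1:3) img[, , ch][m == i] <- rgbv[ch]
    }
    # write with y increasing upward
    EBImage::writeImage(EBImage::Image(aperm(img[rev(seq_len(nrow(m))), , ,
                                                 drop = FALSE],
                                             c(2, 1, 3)),
                                       colormode = "Color"), file)
  }
  m
}

#' Serialise / read a neck geometry as JSON
#'
#' @param geometry a [build_neck_section()] object.
#' @param path file path.
#' @return `read_geometry` returns the reconstructed `neck_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "neck_geometry"))
  doc <- unclass(geometry)
  if (!is.null(doc$nodule)) doc$nodule <- unclass(doc$nodule)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodule <- NULL
  if (!is.null(doc$nodule))
    nodule <- nodule_spec(doc$nodule$diameter_minor, doc$nodule$diameter_major,
                          center = doc$nodule$center,
                          orientation = doc$nodule$orientation)
  build_neck_section(
    fat_thickness = doc$fat_thickness, nodule = nodule,
    overrides = list(core_radius = doc$core_radius,
                     muscle_thickness = doc$muscle_thickness,
                     skin_thickness = doc$skin_thickness,
                     trachea_radius = doc$trachea_radius,
                     thyroid_inner = doc$thyroid_inner,
                     thyroid_outer = doc$thyroid_outer,
                     thyroid_half_angle = doc$thyroid_half_angle))
}
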