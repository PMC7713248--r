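#' Thermogram temperature matrix
#'
#' Wraps a real-valued temperature matrix as produced by an infrared camera
#' (the reference camera yields 640 x 480). Matrices are stored with rows as
#' image lines (`y`) and columns as `x`, both 1-based, matching the camera
#' coordinate convention.
#'
#' @param M numeric matrix of temperatures, degC (`ny` x `nx`).
#' @param I optional companion grey/false-colour image with identical
#'   dimensions.
#' @return object of class `thermogram`.
#' @export
thermogram <- function(M, I = NULL) {
  stopifnot(is.matrix(M), all(is.finite(M)))
  if (!is.null(I) && !identical(dim(I)[1:2], dim(M)))
    stop("M and I must have the same number of elements")
  structure(list(M = M, I = I), class = "thermogram")
}

#' Map in-ROI temperatures to an 8-bit grey image
#'
#' Foreground temperatures are mapped linearly from their in-ROI range onto
#' the grey levels \[1, 255\] (rounded to nearest integer); everything outside
#' the ROI becomes background 0. A constant ROI maps to 255 everywhere
#' (documented convention).
#'
#' @param tg a [thermogram()] (or bare temperature matrix).
#' @param roi_mask logical/0-1 matrix of the same size: the neck region.
#' @return object of class `roi_image`: list with `grey` (integer matrix,
#'   background 0), `mask` (logical), `N_p` (foreground pixel count) and the
#'   temperature range used.
#' @examples
#' M <- matrix(c(30, 30.5, 31, 25), 1)
#' roi <- map_to_grey(thermogram(M), matrix(c(TRUE, TRUE, TRUE, FALSE), 1))
#' roi$grey   # 1 128 255 0
#' @export
map_to_grey <- function(tg, roi_mask) {
  M <- if (inherits(tg, "thermogram")) tg$M else tg
  stopifnot(is.matrix(M))
  mask <- .as_mask(roi_mask, dim(M))
  if (!any(mask)) stop("empty ROI")
  v <- M[mask]
  rng <- range(v)
  grey <- matrix(0L, nrow(M), ncol(M))
  if (rng[1] == rng[2]) {
    grey[mask] <- 255L
  } else {
    grey[mask] <- as.integer(round(1 + (v - rng[1]) / (rng[2] - rng[1]) * 254))
  }
  structure(list(grey = grey, mask = mask, N_p = sum(mask),
                 temp_range = rng),
            class = "roi_image")
}

.as_mask <- function(m, dims) {
  stopifnot(identical(dim(m), dims))
  if (is.logical(m)) m else m != 0
}

#' Geometric centre of the ROI foreground
#'
#' Mean pixel coordinate of the foreground set, the ROI acting as a 0/1
#' indicator: `o_x` is the mean column index, `o_y` the mean row index
#' (1-based). The vertical mirror axis used downstream is the nearest integer
#' column to `o_x`.
#'
#' @param roi a [map_to_grey()] result (or a bare mask matrix).
#' @return named numeric `c(o_x, o_y)` with attribute `axis_col` (the rounded
#'   mirror column).
#' @examples
#' m <- matrix(1, 3, 4)        # full 3-row, 4-column rectangle
#' centroid(m)                 # o_x 2.5, o_y 2
#' @export
centroid <- function(roi) {
  mask <- if (inherits(roi, "roi_image")) roi$mask
          else .as_mask(roi, dim(roi))
  if (!any(mask)) stop("empty ROI")
  idx <- which(mask, arr.ind = TRUE)
  o <- c(o_x = mean(idx[, 2]), o_y = mean(idx[, 1]))
  attr(o, "axis_col") <- as.integer(round(o[["o_x"]]))
  o
}

#' Contralateral asymmetry map
#'
#' For every foreground pixel whose mirror about the vertical axis is also in
#' the foreground, the asymmetry parameter is the temperature difference
#' `P_A(x, y) = M(x, y) - M(2 o_x - x, y)`, computed from the real-valued
#' temperature matrix (never the 8-bit grey image). The mirror column of `x`
#' is `round(2 o_x) - x`: doubling before rounding keeps the mirror a pure
#' pixel lookup while half-integer axes (e.g. a full-width symmetric ROI with
#' `o_x = 320.5`) stay exact. Values above ~0.3 degC flag a possible
#' dysfunction on the hotter side.
#'
#' @param tg a [thermogram()] (or temperature matrix).
#' @param roi a [map_to_grey()] result or mask matrix.
#' @param o_x mirror-axis abscissa (possibly fractional); default the
#'   [centroid()] abscissa.
#' @return object of class `asymmetry_map`: `P_A` (matrix, `NA` where
#'   undefined), `defined` (logical matrix), `axis_col` (the effective axis,
#'   `round(2 o_x) / 2`).
#' @export
asymmetry_map <- function(tg, roi, o_x = NULL) {
  M <- if (inherits(tg, "thermogram")) tg$M else tg
  mask <- if (inherits(roi, "roi_image")) roi$mask else .as_mask(roi, dim(M))
  stopifnot(identical(dim(mask), dim(M)))
  if (is.null(o_x)) o_x <- centroid(roi)[["o_x"]]
  ax2 <- as.integer(round(2 * o_x))      # mirror col = ax2 - x
  nx <- ncol(M)
  if (o_x < 1 || o_x > nx) stop("mirror axis outside the image")
  cols <- matrix(rep(seq_len(nx), each = nrow(M)), nrow(M))
  mcol <- ax2 - cols
  valid <- mcol >= 1L & mcol <= nx
  midx <- cbind(as.vector(row(M))[valid], as.vector(mcol)[valid])
  mirror_in <- matrix(FALSE, nrow(M), nx)
  mirror_in[valid] <- mask[midx]
  defined <- mask & mirror_in
  PA <- matrix(NA_real_, nrow(M), nx)
  dv <- which(defined)
  if (length(dv)) {
    mc <- ax2 - as.vector(col(M))[dv]
    PA[dv] <- M[dv] - M[cbind(as.vector(row(M))[dv], mc)]
  }
  structure(list(P_A = PA, defined = defined, axis_col = ax2 / 2),
            class = "asymmetry_map")
}

#' Threshold the asymmetry map into a hot-side candidate mask
#'
#' Pixels with `P_A > l` form the candidate mask. By antisymmetry this is
#' exactly the hot-side selection: the mirror partner of a selected pixel
#' carries the negative value and is never selected itself.
#'
#' @param pa an [asymmetry_map()].
#' @param l threshold, degC (> 0); default 0.3, the dysfunction level
#'   reported for the asymmetry parameter.
#' @return logical matrix.
#' @export
hot_candidates <- function(pa, l = 0.3) {
  stopifnot(inherits(pa, "asymmetry_map"))
  if (!is.numeric(l) || l <= 0) stop("threshold l must be positive")
  m <- pa$P_A > l
  m[is.na(m)] <- FALSE
  m
}

#' Morphological opening of a candidate mask
#'
#' Erosion followed by dilation with a disc structuring element, removing
#' speckle and thin arms while preserving larger rounded blobs.
#'
#' @param mask logical matrix.
#' @param selem_radius disc radius in pixels (>= 1); default 3.
#' @return logical matrix (a subset of the input's morphological closure).
#' @export
open_mask <- function(mask, selem_radius = 3) {
  stopifnot(is.matrix(mask), selem_radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(selem_radius) + 1L, "disc")
  img <- EBImage::Image(t(mask * 1))
  out <- EBImage::opening(img, brush)
  t(EBImage::imageData(out)) > 0.5
}

# 8-connected components by BFS over the foreground (EBImage::bwlabel is
# 4-connected, which splits diagonally linked candidate blobs)
.label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  cur <- 0L
  nbr <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  stack <- integer(length(fg))
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1L] <- p; lab[p] <- cur
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      ry <- (q - 1L) %% ny + 1L
      for (d in nbr) {
        s <- q + d
        if (s < 1L || s > ny * nx) next
        sy <- (s - 1L) %% ny + 1L
        if (abs(sy - ry) > 1L) next       # column wrap guard
        if (mask[s] && lab[s] == 0L) {
          lab[s] <- cur
          top <- top + 1L; stack[top] <- s
        }
      }
    }
  }
  lab
}

#' Extract candidate regions from a binary mask
#'
#' 8-connected components, each with its tight bounding box and pixel area,
#' sorted by decreasing area. An optional minimum-area filter honours the
#' preference for larger, more rounded regions; it is off by default so the
#' extraction matches the printed processing steps exactly.
#'
#' @param mask logical matrix (typically from [open_mask()]).
#' @param min_area drop regions smaller than this many pixels; default 0
#'   (keep all).
#' @return list of `candidate_region` objects: `bbox` (`x_min`, `y_min`,
#'   `x_max`, `y_max`, 1-based, columns = x), `mask` (logical matrix over the
#'   full frame), `area`, `label` (`"unknown"` until annotated).
#' @export
extract_candidates <- function(mask, min_area = 0) {
  stopifnot(is.matrix(mask))
  lab <- .label8(.as_mask(mask, dim(mask)))
  n <- max(lab)
  if (n == 0) return(list())
  regs <- lapply(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < max(1, min_area)) return(NULL)
    m <- lab == i
    structure(list(bbox = c(x_min = min(idx[, 2]), y_min = min(idx[, 1]),
                            x_max = max(idx[, 2]), y_max = max(idx[, 1])),
                   mask = m, area = nrow(idx), label = "unknown"),
              class = "candidate_region")
  })
  regs <- Filter(Negate(is.null), regs)
  regs[order(vapply(regs, `[[`, 0, "area"), decreasing = TRUE)]
}

#' Crop, resize and normalise a candidate region
#'
#' Crops the grey ROI image over the region's bounding box, resizes the crop
#' bilinearly to 224 x 224, replicates the grey channel to 3 channels and
#' scales intensities from \[0, 255\] to \[0, 1\] -- the input format of the
#' downstream image classifier.
#'
#' @param roi a [map_to_grey()] result.
#' @param region a `candidate_region` (or a bbox vector `c(x_min, y_min,
#'   x_max, y_max)`).
#' @param size output side length; default 224.
#' @return numeric array `size x size x 3` in \[0, 1\].
#' @export
crop_resize_normalize <- function(roi, region, size = 224) {
  grey <- if (inherits(roi, "roi_image")) roi$grey else roi
  bb <- if (inherits(region, "candidate_region")) region$bbox else region
  bb <- as.integer(bb)
  if (bb[1] < 1 || bb[2] < 1 || bb[3] > ncol(grey) || bb[4] > nrow(grey))
    stop("bounding box outside image bounds")
  if (bb[3] < bb[1] || bb[4] < bb[2]) stop("degenerate (zero-area) box")
  crop <- grey[bb[2]:bb[4], bb[1]:bb[3], drop = FALSE]
  res <- EBImage::resize(EBImage::Image(t(crop)), w = size, h = size)
  block <- t(EBImage::imageData(res)) / 255
  array(block, dim = c(size, size, 3))
}

#' Run the full screening pipeline on one thermogram
#'
#' Grey mapping, centroid axis, asymmetry map, thresholding, opening and
#' candidate extraction in one call.
#'
#' @param tg a [thermogram()].
#' @param roi_mask neck ROI mask.
#' @param l asymmetry threshold, degC.
#' @param selem_radius opening disc radius, px.
#' @param min_area optional minimum region area, px.
#' @return list with `roi`, `centre`, `pa`, `mask` (after opening) and
#'   `regions`.
#' @export
detect_candidates <- function(tg, roi_mask, l = 0.3, selem_radius = 3,
                              min_area = 0) {
  roi <- map_to_grey(tg, roi_mask)
  o <- centroid(roi)
  pa <- asymmetry_map(tg, roi, o[["o_x"]])
  m <- open_mask(hot_candidates(pa, l), selem_radius)
  list(roi = roi, centre = o, pa = pa, mask = m,
       regions = extract_candidates(m, min_area))
}

#' Read / write temperature matrices and candidate regions
#'
#' Temperature matrices travel as headerless CSV (one image line per row)
#' with a JSON sidecar recording units; regions as a JSON list of boxes and
#' labels.
#'
#' @param M temperature matrix.
#' @param path file path.
#' @return `read_thermogram` returns a [thermogram()].
#' @export
write_thermogram <- function(M, path) {
  if (inherits(M, "thermogram")) M <- M$M
  data.table::fwrite(data.table::as.data.table(M), path, col.names = FALSE)
  jsonlite::write_json(list(units = "degC", ny = nrow(M), nx = ncol(M)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  thermogram(as.matrix(data.table::fread(path, header = FALSE)))
}

#' @rdname write_thermogram
#' @param regions list of `candidate_region`s.
#' @export
write_regions <- function(regions, path) {
  doc <- lapply(regions, function(r)
    list(bbox = as.list(r$bbox), area = r$area, label = r$label))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
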