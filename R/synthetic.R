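#' Synthetic-thermogram configuration
#'
#' Parameters of the synthetic neck-thermogram generator that stands in for
#' patient imagery: an elliptic neck ROI on a black background, a smooth
#' mirror-symmetric base temperature field, an optional nodular hot ellipse
#' (a truncated-Gaussian bump, the smooth diffusion-like footprint the
#' bioheat study predicts on skin), a low-order left/right drift emulating
#' imperfect patient symmetry, and i.i.d. Gaussian sensor noise.
#'
#' @param width,height image extents in pixels; default 640 x 480 (the
#'   reference camera resolution).
#' @param roi_semi ROI ellipse semi-axes (x, y) in px.
#' @param base_temp skin baseline temperature, degC.
#' @param base_amp amplitude of the symmetric central warm column, degC.
#' @param vert_grad top-to-bottom temperature gradient, degC.
#' @param delta_t nodular bump peak contrast, degC (0 = no nodule).
#' @param nodule_semi nodule ellipse semi-axes (x, y) in px.
#' @param nodule_offset nodule centre offset from the ROI centre (x, y) px;
#'   x must be nonzero so the lesion is lateralised.
#' @param benign_spots number of benign vascular warm streaks (elongated
#'   ellipses, placed randomly on the right side of the ROI); default 0. They
#'   emulate the normally hypervascular gland regions that survive screening
#'   as non-nodular candidates.
#' @param benign_dt,benign_semi peak contrast (degC) and semi-axes (px) of
#'   the benign streaks.
#' @param sigma sensor noise standard deviation, degC; default 0.04 (typical
#'   uncooled-microbolometer sensitivity).
#' @param drift_amp amplitude of the odd (antisymmetric) linear drift at the
#'   ROI edge, degC; default 0.1.
#' @param seed integer random seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(width = 640, height = 480,
                         roi_semi = c(250, 180),
                         base_temp = 32.5, base_amp = 1.5, vert_grad = 0.8,
                         delta_t = 1.0, nodule_semi = c(22, 14),
                         nodule_offset = c(-70, -30),
                         benign_spots = 0, benign_dt = 0.45,
                         benign_semi = c(32, 9),
                         sigma = 0.04, drift_amp = 0.1, seed = 1) {
  stopifnot(width > 0, height > 0, sigma >= 0, delta_t >= 0,
            all(roi_semi > 0), all(nodule_semi > 0), benign_spots >= 0)
  structure(list(width = width, height = height, roi_semi = roi_semi,
                 base_temp = base_temp, base_amp = base_amp,
                 vert_grad = vert_grad, delta_t = delta_t,
                 nodule_semi = nodule_semi, nodule_offset = nodule_offset,
                 benign_spots = benign_spots, benign_dt = benign_dt,
                 benign_semi = benign_semi,
                 sigma = sigma, drift_amp = drift_amp,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one synthetic thermogram
#'
#' The base field is exactly mirror-symmetric about the integer centre column
#' before nodule injection, drift and noise, so with `delta_t = 0`,
#' `sigma = 0` and `drift_amp = 0` the screening pipeline must return zero
#' candidates. The nodular bump has peak `delta_t` at its centre, decays as a
#' Gaussian in the normalised elliptic radius and is truncated at the ellipse
#' boundary; the ground-truth region mask is the ellipse support. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param config a [synth_config()].
#' @return list with `tg` (a [thermogram()]), `roi_mask` (logical matrix) and
#'   `regions` (list with one entry per injected nodule: `mask`, `bbox`,
#'   `label = "nodular"`).
#' @export
synth_thermogram <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cf$seed)

  nx <- cf$width; ny <- cf$height
  cx <- floor(nx / 2); cy <- ceiling(ny / 2)    # integer centre column
  xs <- matrix(rep(seq_len(nx), each = ny), ny)
  ys <- matrix(rep(seq_len(ny), nx), ny)
  ex <- (xs - cx) / cf$roi_semi[1]
  ey <- (ys - cy) / cf$roi_semi[2]
  roi <- ex^2 + ey^2 <= 1

  # mirror-symmetric smooth base: warm central column + vertical gradient
  M <- cf$base_temp + cf$base_amp * exp(-(ex^2) * 2 - (ey^2)) +
    cf$vert_grad * (ys / ny)

  regions <- list()
  if (cf$delta_t > 0) {
    nc <- c(cx, cy) + cf$nodule_offset
    d2 <- ((xs - nc[1]) / cf$nodule_semi[1])^2 +
      ((ys - nc[2]) / cf$nodule_semi[2])^2
    supp <- d2 <= 1
    if (!any(supp) || !all(roi[supp]))
      stop("nodule placed outside the ROI")
    bump <- ifelse(supp, cf$delta_t * exp(-d2 / 2), 0)
    M <- M + bump
    idx <- which(supp, arr.ind = TRUE)
    regions <- list(list(mask = supp,
                         bbox = c(x_min = min(idx[, 2]),
                                  y_min = min(idx[, 1]),
                                  x_max = max(idx[, 2]),
                                  y_max = max(idx[, 1])),
                         label = "nodular"))
  }
  if ((cf$benign_spots %||% 0) > 0) {
    for (b in seq_len(cf$benign_spots)) {
      bx <- cx + stats::runif(1, 0.15, 0.55) * cf$roi_semi[1]
      by <- cy + stats::runif(1, -0.5, 0.5) * cf$roi_semi[2]
      d2b <- ((xs - bx) / cf$benign_semi[1])^2 +
        ((ys - by) / cf$benign_semi[2])^2
      M <- M + ifelse(d2b <= 1, cf$benign_dt * exp(-d2b / 2), 0)
    }
  }
  if (cf$drift_amp != 0)
    M <- M + cf$drift_amp * (xs - cx) / cf$roi_semi[1]
  if (cf$sigma > 0)
    M <- M + matrix(stats::rnorm(nx * ny, 0, cf$sigma), ny)
  M[!roi] <- cf$base_temp - 10    # cold background outside the neck
  list(tg = thermogram(M), roi_mask = roi, regions = regions)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices of equal size.
#' @return IoU in \[0, 1\] (0 if the union is empty).
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# deterministic per-patient seed derived from a master seed (kept < 2^31)
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 1000003) %% 2147483629)
}

#' Generate a labelled crop for classifier experiments
#'
#' Small grey-level crops with the statistical signature of the screening
#' pipeline's output: smooth lateral gradient plus speckle for non-nodular
#' candidates, with an added central rounded hot blob for nodular ones.
#'
#' @param nodular logical.
#' @param seed integer seed.
#' @param size side length in px; default 64 (feature extraction is
#'   resolution-agnostic, so experiments stay light).
#' @return `size x size x 3` array in \[0, 1\].
#' @export
synth_crop <- function(nodular, seed, size = 64) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xs <- matrix(rep(seq_len(size), each = size), size) / size
  ys <- matrix(rep(seq_len(size), size), size) / size
  base <- 0.35 + 0.2 * xs + 0.1 * sin(pi * ys) +
    0.05 * matrix(stats::rnorm(size^2), size)
  if (nodular) {
    c0 <- 0.5 + stats::runif(2, -0.1, 0.1)
    d2 <- ((xs - c0[1]) / 0.22)^2 + ((ys - c0[2]) / 0.18)^2
    base <- base + 0.35 * exp(-d2)
  }
  block <- pmin(1, pmax(0, base))
  array(block, dim = c(size, size, 3))
}

#' Build a study-shaped synthetic dataset on disk
#'
#' Writes per-patient directories (temperature CSV, ROI PNG, labels JSON)
#' plus a top-level manifest. Per-patient seeds are derived deterministically
#' from the master seed. The default counts mirror the study design: 25
#' patients whose screening yielded 109 candidate regions, 26 of them
#' nodular, split 84 training (16 nodular / 68 non-nodular) and 25 testing.
#'
#' @param n_patients number of patients.
#' @param nodular_fraction fraction of patients carrying an injected nodule.
#' @param config a [synth_config()] template (its `seed` is overridden per
#'   patient).
#' @param seed master seed.
#' @param out_dir output directory (created).
#' @return data frame manifest (also written as `manifest.csv`).
#' @export
make_fixture_set <- function(n_patients, nodular_fraction = 0.5,
                             config = synth_config(), seed = 1,
                             out_dir) {
  stopifnot(n_patients >= 1, nodular_fraction >= 0, nodular_fraction <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_nod <- round(n_patients * nodular_fraction)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    cf <- config
    cf$seed <- .derive_seed(seed, i)
    cf$delta_t <- if (i <= n_nod) max(config$delta_t, 1e-6) else 0
    sy <- synth_thermogram(cf)
    pdir <- file.path(out_dir, sprintf("patient_%03d", i))
    dir.create(pdir, showWarnings = FALSE)
    write_thermogram(sy$tg, file.path(pdir, "matrix.csv"))
    EBImage::writeImage(EBImage::Image(t(sy$roi_mask * 1)),
                        file.path(pdir, "roi.png"))
    jsonlite::write_json(
      lapply(sy$regions, function(r) list(bbox = as.list(r$bbox),
                                          label = r$label)),
      file.path(pdir, "labels.json"), auto_unbox = TRUE)
    rows[[i]] <- data.frame(patient = i, dir = pdir,
                            nodular = cf$delta_t > 0, seed = cf$seed)
  }
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Study-shaped crop dataset
#'
#' Generates the candidate-crop dataset with the study's class structure:
#' 109 regions (26 nodular, 83 non-nodular) split into 84 training crops
#' (16 nodular / 68 non-nodular) and 25 test crops (10 nodular / 15
#' non-nodular).
#'
#' @param seed master seed.
#' @param size crop side length, px.
#' @return list with `train`, `test`; each has `crops` (list of arrays) and
#'   `labels` (logical, `TRUE` = nodular).
#' @export
study_shaped_crops <- function(seed = 1, size = 64) {
  lay <- list(train = c(nodular = 16, non_nodular = 68),
              test = c(nodular = 10, non_nodular = 15))
  i <- 0
  out <- lapply(lay, function(cnt) {
    labels <- rep(c(TRUE, FALSE), cnt)
    crops <- lapply(seq_along(labels), function(j) {
      i <<- i + 1
      synth_crop(labels[j], .derive_seed(seed, i), size)
    })
    list(crops = crops, labels = labels)
  })
  out
}
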