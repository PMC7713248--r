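test_that("outer radius and skin arc follow the additive layer model", {
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  expect_equal(g$outer_radius, 3.87 + 1.0 + 1.2 + 0.2)
  expect_equal(skin_arc_length(g), pi * 6.27)
  expect_equal(skin_arc_length(g), 19.7, tolerance = 0.005)

  g2 <- build_neck_section(0.1)
  expect_equal(g2$outer_radius, 5.17)
  expect_equal(skin_arc_length(g2), pi * 5.17)
  expect_equal(skin_arc_length(g2), 16.24, tolerance = 0.001)

  # slope pi in fat thickness
  fats <- c(0.1, 0.6, 1.2)
  arcs <- vapply(fats, function(f) skin_arc_length(build_neck_section(f)),
                 0)
  expect_equal(diff(arcs) / diff(fats), rep(pi, 2))
})

test_that("geometry validation rejects bad inputs", {
  expect_error(build_neck_section(-0.5), "positive")
  expect_error(nodule_spec(0, 1), "positive")
  expect_error(build_neck_section(1.2, nodule_spec(1, 1.57),
                                  overrides = list(skin_thickness = -1)),
               "positive")
  # nodule centred in the fat layer: not in the gland band
  expect_error(build_neck_section(
    1.2, nodule_spec(1.0, 1.57, center = c(0, 5.5))), "containment")
  # nodule centre in the band but ellipse hitting the trachea
  expect_error(build_neck_section(
    1.2, nodule_spec(2.5, 3.0, center = c(0, 2.2))), "containment")
})

test_that("tissue_at classifies layers with outer-owns-boundary rule", {
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  ctr <- g$nodule$center
  expect_identical(tissue_at(g, ctr[1], ctr[2]), "nodule")
  # contralateral point is plain gland
  expect_identical(tissue_at(g, -ctr[1], ctr[2]), "thyroid")
  expect_identical(tissue_at(g, 0, g$outer_radius - 0.1), "skin")
  # point exactly on the fat/skin interface belongs to skin
  r_fs <- g$core_radius + g$muscle_thickness + g$fat_thickness
  expect_identical(tissue_at(g, 0, r_fs), "skin")
  expect_identical(tissue_at(g, 0, r_fs - 1e-9), "fat")
  # muscle/fat interface belongs to fat
  r_mf <- g$core_radius + g$muscle_thickness
  expect_identical(tissue_at(g, 0, r_mf), "fat")
  # deep interior is muscle tissue
  expect_identical(tissue_at(g, 3, 0.5), "muscle")
  # outside the domain and inside the trachea hole
  expect_error(tissue_at(g, 0, g$outer_radius + 1), "outside")
  expect_error(tissue_at(g, 0, 1.0), "outside")
  expect_identical(tissue_at(g, 0, 1.0, on_outside = "na"), NA_character_)
})

test_that("tissue_at partitions the domain and nodule area matches pi*a*b/4", {
  g <- build_neck_section(0.6, nodule_spec(1.5, 2.36))
  set.seed(42)
  n <- 1e6
  R <- g$outer_radius
  x <- runif(n, -R, R); y <- runif(n, 0, R)
  lab <- tissue_at(g, x, y, on_outside = "na")
  inside <- !is.na(lab)
  expect_true(all(lab[inside] %in%
                    c("skin", "fat", "muscle", "thyroid", "nodule")))
  area_box <- 2 * R * R
  mc_area <- mean(lab == "nodule", na.rm = FALSE)
  mc_area <- sum(lab == "nodule", na.rm = TRUE) / n * area_box
  expect_equal(mc_area, pi * 1.5 * 2.36 / 4, tolerance = 0.01)
})

test_that("default nodule anchor sits on the left lobe anterior face", {
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  ctr <- g$nodule$center
  expect_lt(ctr[1], 0)                      # left side
  d <- sqrt(sum((ctr - g$trachea_center)^2))
  expect_equal(d, g$thyroid_outer, tolerance = 1e-9)
  # major axis tangential: perpendicular to the trachea-radial direction
  rad <- atan2(ctr[2] - g$trachea_center[2], ctr[1] - g$trachea_center[1])
  expect_equal(abs(sin(g$nodule$orientation - rad)), 1, tolerance = 1e-9)
})

test_that("geometry JSON round-trip preserves the model", {
  g <- build_neck_section(0.6, nodule_spec(1.0, 1.57),
                          overrides = list(trachea_radius = 1.1,
                                           thyroid_inner = 1.1,
                                           thyroid_half_angle = 1.0))
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$outer_radius, g$outer_radius)
  expect_equal(g2$nodule$center, g$nodule$center, tolerance = 1e-12)
  expect_equal(g2$thyroid_half_angle, 1.0)
})

test_that("rasterized tissue mask is consistent with point lookup", {
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  m <- rasterize_geometry(g, resolution = 0.1)
  lev <- attr(m, "levels")
  expect_setequal(lev[sort(unique(m[m > 0]))],
                  c("skin", "fat", "muscle", "thyroid", "nodule"))
  # nodule pixels exist and are on the left half
  nod <- which(m == match("nodule", lev), arr.ind = TRUE)
  expect_gt(nrow(nod), 0)
  xs <- seq(-g$outer_radius + 0.05, g$outer_radius, by = 0.1)
  expect_true(all(xs[nod[, 2]] < 0))
})
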