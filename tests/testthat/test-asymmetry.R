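test_that("grey mapping sends the ROI range onto [1, 255]", {
  M <- matrix(c(30, 30.5, 31, 25), 1)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1)
  roi <- map_to_grey(thermogram(M), mask)
  expect_identical(roi$grey, matrix(c(1L, 128L, 255L, 0L), 1))
  expect_equal(roi$N_p, 3)

  two <- map_to_grey(matrix(c(30, 31), 1), matrix(c(TRUE, TRUE), 1))
  expect_identical(as.vector(two$grey), c(1L, 255L))

  # constant ROI convention and empty ROI error
  const <- map_to_grey(matrix(30, 2, 2), matrix(TRUE, 2, 2))
  expect_true(all(const$grey == 255L))
  expect_error(map_to_grey(matrix(30, 2, 2), matrix(FALSE, 2, 2)),
               "empty ROI")
})

test_that("centroid averages foreground coordinates", {
  expect_equal(as.vector(centroid(matrix(1, 3, 4))), c(2.5, 2))
  m <- matrix(0, 3, 3)
  m[1, 1] <- 1; m[1, 3] <- 1; m[2, 3] <- 1   # (x,y) = (1,1), (3,1), (3,2)
  o <- centroid(m)
  expect_equal(o[["o_x"]], 7 / 3)
  expect_equal(o[["o_y"]], 4 / 3)
  # mirror-symmetric mask about a column
  ms <- matrix(0, 4, 7); ms[2:3, 2:6] <- 1
  expect_equal(centroid(ms)[["o_x"]], 4)
})

test_that("asymmetry map matches the hand-worked row and is antisymmetric", {
  M <- matrix(c(30, 31, 33, 30), 1)
  mask <- matrix(TRUE, 1, 4)
  pa <- asymmetry_map(thermogram(M), mask)     # o_x = 2.5
  expect_equal(as.vector(pa$P_A), c(0, -2, 2, 0))
  l <- hot_candidates(pa, 0.3)
  expect_identical(as.vector(l), c(FALSE, FALSE, TRUE, FALSE))

  # antisymmetry is exact on every defined pixel of a random thermogram
  set.seed(7)
  M2 <- matrix(rnorm(40 * 60, 31, 0.5), 40)
  mask2 <- matrix(FALSE, 40, 60)
  mask2[5:35, 8:55] <- TRUE
  mask2[10:14, 8:12] <- FALSE                  # ragged ROI
  pa2 <- asymmetry_map(M2, mask2)
  ax2 <- round(2 * pa2$axis_col)
  for (p in sample(which(pa2$defined), 200)) {
    y <- (p - 1) %% 40 + 1; x <- (p - 1) %/% 40 + 1
    expect_equal(pa2$P_A[y, x], -pa2$P_A[y, ax2 - x])
  }
  # defined set only where the mirror is in the ROI
  expect_true(all(is.na(pa2$P_A[!pa2$defined])))
})

test_that("symmetric thermograms yield an identically zero map", {
  M <- matrix(rnorm(30 * 21, 31), 30, 21)
  M <- (M + M[, 21:1]) / 2                     # symmetric about column 11
  mask <- matrix(TRUE, 30, 21)
  pa <- asymmetry_map(M, mask)
  expect_true(all(pa$P_A[pa$defined] == 0))
  expect_equal(sum(hot_candidates(pa, 1e-9)), 0)
})

test_that("threshold monotonicity: higher l selects a subset", {
  set.seed(11)
  M <- matrix(rnorm(50 * 50, 31, 0.6), 50)
  mask <- matrix(TRUE, 50, 50)
  pa <- asymmetry_map(M, mask)
  m1 <- hot_candidates(pa, 0.2)
  m2 <- hot_candidates(pa, 0.8)
  expect_true(all(m1[m2]))
  expect_lte(sum(m2), sum(m1))
  expect_equal(sum(hot_candidates(pa, Inf)), 0)
  expect_error(hot_candidates(pa, 0), "positive")
})

test_that("opening matches a brute-force erosion/dilation oracle", {
  se <- EBImage::makeBrush(7, "disc")
  # isolated pixel disappears
  iso <- matrix(FALSE, 15, 15); iso[8, 8] <- TRUE
  expect_equal(sum(open_mask(iso, 3)), 0)
  # a solid square survives up to disc-rounded corners: oracle comparison
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  expect_identical(open_mask(sq, 3), brute_open(sq, se))
  expect_equal(sum(open_mask(sq, 3)), 400 - 12)  # 3 px lost per corner
  # L-shaped thin arm on a blob: arm removed, blob kept
  L <- matrix(FALSE, 40, 40)
  L[10:24, 10:24] <- TRUE        # blob
  L[25:36, 12] <- TRUE           # 1-px arm
  op <- open_mask(L, 3)
  expect_identical(op, brute_open(L, se))
  expect_false(any(op[28:36, 12]))
  expect_true(all(op[13:21, 13:21]))
  # opening never grows the mask
  expect_true(all(L[op]))
})

test_that("candidate extraction finds 8-connected boxes sorted by area", {
  expect_identical(extract_candidates(matrix(FALSE, 5, 5)), list())
  m <- matrix(FALSE, 20, 30)
  m[3:6, 4:9] <- TRUE            # 24 px blob
  m[10:18, 15:17] <- TRUE        # 27 px blob
  m[7, 10] <- TRUE               # diagonal link to blob 1 corner
  regs <- extract_candidates(m)
  expect_equal(length(regs), 2)
  expect_equal(regs[[1]]$area, 27)
  expect_equal(unname(regs[[1]]$bbox), c(15, 10, 17, 18))
  expect_equal(regs[[2]]$area, 25)   # diagonal pixel joins 8-connected blob
  expect_equal(unname(regs[[2]]$bbox), c(4, 3, 10, 7))
  # agreement with an independent component count
  set.seed(3)
  rnd <- matrix(runif(40 * 40) < 0.2, 40)
  expect_equal(length(extract_candidates(rnd)), brute_components8(rnd))
  # min-area filter
  expect_equal(length(extract_candidates(m, min_area = 26)), 1)
  # full-frame blob
  full <- extract_candidates(matrix(TRUE, 8, 9))
  expect_equal(length(full), 1)
  expect_equal(unname(full[[1]]$bbox), c(1, 1, 9, 8))
})

test_that("crop/resize/normalise produces unit-range 3-channel blocks", {
  grey <- matrix(255L, 40, 40)
  blk <- crop_resize_normalize(grey, c(5, 5, 30, 30))
  expect_equal(dim(blk), c(224, 224, 3))
  expect_true(all(blk == 1))
  # identity resize up to rounding
  g2 <- matrix(sample(0:255, 224 * 224, TRUE), 224)
  blk2 <- crop_resize_normalize(g2, c(1, 1, 224, 224))
  expect_equal(blk2[, , 1], g2 / 255, tolerance = 1e-6)
  expect_identical(blk2[, , 1], blk2[, , 3])
  # 2x2 checkerboard: bilinear plateau keeps range and mean
  cb <- matrix(c(0L, 255L, 255L, 0L), 2)
  blk3 <- crop_resize_normalize(cb, c(1, 1, 2, 2))
  expect_equal(min(blk3), 0)
  expect_equal(max(blk3), 1)
  expect_equal(mean(blk3), 0.5, tolerance = 0.01)
  expect_error(crop_resize_normalize(grey, c(10, 10, 9, 12)), "degenerate")
  expect_error(crop_resize_normalize(grey, c(0, 1, 5, 5)), "bounds")
})

test_that("pipeline equivariance: mirroring the thermogram mirrors the boxes", {
  sy <- synth_thermogram(synth_config(seed = 21, sigma = 0.02))
  det <- detect_candidates(sy$tg, sy$roi_mask, l = 0.3)
  ax2 <- round(2 * det$pa$axis_col)
  Mf <- sy$tg$M[, ncol(sy$tg$M):1]
  # mirror about the pipeline axis equals column reversal here because the
  # ROI is symmetric about the image centre
  detf <- detect_candidates(thermogram(Mf), sy$roi_mask[, ncol(Mf):1],
                            l = 0.3)
  expect_equal(length(det$regions), length(detf$regions))
  if (length(det$regions)) {
    bb <- det$regions[[1]]$bbox
    bf <- detf$regions[[1]]$bbox
    expect_equal(unname(bf[c("x_min", "x_max")]),
                 unname(ncol(Mf) + 1 - bb[c("x_max", "x_min")]))
    expect_equal(unname(bf[c("y_min", "y_max")]),
                 unname(bb[c("y_min", "y_max")]))
  }
})

test_that("thermogram CSV round-trip preserves temperatures", {
  M <- matrix(rnorm(12, 31), 3, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram(M, path)
  back <- read_thermogram(path)
  expect_equal(back$M, M, tolerance = 1e-12, ignore_attr = TRUE)
})
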