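test_that("skin profile spans the arc and is symmetric without a nodule", {
  cf <- cached_field(nodule = NULL, units = "literal")
  prof <- skin_profile(cf$field, cf$geometry, n_samples = 257)
  expect_equal(prof$position[1], 0)
  expect_equal(prof$position[nrow(prof)], skin_arc_length(cf$geometry))
  expect_true(all(diff(prof$position) > 0))
  expect_lt(max(abs(prof$temperature - rev(prof$temperature))), 0.01)
})

test_that("geometry mismatch is caught", {
  cf <- cached_field()
  expect_error(skin_profile(cf$field, build_neck_section(0.6)),
               "not solved on this geometry")
})

test_that("line profile reproduces the reported interior structure", {
  cf <- cached_field()   # fat 1.2, 1.0 x 1.57 nodule, calibrated perfusion
  prof <- line_profile(cf$field)
  expect_true(all(diff(prof$position) > 0))
  expect_true(all(c("nodule", "muscle", "fat", "skin") %in% prof$tissue))
  # layer drops along the radial line through the nodule: the muscle drop is
  # about 0.5 degC and the fat-layer drop dominates (insulation)
  dm <- layer_drop(prof, cf$geometry, "muscle")
  df <- layer_drop(prof, cf$geometry, "fat")
  expect_equal(dm, 0.5, tolerance = 0.3)
  expect_equal(df, 1.8, tolerance = 0.3)
  expect_gt(df, dm)
  # a layer absent from the profile is rejected
  cf0 <- cached_field(nodule = NULL, units = "literal")
  prof0 <- line_profile(cf0$field, c(0, 2.2), c(0, cf0$geometry$outer_radius))
  expect_error(layer_drop(prof0, cf0$geometry, "nodule"), "does not cross")
})

test_that("constant field yields flat profiles and zero drops", {
  ov <- lapply(setNames(nm = c("skin", "fat", "muscle", "thyroid", "nodule")),
               function(n) list(Q_met = 0, w_b = 0))
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  fld <- solve_steady(pennes_problem(g, tissue_properties(overrides = ov),
                                     h_conv = 1e9, T_air = 37), 0.05)
  prof <- line_profile(fld)
  expect_lt(diff(range(prof$temperature)), 1e-8)
  expect_equal(layer_drop(prof, g, "fat"), 0, tolerance = 1e-8)
  sp <- skin_profile(fld, g)
  expect_lt(diff(range(sp$temperature)), 1e-7)
})

test_that("surface contrast flags, mirrors and degenerates correctly", {
  cf <- cached_field(nodule = NULL, units = "literal")
  sp <- skin_profile(cf$field, cf$geometry)
  ct0 <- surface_contrast(sp, cf$geometry, NULL)
  expect_equal(as.numeric(ct0), 0)
  expect_true(attr(ct0, "no_nodule"))

  # thin fat, large nodule: clearly perceptible hot spot in front of it
  cf1 <- cached_field(fat = 0.1, nodule = nodule_spec(2.0, 3.14))
  sp1 <- skin_profile(cf1$field, cf1$geometry, 1024)
  ct1 <- surface_contrast(sp1, cf1$geometry)
  expect_gt(ct1, 0.05)
  expect_true(attr(ct1, "perceptible"))
  # peak of the asymmetry lies near the arc point in front of the nodule
  asym <- sp1$temperature - rev(sp1$temperature)
  s_peak <- sp1$position[which.max(asym)]
  th_nod <- atan2(cf1$geometry$nodule$center[2],
                  cf1$geometry$nodule$center[1])
  s_nod <- (pi - th_nod) * cf1$geometry$outer_radius
  expect_lt(abs(s_peak - s_nod), 1)

  # same fat, small nodule: weaker contrast (monotone in source volume)
  cfs <- cached_field(fat = 0.1, nodule = nodule_spec(0.5, 0.78))
  cts <- surface_contrast(skin_profile(cfs$field, cfs$geometry, 1024),
                          cfs$geometry)
  expect_gt(ct1, cts)
})

test_that("sweep tabulates combinations, deduplicates and propagates errors", {
  one <- run_sweep(list(nodule_spec(1.0, 1.57)), 0.6, resolution = 0.05)
  expect_s3_class(one, "sweep_result")
  expect_equal(nrow(one), 1)
  dup <- run_sweep(list(nodule_spec(1.0, 1.57), nodule_spec(1.0, 1.57)),
                   c(0.6, 0.6), resolution = 0.05)
  expect_equal(nrow(dup), 1)
  expect_error(run_sweep(list(nodule_spec(9, 12)), 0.6, resolution = 0.05),
               "sweep failed at size 9x12")
})

test_that("profile and sweep tables round-trip through CSV", {
  cf <- cached_field()
  prof <- skin_profile(cf$field, cf$geometry, 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  back <- utils::read.csv(path)
  expect_equal(back$temperature, prof$temperature, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".meta.json")))
})
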