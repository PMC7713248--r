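test_that("constant temperature is recovered when all sources vanish", {
  # no metabolic heat, no perfusion, ambient pinned at core temperature with
  # a near-infinite convection coefficient: T = 37 is the exact solution
  ov <- lapply(setNames(nm = c("skin", "fat", "muscle", "thyroid", "nodule")),
               function(n) list(Q_met = 0, w_b = 0))
  pr <- pennes_problem(build_neck_section(1.2, nodule_spec(1.0, 1.57)),
                       tissue_properties(overrides = ov),
                       h_conv = 1e9, T_air = 37, T_core = 37)
  fld <- solve_steady(pr, 0.05)
  expect_lt(max(abs(fld$T - 37), na.rm = TRUE), 1e-8)
})

test_that("solver agrees with the 1-D analytic multilayer oracle", {
  sl <- slab_layers(c("muscle", "fat", "skin"), c(1.0, 1.2, 0.2))
  pr <- pennes_problem(sl, tissue_properties())
  num <- solve_steady(pr, 0.01)
  sol <- analytic_slab(sl, tissue_properties())
  expect_lt(max(abs(num$T - sol$temperature(num$x))), 1e-3)
  # a second stack with the calibrated nodule as inner layer
  sl2 <- slab_layers(c("nodule", "muscle", "fat", "skin"),
                     c(0.5, 1.0, 0.6, 0.2))
  props <- tissue_properties("calibrated")
  num2 <- solve_steady(pennes_problem(sl2, props), 0.01)
  sol2 <- analytic_slab(sl2, props)
  expect_lt(max(abs(num2$T - sol2$temperature(num2$x))), 1e-3)
})

test_that("resolution guard rejects grids coarser than the skin layer", {
  pr <- pennes_problem(build_neck_section(1.2), tissue_properties())
  expect_error(solve_steady(pr, 0.1), "resolution too coarse")
})

test_that("discrete maximum principle holds without metabolic heat", {
  ov <- lapply(setNames(nm = c("skin", "fat", "muscle", "thyroid", "nodule")),
               function(n) list(Q_met = 0))
  pr <- pennes_problem(build_neck_section(0.6, nodule_spec(1.0, 1.57)),
                       tissue_properties(overrides = ov))
  fld <- solve_steady(pr, 0.05)
  expect_gte(min(fld$T, na.rm = TRUE), 20 - 1e-9)
  expect_lte(max(fld$T, na.rm = TRUE), 37 + 1e-9)
})

test_that("nodule-free field is mirror-symmetric about the midline", {
  cf <- cached_field(nodule = NULL, units = "literal")
  Tm <- cf$field$T
  expect_lt(max(abs(Tm - Tm[, rev(seq_len(ncol(Tm)))]), na.rm = TRUE), 1e-6)
})

test_that("halving the grid step barely moves the nodule-centre reading", {
  g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
  ctr <- g$nodule$center
  props <- tissue_properties("calibrated")
  t_coarse <- sample_field(solve_steady(pennes_problem(g, props), 0.05),
                           ctr[1], ctr[2])
  t_fine <- sample_field(solve_steady(pennes_problem(g, props), 0.025),
                         ctr[1], ctr[2])
  expect_lt(abs(t_coarse - t_fine), 0.05)
})

test_that("thicker fat insulates: anterior skin cools as fat grows", {
  skin_T <- vapply(c(0.1, 0.6, 1.2), function(fat) {
    cf <- cached_field(fat = fat, units = "calibrated")
    # skin surface in front of the gland (anterior midline)
    idx <- which.min(abs(cf$field$domain$u - 0.5))
    cf$field$T_surface[idx]
  }, 0)
  expect_true(all(diff(skin_T) < 0))
})

test_that("solved field satisfies the assembled balance tightly", {
  cf <- cached_field()
  expect_lt(cf$field$residual, 1e-8)
})

test_that("transient solver respects its contracts", {
  pr <- pennes_problem(build_neck_section(1.2, nodule_spec(1.0, 1.57)),
                       tissue_properties("calibrated"))
  expect_error(solve_transient(pr, 0.05, t_end = 10, dt = -1), "positive")
  # t_end = 0 returns the initial condition
  out0 <- solve_transient(pr, 0.05, t_end = 0, dt = 1)
  expect_equal(out0$times, 0)
  expect_true(all(abs(out0$fields[[1]]$T - 20) < 1e-12, na.rm = TRUE))
  # the steady field is a fixed point of the implicit scheme
  st <- cached_field()$field
  fix <- solve_transient(pr, 0.05, t_end = 600, dt = 300, init = st,
                         snapshots = 1)
  expect_lt(max(abs(fix$fields[[length(fix$fields)]]$T - st$T),
                na.rm = TRUE), 1e-6)
  # a cold start approaches the steady solution monotonically in sup-norm
  ev <- solve_transient(pr, 0.05, t_end = 4 * 3600, dt = 600,
                        init = "ambient", snapshots = 4)
  gaps <- vapply(ev$fields, function(f)
    max(abs(f$T - st$T), na.rm = TRUE), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 0.35)
})
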