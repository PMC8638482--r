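test_that("feature counts follow the truncated second-order structure", {
  g <- kernel_geometry(1, 2, b1 = 0, b2 = 0, h1 = -1, h2 = 1)  # L=1 B=1 H=3
  expect_identical(n_features(g), 1L + 3L + 3L + 2L + 1L)      # 10
  g <- kernel_geometry(4, 2, b1 = -1, b2 = 2, h1 = -2, h2 = 2) # L=4 B=4 H=5
  expect_identical(n_features(g), 1L + 80L + 80L + 64L + 48L)  # 273
  g1 <- kernel_geometry(4, 2, second_order = FALSE)
  expect_identical(n_features(g1), 1L + 80L)
})

test_that("all-zero sources give the bare constant feature", {
  g <- kernel_geometry(2, 2, b1 = -1, b2 = 1, h1 = -1, h2 = 1)
  slab <- array(0i, c(12, 8, 2))
  f <- build_features(slab, 4L, 3:5, g)
  expect_identical(dim(f), c(3L, n_features(g)))
  expect_true(all(f[, 1] == 1 + 0i))
  expect_true(all(f[, -1] == 0i))
})

test_that("strict edge mode rejects out-of-bounds sources", {
  g <- kernel_geometry(1, 2, b1 = -1, b2 = 1, h1 = -1, h2 = 1)
  slab <- array(1 + 0i, c(8, 6, 1))
  expect_error(build_features(slab, 0L, 3L, g, edge_mode = "strict"), "strict")
  expect_silent(build_features(slab, 0L, 3L, g, edge_mode = "zero"))
})

test_that("calibration recovers an exact truncated second-order model", {
  inst <- exact_nlg_instance()
  kern <- nlg_calibrate(inst$kspace, inst$plan$acs_mask, inst$geom,
                        reg_rel = 0)
  expect_lt(kern$calib_residual_rel, 1e-10)
  filled <- nlg_apply(apply_mask(inst$kspace,
                                 t(matrix(inst$plan$uniform_mask[1, ],
                                          inst$plan$n_pe, inst$plan$n_frames))),
                      kern, inst$plan, measured = inst$kspace)
  expect_lt(sqrt(sum(Mod(filled - inst$kspace)^2) / sum(Mod(inst$kspace)^2)),
            1e-8)
})

test_that("duplicated calibration frames do not change the kernel", {
  inst <- exact_nlg_instance(nf = 2)
  k2 <- inst$kspace[, , c(1, 2, 1, 2), , drop = FALSE]
  plan2 <- sampling_plan(inst$plan$n_pe, inst$plan$n_fe, 4, r1 = 2, r2 = 1,
                         n_acs = inst$plan$n_acs, seed = 1)
  ka <- nlg_calibrate(inst$kspace, inst$plan$acs_mask, inst$geom,
                      reg_rel = 1e-8)
  kb <- nlg_calibrate(k2, plan2$acs_mask, inst$geom, reg_rel = 1e-8)
  for (r in seq_along(ka$weights)) {
    expect_lt(max(Mod(ka$weights[[r]] - kb$weights[[r]])),
              1e-6 * max(Mod(ka$weights[[r]])))
  }
})

test_that("recalibration after complex rescaling stays exact", {
  inst <- exact_nlg_instance()
  cscale <- 0.7 - 1.9i
  kern <- nlg_calibrate(inst$kspace * cscale, inst$plan$acs_mask, inst$geom,
                        reg_rel = 0)
  expect_lt(kern$calib_residual_rel, 1e-8)
})

test_that("orf = 1 kernels apply as the identity", {
  set.seed(10)
  k <- array(rcomplex(16 * 8 * 2 * 2), c(16, 8, 2, 2))
  plan <- sampling_plan(16, 8, 2, r1 = 1, r2 = 1, n_acs = 6, seed = 1)
  g <- kernel_geometry(2, 1)
  kern <- nlg_calibrate(k, plan$acs_mask, g)
  expect_identical(nlg_apply(k, kern, plan), k)
})

test_that("geometry inconsistent with the plan is rejected", {
  inst <- exact_nlg_instance()
  kern <- nlg_calibrate(inst$kspace, inst$plan$acs_mask, inst$geom, 1e-8)
  plan3 <- sampling_plan(inst$plan$n_pe, inst$plan$n_fe, 3, r1 = 3, r2 = 1,
                         n_acs = 24, seed = 1)
  expect_error(nlg_apply(inst$kspace, kern, plan3), "inconsistent")
})

test_that("acquired and lattice locations pass through bit-identically", {
  dat <- tiny_dataset(n = 32, nf = 3, coils = 2, r1 = 2, r2 = 1, n_acs = 12)
  k <- dat$ds$kspace
  g <- kernel_geometry(2, 2, h1 = -1, h2 = 1)
  kern <- nlg_calibrate(k, dat$plan$acs_mask, g, reg_rel = 1e-8)
  out <- nlg_apply(k, kern, dat$plan)
  lat <- dat$plan$uniform_mask[1, ]
  expect_identical(out[lat, , , ], k[lat, , , ])
  for (f in 1:3) {
    rows <- dat$plan$acquired_mask[f, ] | dat$plan$acs_mask
    expect_identical(out[rows, , f, ], k[rows, , f, ])
  }
  # nothing left unfilled
  expect_true(all(Mod(out[, , , ]) > 0 | Mod(k[, , , ]) == 0))
})

test_that("frame permutation commutes with kernel application", {
  inst <- exact_nlg_instance(nf = 3)
  kern <- nlg_calibrate(inst$kspace, inst$plan$acs_mask, inst$geom, 1e-8)
  latmask <- t(matrix(inst$plan$uniform_mask[1, ], inst$plan$n_pe, 3))
  kin <- apply_mask(inst$kspace, latmask)
  out <- nlg_apply(kin, kern, inst$plan, measured = inst$kspace)
  perm <- c(2, 3, 1)
  outp <- nlg_apply(kin[, , perm, , drop = FALSE], kern, inst$plan,
                    measured = inst$kspace[, , perm, , drop = FALSE])
  expect_identical(as.vector(outp), as.vector(out[, , perm, , drop = FALSE]))
})

test_that("first-order-only kernels match an independent linear GRAPPA", {
  dat <- tiny_dataset(n = 24, nf = 2, coils = 2, r1 = 2, r2 = 1, n_acs = 12)
  k <- dat$ds$kspace
  g <- kernel_geometry(2, 2, b1 = -1, b2 = 1, h1 = -1, h2 = 1,
                       second_order = FALSE)
  kern <- nlg_calibrate(k, dat$plan$acs_mask, g, reg_rel = 0)
  ours <- nlg_apply(apply_mask(k, t(matrix(dat$plan$uniform_mask[1, ], 24, 2))),
                    kern, dat$plan, measured = k)
  oracle <- linear_grappa_oracle(k, dat$plan$acs_mask, 2, -1, 1, -1, 1,
                                 dat$plan)
  expect_lt(max(Mod(ours - oracle)), 1e-10 * max(Mod(k)))
})
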