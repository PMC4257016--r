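test_that("gamma-variate AIF: support, linearity, peak location", {
  tg <- seq(0, 90, by = 2)
  p <- gamma_variate_params(amplitude = 5, t0 = 20, alpha = 2, beta = 1)
  crv <- gamma_variate_aif(p, tg)
  expect_true(all(crv >= 0))
  expect_true(all(crv[tg <= p$t0] == 0))
  # unimodal: one sign change of the finite difference
  d <- diff(crv[crv > 0 | c(diff(crv) != 0, FALSE)])
  expect_lte(sum(diff(sign(diff(crv))) != 0), 2)

  # all t before arrival -> all-zero curve
  expect_equal(gamma_variate_aif(gamma_variate_params(t0 = 200), tg),
               rep(0, length(tg)))

  # linear in amplitude
  p2 <- gamma_variate_params(amplitude = 10, t0 = 20, alpha = 2, beta = 1)
  expect_equal(gamma_variate_aif(p2, tg), 2 * crv)

  # peak at t0 + alpha * beta on a 1 ms grid
  pf <- gamma_variate_params(amplitude = 1, t0 = 10, alpha = 3, beta = 1.5)
  fine <- seq(0, 40, by = 0.001)
  crvf <- gamma_variate_aif(pf, fine)
  expect_equal(fine[which.max(crvf)], 14.5, tolerance = 1e-6)
  expect_equal(max(crvf), pf$amplitude, tolerance = 1e-9)

  # non-uniform grid rejected
  expect_error(gamma_variate_aif(p, c(0, 1, 3, 4)), "uniform")
})

test_that("tissue concentration follows the discrete convolution model", {
  tg <- (0:44) * 2
  aif <- gamma_variate_aif(gamma_variate_params(), tg)

  # zero flow -> zero curve, not an error
  dead <- tissue_class("core", cbf_true = 0, cbv_true = 0, delay_true = 0,
                       adc_true = 400e-6)
  expect_equal(tissue_concentration(aif, dead, 2), rep(0, 45))

  # boxcar with MTT below dt: tissue curve is a scaled copy of the AIF
  fastcls <- tissue_class("vessel", cbf_true = 100, cbv_true = 1,
                          delay_true = 0, adc_true = 3e-3,
                          residue_model = "boxcar")
  ct <- tissue_concentration(aif, fastcls, 2)
  fr <- 100 * 1.04 / (100 * 60 * 0.73)  # flow scale, 1/s
  expect_equal(ct, 2 * fr * aif, tolerance = 1e-12)
  expect_equal(ct, direct_convolution_oracle(aif, c(fr, rep(0, 44)), 2))

  # area ratio equals the blood-volume fraction (trapezoid oracle)
  for (cls in default_tissue_classes()[c("normal_wm", "core")]) {
    ct <- tissue_concentration(aif, cls, 2)
    trap <- function(x) sum((x[-1] + x[-length(x)]) / 2) * 2
    expect_equal(trap(ct) / trap(aif), cbv_fraction(cls$cbv_true),
                 tolerance = 5e-3)
  }

  # matches the direct convolution oracle for a delayed exponential class
  cls <- default_tissue_classes()$penumbra
  ct <- tissue_concentration(aif, cls, 2)
  a <- 1 - 2 / cls$mtt_true
  fr <- cls$cbf_true * 1.04 / (100 * 60 * 0.73) *
    ifelse(tg < cls$delay_true, 0, a^((tg - cls$delay_true) / 2))
  expect_equal(ct, direct_convolution_oracle(aif, fr, 2), tolerance = 1e-12)
})

test_that("rendered PWI is deterministic and constant without contrast", {
  # zero concentration everywhere -> constant S0
  cls <- list(normal_wm = tissue_class("normal_wm", 0, 0, 0, 800e-6))
  spec <- phantom_spec(grid_shape = c(4, 4, 2), noise_sigma = 0,
                       class_map = array(1L, c(4, 4, 2)), classes = cls)
  out <- render_pwi(spec)
  expect_true(all(out$series$data == spec$s0))

  # identical spec + seed -> bit-identical data
  s1 <- phantom_spec(noise_sigma = 5, rng_seed = 42L)
  expect_identical(render_pwi(s1)$series$data, render_pwi(s1)$series$data)
  s2 <- phantom_spec(noise_sigma = 5, rng_seed = 43L)
  expect_false(identical(render_pwi(s1)$series$data,
                         render_pwi(s2)$series$data))
})

test_that("rendered DWI inverts exactly and honours its truth map", {
  # zero ADC -> S_b equals S0 exactly (noiseless)
  cls <- list(normal_wm = tissue_class("normal_wm", 22, 1.5, 0, 0))
  spec <- phantom_spec(grid_shape = c(4, 4, 2), noise_sigma = 0,
                       class_map = array(1L, c(4, 4, 2)), classes = cls)
  out <- render_dwi(spec)
  expect_equal(out$dwi[[1]], array(spec$s0, c(4, 4, 2)))

  # adc = 550e-6 at b = 1000 -> S_b/S0 = exp(-0.55)
  cls2 <- list(normal_wm = tissue_class("normal_wm", 22, 1.5, 0, 550e-6))
  spec2 <- phantom_spec(grid_shape = c(4, 4, 2), noise_sigma = 0,
                        class_map = array(1L, c(4, 4, 2)), classes = cls2)
  out2 <- render_dwi(spec2)
  expect_equal(out2$dwi[[2]][1, 1, 1] / spec2$s0, exp(-0.55),
               tolerance = 1e-12)

  # three directions identical in the noiseless isotropic phantom
  expect_identical(out2$dwi[[1]], out2$dwi[[3]])

  # round trip through the ADC computation
  spec3 <- noiseless_phantom()
  d <- render_dwi(spec3)
  adc <- compute_adc(d$b0, d$dwi, d$b)
  expect_lt(max(abs(adc$adc - d$truth$adc)), 1e-12)
})

test_that("ground-truth maps are consistent with the segmentation thresholds", {
  spec <- noiseless_phantom()
  truth <- render_pwi(spec)$truth
  adc_truth <- render_dwi(spec)$truth
  code <- stats::setNames(seq_along(spec$classes), names(spec$classes))
  core <- spec$class_map == code[["core"]]
  pen <- spec$class_map == code[["penumbra"]]
  expect_true(all(adc_truth$adc[core] < 550e-6))
  expect_true(all(adc_truth$adc[!core] >= 550e-6))
  expect_true(all(truth$tmax[core | pen] > 6))
  expect_true(all(truth$tmax[!(core | pen)] <= 6))
  # central volume theorem holds in the truth maps
  ok <- is.finite(truth$mtt)
  expect_equal(truth$mtt[ok], 60 * truth$cbv[ok] / truth$cbf[ok])
})

test_that("phantom writer produces readable NIfTI and a sidecar", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(grid_shape = c(8, 8, 2), noise_sigma = 0,
                       class_map = array(1L, c(8, 8, 2)),
                       classes = default_tissue_classes()["normal_wm"])
  paths <- write_phantom(spec, dir)
  expect_true(all(file.exists(paths)))
  back <- read_nifti_vol(file.path(dir, "pwi.nii.gz"))
  expect_equal(dim(back$data), c(8L, 8L, 2L, 45L))
  expect_equal(back$voxel_size, c(0.94, 0.94, 5), tolerance = 1e-6)
  side <- jsonlite::read_json(file.path(dir, "phantom.json"))
  expect_equal(side$te_ms, 45)
  expect_equal(side$tr_s, 2)
})
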