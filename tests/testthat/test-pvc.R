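# A two-tissue phantom with known activities is ground truth for the
# Mueller-Gartner correction: after blurring, the corrected gray-matter mean
# must land close to the true value and always closer than the uncorrected one.
pvc_phantom <- function(seed = 1, A = 10, B = 4) {
  ph <- make_phantom(shape = c(40, 40, 40), seed = seed)
  pet <- array(0, dim(ph$gm_map))
  pet[ph$gm_map >= 0.5] <- A
  pet[ph$wm_map >= 0.5] <- B
  list(ph = ph, pet = pet, A = A, B = B)
}

test_that("zero-width PSF is the identity and kernels conserve mass", {
  img <- array(stats::runif(27000), c(30, 30, 30))
  expect_identical(apply_psf(img, 0, 2), img)
  pt <- array(0, c(31, 31, 31)); pt[16, 16, 16] <- 1
  sm <- apply_psf(pt, 6, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  # profile matches the analytic separable Gaussian within 1%
  sd_vox <- 6 / 2.3548 / 2
  g <- function(d) exp(-d^2 / (2 * sd_vox^2)) / (sqrt(2 * pi) * sd_vox)
  for (off in 0:3) {
    expect_equal(sm[16 + off, 16, 16], g(off) * g(0)^2, tolerance = 0.01)
    expect_equal(sm[16 + off, 16 + off, 16], g(off)^2 * g(0), tolerance = 0.01)
  }
})

test_that("Mueller-Gartner reduces to identity without blur on pure GM", {
  p <- pvc_phantom()
  out <- mg_correct(p$pet, p$ph$gm_map, p$ph$wm_map, wm_ref = p$B,
                    fwhm = 0, voxel_size = 2)
  gm1 <- p$ph$gm_map >= 0.999
  expect_equal(out[gm1], p$pet[gm1])
  # voxels below the GM threshold are masked out
  expect_true(all(is.na(out[p$ph$gm_map < 0.3])))
})

test_that("corrected GM mean recovers truth within 5% and beats no correction", {
  p <- pvc_phantom()
  gm_sel <- p$ph$gm_map >= 0.5
  for (fwhm in c(4, 6, 8)) {
    blurred <- apply_psf(p$pet, fwhm, 2)
    wm_ref <- estimate_wm_reference(blurred, p$ph$wm_map)
    corr <- mg_correct(blurred, p$ph$gm_map, p$ph$wm_map, wm_ref,
                       fwhm = fwhm, voxel_size = 2)
    err_corr <- abs(mean(corr[gm_sel], na.rm = TRUE) - p$A)
    err_raw <- abs(mean(blurred[gm_sel]) - p$A)
    expect_lt(err_corr / p$A, 0.05)
    expect_lt(err_corr, err_raw)
  }
})

test_that("correction is equivariant to global intensity scaling", {
  p <- pvc_phantom()
  blurred <- apply_psf(p$pet, 6, 2)
  wm_ref <- estimate_wm_reference(blurred, p$ph$wm_map)
  c1 <- mg_correct(blurred, p$ph$gm_map, p$ph$wm_map, wm_ref, 6, 2)
  c3 <- mg_correct(3 * blurred, p$ph$gm_map, p$ph$wm_map, 3 * wm_ref, 6, 2)
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
})

test_that("white-matter reference estimation is accurate and guarded", {
  p <- pvc_phantom()
  # noiseless, unblurred: exact
  expect_equal(estimate_wm_reference(p$pet, p$ph$wm_map), p$B)
  # uniform activity everywhere: blurring cannot bias the estimate
  uni <- array(p$B, dim(p$ph$wm_map))
  expect_equal(estimate_wm_reference(apply_psf(uni, 6, 2), p$ph$wm_map), p$B,
               tolerance = 0.02)
  # pure-GM phantom has no qualifying deep-WM voxels
  no_wm <- array(0, c(20, 20, 20))
  expect_error(estimate_wm_reference(array(1, c(20, 20, 20)), no_wm),
               "no deep white-matter")
})

test_that("misaligned grids are rejected", {
  p <- pvc_phantom()
  expect_error(mg_correct(p$pet[1:20, , ], p$ph$gm_map, p$ph$wm_map, 1, 6, 2),
               "share one grid")
  expect_error(apply_psf(p$pet, 6, 0), "voxel_size")
})
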