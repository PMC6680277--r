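test_that("contrast factor follows its defining ratio", {
  expect_equal(contrast_factor(material_levels(50, 100)), 0.5)
  expect_warning(cf0 <- contrast_factor(material_levels(100, 100)), "non-physical")
  expect_equal(cf0, 0)
  # calibrated data: air at 0 gives a contrast factor of exactly 1
  expect_equal(contrast_factor(material_levels(0, 30419)), 1.0)
  expect_error(contrast_factor(material_levels(10, 0)), "i_wax = 0")
})

test_that("calibration factor is the phantom/sample contrast ratio", {
  expect_equal(calibration_factor(0.5, 0.25), 2.0)
  for (x in c(0.1, 0.5, 0.93)) expect_equal(calibration_factor(x, x), 1.0)
  expect_error(calibration_factor(0.5, 0), "0")
})

test_that("material levels are recovered from histograms and ROIs", {
  # exact two-valued slice
  dat <- array(rep(c(10, 200), each = 32), c(1, 8, 8))
  lv <- estimate_material_levels(volume(dat))
  expect_equal(lv$i_air, 10)
  expect_equal(lv$i_wax, 200)
  # degenerate constant slice
  expect_error(estimate_material_levels(volume(array(5, c(1, 8, 8)))),
               "fewer than two")
  # ROI masks give exact means
  m <- dat >= 100
  lv2 <- estimate_material_levels(volume(dat), "roi_masks",
                                  masks = list(air = !m, wax = m))
  expect_equal(lv2$i_air, 10)
  expect_equal(lv2$i_wax, 200)
  expect_error(estimate_material_levels(volume(dat), "roi_masks",
                                        masks = list(air = !m, wax = m & FALSE)),
               "empty")
})

test_that("histogram peak means are within sampling error of the truth", {
  # noisy phantom slice: two Gaussian populations
  spec <- phantom_spec(shape = c(9L, 48L, 48L), gray_air = 100, gray_wax = 1000,
                       gray_tissue = 1100, noise_sigma = 5, seed = 21)
  ph <- make_calibration_phantom(spec)
  lv <- estimate_material_levels(ph)
  n_air <- sum(attr(ph, "air_mask")[5, , ])
  n_wax <- sum(attr(ph, "wax_mask")[5, , ])
  expect_lt(abs(lv$i_air - 100), 3 * 5 / sqrt(n_air) + 0.5)
  expect_lt(abs(lv$i_wax - 1000), 3 * 5 / sqrt(n_wax) + 0.5)
})

test_that("self-calibration is the identity up to the air offset", {
  ph <- make_calibration_phantom(phantom_spec(shape = c(12L, 40L, 40L),
                                              gray_air = 20, gray_wax = 100))
  masks <- list(air = attr(ph, "air_mask"), wax = attr(ph, "wax_mask"))
  res <- calibrate(ph, ph, method = "roi_masks",
                   sample_masks = masks, phantom_masks = masks)
  expect_identical(res$calibration_factor, 1)
  out <- apply_calibration(ph, res)
  expect_equal(out$data, ph$data - 20)
  expect_equal(mean(out$data[masks$air]), 0)
  expect_equal(out$meta$calibration_state, "calibrated")
  expect_error(apply_calibration(out, res), "already calibrated")
})

test_that("calibration matches the hand-derived worked example", {
  # sample (i_air = 50, i_wax = 100) against a phantom with contrast 0.75:
  # cf_sample = 0.5, factor = 1.5, output = 1.5 v - 75 -> air 0, wax 75
  dat <- array(rep(c(50, 100), each = 50), c(1, 10, 10))
  smp <- volume(dat, 8.48, "float32", "preprocessed")
  phd <- array(rep(c(25, 100), each = 50), c(1, 10, 10))  # cf = 0.75
  ph <- volume(phd, 8.48, "float32", "preprocessed")
  am <- dat == 50; wm <- dat == 100
  res <- calibrate(smp, ph, method = "roi_masks",
                   sample_masks = list(air = am, wax = wm),
                   phantom_masks = list(air = phd == 25, wax = phd == 100))
  expect_equal(res$contrast_factor_phantom, 0.75)
  expect_equal(res$contrast_factor_sample, 0.5)
  expect_equal(res$calibration_factor, 1.5)
  out <- apply_calibration(smp, res)
  expect_equal(mean(out$data[am]), 0)
  expect_equal(mean(out$data[wm]), 75)
  # contrast transfer: calibrated sample vs calibrated phantom, both air->0
  cal_ph <- apply_calibration(ph, calibrate(ph, ph, method = "roi_masks",
    sample_masks = list(air = phd == 25, wax = phd == 100),
    phantom_masks = list(air = phd == 25, wax = phd == 100)))
  cf_s <- contrast_factor(estimate_material_levels(out, "roi_masks",
    masks = list(air = am, wax = wm)))
  cf_p <- contrast_factor(estimate_material_levels(cal_ph, "roi_masks",
    masks = list(air = phd == 25, wax = phd == 100)))
  expect_equal(cf_s, cf_p)
})

test_that("calibrated output equals the oracle recomputation for scaled input", {
  # Eq.-1 contrast is scale-invariant, so scaling the raw grays by c scales
  # the calibrated output by c; assert the exact algebra, not a slogan.
  dat <- array(rep(c(40, 90), 32), c(4, 4, 4))
  am <- dat == 40; wm <- dat == 90
  ph <- volume(array(rep(c(30, 120), 32), c(4, 4, 4)), 8.48, "float32", "preprocessed")
  phm <- list(air = ph$data == 30, wax = ph$data == 120)
  for (c_scale in c(1, 2.5, 0.4)) {
    smp <- volume(dat * c_scale, 8.48, "float32", "preprocessed")
    res <- calibrate(smp, ph, method = "roi_masks",
                     sample_masks = list(air = am, wax = wm),
                     phantom_masks = phm)
    out <- apply_calibration(smp, res)
    f_expect <- ((120 - 30) / 120) / ((90 - 40) / 90)
    oracle <- pmax(dat * c_scale * f_expect - f_expect * c_scale * 40, 0)
    expect_equal(out$data, array(oracle, dim(dat)), tolerance = 1e-12)
  }
})

test_that("stability report summarizes per-specimen means as specified", {
  mk <- function(wax_val) {
    v <- volume(array(wax_val, c(2, 4, 4)), 8.48, "float32", "calibrated")
    v
  }
  mask <- array(TRUE, c(2, 4, 4))
  # identical volumes: zero variance
  rep0 <- stability_report(rep(list(mk(100)), 9), wax_masks = mask)
  expect_equal(rep0$wax$max_pct_fluctuation, 0)
  expect_equal(rep0$wax$sem, 0)
  # hand-computed two-specimen case
  rep2 <- stability_report(list(mk(100), mk(120)), wax_masks = mask)
  expect_equal(rep2$wax$grand_mean, 110)
  expect_equal(rep2$wax$max_pct_fluctuation, 10 / 110 * 100)
  expect_equal(rep2$wax$sem, sd(c(100, 120)) / sqrt(2))
  # guards
  expect_error(stability_report(list(mk(100)), mask), "at least two")
  raw <- volume(array(1, c(2, 4, 4)))
  expect_error(stability_report(list(raw, raw), mask), "calibrated")
})

test_that("nine calibrated phantoms with tight wax means stay under 1%", {
  # wax means drawn around 30,419 with a spread well inside 1%
  set.seed(33)
  wax_means <- 30419 + rnorm(9, 0, 60)
  vols <- lapply(wax_means, function(w)
    volume(array(w, c(2, 6, 6)), 8.48, "float32", "calibrated"))
  mask <- array(TRUE, c(2, 6, 6))
  repn <- stability_report(vols, wax_masks = mask)
  expect_lt(repn$wax$max_pct_fluctuation, 1)
  expect_equal(repn$wax$specimen_means, wax_means)
})
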