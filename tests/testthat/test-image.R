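# Rendering and detection on synthetic ex vivo fluorescence images.

well_separated_burden <- function(n, harvest_hours = 504, td = 26.5,
                                  signal_base = 1e6) {
  # signals spread over ~1 order of magnitude, deterministic
  burden_from_signals(signal_base * seq(1, 10, length.out = n),
                      harvest_hours = harvest_hours)
}

test_that("an empty burden renders as constant background", {
  img <- render_liver_image(burden_from_signals(numeric(0)),
                            shape = c(64, 64), background = 7, noise_sd = 0)
  expect_true(all(img$pixels == 7))
  expect_null(img$placements)
  expect_equal(nrow(detect_colonies(img)), 0L)
})

test_that("rendering conserves each colony's integrated signal", {
  b <- well_separated_burden(5)
  img <- render_liver_image(b, shape = c(256, 256), background = 3,
                            noise_sd = 0, min_separation = 4, seed = 2)
  total <- sum(img$pixels) - 3 * length(img$pixels)
  expect_equal(total, sum(b$colonies$fluor_signal), tolerance = 0.01)
  # same seed renders the identical image
  img2 <- render_liver_image(b, shape = c(256, 256), background = 3,
                             noise_sd = 0, min_separation = 4, seed = 2)
  expect_identical(img$pixels, img2$pixels)
})

test_that("placement fails loudly when the field cannot hold the colonies", {
  b <- well_separated_burden(30)
  expect_error(render_liver_image(b, shape = c(80, 80), min_separation = 5,
                                  seed = 1, max_tries = 50),
               "could not place")
  expect_error(render_liver_image(b, shape = c(20, 20)), "field too small")
})

test_that("noiseless well-separated colonies are detected exactly", {
  for (n in c(3, 12)) {
    b <- well_separated_burden(n)
    img <- render_liver_image(b, shape = c(360, 360), noise_sd = 0,
                              min_separation = 3.5, seed = n)
    det <- detect_colonies(img)
    expect_equal(nrow(det), n)
    m <- match_detections(img, det, max_dist = 0.5)
    expect_equal(m$true_positives, n)
    expect_equal(m$false_positives, 0L)
    expect_equal(m$false_negatives, 0L)
    # per-colony integrated signal within 5% of the rendered truth
    truth_sig <- img$placements$fluor_signal[m$matches$truth_idx]
    det_sig <- det$integrated_signal[match(m$matches$detection_label, det$label)]
    expect_true(all(abs(det_sig - truth_sig) / truth_sig <= 0.05))
  }
})

test_that("detection is invariant to a constant offset and robust to noise", {
  b <- well_separated_burden(6)
  img <- render_liver_image(b, shape = c(300, 300), noise_sd = 0,
                            min_separation = 3.5, seed = 7)
  det0 <- detect_colonies(img)
  shifted <- img
  shifted$pixels <- img$pixels + 50
  det1 <- detect_colonies(shifted)
  expect_equal(det1$integrated_signal, det0$integrated_signal, tolerance = 1e-9)
  expect_equal(det1$area_px, det0$area_px)
  # moderate additive noise: count preserved at default k_sigma
  imgn <- render_liver_image(b, shape = c(300, 300), background = 100,
                             noise_sd = 20, min_separation = 3.5, seed = 7)
  detn <- detect_colonies(imgn)
  mn <- match_detections(imgn, detn, max_dist = 0.5)
  expect_equal(mn$true_positives, 6)
  expect_equal(mn$false_negatives, 0L)
})

test_that("matching counts spurious and missed detections correctly", {
  b <- well_separated_burden(4)
  img <- render_liver_image(b, shape = c(300, 300), noise_sd = 0,
                            min_separation = 3.5, seed = 3)
  det <- detect_colonies(img)
  # empty detection set: everything is a miss
  m0 <- match_detections(img, det[0, ], max_dist = 0.5)
  expect_equal(m0$true_positives, 0L)
  expect_equal(m0$false_negatives, 4L)
  # one spurious far-away detection: counted as a false positive only
  spur <- rbind(det, data.frame(label = 99L, row = 5, col = 5, area_px = 10L,
                                integrated_signal = 1, equiv_diam_mm = 0.1))
  m1 <- match_detections(img, spur, max_dist = 0.5)
  expect_equal(m1$true_positives, 4L)
  expect_equal(m1$false_positives, 1L)
  expect_equal(m1$false_negatives, 0L)
})

test_that("image-based doubling times agree with table-based estimates", {
  p <- sim_params("img", fc = 8e-5, td_mean = 26.5, harvest_hours = 504,
                  n_injected = 2e5, td_cv = 0.05, noise_cv = 0, seed = 19)
  b <- simulate_liver(p, 1)
  expect_lte(nrow(b$colonies), 50)
  img <- render_liver_image(b, shape = c(420, 420), noise_sd = 0,
                            min_separation = 3.5, seed = 4)
  det <- detect_colonies(img)
  expect_equal(nrow(det), nrow(b$colonies))
  img_burden <- burden_from_signals(det$integrated_signal, harvest_hours = 504)
  td_img <- estimate_td(img_burden, p$fluor_curve, all_colonies = TRUE)
  td_tab <- estimate_td(b, p$fluor_curve, all_colonies = TRUE)
  expect_equal(td_img$mean, td_tab$mean, tolerance = 0.05)
})

test_that("images round-trip through 32-bit TIFF with sidecar metadata", {
  b <- well_separated_burden(3)
  img <- render_liver_image(b, shape = c(128, 128), background = 2,
                            noise_sd = 0, min_separation = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fluorescence_image(img, path)
  back <- read_fluorescence_image(path)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-6)
  expect_equal(back$pixel_size, img$pixel_size)
  det_a <- detect_colonies(img)
  det_b <- detect_colonies(back)
  expect_equal(nrow(det_b), nrow(det_a))
  expect_equal(det_b$integrated_signal, det_a$integrated_signal,
               tolerance = 1e-5)
  # 16-bit export also readable
  path16 <- withr::local_tempfile(fileext = ".tif")
  write_fluorescence_image(img, path16, bits = 16)
  back16 <- read_fluorescence_image(path16)
  expect_equal(back16$pixels, img$pixels, tolerance = 1e-3 * max(img$pixels))
})
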