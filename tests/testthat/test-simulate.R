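test_that("simulate_liver honors degenerate parameter settings", {
  p0 <- sim_params("x", fc = 0, td_mean = 24, harvest_hours = 336, seed = 1)
  expect_equal(nrow(simulate_liver(p0, 1)$colonies), 0L)
  pdet <- sim_params("x", fc = 1e-4, td_mean = 24, harvest_hours = 336,
                     n_injected = 1e5, td_cv = 0, noise_cv = 0, seed = 2)
  b <- simulate_liver(pdet, 1)
  expect_gt(nrow(b$colonies), 0L)
  expect_true(all(b$colonies$cell_count == 2^(336 / 24)))
  expect_true(all(b$colonies$fluor_signal == 100 * 2^(336 / 24)))
  # diameter consistent with sphere packing
  expect_equal(sphere_volume(b$colonies$diameter_mm[1]) * 1e6,
               b$colonies$cell_count[1], tolerance = 1e-9)
  expect_error(sim_params("x", fc = 1.5, td_mean = 24, harvest_hours = 1), "fc")
})

test_that("mean simulated colony count matches the Binomial expectation", {
  p <- scenario_params("P1", seed = 42)
  counts <- vapply(1:400, function(i) nrow(simulate_liver(p, i)$colonies), 0L)
  se <- sqrt(2e6 * 8.2e-5 / 400)
  expect_lt(abs(mean(counts) - 164), 3 * se)
})

test_that("colony counts pass a chi-square goodness-of-fit against Binomial", {
  p <- sim_params("gof", fc = 0.1, td_mean = 24, harvest_hours = 48,
                  n_injected = 50, seed = 9)
  counts <- vapply(1:1000, function(i) nrow(simulate_liver(p, i)$colonies), 0L)
  k <- 0:50
  probs <- stats::dbinom(k, 50, 0.1)
  expected <- 1000 * probs
  # pool bins with expected < 5 into the tails; drop empty zero-mass tails
  keep <- range(which(expected >= 5))
  lo_c <- k[keep[1]]; hi_c <- k[keep[2]]
  obs <- vapply(lo_c:hi_c, function(v) sum(counts == v), 0L)
  pr <- probs[k >= lo_c & k <= hi_c]
  if (lo_c > 0) { obs <- c(sum(counts < lo_c), obs); pr <- c(sum(probs[k < lo_c]), pr) }
  if (hi_c < 50) { obs <- c(obs, sum(counts > hi_c)); pr <- c(pr, sum(probs[k > hi_c])) }
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohorts are reproducible given the seed and differ across seeds", {
  p <- scenario_params("P2", seed = 5)
  c1 <- simulate_cohort(p, 3)
  c2 <- simulate_cohort(p, 3)
  expect_identical(c1, c2)
  expect_identical(vapply(c1$burdens, `[[`, "", "mouse_id"),
                   c("P2_m1", "P2_m2", "P2_m3"))
  # mouse i is the same whether simulated alone or inside a cohort
  expect_identical(c1$burdens[[2]], simulate_liver(p, 2))
  p2 <- scenario_params("P2", seed = 6)
  c3 <- simulate_cohort(p2, 3)
  expect_false(identical(vapply(c1$burdens, function(b) nrow(b$colonies), 0L),
                         vapply(c3$burdens, function(b) nrow(b$colonies), 0L)) &&
               isTRUE(all.equal(c1$burdens[[1]]$colonies$fluor_signal,
                                c3$burdens[[1]]$colonies$fluor_signal)))
})

test_that("high-colonization cohorts out-count low-colonization cohorts", {
  hits <- vapply(1:100, function(s) {
    med <- function(cl) {
      coh <- simulate_cohort(scenario_params(cl, seed = s), 20)
      stats::median(vapply(coh$burdens, function(b) nrow(b$colonies), 0L))
    }
    med("P1") > med("O1")
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("longitudinal flux tracks the harvested colonies and grows in time", {
  p <- sim_params("x", fc = 5e-5, td_mean = 24, harvest_hours = 504,
                  n_injected = 1e5, noise_cv = 0,
                  lum_curve = calibration_curve(1000, 1e4,
                                                modality = "luminescence"),
                  seed = 3)
  lg <- simulate_longitudinal(p, weeks = 1:3, n_mice = 2)
  expect_identical(names(lg), c("mouse_id", "week", "total_flux"))
  expect_equal(nrow(lg), 6L)
  # noiseless flux equals the calibrated total of the same colonies that
  # simulate_liver harvests (cross-consistency of the shared sub-streams)
  b1 <- simulate_liver(p, 1)
  td_b <- 504 * log(2) / log(b1$colonies$cell_count)
  for (w in 1:3) {
    total <- sum(2^(168 * w / td_b))
    expect_equal(lg$total_flux[lg$mouse_id == "x_m1" & lg$week == w],
                 1000 * total + 1e4, tolerance = 1e-9)
  }
  # expectation is nondecreasing over weeks for every mouse
  for (m in unique(lg$mouse_id)) {
    expect_true(all(diff(lg$total_flux[lg$mouse_id == m]) > 0))
  }
  # one colony at Td 24 h gains exactly 7 doublings per week
  p1c <- sim_params("y", fc = 1e-4, td_mean = 24, harvest_hours = 336,
                    n_injected = 1e4, td_cv = 0, noise_cv = 0,
                    lum_curve = calibration_curve(1000, 0,
                                                  modality = "luminescence"),
                    seed = 8)
  lg1 <- simulate_longitudinal(p1c, weeks = 1:2, n_mice = 1)
  expect_equal(lg1$total_flux[2] / lg1$total_flux[1], 2^7)
  # fc = 0 leaves flux at the calibration background
  pz <- sim_params("z", fc = 0, td_mean = 24, harvest_hours = 336,
                   noise_cv = 0,
                   lum_curve = calibration_curve(1000, 1e4,
                                                 modality = "luminescence"))
  lgz <- simulate_longitudinal(pz, weeks = 1:4, n_mice = 1)
  expect_true(all(lgz$total_flux == 1e4))
})

test_that("calibration plates are exact without noise and error on bad input", {
  plate <- generate_calibration_plate(123, 456, noise_cv = 0, seed = 1)
  expect_equal(nrow(plate), 27L)
  fit <- fit_calibration(plate)
  expect_equal(fit$slope, 123, tolerance = 1e-9)
  expect_equal(fit$intercept, 456, tolerance = 1e-9)
  expect_error(generate_calibration_plate(-1, 0), "true_slope")
  degenerate <- generate_calibration_plate(100, 0, densities = 0, seed = 1)
  expect_error(fit_calibration(degenerate), "degenerate")
})

test_that("fixtures round-trip through CSV/JSON losslessly", {
  coh <- simulate_cohort(scenario_params("P2", seed = 31), 3)
  dir <- withr::local_tempdir()
  write_fixtures(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("colonies.csv", "mice.csv",
                                               "params.json")))))
  back <- read_fixtures(dir)
  expect_equal(back$params[setdiff(names(back$params), c("fluor_curve", "lum_curve"))],
               coh$params[setdiff(names(coh$params), c("fluor_curve", "lum_curve"))])
  expect_equal(back$params$fluor_curve$slope, coh$params$fluor_curve$slope)
  expect_length(back$burdens, 3)
  for (i in 1:3) {
    expect_identical(back$burdens[[i]]$mouse_id, coh$burdens[[i]]$mouse_id)
    expect_equal(back$burdens[[i]]$harvest_hours, coh$burdens[[i]]$harvest_hours)
    expect_equal(back$burdens[[i]]$colonies$fluor_signal,
                 coh$burdens[[i]]$colonies$fluor_signal, tolerance = 1e-12)
    expect_equal(back$burdens[[i]]$colonies$diameter_mm,
                 coh$burdens[[i]]$colonies$diameter_mm, tolerance = 1e-12)
  }
  # empty cohort still writes valid headers-only tables
  empty <- simulate_cohort(sim_params("e", fc = 0, td_mean = 24,
                                      harvest_hours = 336), 3)
  dir2 <- withr::local_tempdir()
  write_fixtures(empty, dir2)
  back2 <- read_fixtures(dir2)
  expect_length(back2$burdens, 3)
  expect_equal(nrow(back2$burdens[[1]]$colonies), 0L)
  # two clones of 3 mice each -> 6 mouse rows in total
  mice_rows <- nrow(utils::read.csv(file.path(dir, "mice.csv"))) +
               nrow(utils::read.csv(file.path(dir2, "mice.csv")))
  expect_equal(mice_rows, 6L)
})
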