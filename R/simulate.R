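#' Default plated densities for a calibration plate
#'
#' The cell-per-well grid of the standard 96-well calibration design:
#' 0, 1e3, 1e4, 2e4, 3e4, 5e4, 7e4, 9e4 and 1e5 cells per well.
#'
#' @return Integer vector of plated densities.
#' @export
default_plate_densities <- function() {
  c(0, 1e3, 1e4, 2e4, 3e4, 5e4, 7e4, 9e4, 1e5)
}

#' Generative parameters of the liver-colonization model
#'
#' Bundles everything needed to simulate the intrasplenic-injection
#' experiment for one clone: each injected cell independently founds a liver
#' colony with probability `fc`; each founded colony draws its own doubling
#' time from a lognormal centred on `td_mean` with coefficient of variation
#' `td_cv` and grows exponentially from one cell until `harvest_hours`;
#' optical readouts pass through the calibration curves with multiplicative
#' lognormal measurement noise of CV `noise_cv`; macroscopic diameter follows
#' from cell number through a spherical packing density.
#'
#' @param clone_id Clone label.
#' @param fc Colonizing fraction in `[0, 1]`.
#' @param td_mean Mean doubling time, hours.
#' @param harvest_hours Hours from injection to harvest.
#' @param n_injected Injected dose in cells (default 2e6, the standard
#'   splenic-injection dose).
#' @param td_cv Inter-colony lognormal CV of the doubling time (default 0.05).
#' @param noise_cv Multiplicative measurement-noise CV (default 0.05).
#' @param packing_density Cells per mm^3 of tumor (default 1e6, typical
#'   solid-tumor cellularity); links cell number to macroscopic diameter.
#' @param fluor_curve,lum_curve Calibration curves for ex vivo fluorescence
#'   and in vivo bioluminescence. `lum_curve` is only needed for longitudinal
#'   simulation.
#' @param seed Integer master seed; mice, colonies and measurement occasions
#'   use deterministic sub-streams derived from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(clone_id, fc, td_mean, harvest_hours,
                       n_injected = 2e6, td_cv = 0.05, noise_cv = 0.05,
                       packing_density = 1e6,
                       fluor_curve = calibration_curve(slope = 100, intercept = 0,
                                                       modality = "fluorescence"),
                       lum_curve = NULL, seed = 1L) {
  assert_scalar_number(fc, "fc", lower = 0, upper = 1)
  assert_scalar_number(td_mean, "td_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(harvest_hours, "harvest_hours", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_injected, "n_injected", lower = 0, strict_lower = TRUE)
  assert_scalar_number(td_cv, "td_cv", lower = 0)
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  assert_scalar_number(packing_density, "packing_density", lower = 0,
                       strict_lower = TRUE)
  stopifnot(inherits(fluor_curve, "calibration_curve"))
  if (!is.null(lum_curve)) stopifnot(inherits(lum_curve, "calibration_curve"))
  structure(
    list(clone_id = as.character(clone_id), n_injected = n_injected, fc = fc,
         td_mean = td_mean, td_cv = td_cv, harvest_hours = harvest_hours,
         noise_cv = noise_cv, packing_density = packing_density,
         fluor_curve = fluor_curve, lum_curve = lum_curve,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> clone %s: dose %.3g, Fc %.3g, Td %.1f h (CV %.2g), harvest %g h, seed %d\n",
              x$clone_id, x$n_injected, x$fc, x$td_mean, x$td_cv,
              x$harvest_hours, x$seed))
  invisible(x)
}

# One mouse's colony draws: count, per-colony doubling times and measurement
# noise, in a fixed order inside the (seed, mouse) sub-stream.
draw_colonies <- function(params, mouse_index) {
  withr::with_seed(child_seed(params$seed, 1L, mouse_index), {
    n_col <- stats::rbinom(1L, size = params$n_injected, prob = params$fc)
    td <- rlnorm_mcv(n_col, params$td_mean, params$td_cv)
    noise <- rlnorm_mcv(n_col, 1, params$noise_cv)
    list(n_col = n_col, td = td, noise = noise)
  })
}

#' Simulate one mouse liver at harvest
#'
#' Colony count is Binomial(`n_injected`, `fc`); each colony grows to
#' `2^(harvest_hours / Td)` cells from a single founder with its own
#' lognormal doubling time; integrated fluorescence is the calibrated forward
#' signal times multiplicative lognormal noise; diameter follows from cell
#' number assuming a sphere at the packing density. Deterministic given
#' `(params$seed, mouse_index)`.
#'
#' @param params A [sim_params()].
#' @param mouse_index Positive integer identifying the mouse within the
#'   cohort's seed stream.
#' @return A [liver_burden()].
#' @export
simulate_liver <- function(params, mouse_index = 1L) {
  stopifnot(inherits(params, "sim_params"))
  assert_scalar_number(mouse_index, "mouse_index", lower = 1)
  d <- draw_colonies(params, mouse_index)
  if (d$n_col > 0L) {
    cells <- 2^(params$harvest_hours / d$td)
    fluor <- predict_signal(params$fluor_curve, cells) * d$noise
    diam <- (6 * cells / (pi * params$packing_density))^(1 / 3)
    colonies <- data.frame(colony_id = seq_len(d$n_col), diameter_mm = diam,
                           fluor_signal = fluor, cell_count = cells)
  } else {
    colonies <- empty_colonies()
  }
  liver_burden(mouse_id = sprintf("%s_m%d", params$clone_id, mouse_index),
               clone_id = params$clone_id, n_injected = params$n_injected,
               harvest_hours = params$harvest_hours, colonies = colonies)
}

#' Simulate a cohort of mice
#'
#' Mice are independent through per-mouse sub-streams of the master seed, so
#' the cohort is reproducible bit-for-bit given `(seed, n_mice)` and mouse
#' `i` is identical whether simulated alone or within a cohort.
#'
#' @param params A [sim_params()].
#' @param n_mice Number of mice (`>= 1`; the standard group size is 3).
#' @return An object of class `cohort`: list with `params` and `burdens`.
#' @export
simulate_cohort <- function(params, n_mice = 3L) {
  stopifnot(inherits(params, "sim_params"))
  assert_scalar_number(n_mice, "n_mice", lower = 1)
  burdens <- lapply(seq_len(n_mice), function(i) simulate_liver(params, i))
  structure(list(params = params, burdens = burdens), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  counts <- vapply(x$burdens, function(b) nrow(b$colonies), 0L)
  cat(sprintf("<cohort> clone %s: %d mice, colony counts %s\n",
              x$params$clone_id, length(x$burdens),
              paste(counts, collapse = ", ")))
  invisible(x)
}

#' Simulate weekly whole-body bioluminescence
#'
#' Evaluates every colony's cell number at `t = 168 * week` hours and pushes
#' the whole-liver total through the bioluminescence calibration, with fresh
#' multiplicative lognormal noise at each measurement occasion. Colony
#' identities (count and per-colony Td) are shared with [simulate_liver()]
#' for the same `(seed, mouse)`, so the longitudinal trace ends at the
#' harvested burden.
#'
#' @param params A [sim_params()] with a `lum_curve`.
#' @param weeks Positive integer weeks at which to measure.
#' @param n_mice Number of mice (default 3).
#' @return Data frame `mouse_id, week, total_flux`.
#' @export
simulate_longitudinal <- function(params, weeks, n_mice = 3L) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(params$lum_curve))
    stop_input("longitudinal simulation needs params$lum_curve")
  if (!length(weeks) || any(weeks < 1))
    stop_domain("weeks must be a nonempty vector of positive integers")
  out <- lapply(seq_len(n_mice), function(i) {
    d <- draw_colonies(params, i)
    flux <- vapply(weeks, function(w) {
      t_h <- 168 * w
      total_cells <- if (d$n_col > 0L) sum(2^(t_h / d$td)) else 0
      noise <- withr::with_seed(child_seed(params$seed, 2L, i, w),
                                rlnorm_mcv(1L, 1, params$noise_cv))
      predict_signal(params$lum_curve, total_cells) * noise
    }, 0)
    data.frame(mouse_id = sprintf("%s_m%d", params$clone_id, i),
               week = as.integer(weeks), total_flux = flux)
  })
  do.call(rbind, out)
}

#' Generate a synthetic calibration plate
#'
#' Simulates the standard in vitro calibration experiment: cells plated at a
#' grid of densities in replicate wells, each well's signal equal to the true
#' line times multiplicative lognormal noise.
#'
#' @param true_slope True signal per cell (`> 0`).
#' @param true_intercept True background signal.
#' @param densities Plated cell counts per well
#'   (default [default_plate_densities()]).
#' @param replicates Wells per density (default 3).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param seed Integer seed.
#' @param modality Modality recorded on the points.
#' @return Data frame of calibration points
#'   (`modality, cell_count, signal, replicate`).
#' @export
generate_calibration_plate <- function(true_slope, true_intercept = 0,
                                       densities = default_plate_densities(),
                                       replicates = 3L, noise_cv = 0.05,
                                       seed = 1L,
                                       modality = c("fluorescence", "luminescence")) {
  modality <- match.arg(modality)
  assert_scalar_number(true_slope, "true_slope", lower = 0, strict_lower = TRUE)
  assert_scalar_number(replicates, "replicates", lower = 1)
  if (!length(densities)) stop_input("densities must be nonempty")
  cells <- rep(densities, each = replicates)
  replicate <- rep(seq_len(replicates), times = length(densities))
  noise <- withr::with_seed(as.integer(seed),
                            rlnorm_mcv(length(cells), 1, noise_cv))
  data.frame(modality = modality, cell_count = cells,
             signal = (true_slope * cells + true_intercept) * noise,
             replicate = replicate)
}

#' Write / read a simulated cohort as plain-text fixtures
#'
#' Emits `colonies.csv` and `mice.csv` in the layouts consumed by
#' [read_burdens()], plus `params.json` mirroring the generating
#' [sim_params()]. The round trip is lossless up to double-precision text
#' formatting.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Writable directory (created if absent).
#' @return `write_fixtures` returns `dir` invisibly; `read_fixtures` a
#'   `cohort`.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mice <- do.call(rbind, lapply(cohort$burdens, function(b) {
    data.frame(mouse_id = b$mouse_id, clone_id = b$clone_id,
               n_injected = b$n_injected, harvest_hours = b$harvest_hours)
  }))
  colonies <- do.call(rbind, lapply(cohort$burdens, function(b) {
    co <- b$colonies
    if (!nrow(co)) return(NULL)
    data.frame(mouse_id = b$mouse_id, clone_id = b$clone_id,
               colony_id = co$colony_id, diameter_mm = co$diameter_mm,
               fluor_signal = co$fluor_signal)
  }))
  if (is.null(colonies))
    colonies <- data.frame(mouse_id = character(0), clone_id = character(0),
                           colony_id = integer(0), diameter_mm = numeric(0),
                           fluor_signal = numeric(0))
  utils::write.csv(mice, file.path(dir, "mice.csv"), row.names = FALSE)
  utils::write.csv(format(colonies, digits = 17, trim = TRUE, scientific = NA),
                   file.path(dir, "colonies.csv"), row.names = FALSE,
                   quote = FALSE)
  write_sim_params(cohort$params, file.path(dir, "params.json"))
  invisible(dir)
}

#' Write / read simulation parameters as JSON
#'
#' The JSON mirrors [sim_params()] field-for-field, with the calibration
#' curves nested under `fluor_curve` / `lum_curve`.
#'
#' @param params A [sim_params()].
#' @param path Destination / source path.
#' @return `write_sim_params` returns `path` invisibly; `read_sim_params`
#'   a [sim_params()].
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  pj <- list(clone_id = p$clone_id, n_injected = p$n_injected, fc = p$fc,
             td_mean = p$td_mean, td_cv = p$td_cv,
             harvest_hours = p$harvest_hours, noise_cv = p$noise_cv,
             packing_density = p$packing_density,
             fluor_curve = unclass(p$fluor_curve),
             lum_curve = if (!is.null(p$lum_curve)) unclass(p$lum_curve),
             seed = p$seed)
  jsonlite::write_json(pj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  pj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curve_from <- function(x) {
    if (is.null(x)) return(NULL)
    calibration_curve(slope = x$slope, intercept = x$intercept,
                      pearson_r = x$pearson_r %||% NA_real_,
                      n_points = as.integer(x$n_points %||% NA_integer_),
                      modality = x$modality)
  }
  sim_params(clone_id = pj$clone_id, fc = pj$fc, td_mean = pj$td_mean,
             harvest_hours = pj$harvest_hours, n_injected = pj$n_injected,
             td_cv = pj$td_cv, noise_cv = pj$noise_cv,
             packing_density = pj$packing_density,
             fluor_curve = curve_from(pj$fluor_curve),
             lum_curve = curve_from(pj$lum_curve), seed = pj$seed)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  params <- read_sim_params(file.path(dir, "params.json"))
  burdens <- read_burdens(file.path(dir, "colonies.csv"),
                          file.path(dir, "mice.csv"))
  structure(list(params = params, burdens = burdens), class = "cohort")
}

#' Reference parameter sets for the characterized metastatic scenarios
#'
#' Generative parameters for the three characterized clone phenotypes, at the
#' standard splenic dose of 2e6 cells: the polymetastatic high-colonization
#' clone P1 (Fc 8.2e-5, Td 26.5 h), the polymetastatic fast-growing clone P2
#' (Fc 1.1e-5, Td 22.7 h) and the oligometastatic clone O1 (Fc 6.0e-6,
#' Td 26.5 h). P clones are harvested at 504 h (3 weeks of weekly follow-up),
#' O clones at 672 h (4 weeks). Inter-colony Td CV and measurement-noise CV
#' default to 0.05; both calibration curves are attached so the same params
#' drive harvest and longitudinal simulation.
#'
#' @param clone One of `"P1"`, `"P2"`, `"O1"`.
#' @param seed Master seed for the returned [sim_params()].
#' @param ... Overrides passed to [sim_params()] (e.g. `td_cv`, `noise_cv`).
#' @return A [sim_params()].
#' @examples
#' simulate_cohort(scenario_params("P1", seed = 1), n_mice = 3)
#' @export
scenario_params <- function(clone = c("P1", "P2", "O1"), seed = 1L, ...) {
  clone <- match.arg(clone)
  base <- switch(clone,
    P1 = list(fc = 8.2e-5, td_mean = 26.5, harvest_hours = 504),
    P2 = list(fc = 1.1e-5, td_mean = 22.7, harvest_hours = 504),
    O1 = list(fc = 6.0e-6, td_mean = 26.5, harvest_hours = 672))
  args <- utils::modifyList(
    c(list(clone_id = clone, n_injected = 2e6, seed = seed,
           fluor_curve = calibration_curve(slope = 100, intercept = 0,
                                           modality = "fluorescence"),
           lum_curve = calibration_curve(slope = 1000, intercept = 1e4,
                                         modality = "luminescence")),
      base),
    list(...))
  do.call(sim_params, args)
}
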