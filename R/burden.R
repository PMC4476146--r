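#' Colonizing fraction Fc
#'
#' Fraction of injected tumor cells that founded a macroscopic liver colony:
#' the number of tumors counted in the liver divided by the number of cells
#' injected into the spleen. Under the single-founder assumption every tumor
#' marks exactly one successfully colonizing cell.
#'
#' @param n_tumors Number of macroscopic tumors counted (`>= 0`).
#' @param n_injected Number of cells injected (`> 0`).
#' @return Fc as an exact ratio in `[0, 1]`.
#' @examples
#' colonizing_fraction(164, 2e6) # 8.2e-05
#' @export
colonizing_fraction <- function(n_tumors, n_injected) {
  assert_scalar_number(n_injected, "n_injected", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_tumors, "n_tumors", lower = 0)
  if (n_tumors > n_injected)
    stop_input("inconsistent counts: n_tumors (", n_tumors,
               ") exceeds n_injected (", n_injected, ")")
  n_tumors / n_injected
}

#' Doubling time under single-founder exponential growth
#'
#' Each colony is assumed to grow exponentially from exactly one founding
#' cell with no lag, so a colony of `N` cells after `t` hours implies
#' `Td = t * ln(2) / ln(N)`.
#'
#' @param cell_count Final cell number, `>= 2` (at least one division must
#'   have happened for Td to be identified).
#' @param elapsed Hours of growth since injection, `> 0`.
#' @return Doubling time in hours.
#' @examples
#' doubling_time(1024, 240)    # 24 h: 10 divisions in 240 h
#' doubling_time(4.31e7, 672)  # 26.5 h
#' @export
doubling_time <- function(cell_count, elapsed) {
  assert_scalar_number(elapsed, "elapsed", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(cell_count)) || any(cell_count < 2))
    stop_domain("undefined doubling time: cell_count must be >= 2 ",
                "(colony indistinguishable from its founder)")
  elapsed * log(2) / log(cell_count)
}

#' Number of cell divisions from founder to colony
#'
#' @param cell_count Cell number, `>= 1`.
#' @return `log2(cell_count)` divisions.
#' @export
n_divisions <- function(cell_count) {
  if (any(!is.finite(cell_count)) || any(cell_count < 1))
    stop_domain("cell_count must be >= 1")
  log2(cell_count)
}

#' Sphere-model tumor volume
#'
#' Macroscopic tumors are treated as spheres of the measured diameter.
#'
#' @param diameter Diameter in mm, `> 0`.
#' @return Volume `pi * d^3 / 6` in mm^3.
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop_domain("diameter must be positive")
  pi * diameter^3 / 6
}

#' Construct a per-mouse liver burden
#'
#' Container for all colonies harvested from one mouse liver, plus the
#' injection metadata needed to turn colony counts and signals into Fc and Td.
#'
#' @param mouse_id,clone_id Identifiers.
#' @param n_injected Injected dose in cells (`> 0`).
#' @param harvest_hours Hours between injection and harvest (`> 0`).
#' @param colonies Data frame with columns `colony_id`, `diameter_mm`
#'   (NA allowed), `fluor_signal`, optional `cell_count`; zero rows allowed.
#' @return An object of class `liver_burden`. Colony volumes (`volume_mm3`)
#'   are derived from diameters where present.
#' @export
liver_burden <- function(mouse_id, clone_id, n_injected, harvest_hours,
                         colonies = empty_colonies()) {
  assert_scalar_number(n_injected, "n_injected", lower = 0, strict_lower = TRUE)
  assert_scalar_number(harvest_hours, "harvest_hours", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(colonies))
    stop_input("colonies must be a data frame")
  if (nrow(colonies)) {
    if (!all(c("fluor_signal") %in% names(colonies)))
      stop_input("colonies must carry a fluor_signal column")
    if (is.null(colonies$colony_id)) colonies$colony_id <- seq_len(nrow(colonies))
    if (is.null(colonies$diameter_mm)) colonies$diameter_mm <- NA_real_
    if (is.null(colonies$cell_count)) colonies$cell_count <- NA_real_
    if (any(colonies$fluor_signal < 0, na.rm = TRUE))
      stop_domain("colony fluor_signal must be nonnegative")
    if (any(colonies$diameter_mm <= 0, na.rm = TRUE))
      stop_domain("colony diameters must be positive where given")
    colonies$volume_mm3 <- ifelse(is.na(colonies$diameter_mm), NA_real_,
                                  pi * colonies$diameter_mm^3 / 6)
  } else {
    colonies <- empty_colonies()
  }
  structure(
    list(mouse_id = as.character(mouse_id), clone_id = as.character(clone_id),
         n_injected = n_injected, harvest_hours = harvest_hours,
         colonies = colonies),
    class = "liver_burden"
  )
}

empty_colonies <- function() {
  data.frame(colony_id = integer(0), diameter_mm = numeric(0),
             fluor_signal = numeric(0), cell_count = numeric(0),
             volume_mm3 = numeric(0))
}

#' @export
print.liver_burden <- function(x, ...) {
  cat(sprintf("<liver_burden> mouse %s (clone %s): %d colonies, dose %.3g cells, harvest %g h\n",
              x$mouse_id, x$clone_id, nrow(x$colonies), x$n_injected,
              x$harvest_hours))
  invisible(x)
}

#' Totals over one liver
#'
#' @param burden A [liver_burden()].
#' @return List with `total_volume` (mm^3, NA diameters contribute 0),
#'   `total_fluor` and `n_tumors`.
#' @export
total_burden <- function(burden) {
  stopifnot(inherits(burden, "liver_burden"))
  co <- burden$colonies
  list(total_volume = sum(co$volume_mm3, na.rm = TRUE),
       total_fluor = sum(co$fluor_signal),
       n_tumors = nrow(co))
}

#' Infer per-colony cell numbers from fluorescence
#'
#' Applies the fluorescence calibration to each colony's integrated radiant
#' efficiency. Any detected colony contains at least its founder, so inferred
#' counts are floored at 1 cell; faint colonies therefore still contribute to
#' Fc and to the average colony size.
#'
#' @param curve A fluorescence [calibration_curve()].
#' @param burden A [liver_burden()] (or a colonies data frame).
#' @return The input with `cell_count` filled in.
#' @export
colony_cells <- function(curve, burden) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$modality != "fluorescence")
    stop_input("modality mismatch: per-colony cell inference requires the ",
               "fluorescence curve, got ", curve$modality)
  co <- if (inherits(burden, "liver_burden")) burden$colonies else burden
  if (nrow(co)) {
    cells <- withCallingHandlers(
      cells_from_signal(curve, co$fluor_signal),
      warning = function(w) invokeRestart("muffleWarning"))
    co$cell_count <- pmax(1, cells)
  }
  if (inherits(burden, "liver_burden")) {
    burden$colonies <- co
    burden
  } else {
    co
  }
}

#' Clone-level phenotype summary
#'
#' Summarizes a group of mice injected with the same clone into the two
#' parameters that define its metastatic phenotype: colonizing fraction Fc
#' (mean +/- SD across mice) and doubling time Td (mean +/- SD across sampled
#' colonies pooled over mice), together with the average colony size `n_av`
#' and the implied mean number of divisions `log2(n_av)`.
#'
#' Td is computed per colony from the fluorescence-calibrated cell number and
#' the mouse's harvest time; by default a seeded random sample of up to
#' `sample_size` colonies per liver is used, mirroring per-liver quantification
#' of a handful of representative colonies.
#'
#' @param burdens List of [liver_burden()]s, all with the same `clone_id`.
#' @param curve Fluorescence [calibration_curve()].
#' @param sample_size Colonies sampled per liver for Td (default 5).
#' @param all_colonies If `TRUE`, use every colony instead of sampling.
#' @param seed Integer seed controlling the colony sample.
#' @return An object of class `clone_phenotype`: list with `clone_id`,
#'   `fc_mean`, `fc_sd`, `td_mean`, `td_sd`, `n_av`, `divisions_mean`,
#'   `n_mice`, `n_colonies`.
#' @export
clone_phenotype <- function(burdens, curve, sample_size = 5L,
                            all_colonies = FALSE, seed = 1L) {
  if (inherits(burdens, "liver_burden")) burdens <- list(burdens)
  if (!length(burdens)) stop_input("need at least one liver burden")
  clones <- unique(vapply(burdens, `[[`, "", "clone_id"))
  if (length(clones) > 1L)
    stop_input("mixed clone_ids in one phenotype: ", paste(clones, collapse = ", "))

  fc <- estimate_fc(burdens)
  burdens <- lapply(burdens, colony_cells, curve = curve)
  n_colonies <- sum(vapply(burdens, function(b) nrow(b$colonies), 0L))
  if (n_colonies > 0L) {
    cells_all <- unlist(lapply(burdens, function(b) b$colonies$cell_count))
    n_av <- mean(cells_all)
    td <- estimate_td(burdens, curve, sample_size = sample_size,
                      all_colonies = all_colonies, seed = seed)
    divisions_mean <- log2(n_av)
  } else {
    n_av <- NA_real_
    td <- list(mean = NA_real_, sd = NA_real_, n = 0L)
    divisions_mean <- NA_real_
  }
  structure(
    list(clone_id = clones, fc_mean = fc$mean, fc_sd = fc$sd,
         td_mean = td$mean, td_sd = td$sd, n_av = n_av,
         divisions_mean = divisions_mean, n_mice = length(burdens),
         n_colonies = n_colonies),
    class = "clone_phenotype"
  )
}

#' @export
print.clone_phenotype <- function(x, ...) {
  cat(sprintf("<clone_phenotype> %s (%d mice, %d colonies)\n",
              x$clone_id, x$n_mice, x$n_colonies))
  cat(sprintf("  Fc = %.3g +/- %.2g\n", x$fc_mean, x$fc_sd))
  cat(sprintf("  Td = %.1f +/- %.2g h, n_av = %.3g cells (%.2f divisions)\n",
              x$td_mean, x$td_sd, x$n_av, x$divisions_mean))
  invisible(x)
}

#' Classify a clone's metastatic scenario from (Fc, Td)
#'
#' Splits the (Fc, Td) plane into the qualitative scenarios of metastatic
#' development: a high colonizing fraction with slow growth yields many small
#' tumors; a low fraction with fast growth yields few large tumors; low and
#' slow yields few small tumors (the oligometastatic-like picture). The
#' remaining quadrant (high Fc, fast growth: many large tumors) is labeled for
#' completeness although no clone of that kind was characterized.
#'
#' @param ph A [clone_phenotype()], or a list/vector with `fc_mean` and
#'   `td_mean`.
#' @param fc_threshold Fc above which colonization counts as high
#'   (default 2e-5).
#' @param td_threshold Td in hours above which growth counts as slow
#'   (default 24.5).
#' @return One of `"many_small"`, `"few_large"`, `"few_small"`,
#'   `"many_large"`.
#' @export
classify_phenotype <- function(ph, fc_threshold = 2e-5, td_threshold = 24.5) {
  assert_scalar_number(fc_threshold, "fc_threshold", lower = 0, strict_lower = TRUE)
  assert_scalar_number(td_threshold, "td_threshold", lower = 0, strict_lower = TRUE)
  fc <- if (is.list(ph)) ph$fc_mean else ph[["fc_mean"]]
  td <- if (is.list(ph)) ph$td_mean else ph[["td_mean"]]
  high_fc <- fc > fc_threshold
  slow <- td > td_threshold
  if (high_fc && slow) "many_small"
  else if (!high_fc && !slow) "few_large"
  else if (!high_fc && slow) "few_small"
  else "many_large"
}

#' Read colony and mouse tables and assemble liver burdens
#'
#' The colonies CSV has columns `mouse_id,clone_id,colony_id,diameter_mm,
#' fluor_signal`; the mice CSV has `mouse_id,clone_id,n_injected,
#' harvest_hours`. Mice with no colony rows get an empty burden.
#'
#' @param colonies_path,mice_path CSV paths.
#' @return List of [liver_burden()] objects, one per row of the mice table.
#' @export
read_burdens <- function(colonies_path, mice_path) {
  colonies <- utils::read.csv(colonies_path, stringsAsFactors = FALSE)
  mice <- utils::read.csv(mice_path, stringsAsFactors = FALSE)
  burdens_from_tables(colonies, mice)
}

#' @rdname read_burdens
#' @param colonies,mice Data frames in the CSV layouts above.
#' @export
burdens_from_tables <- function(colonies, mice) {
  need_m <- c("mouse_id", "clone_id", "n_injected", "harvest_hours")
  if (!all(need_m %in% names(mice)))
    stop_input("mice table missing column(s): ",
               paste(setdiff(need_m, names(mice)), collapse = ", "))
  need_c <- c("mouse_id", "clone_id", "colony_id", "diameter_mm", "fluor_signal")
  if (nrow(colonies) && !all(need_c %in% names(colonies)))
    stop_input("colonies table missing column(s): ",
               paste(setdiff(need_c, names(colonies)), collapse = ", "))
  lapply(seq_len(nrow(mice)), function(i) {
    m <- mice[i, ]
    co <- colonies[colonies$mouse_id == m$mouse_id, , drop = FALSE]
    cols <- if (nrow(co)) {
      data.frame(colony_id = co$colony_id, diameter_mm = co$diameter_mm,
                 fluor_signal = co$fluor_signal)
    } else empty_colonies()
    liver_burden(m$mouse_id, m$clone_id, m$n_injected, m$harvest_hours, cols)
  })
}
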