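#' Estimate the colonizing fraction from a cohort
#'
#' Computes per-mouse Fc (colony count over injected dose) and summarizes as
#' mean +/- sample SD across mice.
#'
#' @param burdens List of [liver_burden()]s (or a `cohort`).
#' @return List with `mean`, `sd` (`NA` with a warning for a single mouse),
#'   `per_mouse` and `n_mice`.
#' @export
estimate_fc <- function(burdens) {
  if (inherits(burdens, "cohort")) burdens <- burdens$burdens
  if (inherits(burdens, "liver_burden")) burdens <- list(burdens)
  if (!length(burdens)) stop_input("need at least one liver burden")
  fc <- vapply(burdens, function(b) {
    if (is.null(b$n_injected) || !is.finite(b$n_injected))
      stop_input("burden for mouse ", b$mouse_id, " has no recorded dose")
    colonizing_fraction(nrow(b$colonies), b$n_injected)
  }, 0)
  sd <- if (length(fc) > 1L) stats::sd(fc) else {
    warning("single mouse: Fc dispersion undefined", call. = FALSE)
    NA_real_
  }
  list(mean = mean(fc), sd = sd, per_mouse = fc, n_mice = length(fc))
}

#' Estimate the doubling time from harvested colonies
#'
#' For each liver, up to `sample_size` colonies are drawn uniformly at random
#' without replacement (seeded), their cell numbers inferred through the
#' fluorescence calibration, and a per-colony Td computed under
#' single-founder exponential growth using that mouse's harvest time.
#' Colonies are then pooled across mice into a mean +/- sample SD.
#'
#' @param burdens List of [liver_burden()]s (or a `cohort`).
#' @param curve Fluorescence [calibration_curve()].
#' @param sample_size Colonies sampled per liver (default 5).
#' @param all_colonies If `TRUE`, use every colony.
#' @param seed Integer seed for the per-liver colony sample.
#' @return List with `mean`, `sd`, `per_colony` and `n` (colonies used).
#' @export
estimate_td <- function(burdens, curve, sample_size = 5L,
                        all_colonies = FALSE, seed = 1L) {
  if (inherits(burdens, "cohort")) burdens <- burdens$burdens
  if (inherits(burdens, "liver_burden")) burdens <- list(burdens)
  stopifnot(inherits(curve, "calibration_curve"))
  assert_scalar_number(sample_size, "sample_size", lower = 1)
  td <- unlist(lapply(seq_along(burdens), function(i) {
    b <- colony_cells(curve, burdens[[i]])
    co <- b$colonies
    if (!nrow(co)) return(numeric(0))
    keep <- if (all_colonies || nrow(co) <= sample_size) seq_len(nrow(co))
            else withr::with_seed(child_seed(seed, 3L, i),
                                  sample.int(nrow(co), sample_size))
    cells <- co$cell_count[keep]
    cells <- cells[cells >= 2]
    if (!length(cells)) return(numeric(0))
    doubling_time(cells, b$harvest_hours)
  }))
  if (!length(td))
    stop_domain("undefined doubling time: no colony with at least 2 inferred cells")
  list(mean = mean(td), sd = if (length(td) > 1L) stats::sd(td) else NA_real_,
       per_colony = td, n = length(td))
}

#' Fit an in vitro exponential growth curve
#'
#' Ordinary least squares of `log2(signal)` on time, so the slope is directly
#' divisions per hour and the doubling time is its reciprocal. Optionally
#' normalizes signals to the time-zero intensity first (the fitted Td is
#' invariant to overall signal scaling either way).
#'
#' @param times Hours, `>= 3` points including 0.
#' @param signals Positive signals, same length.
#' @param normalize Divide by the time-zero signal first (default `TRUE`).
#' @return List with `td` (hours; `Inf` with a warning when no growth is
#'   detectable), `r` (Pearson correlation of the log-linear fit), `slope`
#'   (divisions per hour).
#' @export
fit_invitro_growth <- function(times, signals, normalize = TRUE) {
  if (length(times) != length(signals) || length(times) < 3L)
    stop_input("need >= 3 paired (time, signal) points")
  if (!any(times == 0))
    stop_input("growth curve must include a time-zero point")
  if (any(signals <= 0))
    stop_domain("signals must be positive")
  if (normalize) signals <- signals / mean(signals[times == 0])
  y <- log2(signals)
  if (stats::sd(y) == 0) {
    warning("no growth detectable: doubling time is infinite", call. = FALSE)
    return(list(td = Inf, r = NA_real_, slope = 0))
  }
  fit <- stats::lm(y ~ times)
  slope <- unname(stats::coef(fit)["times"])
  if (slope == 0) {
    warning("no growth detectable: doubling time is infinite", call. = FALSE)
    return(list(td = Inf, r = NA_real_, slope = 0))
  }
  list(td = 1 / slope, r = pearson_correlation(times, y), slope = slope)
}

#' Simulation-based recovery of (Fc, Td)
#'
#' Repeatedly simulates a cohort under known generative parameters and runs
#' the inverse estimators, reporting the aggregate bias and relative error of
#' the recovered colonizing fraction and doubling time. This is the
#' verification harness showing that the estimators identify the generative
#' parameters under the model's own assumptions.
#'
#' @param true_params A [sim_params()].
#' @param n_mice Mice per simulated cohort.
#' @param n_replicates Number of independent cohorts.
#' @param sample_size,all_colonies Passed to [estimate_td()].
#' @return An object of class `recovery_report`: list with the true values,
#'   the mean and SD of the per-replicate estimates, relative errors of the
#'   means, `n_mice`, `n_replicates` and the generating seed.
#' @export
recover_params <- function(true_params, n_mice = 20L, n_replicates = 50L,
                           sample_size = 5L, all_colonies = FALSE) {
  stopifnot(inherits(true_params, "sim_params"))
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  est <- lapply(seq_len(n_replicates), function(r) {
    p <- true_params
    p$seed <- child_seed(true_params$seed, 4L, r)
    coh <- simulate_cohort(p, n_mice)
    fc <- suppressWarnings(estimate_fc(coh))
    td <- estimate_td(coh, true_params$fluor_curve, sample_size = sample_size,
                      all_colonies = all_colonies, seed = p$seed)
    c(fc = fc$mean, td = td$mean)
  })
  est <- do.call(rbind, est)
  fc_mean <- mean(est[, "fc"]); td_mean <- mean(est[, "td"])
  structure(
    list(true_fc = true_params$fc, est_fc_mean = fc_mean,
         est_fc_sd = stats::sd(est[, "fc"]),
         true_td = true_params$td_mean, est_td_mean = td_mean,
         est_td_sd = stats::sd(est[, "td"]),
         rel_err_fc = abs(fc_mean - true_params$fc) / true_params$fc,
         rel_err_td = abs(td_mean - true_params$td_mean) / true_params$td_mean,
         n_mice = n_mice, n_replicates = n_replicates,
         seed = true_params$seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates x %d mice (seed %d)\n",
              x$n_replicates, x$n_mice, x$seed))
  cat(sprintf("  Fc: true %.3g, est %.3g +/- %.2g (rel err %.2f%%)\n",
              x$true_fc, x$est_fc_mean, x$est_fc_sd, 100 * x$rel_err_fc))
  cat(sprintf("  Td: true %.2f, est %.2f +/- %.2g h (rel err %.2f%%)\n",
              x$true_td, x$est_td_mean, x$est_td_sd, 100 * x$rel_err_td))
  invisible(x)
}
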