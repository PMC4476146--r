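#' Synthetic ex vivo fluorescence image
#'
#' Lightweight container for a single-channel radiant-efficiency raster:
#' a nonnegative numeric matrix (row 0-equivalent at the top, column 1 at the
#' left, row-major physical layout) with a pixel size in mm and the constant
#' background level used at render time. Rendered images additionally carry a
#' `placements` data frame with the true sub-pixel colony centers.
#'
#' @param pixels Numeric matrix of nonnegative values.
#' @param pixel_size Edge length of one pixel in mm (`> 0`).
#' @param background Constant background level added at render time.
#' @param placements Optional data frame of true colony positions
#'   (`colony_id, row, col, fluor_signal`).
#' @return An object of class `fluorescence_image`.
#' @export
fluorescence_image <- function(pixels, pixel_size, background = 0,
                               placements = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_input("pixels must be a numeric matrix")
  if (any(pixels < 0)) stop_domain("pixel values must be nonnegative")
  assert_scalar_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 background = background, placements = placements),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %d x %d px (%.3g mm/px), range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render a synthetic ex vivo liver image from a burden
#'
#' Places each colony at a uniform-random sub-pixel position (rejection
#' sampling against a minimum pairwise separation and a border margin) and
#' deposits an isotropic Gaussian blob whose integrated signal equals the
#' colony's `fluor_signal` exactly (the discrete kernel is renormalized over
#' its support). Constant background and optional additive Gaussian pixel
#' noise, clipped at zero, are added on top. Deterministic given `seed`.
#'
#' @param burden A [liver_burden()].
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size mm per pixel (default 0.1).
#' @param psf_sigma Gaussian blob standard deviation in mm (default 0.3,
#'   i.e. 3 px at the default pixel size).
#' @param background Constant background level (default 0).
#' @param noise_sd Additive Gaussian pixel-noise SD (default 0).
#' @param min_separation Minimum center-to-center distance in mm
#'   (default `3 * psf_sigma`).
#' @param seed Integer seed for placement and noise.
#' @param max_tries Rejection-sampling retries per colony before failing.
#' @return A [fluorescence_image()] with `placements` filled in.
#' @export
render_liver_image <- function(burden, shape = c(256L, 256L), pixel_size = 0.1,
                               psf_sigma = 0.3, background = 0, noise_sd = 0,
                               min_separation = 3 * psf_sigma, seed = 1L,
                               max_tries = 5000L) {
  stopifnot(inherits(burden, "liver_burden"))
  assert_scalar_number(psf_sigma, "psf_sigma", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  nr <- shape[1]; nc <- shape[2]
  sigma_px <- psf_sigma / pixel_size
  half <- ceiling(5 * sigma_px)          # kernel support radius, px
  margin <- half + 1
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
    stop_input("field too small for the requested PSF: ", nr, "x", nc,
               " px with margin ", margin, " px")
  co <- burden$colonies
  img <- matrix(0, nr, nc)
  placements <- NULL

  if (nrow(co)) {
    sep_px <- min_separation / pixel_size
    pos <- withr::with_seed(as.integer(seed), {
      acc <- matrix(NA_real_, nrow(co), 2)
      for (i in seq_len(nrow(co))) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          p <- c(stats::runif(1, margin, nr - margin),
                 stats::runif(1, margin, nc - margin))
          if (i == 1L || all(sqrt(rowSums((acc[seq_len(i - 1L), , drop = FALSE] -
                                           matrix(p, i - 1L, 2, byrow = TRUE))^2)) >= sep_px)) {
            acc[i, ] <- p; ok <- TRUE; break
          }
        }
        if (!ok)
          stop_input("could not place colony ", i, " of ", nrow(co),
                     " with ", min_separation, " mm separation in a ",
                     nr, "x", nc, " px field; enlarge the field or relax ",
                     "min_separation")
      }
      acc
    })
    for (i in seq_len(nrow(co))) {
      r0 <- pos[i, 1]; c0 <- pos[i, 2]
      rows <- max(1L, floor(r0) - half):min(nr, floor(r0) + half)
      cols <- max(1L, floor(c0) - half):min(nc, floor(c0) + half)
      k <- outer(exp(-(rows - r0)^2 / (2 * sigma_px^2)),
                 exp(-(cols - c0)^2 / (2 * sigma_px^2)))
      img[rows, cols] <- img[rows, cols] + co$fluor_signal[i] * k / sum(k)
    }
    placements <- data.frame(colony_id = co$colony_id, row = pos[, 1],
                             col = pos[, 2], fluor_signal = co$fluor_signal)
  }

  img <- img + background
  if (noise_sd > 0) {
    noise <- withr::with_seed(child_seed(seed, 5L),
                              stats::rnorm(nr * nc, 0, noise_sd))
    img <- img + matrix(noise, nr, nc)
  }
  img[img < 0] <- 0
  fluorescence_image(img, pixel_size = pixel_size, background = background,
                     placements = placements)
}

# 8-connected component labeling of a logical matrix by vectorized
# frontier expansion; returns an integer label matrix (0 = background).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  offsets <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  todo <- which(fg)
  lab <- 0L
  for (seed_px in todo) {
    if (labels[seed_px] != 0L) next
    lab <- lab + 1L
    frontier <- seed_px
    labels[frontier] <- lab
    while (length(frontier)) {
      rows <- (frontier - 1L) %% nr + 1L
      nbr <- rep(frontier, each = 8L) + rep(offsets, times = length(frontier))
      nbr_row <- rep(rows, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                                            times = length(frontier))
      valid <- nbr >= 1L & nbr <= nr * nc & nbr_row >= 1L & nbr_row <= nr
      nbr <- unique(nbr[valid])
      nbr <- nbr[fg[nbr] & labels[nbr] == 0L]
      labels[nbr] <- lab
      frontier <- nbr
    }
  }
  labels
}

#' Detect colonies on a fluorescence image
#'
#' Thresholds at a robust background estimate (median) plus `k_sigma` times a
#' robust noise estimate (scaled MAD), labels 8-connected components, drops
#' components smaller than `min_pixels`, and integrates background-subtracted
#' signal per component. On a noiseless image (MAD zero) the threshold falls
#' back to a tiny fraction of the dynamic range above background. Detection
#' is invariant under adding a constant to the whole image because the
#' background is re-estimated from the image itself.
#'
#' @param image A [fluorescence_image()] or numeric matrix.
#' @param k_sigma Threshold height in robust-noise units (default 5).
#' @param min_pixels Minimum component area in pixels (default 4).
#' @param pixel_size mm per pixel; taken from the image object when present.
#' @return Data frame `label, row, col, area_px, integrated_signal,
#'   equiv_diam_mm` (centroids in pixel coordinates, signal-weighted), sorted
#'   by label; zero rows when nothing is detected.
#' @export
detect_colonies <- function(image, k_sigma = 5, min_pixels = 4L,
                            pixel_size = NULL) {
  if (inherits(image, "fluorescence_image")) {
    pixel_size <- pixel_size %||% image$pixel_size
    px <- image$pixels
  } else {
    px <- image
    pixel_size <- pixel_size %||% 1
  }
  assert_scalar_number(k_sigma, "k_sigma", lower = 0, strict_lower = TRUE)
  assert_scalar_number(min_pixels, "min_pixels", lower = 1)
  bg <- stats::median(px)
  noise <- stats::mad(px)
  thr <- if (noise > 0) bg + k_sigma * noise
         else bg + 1e-6 * max(max(px) - bg, 0)
  fg <- px > thr
  empty <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area_px = integer(0), integrated_signal = numeric(0),
                      equiv_diam_mm = numeric(0))
  if (!any(fg)) return(empty)
  labels <- label_components(fg)
  out <- lapply(seq_len(max(labels)), function(l) {
    idx <- which(labels == l)
    if (length(idx) < min_pixels) return(NULL)
    v <- px[idx] - bg
    rows <- (idx - 1L) %% nrow(px) + 1L
    cols <- (idx - 1L) %/% nrow(px) + 1L
    data.frame(label = l, row = sum(rows * v) / sum(v),
               col = sum(cols * v) / sum(v), area_px = length(idx),
               integrated_signal = sum(v),
               equiv_diam_mm = 2 * sqrt(length(idx) * pixel_size^2 / pi))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out$label <- seq_len(nrow(out))
  out
}

#' Match detections against true colony positions
#'
#' Greedy nearest-neighbor matching of detection centroids to true colony
#' centers: candidate pairs within `max_dist` are assigned in order of
#' increasing distance (ties broken by lowest detection label), each truth and
#' each detection used at most once.
#'
#' @param truth Data frame of true positions (`row, col` in pixels), e.g. the
#'   `placements` of a rendered image, or a rendered [fluorescence_image()].
#' @param detected Data frame from [detect_colonies()].
#' @param max_dist Maximum center distance in mm for a match.
#' @param pixel_size mm per pixel (taken from the image when `truth` is one).
#' @return List with `true_positives`, `false_positives`, `false_negatives`
#'   and a `matches` data frame (`truth_idx, detection_label, dist_mm`).
#' @export
match_detections <- function(truth, detected, max_dist, pixel_size = NULL) {
  if (inherits(truth, "fluorescence_image")) {
    pixel_size <- pixel_size %||% truth$pixel_size
    truth <- truth$placements
  }
  if (is.null(pixel_size)) stop_input("pixel_size required to express distances in mm")
  assert_scalar_number(max_dist, "max_dist", lower = 0, strict_lower = TRUE)
  n_t <- if (is.null(truth)) 0L else nrow(truth)
  n_d <- nrow(detected)
  matches <- data.frame(truth_idx = integer(0), detection_label = integer(0),
                        dist_mm = numeric(0))
  if (n_t && n_d) {
    pairs <- expand.grid(t = seq_len(n_t), d = seq_len(n_d))
    pairs$dist <- sqrt((truth$row[pairs$t] - detected$row[pairs$d])^2 +
                       (truth$col[pairs$t] - detected$col[pairs$d])^2) * pixel_size
    pairs <- pairs[pairs$dist <= max_dist, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, detected$label[pairs$d]), , drop = FALSE]
    used_t <- logical(n_t); used_d <- logical(n_d)
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$t[i]; di <- pairs$d[i]
      if (!used_t[ti] && !used_d[di]) {
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        matches <- rbind(matches,
                         data.frame(truth_idx = ti,
                                    detection_label = detected$label[di],
                                    dist_mm = pairs$dist[i]))
      }
    }
  }
  tp <- nrow(matches)
  list(true_positives = tp, false_positives = n_d - tp,
       false_negatives = n_t - tp, matches = matches)
}

#' Write / read a fluorescence image as 32-bit TIFF plus JSON sidecar
#'
#' Pixel values are stored normalized to `[0, 1]` as 32-bit float TIFF; the
#' scale factor, pixel size and background level travel in a `.json` sidecar
#' next to the image so the round trip restores radiant-efficiency units.
#' A 16-bit export (`bits = 16`) is available for viewers.
#'
#' @param image A [fluorescence_image()].
#' @param path Destination `.tif` path (sidecar written at `path + ".json"`).
#' @param bits 32 (default, float) or 16 (integer export).
#' @return `write_fluorescence_image` returns `path` invisibly;
#'   `read_fluorescence_image` a [fluorescence_image()] (placements are not
#'   persisted).
#' @export
write_fluorescence_image <- function(image, path, bits = 32L) {
  stopifnot(inherits(image, "fluorescence_image"))
  if (!bits %in% c(16L, 32L)) stop_input("bits must be 16 or 32")
  scale <- max(image$pixels, 1e-300)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  jsonlite::write_json(list(scale = scale, pixel_size = image$pixel_size,
                            background = image$background),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fluorescence_image
#' @export
read_fluorescence_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  fluorescence_image(px, pixel_size = meta$pixel_size,
                     background = meta$background)
}

#' Write detections to CSV
#'
#' Columns: `label,row,col,area_px,integrated_signal,equiv_diam_mm`.
#'
#' @param detections Data frame from [detect_colonies()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
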