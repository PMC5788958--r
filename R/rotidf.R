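#' Preprocess a raster image into a standard panorama
#'
#' Reduces a full-360-degree raster to the working format: keep only the
#' blue channel if the input is RGB (preserving the terrestrial-object /
#' sky contrast), then block-average down to one pixel per degree of azimuth
#' (360 x 117 by default). Input dimensions must be whole multiples of the
#' target so that block averaging is exact.
#'
#' @param img a numeric matrix (greyscale) or h x w x 3+ array (RGB); values
#'   on either the 0-1 or 0-255 scale.
#' @param width,height target size in px.
#' @return a `trunknav_panorama`.
#' @examples
#' m <- matrix(rep(c(0, 200), length.out = 720 * 234), 234, 720)
#' p <- preprocess(m)
#' p$grid[1, 1] # block means of the checkerboard
#' @export
preprocess <- function(img, width = 360, height = 117) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] < 3) stop("RGB input must have at least 3 channels")
    img <- img[, , 3]
  }
  if (!is.matrix(img)) stop("input must be a matrix or RGB array")
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  if (ncol(img) < width) {
    stop("input width ", ncol(img), " is narrower than the target ", width)
  }
  if (ncol(img) %% width != 0 || nrow(img) %% height != 0) {
    stop("input dimensions must be whole multiples of the target size")
  }
  fw <- ncol(img) %/% width
  fh <- nrow(img) %/% height
  r1 <- rowsum(img, rep(seq_len(height), each = fh))
  r2 <- t(rowsum(t(r1), rep(seq_len(width), each = fw)))
  grid <- r2 / (fh * fw)
  if (any(grid < 0 | grid > 255)) stop("intensities must lie in [0, 255]")
  new_panorama(grid)
}

#' Rotate a panorama by whole degrees
#'
#' Returns the same scene as seen after rotating the test image `r` degrees
#' clockwise: `rotate_panorama(p, r)` column `c` equals `p` column
#' `(c + r) mod 360`. Rotation works in whole-degree (whole-column) steps
#' only, matching the one-degree resolution of the mismatch scan.
#'
#' @param p a `trunknav_panorama`.
#' @param r rotation in integer degrees (any sign).
#' @return the rotated `trunknav_panorama`.
#' @export
rotate_panorama <- function(p, r) {
  stopifnot(inherits(p, "trunknav_panorama"))
  if (length(r) != 1 || !is.finite(r) || r != round(r)) {
    stop("rotation must be a single whole number of degrees")
  }
  step <- 360 / p$width
  if (r %% step != 0) stop("rotation must be a multiple of ", step, " degrees")
  shift <- (r / step) %% p$width
  idx <- ((seq_len(p$width) - 1 + shift) %% p$width) + 1
  new_panorama(p$grid[, idx, drop = FALSE], orientation = p$orientation,
               viewpoint = p$viewpoint, rotation = wrap_deg(p$rotation + r))
}

#' Rotational image difference function
#'
#' Mismatch between a reference and a test panorama at every possible
#' rotation of the test image in one-degree steps. The default metric is the
#' sum of absolute pixel-intensity differences (SAD); the root-mean-square
#' pixel difference (RMS) is also available. Low mismatch at rotation r means
#' the test view, turned r degrees clockwise, resembles the reference.
#'
#' `best_rotation` is the argmin, with ties broken toward the smallest
#' absolute signed rotation (wrapped to (-180, 180]), residual ties toward
#' positive (clockwise), so "no turn" is favoured.
#'
#' @param reference,test `trunknav_panorama`s of identical size.
#' @param metric `"sad"` or `"rms"`.
#' @return a `trunknav_rotidf` with fields `mismatch` (360 values),
#'   `metric`, `best_rotation`, `best_mismatch` and `valley_depth`.
#' @examples
#' sc <- default_scene()
#' base <- render_panorama(sc, trunk_viewpoint(sc, "foraging", 0, 0))
#' curve <- rotidf(base, base)
#' curve$best_rotation # 0: a view matches itself unrotated
#' @export
rotidf <- function(reference, test, metric = c("sad", "rms")) {
  stopifnot(inherits(reference, "trunknav_panorama"),
            inherits(test, "trunknav_panorama"))
  metric <- match.arg(metric)
  if (reference$width != test$width || reference$height != test$height) {
    stop("reference and test panoramas must have identical dimensions")
  }
  m <- cpp_rotidf(reference$grid, test$grid, metric == "rms")
  rot <- (seq_along(m) - 1) * (360 / reference$width)
  best <- pick_best_rotation(m, rot)
  structure(
    list(mismatch = m, rotation = rot, metric = metric,
         best_rotation = best, best_mismatch = min(m),
         valley_depth = valley_depth_values(m)),
    class = "trunknav_rotidf"
  )
}

# smallest |wrapped rotation| among exact minima; residual tie -> clockwise
pick_best_rotation <- function(m, rot) {
  cand <- rot[m == min(m)]
  sgn <- wrap_signed(cand)
  cand <- cand[abs(sgn) == min(abs(sgn))]
  sgn <- wrap_signed(cand)
  if (any(sgn > 0)) cand[sgn > 0][1] else cand[1]
}

valley_depth_values <- function(m) {
  mu <- mean(m)
  if (mu <= 0) return(0)
  1 - min(m) / mu
}

#' Valley depth of a rotIDF curve
#'
#' `1 - min(mismatch) / mean(mismatch)`: 0 for a flat curve, approaching 1
#' for a curve whose minimum dips far below its typical level. An all-zero
#' curve is defined to have depth 0.
#'
#' @param curve a `trunknav_rotidf`.
#' @return a value in `[0, 1]`.
#' @export
valley_depth <- function(curve) {
  stopifnot(inherits(curve, "trunknav_rotidf"))
  curve$valley_depth
}

#' Does a rotIDF curve show a clear minimum?
#'
#' Operationalises "a distinct valley of minimum mismatch": the valley depth
#' must reach `theta`, and the minimum must be unique in the sense that
#' every rotation whose mismatch comes within 5% of the valley depth of the
#' minimum lies inside `plateau` degrees of the best rotation. A broad or
#' multimodal trough fails the uniqueness condition.
#'
#' @param curve a `trunknav_rotidf`.
#' @param theta depth threshold (default 0.15).
#' @param plateau uniqueness window in degrees (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
has_clear_minimum <- function(curve, theta = 0.15, plateau = 5) {
  stopifnot(inherits(curve, "trunknav_rotidf"))
  if (curve$valley_depth < theta) return(FALSE)
  tol <- 0.05 * (mean(curve$mismatch) - curve$best_mismatch)
  near <- curve$rotation[curve$mismatch <= curve$best_mismatch + tol]
  all(abs(ang_diff(near, curve$best_rotation)) <= plateau)
}

#' @export
print.trunknav_rotidf <- function(x, ...) {
  cat(sprintf(
    "<trunknav_rotidf> metric %s: best rotation %d deg, mismatch %.4g, valley depth %.3f\n",
    toupper(x$metric), x$best_rotation, x$best_mismatch, x$valley_depth))
  invisible(x)
}

#' @export
tidy.trunknav_rotidf <- function(x, ...) {
  tibble::tibble(rotation_deg = x$rotation, mismatch = x$mismatch)
}

#' @export
glance.trunknav_rotidf <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 best_rotation = x$best_rotation,
                 best_mismatch = x$best_mismatch,
                 valley_depth = x$valley_depth,
                 clear_minimum = has_clear_minimum(x))
}

#' @export
autoplot.trunknav_rotidf <- function(object, ...) {
  df <- tidy(object)
  df$rotation_deg <- wrap_signed(df$rotation_deg)
  df <- df[order(df$rotation_deg), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$rotation_deg, .data$mismatch)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "rotation (deg, nest direction at 0)",
                  y = paste0("mismatch (", toupper(object$metric), ")"))
}

#' Export a rotIDF curve as CSV plus a JSON summary
#'
#' @param curve a `trunknav_rotidf`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_rotidf <- function(curve, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(tidy(curve), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(curve)), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(curve)
}
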