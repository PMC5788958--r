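#' Render an equirectangular panorama from a viewpoint
#'
#' Casts one ray per pixel into the scene. Column `c` (1-based) looks along
#' azimuth `(c - 0.5) * 360 / width` degrees clockwise from the viewpoint's
#' reference bearing (the nest direction for trunk viewpoints); rows span
#' elevations +66 (top) to -50 degrees (bottom) in one-degree steps at the
#' default height of 117 pixels, placing the horizon about 50 rows up from
#' the bottom as in one-pixel-per-degree ant-vision imaging. Each pixel takes
#' the intensity of the nearest intersected primitive (trunk, canopy, screen
#' or ground) plus world-anchored texture noise, or the sky intensity if no
#' primitive is hit. Occlusion is respected, including self-occlusion by the
#' trunk the viewer stands beside.
#'
#' The viewer height is clamped to a minimum of 1 cm so that ground-level
#' views keep a well-defined horizon.
#'
#' @param scene a [scene()].
#' @param viewpoint a [trunk_viewpoint()] or [viewpoint()].
#' @param width,height image size in px; `width` must divide 360.
#' @param noise render with texture noise (`TRUE`) or noise-free (`FALSE`).
#' @return a `trunknav_panorama`: a `height` x `width` intensity grid
#'   (0-255) with the orientation convention recorded.
#' @export
render_panorama <- function(scene, viewpoint, width = 360, height = 117,
                            noise = TRUE) {
  stopifnot(inherits(scene, "trunknav_scene"),
            inherits(viewpoint, "trunknav_viewpoint"))
  if (width <= 0 || height <= 0) stop("width and height must be positive")
  if (360 %% width != 0) stop("width must divide 360 into whole-degree bins")
  if (point_in_solid(scene, viewpoint$x, viewpoint$y, viewpoint$z)) {
    stop("viewpoint lies inside a solid primitive")
  }
  elev_top <- 66
  tr <- scene$trees
  ttone <- ifelse(is.na(tr$trunk_intensity %||% NA), scene$intensity$trunk,
                  tr$trunk_intensity)
  trunks <- cbind(tr$x, tr$y, tr$radius, tr$height, ttone)
  can <- tr[tr$canopy_radius > 0, ]
  canopies <- if (nrow(can) > 0) {
    ctone <- ifelse(is.na(can$canopy_intensity %||% NA),
                    scene$intensity$canopy, can$canopy_intensity)
    cbind(can$x, can$y, can$canopy_height, can$canopy_radius, ctone)
  } else matrix(0, 0, 5)
  scr <- if (!is.null(scene$screen)) {
    s <- scene$screen
    c(s$center_x, s$center_y, s$half_width, s$z_min, s$z_max,
      scene$intensity$screen)
  } else numeric(0)

  grid <- cpp_render_panorama(
    trunks, canopies,
    scene$intensity$ground, scene$intensity$sky, scr,
    viewpoint$x, viewpoint$y, max(viewpoint$z, 0.01),
    viewpoint$ref_bearing, as.integer(width), as.integer(height),
    elev_top,
    if (noise) scene$noise$amplitude else 0,
    if (noise) (scene$noise$bark_amplitude %||% scene$noise$amplitude) else 0,
    as.integer(scene$noise$seed)
  )
  new_panorama(grid, orientation = 0, viewpoint = viewpoint)
}

#' Construct a panorama from an intensity matrix
#'
#' @param grid numeric matrix, rows = elevation bins (top row first),
#'   columns = azimuth bins; intensities in `[0, 255]`.
#' @param orientation world azimuth of column 1 in degrees clockwise from
#'   the nest direction.
#' @return a `trunknav_panorama`.
#' @export
as_panorama <- function(grid, orientation = 0) {
  if (!is.matrix(grid) || !is.numeric(grid)) stop("grid must be a numeric matrix")
  if (any(grid < 0 | grid > 255)) stop("intensities must lie in [0, 255]")
  new_panorama(grid, orientation = orientation)
}

new_panorama <- function(grid, orientation = 0, viewpoint = NULL,
                         rotation = 0) {
  structure(
    list(grid = grid, width = ncol(grid), height = nrow(grid),
         orientation = wrap_deg(orientation), rotation = rotation,
         viewpoint = viewpoint),
    class = "trunknav_panorama"
  )
}

#' @export
print.trunknav_panorama <- function(x, ...) {
  cat(sprintf("<trunknav_panorama> %d x %d px, orientation %g deg\n",
              x$width, x$height, x$orientation))
  invisible(x)
}

#' @describeIn render_panorama tidy a panorama into a long tibble with one
#'   row per pixel (`azimuth_deg`, `elevation_deg`, `intensity`).
#' @param x a `trunknav_panorama`.
#' @param ... unused.
#' @export
tidy.trunknav_panorama <- function(x, ...) {
  az <- (seq_len(x$width) - 0.5) * (360 / x$width)
  el <- 66 - (seq_len(x$height) - 1)
  tibble::tibble(
    azimuth_deg = rep(az, each = x$height),
    elevation_deg = rep(el, times = x$width),
    intensity = as.vector(x$grid)
  )
}

#' @export
autoplot.trunknav_panorama <- function(object, center_nest = TRUE, ...) {
  df <- tidy(object)
  if (center_nest) {
    df$azimuth_deg <- wrap_signed(df$azimuth_deg)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth from nest direction (deg)",
                  y = "elevation (deg)", fill = "intensity")
}

#' Write / read panoramas as greyscale PNG with a JSON sidecar
#'
#' The sidecar records the orientation convention and, when known, the
#' viewpoint, so an image on disk can be re-associated with its geometry.
#'
#' @param p a `trunknav_panorama`.
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @return `write_panorama` returns `path` invisibly; `read_panorama` a
#'   `trunknav_panorama`.
#' @export
write_panorama <- function(p, path) {
  stopifnot(inherits(p, "trunknav_panorama"))
  png::writePNG(p$grid / 255, target = path)
  vp <- p$viewpoint
  side <- list(
    orientation_deg = p$orientation,
    rotation_deg = p$rotation,
    convention = "column 1 = nest direction, azimuth clockwise; row 1 = +66 deg elevation",
    width = p$width, height = p$height,
    viewpoint = if (!is.null(vp)) {
      list(x = vp$x, y = vp$y, z = vp$z, tree = vp$tree,
           azimuth_deg = vp$azimuth, height_m = vp$height)
    }
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panorama
#' @param path PNG path to read.
#' @export
read_panorama <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 3] # blue channel
  grid <- round(img * 255)
  orientation <- 0
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    orientation <- side$orientation_deg %||% 0
  }
  new_panorama(grid, orientation = orientation)
}
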