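#' Build a synthetic woodland scene
#'
#' A scene is the geometric world the renderer casts rays into: vertical
#' cylindrical trunks standing on a ground plane, spherical canopies, an
#' optional square landmark-blocking screen, and a nest position at the base
#' of one tree. Intensities are 8-bit grey levels; the sky is bright and
#' terrestrial objects dark, emulating blue-channel imaging in which the
#' skyline carries the dominant contrast.
#'
#' @param trees a data frame with one row per tree and columns `id`, `x`, `y`
#'   (trunk centre, m), `radius` (m), `height` (m), `canopy_radius` (m, 0 for
#'   none) and `canopy_height` (centre of the canopy sphere, m).
#' @param nest list with elements `x`, `y` (position, m) and `tree` (the id of
#'   the tree the nest abuts).
#' @param screen optional list with `center_x`, `center_y`, `half_width` (m),
#'   `z_min`, `z_max` (height range, m). `NULL` for no screen.
#' @param intensity named list of grey levels for `sky`, `ground`, `trunk`,
#'   `canopy`, `screen`, each in `[0, 255]`.
#' @param noise list with `amplitude` (grey levels, additive world-anchored
#'   texture on non-bark surfaces), `bark_amplitude` (texture on trunk
#'   surfaces; real bark is strongly mottled, so this is much larger) and
#'   `seed`.
#' @return an object of class `trunknav_scene`.
#' @examples
#' sc <- default_scene()
#' sc$trees
#' @export
scene <- function(trees, nest,
                  screen = NULL,
                  intensity = list(sky = 255, ground = 45, trunk = 60,
                                   canopy = 50, screen = 30),
                  noise = list(amplitude = 10, bark_amplitude = 70,
                               seed = 1)) {
  trees <- tibble::as_tibble(trees)
  need <- c("id", "x", "y", "radius", "height", "canopy_radius", "canopy_height")
  if (!all(need %in% names(trees))) {
    stop("`trees` must have columns ", paste(need, collapse = ", "))
  }
  # per-tree tones are optional; NA falls back to the global intensities
  if (!"trunk_intensity" %in% names(trees)) trees$trunk_intensity <- NA_real_
  if (!"canopy_intensity" %in% names(trees)) trees$canopy_intensity <- NA_real_
  tone <- c(trees$trunk_intensity, trees$canopy_intensity)
  if (any(!is.na(tone) & (tone < 0 | tone > 255))) {
    stop("per-tree intensities must lie in [0, 255]")
  }
  if (nrow(trees) < 1) stop("a scene needs at least one tree")
  if (any(trees$radius <= 0)) stop("trunk radius must be > 0")
  if (any(trees$height <= 0)) stop("trunk height must be > 0")
  if (anyDuplicated(trees$id)) stop("tree ids must be unique")
  ints <- unlist(intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")

  # reject overlapping trunk cross-sections
  if (nrow(trees) > 1) {
    for (i in seq_len(nrow(trees) - 1)) {
      for (j in seq(i + 1, nrow(trees))) {
        d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
        if (d < trees$radius[i] + trees$radius[j]) {
          stop("trunk cross-sections of trees '", trees$id[i], "' and '",
               trees$id[j], "' overlap")
        }
      }
    }
  }

  if (!all(c("x", "y", "tree") %in% names(nest))) {
    stop("`nest` must have elements x, y, tree")
  }
  if (!nest$tree %in% trees$id) stop("nest tree '", nest$tree, "' not in scene")
  dn <- sqrt((trees$x - nest$x)^2 + (trees$y - nest$y)^2)
  if (any(dn < trees$radius)) stop("nest lies inside a trunk cross-section")

  if (!is.null(screen)) {
    sneed <- c("center_x", "center_y", "half_width", "z_min", "z_max")
    if (!all(sneed %in% names(screen))) {
      stop("`screen` must have elements ", paste(sneed, collapse = ", "))
    }
    if (screen$half_width <= 0) stop("screen half_width must be > 0")
    if (screen$z_max <= screen$z_min) stop("screen height range is empty")
  }

  structure(
    list(trees = trees, nest = nest, screen = screen,
         intensity = intensity, noise = noise),
    class = "trunknav_scene"
  )
}

#' @export
print.trunknav_scene <- function(x, ...) {
  cat("<trunknav_scene> ", nrow(x$trees), " trees, nest at tree '",
      x$nest$tree, "'", if (!is.null(x$screen)) ", screen present" else "",
      "\n", sep = "")
  print(x$trees, n = 5)
  invisible(x)
}

#' Default study scene
#'
#' A nest tree with the nest 10 cm from its base, a foraging tree a few
#' metres away on the nest's far side, and a fixed set of distractor trees
#' of two kinds that together emulate open eucalypt woodland: nearby tall
#' thin saplings, whose trunks appear as full-height vertical stripes (their
#' small canopies sit above the rendered field of view), and mid-distance
#' canopy trees whose crowns form an azimuthally varied skyline. The nest
#' lies due "north" (+y) of the foraging tree, so the nest direction from
#' the foraging tree is world bearing 0. Distractor placement is fixed (not
#' random) so the default world is one concrete, reproducible environment.
#'
#' @param foraging_distance distance (m) from nest entrance to the foraging
#'   tree; the study trees were 3-4 m from the nest.
#' @param n_distractors number of surrounding trees (3-8).
#' @param screen if `TRUE`, add the landmark-blocking screen: a 1.5 x 1.5 m
#'   square of 2 m high walls around the nest tree, suspended 5 cm off the
#'   ground.
#' @param noise_seed seed for the world-anchored texture noise.
#' @param noise_amplitude texture amplitude (grey levels) for ground,
#'   canopy and screen surfaces.
#' @param bark_amplitude texture amplitude for trunk bark, which is far
#'   more strongly mottled than the other surfaces.
#' @return a `trunknav_scene`.
#' @export
default_scene <- function(foraging_distance = 3, n_distractors = 8,
                          screen = FALSE, noise_seed = 1,
                          noise_amplitude = 40, bark_amplitude = 70) {
  if (n_distractors < 3 || n_distractors > 8) {
    stop("n_distractors must be between 3 and 8")
  }
  nest <- list(x = 0, y = foraging_distance, tree = "nest")
  r_nest <- 0.12
  nest_tree_y <- foraging_distance + 0.10 + r_nest

  # Distractors, bearings in deg clockwise from the nest direction as seen
  # from the foraging tree: two mid-distance canopy trees (crowns between
  # ~30 and ~60 deg elevation) and a regrowth thicket of near, thin, tall
  # saplings whose trunks read as full-height vertical stripes. The thicket
  # sits on one flank (bearings 65-115) so that no rotation of the panorama
  # maps it onto itself or onto the crowns.
  db <- c(65, 74, 84, 94, 105, 115, 35, 150)[seq_len(n_distractors)]
  dd <- c(0.9, 1.6, 1.1, 2.0, 1.3, 1.8, 4.0, 4.2)[seq_len(n_distractors)]
  dr <- c(0.11, 0.09, 0.12, 0.10, 0.11, 0.09, 0.28, 0.30)[seq_len(n_distractors)]
  dh <- c(7, 7, 7, 7, 7, 7, 10, 11)[seq_len(n_distractors)]
  dcr <- c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 3.2, 3.4)[seq_len(n_distractors)]
  dch <- c(7.8, 7.8, 7.8, 7.8, 7.8, 7.8, 7.0, 8.0)[seq_len(n_distractors)]

  trees <- tibble::tibble(
    id = c("foraging", "nest", paste0("d", seq_len(n_distractors))),
    x = c(0, 0, sin(deg2rad(db)) * dd),
    y = c(0, nest_tree_y, cos(deg2rad(db)) * dd),
    radius = c(0.15, r_nest, dr),
    height = c(8, 6, dh),
    canopy_radius = c(2.0, 1.5, dcr),
    canopy_height = c(6.5, 4.5, dch),
    # species differ in bark and crown tone; variation across trees is what
    # makes misrotated panoramas costly to match
    trunk_intensity = c(60, 70, 40, 90, 55, 85, 45, 95, 75, 50)[
      seq_len(n_distractors + 2)],
    canopy_intensity = c(50, 55, 45, 45, 45, 45, 45, 45, 35, 60)[
      seq_len(n_distractors + 2)]
  )

  scr <- NULL
  if (screen) {
    scr <- list(center_x = 0, center_y = nest_tree_y, half_width = 0.75,
                z_min = 0.05, z_max = 2.0)
  }
  scene(trees, nest, screen = scr,
        noise = list(amplitude = noise_amplitude,
                     bark_amplitude = bark_amplitude, seed = noise_seed))
}

#' Read a scene from a YAML or JSON config file
#'
#' The config mirrors the arguments of [scene()]: a `trees` list (each entry
#' with id, x, y, radius, height, canopy_radius, canopy_height; metres), a
#' `nest` entry, optional `screen`, `intensity` and `noise` entries.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `trunknav_scene`.
#' @export
read_scene_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  trees <- cfg$trees
  if (is.data.frame(trees)) {
    trees <- tibble::as_tibble(trees)
  } else {
    trees <- purrr::map_dfr(trees, tibble::as_tibble)
  }
  args <- list(trees = trees, nest = cfg$nest)
  if (!is.null(cfg$screen)) args$screen <- cfg$screen
  if (!is.null(cfg$intensity)) args$intensity <- cfg$intensity
  if (!is.null(cfg$noise)) args$noise <- cfg$noise
  do.call(scene, args)
}

scene_tree <- function(scene, tree_id) {
  i <- match(tree_id, scene$trees$id)
  if (is.na(i)) stop("unknown tree id '", tree_id, "'")
  scene$trees[i, ]
}

#' Bearing of the nest from a tree's trunk axis
#'
#' @param scene a `trunknav_scene`.
#' @param tree_id a tree id in the scene.
#' @return world bearing in degrees (clockwise from +y) from the trunk axis
#'   to the nest; this bearing is trunk azimuth 0 for that tree.
#' @export
nest_bearing <- function(scene, tree_id) {
  tr <- scene_tree(scene, tree_id)
  bearing_deg(tr$x, tr$y, scene$nest$x, scene$nest$y)
}

#' Viewpoint on a trunk surface
#'
#' Places the eye just outside the bark of a tree at a given trunk azimuth
#' (degrees clockwise from the nest direction, nest side = 0) and height.
#'
#' @param scene a `trunknav_scene`.
#' @param tree_id which tree to stand on.
#' @param azimuth trunk azimuth in degrees (0 = nest side, clockwise).
#' @param height height above ground in m; must not exceed the trunk height.
#' @param offset eye clearance outside the bark in m (default 2 cm).
#' @return a `trunknav_viewpoint`: position `x`, `y`, `z` plus the reference
#'   bearing that maps panorama column 1 to the nest direction.
#' @export
trunk_viewpoint <- function(scene, tree_id, azimuth, height, offset = 0.02) {
  tr <- scene_tree(scene, tree_id)
  if (offset <= 0) stop("offset must be > 0")
  if (height < 0) stop("height must be >= 0")
  if (height > tr$height) {
    stop("height ", height, " m is above the top of tree '", tree_id, "'")
  }
  nb <- nest_bearing(scene, tree_id)
  b <- wrap_deg(nb + azimuth)
  d <- tr$radius + offset
  structure(
    list(x = tr$x + d * sin(deg2rad(b)),
         y = tr$y + d * cos(deg2rad(b)),
         z = height,
         ref_bearing = nb,
         tree = tree_id, azimuth = wrap_deg(azimuth),
         height = height, offset = offset),
    class = "trunknav_viewpoint"
  )
}

#' @export
print.trunknav_viewpoint <- function(x, ...) {
  cat(sprintf(
    "<trunknav_viewpoint> tree '%s', azimuth %.1f deg, height %.2f m (%.3f, %.3f, %.3f)\n",
    x$tree, x$azimuth, x$height, x$x, x$y, x$z))
  invisible(x)
}

#' Free-standing viewpoint at an arbitrary position
#'
#' @param x,y,z position in m (`z >= 0`).
#' @param ref_bearing world bearing (deg) of panorama column 1; by default the
#'   nest direction must be supplied by the caller.
#' @return a `trunknav_viewpoint`.
#' @export
viewpoint <- function(x, y, z, ref_bearing = 0) {
  if (z < 0) stop("z must be >= 0")
  structure(list(x = x, y = y, z = z, ref_bearing = wrap_deg(ref_bearing),
                 tree = NA_character_, azimuth = NA_real_, height = z,
                 offset = NA_real_),
            class = "trunknav_viewpoint")
}

# TRUE if the point sits strictly inside a trunk or canopy
point_in_solid <- function(scene, x, y, z) {
  tr <- scene$trees
  in_trunk <- any((x - tr$x)^2 + (y - tr$y)^2 < tr$radius^2 &
                    z >= 0 & z <= tr$height)
  has_can <- tr$canopy_radius > 0
  in_can <- any(((x - tr$x)^2 + (y - tr$y)^2 +
                   (z - tr$canopy_height)^2) < tr$canopy_radius^2 & has_can)
  in_trunk || in_can
}
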