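# Fixtures are built in code; nothing is read from disk.

# Minimal two-tree scene (nest tree + foraging tree), no distractors.
two_tree_scene <- function(noise_amplitude = 0, screen = FALSE) {
  trees <- tibble::tibble(
    id = c("foraging", "nest"),
    x = c(0, 0), y = c(0, 3.22),
    radius = c(0.15, 0.12), height = c(8, 6),
    canopy_radius = c(2.0, 1.5), canopy_height = c(6.5, 4.5)
  )
  scr <- if (screen) {
    list(center_x = 0, center_y = 3.22, half_width = 0.75,
         z_min = 0.05, z_max = 2.0)
  }
  scene(trees, nest = list(x = 0, y = 3, tree = "nest"), screen = scr,
        noise = list(amplitude = noise_amplitude,
                     bark_amplitude = noise_amplitude, seed = 1))
}

# "Empty" world for sky/ground checks: the one mandatory tree is so far and
# thin that no ray at one-degree resolution intersects it.
open_scene <- function(sky = 255, ground = 40) {
  trees <- tibble::tibble(
    id = "far", x = sin(89.7 * pi / 180) * 100,
    y = cos(89.7 * pi / 180) * 100,
    radius = 0.01, height = 1, canopy_radius = 0, canopy_height = 0
  )
  scene(trees, nest = list(x = 0, y = 3, tree = "far"),
        intensity = list(sky = sky, ground = ground, trunk = 60,
                         canopy = 50, screen = 30),
        noise = list(amplitude = 0, bark_amplitude = 0, seed = 1))
}

# Single visible trunk at a chosen bearing/distance, optional short height.
one_trunk_scene <- function(distance = 5, bearing = 90, radius = 0.5,
                            height = 8, ground = 40) {
  trees <- tibble::tibble(
    id = "t", x = sin(bearing * pi / 180) * distance,
    y = cos(bearing * pi / 180) * distance,
    radius = radius, height = height, canopy_radius = 0, canopy_height = 0
  )
  scene(trees, nest = list(x = 0, y = 3, tree = "t"),
        intensity = list(sky = 255, ground = ground, trunk = 60,
                         canopy = 50, screen = 30),
        noise = list(amplitude = 0, bark_amplitude = 0, seed = 1))
}

random_panorama <- function(seed, width = 360, height = 117) {
  withr::with_seed(seed, {
    as_panorama(matrix(sample(0:255, width * height, replace = TRUE),
                       height, width))
  })
}

# Independent slow SAD/RMS oracle: explicit loop over rotations and columns.
rotidf_oracle <- function(ref, test, rms = FALSE) {
  W <- ncol(ref); H <- nrow(ref)
  out <- numeric(W)
  for (r in 0:(W - 1)) {
    s <- 0
    for (cc in 1:W) {
      tc <- ((cc - 1 + r) %% W) + 1
      d <- ref[, cc] - test[, tc]
      s <- s + if (rms) sum(d^2) else sum(abs(d))
    }
    out[r + 1] <- if (rms) sqrt(s / (H * W)) else s
  }
  out
}

# Independent brute-force per-ray intersection oracle for a single vertical
# cylinder (no occlusion logic needed with one primitive + ground).
ray_hits_cylinder <- function(vx, vy, vz, az_deg, el_deg, cx, cy, r, h) {
  b <- az_deg * pi / 180; e <- el_deg * pi / 180
  dx <- cos(e) * sin(b); dy <- cos(e) * cos(b); dz <- sin(e)
  A <- dx^2 + dy^2
  if (A < 1e-14) return(FALSE)
  ox <- vx - cx; oy <- vy - cy
  B <- 2 * (ox * dx + oy * dy); C <- ox^2 + oy^2 - r^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(FALSE)
  for (t in c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))) {
    if (t > 1e-9) {
      z <- vz + t * dz
      # the ground plane would occlude beyond its intersection
      tg <- if (dz < 0) -vz / dz else Inf
      if (z >= 0 && z <= h && t < tg) return(TRUE)
    }
  }
  FALSE
}

# Brute-force final-descent oracle: earliest index whose suffix never rises.
final_descent_oracle <- function(h) {
  n <- length(h)
  for (i in 1:n) {
    if (all(diff(h[i:n]) <= 0)) return(i)
  }
  n
}
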