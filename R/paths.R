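#' Keep only the final descent of a trunk path
#'
#' When an animal abandons a descent and climbs back up, only the final
#' descent is informative about where it ends up. This returns the suffix of
#' the path from the last local maximum of height onward: the final run over
#' which height never increases (ties allowed).
#'
#' @param path a data frame ordered in time with at least a `height_m`
#'   column; typically also `azimuth_deg` and `step`.
#' @return the filtered path as a tibble (same columns).
#' @examples
#' p <- tibble::tibble(step = 1:6, height_m = c(1.5, 1.2, 1.8, 2.1, 1.0, 0))
#' final_descent_filter(p) # keeps the 2.1 -> 0 suffix
#' @export
final_descent_filter <- function(path) {
  path <- tibble::as_tibble(path)
  if (nrow(path) == 0) stop("path is empty")
  h <- path$height_m
  if (is.null(h)) stop("path must have a height_m column")
  i <- length(h)
  while (i > 1 && h[i - 1] >= h[i]) i <- i - 1
  path[seq(i, length(h)), ]
}

#' Azimuths at which a path crosses given heights
#'
#' For each target height, finds the first time the (final-descent filtered)
#' path reaches or passes below it and linearly interpolates the azimuth
#' between the bracketing steps. Azimuths are interpolated on the continuous
#' (unwrapped) track and reported wrapped to `[0, 360)`.
#'
#' @param path a path tibble with `height_m` and `azimuth_deg` (unwrapped,
#'   i.e. continuous across the +/-180 seam) columns.
#' @param heights target heights in m (default 1 and 0).
#' @param filter apply [final_descent_filter()] first (default `TRUE`).
#' @return a tibble with `height_m` and `azimuth_deg` per crossing; targets
#'   the path never reaches are omitted.
#' @export
height_crossings <- function(path, heights = c(1, 0), filter = TRUE) {
  if (filter) path <- final_descent_filter(path)
  h <- path$height_m
  a <- path$azimuth_deg
  purrr::map_dfr(heights, function(target) {
    idx <- which(h <= target)
    if (length(idx) == 0) return(tibble::tibble())
    j <- idx[1]
    az <- if (j == 1 || h[j] == target) {
      a[j]
    } else {
      w <- (h[j - 1] - target) / (h[j - 1] - h[j])
      a[j - 1] + w * (a[j] - a[j - 1])
    }
    tibble::tibble(height_m = target, azimuth_deg = wrap_deg(az))
  })
}
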