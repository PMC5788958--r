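# Angle helpers. All public angles are degrees; radians only inside formulas.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#' @param x angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @export
wrap_deg <- function(x) x %% 360

#' Wrap angles to the signed interval (-180, 180]
#'
#' Used for trunk positions in path plots, where +180 and -180 are the same
#' point on the far side of the trunk.
#' @param x angles in degrees.
#' @return numeric vector in `(-180, 180]`.
#' @export
wrap_signed <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

# bearing (deg clockwise from +y, compass style) from point a to point b
bearing_deg <- function(ax, ay, bx, by) {
  wrap_deg(rad2deg(atan2(bx - ax, by - ay)))
}

# shortest signed angular difference a - b in (-180, 180]
ang_diff <- function(a, b) wrap_signed(a - b)

`%||%` <- function(x, y) if (is.null(x)) y else x
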