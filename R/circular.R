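#' Circular mean direction and resultant length
#'
#' @param angles directions in degrees.
#' @return a list with `mu` (mean direction in `[0, 360)` degrees, `NA` when
#'   the resultant length is numerically zero) and `R` (mean resultant
#'   length in `[0, 1]`).
#' @examples
#' circ_mean(c(10, 350, 20, 340, 0)) # mu = 0 by symmetry
#' @export
circ_mean <- function(angles) {
  if (length(angles) < 1) stop("at least one angle is required")
  th <- deg2rad(angles)
  S <- mean(sin(th)); C <- mean(cos(th))
  R <- sqrt(S^2 + C^2)
  mu <- if (R < 1e-12) NA_real_ else wrap_deg(rad2deg(atan2(S, C)))
  list(mu = mu, R = R)
}

new_circ_test <- function(method, n, mu, R, statistic, p, ci = NULL,
                          alpha = 0.05, mu0 = NA_real_) {
  structure(
    list(method = method, n = n, mu = mu, R = R, statistic = statistic,
         p = min(max(p, 0), 1), ci = ci, alpha = alpha, mu0 = mu0),
    class = "trunknav_circ_test"
  )
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether directions are uniformly spread around the circle against
#' the alternative of unimodal clustering. The statistic is `Z = n * R^2`;
#' the p-value uses the standard series approximation
#' `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clipped to `[0, 1]`. The series is accurate from about `n = 10`
#' upward; below that (`method = "auto"`) the p-value comes from a
#' simulated uniform null of `Z` instead, which draws from the current RNG
#' stream.
#'
#' @param angles directions in degrees (n >= 3; a warning below 5).
#' @param method `"auto"` (series for n >= 10, simulation below),
#'   `"series"`, or `"simulation"`.
#' @param n_sim replicates for the simulated null.
#' @return a `trunknav_circ_test` with fields `n`, `mu`, `R`, `statistic`
#'   (Z), `p`.
#' @export
rayleigh_test <- function(angles, method = c("auto", "series", "simulation"),
                          n_sim = 20000) {
  method <- match.arg(method)
  n <- length(angles)
  if (n < 3) stop("the Rayleigh test needs at least 3 angles")
  if (n < 5) warning("Rayleigh test on fewer than 5 angles is unreliable")
  if (method == "auto") method <- if (n >= 10) "series" else "simulation"
  cm <- circ_mean(angles)
  Z <- n * cm$R^2
  p <- if (method == "series") {
    exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                 (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  } else {
    th <- matrix(runif(n_sim * n, 0, 2 * pi), n_sim)
    Znull <- n * (rowMeans(sin(th))^2 + rowMeans(cos(th))^2)
    (sum(Znull >= Z) + 1) / (n_sim + 1)
  }
  new_circ_test(paste0("Rayleigh test of uniformity (", method, ")"),
                n, cm$mu, cm$R, c(Z = Z), p)
}

#' V-test of clustering toward a predicted direction
#'
#' Modified Rayleigh test against an a-priori direction `mu0` (the nest
#' direction, 0 degrees, by default). `V = R * cos(mu - mu0)` and
#' `u = V * sqrt(2n)`; the one-tailed p-value comes from the upper tail of
#' the standard normal, or from a uniform-null permutation distribution of
#' `V` when `method = "permutation"`. The normal approximation is accurate
#' from about `n = 15` upward; below that (`method = "auto"`) the
#' permutation p is used, drawing from the current RNG stream.
#'
#' @param angles directions in degrees (n >= 3).
#' @param mu0 predicted direction in degrees, specified a priori.
#' @param method `"auto"` (normal for n >= 15, permutation below),
#'   `"normal"` (large-sample approximation) or `"permutation"`.
#' @param n_perm number of uniform-null replicates for the permutation p.
#' @return a `trunknav_circ_test` with statistic components `V` and `u`.
#' @export
v_test <- function(angles, mu0 = 0,
                   method = c("auto", "normal", "permutation"),
                   n_perm = 20000) {
  method <- match.arg(method)
  n <- length(angles)
  if (n < 3) stop("the V-test needs at least 3 angles")
  if (method == "auto") method <- if (n >= 15) "normal" else "permutation"
  cm <- circ_mean(angles)
  # R * cos(mu - mu0) equals the mean cosine about mu0, defined even if R = 0
  V <- mean(cos(deg2rad(angles - mu0)))
  u <- V * sqrt(2 * n)
  p <- if (method == "normal") {
    pnorm(u, lower.tail = FALSE)
  } else {
    vn <- rowMeans(cos(matrix(runif(n_perm * n, 0, 2 * pi), n_perm)))
    (sum(vn >= V) + 1) / (n_perm + 1)
  }
  new_circ_test(paste0("V-test (", method, ")"), n, cm$mu, cm$R,
                c(V = V, u = u), p, mu0 = mu0)
}

#' Confidence interval for the mean direction
#'
#' Large-sample interval based on the circular dispersion
#' `delta = (1 - rho2) / (2 R^2)` where `rho2` is the mean cosine of twice
#' the deviations from the mean direction: the half-width is
#' `asin(z * sqrt(delta / n))` degrees around `mu`. When the interval does
#' not exist (resultant too small, so the asin argument exceeds 1, or the
#' mean direction is undefined) an explicitly undefined result is returned
#' rather than a silently wrapped interval.
#'
#' @param angles directions in degrees (n >= 5).
#' @param conf confidence level (default 0.95).
#' @return a list with `lower`, `upper` (degrees in `[0, 360)`; traversing
#'   clockwise from lower to upper through `mu` spans the interval), `mu`,
#'   and `defined` (`FALSE` when the interval does not exist, in which case
#'   lower/upper are `NA`).
#' @export
mean_ci <- function(angles, conf = 0.95) {
  n <- length(angles)
  if (n < 5) stop("the mean-direction CI needs at least 5 angles")
  cm <- circ_mean(angles)
  undefined <- list(lower = NA_real_, upper = NA_real_, mu = cm$mu,
                    defined = FALSE, conf = conf)
  if (is.na(cm$mu) || cm$R < 1e-8) return(undefined)
  rho2 <- mean(cos(2 * deg2rad(angles - cm$mu)))
  delta <- (1 - rho2) / (2 * cm$R^2)
  arg <- qnorm(1 - (1 - conf) / 2) * sqrt(delta / n)
  if (!is.finite(arg) || arg > 1) return(undefined)
  half <- rad2deg(asin(arg))
  list(lower = wrap_deg(cm$mu - half), upper = wrap_deg(cm$mu + half),
       mu = cm$mu, defined = TRUE, conf = conf)
}

#' Is a direction inside a circular confidence interval?
#'
#' Membership is decided on the wrapped arc running clockwise from `lower`
#' through `mu` to `upper`, so intervals crossing 0 (e.g. 352 to 37 degrees)
#' behave correctly.
#'
#' @param ci a result of [mean_ci()].
#' @param direction direction in degrees to test.
#' @return `TRUE`, `FALSE`, or `NA` if the interval is undefined.
#' @export
ci_contains <- function(ci, direction) {
  if (!isTRUE(ci$defined)) return(NA)
  half_lo <- wrap_deg(ci$mu - ci$lower)   # arc from lower up to mu
  off <- ang_diff(direction, ci$mu)
  half_hi <- wrap_deg(ci$upper - ci$mu)
  if (off >= 0) off <= half_hi else -off <= half_lo
}

#' @export
print.trunknav_circ_test <- function(x, ...) {
  stat <- paste(names(x$statistic), signif(x$statistic, 4),
                sep = " = ", collapse = ", ")
  cat(sprintf("%s: n = %d, mu = %s deg, R = %.3f, %s, p = %.4g\n",
              x$method, x$n,
              if (is.na(x$mu)) "undefined" else sprintf("%.3f", x$mu),
              x$R, stat, x$p))
  invisible(x)
}

#' @export
tidy.trunknav_circ_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n, mu = x$mu, R = x$R,
    statistic = x$statistic[[1]],
    statistic_name = names(x$statistic)[1],
    p.value = x$p
  )
}

#' @export
glance.trunknav_circ_test <- function(x, ...) tidy(x, ...)

#' Table-style summary of angular observations
#'
#' One row in the style of the study's results table: mean vector, 95% CI
#' bounds, Rayleigh Z and p, V and p toward `mu0`, and whether `mu0` falls
#' inside the CI.
#'
#' @param angles directions in degrees.
#' @param mu0 predicted direction (deg).
#' @return a one-row tibble.
#' @export
circ_summary_row <- function(angles, mu0 = 0) {
  cm <- circ_mean(angles)
  ray <- rayleigh_test(angles)
  vt <- v_test(angles, mu0 = mu0)
  ci <- if (length(angles) >= 5) mean_ci(angles) else
    list(lower = NA_real_, upper = NA_real_, defined = FALSE)
  tibble::tibble(
    n = length(angles),
    mu = cm$mu, R = cm$R,
    ci_minus = ci$lower, ci_plus = ci$upper,
    rayleigh_Z = unname(ray$statistic["Z"]), rayleigh_p = ray$p,
    V = unname(vt$statistic["V"]), v_p = vt$p,
    mu0_in_ci = ci_contains(ci, mu0)
  )
}
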