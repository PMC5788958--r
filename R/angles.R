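#' Draw angular behavioural samples
#'
#' Synthetic stand-in for forager positions: directions drawn from a von
#' Mises distribution (clustered, concentration `kappa`) or the circular
#' uniform. A von Mises with `kappa = 0` is uniform.
#'
#' @param n number of angles (>= 1).
#' @param distribution `"vonmises"` or `"uniform"`.
#' @param mu mean direction in degrees (von Mises only).
#' @param kappa concentration parameter (>= 0).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @param condition,height_m,replicate optional labels carried into the
#'   output table.
#' @return a tibble with columns `angle_deg` (in `[0, 360)`), `condition`,
#'   `height_m`, `replicate`.
#' @examples
#' sample_angles(5, "vonmises", mu = 0, kappa = 4, seed = 1)
#' @export
sample_angles <- function(n, distribution = c("vonmises", "uniform"),
                          mu = 0, kappa = 1, seed = 1,
                          condition = NA_character_, height_m = NA_real_,
                          replicate = 1L) {
  distribution <- match.arg(distribution)
  if (n < 1) stop("n must be >= 1")
  if (kappa < 0) stop("kappa must be >= 0")
  angles <- withr::with_seed(seed, {
    if (distribution == "uniform" || kappa == 0) {
      runif(n, 0, 360)
    } else {
      rvonmises_deg(n, mu, kappa)
    }
  })
  tibble::tibble(angle_deg = wrap_deg(angles),
                 condition = condition, height_m = height_m,
                 replicate = replicate)
}

#' von Mises random deviates in degrees
#'
#' Best-Fisher rejection sampler. Exported because the simulation oracles in
#' the test-suite and the descent agents' motor noise both draw from it.
#'
#' @param n sample size.
#' @param mu mean direction (deg).
#' @param kappa concentration (> 0).
#' @return `n` angles in `[0, 360)` degrees.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_deg(mu + rad2deg(out))
}

#' Write an angular sample table to CSV
#'
#' @param angles a tibble as returned by [sample_angles()].
#' @param path output path.
#' @export
write_angles_csv <- function(angles, path) {
  utils::write.csv(angles, path, row.names = FALSE)
  invisible(path)
}
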