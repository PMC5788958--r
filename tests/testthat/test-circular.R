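test_that("the circular mean handles concentration, symmetry and balance", {
  expect_equal(circ_mean(c(0, 0, 0)), list(mu = 0, R = 1))
  sym <- circ_mean(c(0, 90, 180, 270))
  expect_true(is.na(sym$mu))
  expect_equal(sym$R, 0, tolerance = 1e-12)
  # balanced sample around 0, R cross-checked by direct summation
  a <- c(10, 350, 20, 340, 0)
  got <- circ_mean(a)
  expect_equal(wrap_signed(got$mu), 0, tolerance = 1e-9)
  th <- a * pi / 180
  expect_equal(got$R, sqrt(mean(sin(th))^2 + mean(cos(th))^2))
  expect_error(circ_mean(numeric(0)), "at least one")
})

test_that("the Rayleigh statistic follows Z = n R^2", {
  res <- rayleigh_test(rep(42, 12))
  expect_equal(unname(res$statistic["Z"]), 12)
  expect_equal(res$R, 1)
  spread <- rayleigh_test(seq(0, 315, by = 45))
  expect_equal(unname(spread$statistic["Z"]), 0, tolerance = 1e-12)
  expect_equal(spread$p, 1, tolerance = 1e-3)
  expect_error(rayleigh_test(c(1, 2)), "at least 3")
  expect_warning(rayleigh_test(c(1, 2, 3, 4)), "fewer than 5")
})

test_that("Rayleigh p-values agree with a simulated uniform null", {
  n <- 12
  x <- withr::with_seed(71, rvonmises_deg(n, 0, 0.8))
  res <- rayleigh_test(x)
  nulls <- withr::with_seed(72, {
    replicate(20000, {
      u <- runif(n, 0, 2 * pi)
      n * (mean(sin(u))^2 + mean(cos(u))^2)
    })
  })
  p_mc <- mean(nulls >= unname(res$statistic["Z"]))
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(res$p - p_mc), 3 * se + 1e-4)
})

test_that("the V-test statistic and tails behave at the alignment extremes", {
  aligned <- v_test(rep(0, 10), mu0 = 0)
  expect_equal(unname(aligned$statistic["V"]), 1)
  expect_equal(unname(aligned$statistic["u"]), sqrt(20))
  expect_lt(aligned$p, 0.001)
  anti <- v_test(rep(180, 10), mu0 = 0)
  expect_equal(unname(anti$statistic["V"]), -1)
  expect_gt(anti$p, 0.99)
  expect_error(v_test(c(0, 10)), "at least 3")
})

test_that("normal and permutation V-test p-values agree for moderate data", {
  x <- withr::with_seed(5, rvonmises_deg(15, 20, 2))
  pn <- v_test(x, mu0 = 0)
  pp <- withr::with_seed(6, v_test(x, mu0 = 0, method = "permutation",
                                   n_perm = 20000))
  expect_equal(unname(pn$statistic["V"]), unname(pp$statistic["V"]))
  se <- sqrt(pp$p * (1 - pp$p) / 20000)
  expect_lt(abs(pn$p - pp$p), 3 * se + 5e-3)
})

test_that("the mean-direction CI shrinks with concentration and wraps", {
  tight <- withr::with_seed(8, rvonmises_deg(20, 0, 1e6))
  ci <- mean_ci(tight)
  expect_true(ci$defined)
  width <- (ci$upper - ci$lower) %% 360
  expect_lt(width, 1)
  expect_true(ci_contains(ci, ci$mu))
  # concentrated at 0: the interval crosses the 0/360 seam
  x <- c(350, 355, 0, 5, 10, 352, 8, 357, 3, 14)
  ci2 <- mean_ci(x)
  expect_gt(ci2$lower, 300)
  expect_lt(ci2$upper, 60)
  expect_true(ci_contains(ci2, 0))
  expect_false(ci_contains(ci2, 180))
  # clockwise span from lower to upper is below 180 for concentrated data
  expect_lt((ci2$upper - ci2$lower) %% 360, 180)
})

test_that("near-uniform samples yield an explicitly undefined CI", {
  x <- c(0, 90, 180, 270, 45, 135, 225, 315)
  ci <- mean_ci(x)
  expect_false(ci$defined)
  expect_true(is.na(ci$lower))
  expect_true(is.na(ci_contains(ci, 0)))
  expect_error(mean_ci(c(1, 2, 3)), "at least 5")
})

test_that("circular statistics are equivariant under rotation of the data", {
  x <- withr::with_seed(9, rvonmises_deg(15, 77, 2))
  for (shift in c(33, 200)) {
    a <- rayleigh_test(x); b <- rayleigh_test(x + shift)
    expect_equal(b$mu, (a$mu + shift) %% 360, tolerance = 1e-9)
    expect_equal(b$R, a$R)
    expect_equal(b$statistic, a$statistic)
    cia <- mean_ci(x); cib <- mean_ci(x + shift)
    expect_equal(cib$lower, (cia$lower + shift) %% 360, tolerance = 1e-9)
    expect_equal(cib$upper, (cia$upper + shift) %% 360, tolerance = 1e-9)
  }
})

test_that("tidiers return one-row summaries", {
  x <- withr::with_seed(10, rvonmises_deg(15, 0, 2))
  td <- tidy(rayleigh_test(x))
  expect_equal(nrow(td), 1)
  expect_equal(td$statistic_name, "Z")
  tv <- glance(v_test(x))
  expect_equal(tv$statistic_name, "V")
  row <- circ_summary_row(x)
  expect_named(row, c("n", "mu", "R", "ci_minus", "ci_plus", "rayleigh_Z",
                      "rayleigh_p", "V", "v_p", "mu0_in_ci"))
})

test_that("angular samples are reproducible and match their distributions", {
  s1 <- sample_angles(50, "vonmises", mu = 0, kappa = 4, seed = 3)
  s2 <- sample_angles(50, "vonmises", mu = 0, kappa = 4, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$angle_deg >= 0 & s1$angle_deg < 360))

  # near-degenerate concentration collapses on the mean
  tight <- sample_angles(5, "vonmises", mu = 0, kappa = 1e6, seed = 4)
  expect_true(all(abs(wrap_signed(tight$angle_deg)) < 0.5))

  # large uniform sample has a near-zero resultant
  unif <- sample_angles(1e4, "uniform", seed = 5)
  expect_lt(circ_mean(unif$angle_deg)$R, 0.05)
  # von Mises with kappa 0 is uniform too
  vm0 <- sample_angles(1e4, "vonmises", kappa = 0, seed = 6)
  expect_lt(circ_mean(vm0$angle_deg)$R, 0.05)

  expect_error(sample_angles(0, "uniform"), "n must be")
  expect_error(sample_angles(5, "vonmises", kappa = -1), "kappa")

  csv <- file.path(tempdir(), "angles.csv")
  write_angles_csv(s1, csv)
  expect_equal(utils::read.csv(csv)$angle_deg, s1$angle_deg)
})

test_that("the von Mises sampler matches theory at moderate concentration", {
  x <- withr::with_seed(11, rvonmises_deg(20000, 90, 2))
  cm <- circ_mean(x)
  expect_equal(cm$mu, 90, tolerance = 2)
  # E[R] = I1(k)/I0(k) ~ 0.6978 at kappa = 2
  expect_equal(cm$R, besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
})
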