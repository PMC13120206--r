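test_that("moment fits reproduce the requested moments", {
  s <- list(min = 6.93, max = 25.3, mean = 12.43, sd = 4.8253)

  for (fam in c("normal", "lognormal", "beta_scaled", "weibull")) {
    sp <- fit_by_moments(fam, s)
    expect_equal(dist_mean(sp), s$mean, tolerance = 1e-9)
  }
  # unclamped triangular mode 3*mean - min - max also matches the mean exactly
  tri <- fit_by_moments("triangular", list(min = 57, mean = 73.71, max = 85.1))
  expect_equal(tri$params$mode, 79.03, tolerance = 1e-12)
  expect_equal(dist_mean(tri), 73.71, tolerance = 1e-9)

  # uniform is pinned to [min, max]; its mean is the midpoint
  u <- fit_by_moments("uniform", list(min = 0, max = 2))
  expect_equal(dist_mean(u), 1)

  # lognormal closed form: sdlog^2 = log(1 + cv^2), meanlog = log(m) - sdlog^2/2
  oracle <- lnorm_pars(0.17, 0.5507)
  sp <- fit_by_moments("lognormal", list(mean = 0.17, cv = 55.07))
  expect_equal(sp$params$meanlog, oracle$meanlog, tolerance = 1e-12)
  expect_equal(sp$params$sdlog, oracle$sdlog, tolerance = 1e-12)

  # discrete-uniform fallback follows the triangular rule by default
  d <- fit_by_moments("discrete_uniform",
                      list(min = 567, mean = 1112.95, max = 1850))
  expect_equal(d$family, "triangular")
  expect_equal(dist_mean(d), 1112.95, tolerance = 1e-9)
  d2 <- fit_by_moments("discrete_uniform",
                       list(min = 567, mean = 1112.95, max = 1850, cv = 33.34),
                       discrete_fallback = "lognormal")
  expect_equal(d2$family, "lognormal")
})

test_that("infeasible moment fits fail with informative errors", {
  # beta variance too large for its support
  expect_error(
    fit_by_moments("beta_scaled", list(min = 0, max = 1, mean = 0.5, sd = 0.6)),
    "variance too large")
  expect_error(fit_by_moments("lognormal", list(mean = 2, cv = -1)), "cv")
  expect_error(fit_by_moments("weibull", list(mean = 2)), "sd or cv")
  expect_error(dist_spec("triangular", lower = 2, mode = 1, upper = 3),
               "lower <= mode")
})

test_that("Anderson-Darling statistic matches direct evaluation", {
  # independent oracle: literal evaluation of the A^2 sum
  ad_oracle <- function(x, cdf) {
    x <- sort(x); n <- length(x)
    u <- pmin(pmax(cdf(x), 1e-12), 1 - 1e-12)
    s <- 0
    for (i in seq_len(n))
      s <- s + (2 * i - 1) * (log(u[i]) + log(1 - u[n + 1 - i]))
    -n - s / n
  }
  x <- c(0.25, 0.5, 0.75)
  u1 <- dist_spec("uniform", lower = 0, upper = 1)
  u2 <- dist_spec("uniform", lower = 0, upper = 2)
  expect_equal(anderson_darling(x, u1), ad_oracle(x, function(q) q))
  expect_equal(anderson_darling(x, u2), ad_oracle(x, function(q) q / 2))
  expect_lt(abs(anderson_darling(x, u1) - 0.2694), 1e-4)
  expect_lt(abs(anderson_darling(x, u2) - 1.3810), 1e-4)

  # invariant under a common affine transform of samples and spec
  y <- c(1.1, 2.3, 2.9, 4.2, 5.0)
  n1 <- dist_spec("normal", mean = 3, sd = 1.5)
  n2 <- dist_spec("normal", mean = 2 * 3 + 7, sd = 2 * 1.5)
  expect_equal(anderson_darling(y, n1), anderson_darling(2 * y + 7, n2))

  # samples at the spec's (i - 0.5)/n quantiles beat any location shift
  q <- stats::qnorm((1:20 - 0.5) / 20, 10, 2)
  base <- anderson_darling(q, dist_spec("normal", mean = 10, sd = 2))
  for (shift in c(-1, -0.2, 0.3, 1.5)) {
    expect_lt(base, anderson_darling(
      q, dist_spec("normal", mean = 10 + shift, sd = 2)))
  }

  expect_error(anderson_darling(c(1, 2), u1), "3 samples")
  expect_error(anderson_darling(x, dist_spec("point", value = 1)), "continuous")
})

test_that("AD statistic for a normal moment fit agrees with nortest", {
  skip_if_not_installed("nortest")
  set.seed(99)
  x <- stats::rnorm(200, 5, 2)
  sp <- fit_by_moments("normal", list(mean = mean(x), sd = stats::sd(x)))
  expect_equal(unname(anderson_darling(x, sp)),
               unname(nortest::ad.test(x)$statistic), tolerance = 1e-8)
})

test_that("family selection ranks by AD with stable tie-breaks", {
  one <- select_family(c(1, 2, 3, 4), "normal")
  expect_equal(one$family, "normal")

  set.seed(42)
  x <- stats::runif(500)
  ranked <- select_family(x, c("uniform", "normal"))
  expect_equal(ranked$family[1], "uniform")
  expect_lt(ranked$ad[1], ranked$ad[2])

  # exactly tied statistics keep candidate-list order
  tie <- select_family(x, c("normal", "normal"))
  expect_equal(tie$ad[1], tie$ad[2])
  expect_equal(tie$family, c("normal", "normal"))
})

test_that("sampling honours support, determinism and the moment fit", {
  expect_equal(dist_sample(dist_spec("point", value = 3.7), 5, seed = 1),
               rep(3.7, 5))

  sp <- fit_by_moments("lognormal", list(mean = 0.17, cv = 55.07))
  a <- dist_sample(sp, 1000, seed = 7)
  b <- dist_sample(sp, 1000, seed = 7)
  expect_identical(a, b)

  # seeded sampling must not disturb the caller's RNG stream
  set.seed(123); r1 <- stats::runif(1)
  set.seed(123); invisible(dist_sample(sp, 10, seed = 5)); r2 <- stats::runif(1)
  expect_identical(r1, r2)

  big <- dist_sample(sp, 1e5, seed = 11)
  se <- 0.17 * 0.5507 / sqrt(1e5)
  expect_lt(abs(mean(big) - 0.17), 3 * se)

  for (fam in list(
    fit_by_moments("beta_scaled", list(min = 0.17, max = 0.77, mean = 0.46,
                                       sd = 0.158)),
    fit_by_moments("triangular", list(min = 57, mean = 73.71, max = 85.1)),
    fit_by_moments("uniform", list(min = 21.9, max = 38.3)))) {
    d <- dist_sample(fam, 2000, seed = 3)
    expect_true(all(d >= fam$support[1] & d <= fam$support[2]))
  }

  d <- dist_sample(dist_spec("discrete_uniform", values = c(2, 4, 8)), 100,
                   seed = 2)
  expect_true(all(d %in% c(2, 4, 8)))
})

test_that("sample -> summarize -> fit recovers lognormal parameters", {
  true <- lnorm_pars(0.17, 0.5507)
  x <- dist_sample(dist_spec("lognormal", meanlog = true$meanlog,
                             sdlog = true$sdlog), 1e5, seed = 21)
  refit <- fit_by_moments("lognormal",
                          list(mean = mean(x), sd = stats::sd(x)))
  expect_equal(refit$params$meanlog, true$meanlog, tolerance = 0.05)
  expect_equal(refit$params$sdlog, true$sdlog, tolerance = 0.05)
})

test_that("specs serialize to plain lists and YAML and back", {
  sp <- fit_by_moments("weibull", list(mean = 35.76, cv = 20.74))
  lst <- dist_to_list(sp)
  expect_named(lst, c("family", "params", "support"))
  expect_equal(dist_from_list(lst), sp)

  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(lst, path)
  expect_equal(dist_from_list(yaml::read_yaml(path))$params$shape,
               sp$params$shape, tolerance = 1e-6)
})

test_that("substream seeds are stable and name-sensitive", {
  expect_identical(derive_seed(42, "Hg"), derive_seed(42, "Hg"))
  expect_false(derive_seed(42, "Hg") == derive_seed(42, "Mn"))
  expect_true(derive_seed(.Machine$integer.max, "a_very_long_input_name") >= 0)
})
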