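test_that("point-mass propagation equals direct evaluation", {
  inputs <- list(a = dist_spec("point", value = 3),
                 b = dist_spec("point", value = 4))
  res <- run_mc(function(x) sqrt(x$a^2 + x$b^2), inputs, mc_config(1000, 1))
  expect_true(all(res$draws == 5))
  expect_equal(res$mean, 5)
  expect_equal(res$ci_low, 5)
  expect_equal(res$ci_high, 5)
})

test_that("identical configuration reproduces identical results", {
  inputs <- list(x = dist_spec("lognormal", meanlog = 0, sdlog = 1),
                 y = dist_spec("uniform", lower = 0, upper = 1))
  r1 <- run_mc(function(d) d$x + d$y, inputs, mc_config(5000, seed = 9))
  r2 <- run_mc(function(d) d$x + d$y, inputs, mc_config(5000, seed = 9))
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$mean, r2$mean)
  # different seed, different draws
  r3 <- run_mc(function(d) d$x + d$y, inputs, mc_config(5000, seed = 10))
  expect_false(identical(r1$draws, r3$draws))
})

test_that("adding an input never perturbs another input's substream", {
  cfg <- mc_config(2000, seed = 4)
  lone <- run_mc(function(d) d$x, list(x = dist_spec("normal", mean = 0,
                                                     sd = 1)), cfg)
  joint <- run_mc(function(d) d$x,
                  list(x = dist_spec("normal", mean = 0, sd = 1),
                       z = dist_spec("uniform", lower = 0, upper = 1)), cfg)
  expect_identical(lone$draws, joint$draws)
})

test_that("percentile confidence interval matches order statistics", {
  res <- run_mc(function(d) d$u,
                list(u = dist_spec("uniform", lower = 0, upper = 1)),
                mc_config(1e5, seed = 2))
  expect_lt(abs(res$ci_low - 0.025), 0.005)
  expect_lt(abs(res$ci_high - 0.975), 0.005)
  expect_true(res$ci_low <= res$median && res$median <= res$ci_high)
})

test_that("model failures abort with the offending input tuple", {
  inputs <- list(u = dist_spec("uniform", lower = -1, upper = 1))
  suppressWarnings(
    expect_error(run_mc(function(d) log(d$u), inputs, mc_config(1000, 1)),
                 "draw .* u="))
  expect_error(run_mc(function(d) 1, inputs, mc_config(1000, 1)),
               "per draw")
})

test_that("class probabilities agree with the analytic lognormal oracle", {
  # point mass below the first breakpoint: all mass in class 0
  pt <- run_mc(function(d) d$x, list(x = dist_spec("point", value = -2)),
               mc_config(1000, 1))
  cp <- class_probabilities(pt, igeo_scheme())
  expect_equal(unname(cp[1]), 1)
  expect_equal(sum(cp), 1)

  # Igeo of the moment-matched Hg model: P(1 < Igeo <= 2) has a closed form
  # via the normal CDF of log-concentration
  pars <- lnorm_pars(0.17, 0.5507)
  spec <- dist_spec("lognormal", meanlog = pars$meanlog, sdlog = pars$sdlog)
  res <- run_mc(function(d) igeo(d$conc, 0.047), list(conc = spec),
                mc_config(5e4, seed = 6))
  cp <- class_probabilities(res, igeo_scheme())
  oracle <- stats::pnorm((log(0.047 * 1.5 * 4) - pars$meanlog) / pars$sdlog) -
    stats::pnorm((log(0.047 * 1.5 * 2) - pars$meanlog) / pars$sdlog)
  expect_equal(unname(cp[["Moderately contaminated"]]), oracle,
               tolerance = 0.02)
  expect_equal(sum(cp), 1, tolerance = 1e-12)

  # symmetric distribution split at its median: 0.5 / 0.5
  sym <- run_mc(function(d) d$x, list(x = dist_spec("normal", mean = 2,
                                                    sd = 1)),
                mc_config(5e4, seed = 8))
  two <- classification_scheme(2, c("low", "high"))
  cps <- class_probabilities(sym, two)
  expect_equal(unname(cps[["low"]]), 0.5, tolerance = 0.01)
})

test_that("exceedance probability is strict and consistent with classes", {
  draws <- c(1, 2, 3)
  expect_equal(exceedance_probability(draws, 0), 1)
  expect_equal(exceedance_probability(draws, 5), 0)
  expect_equal(exceedance_probability(draws, 3), 0)  # strict >

  u <- dist_sample(dist_spec("uniform", lower = 0, upper = 1), 1e4, seed = 3)
  expect_lt(abs(exceedance_probability(u, 0.9) - 0.10), 0.01)

  # exceedance at a breakpoint equals the summed mass of higher classes
  sch <- igeo_scheme()
  cp <- class_probabilities(u * 5, sch)
  for (k in seq_along(sch$breakpoints)) {
    expect_equal(exceedance_probability(u * 5, sch$breakpoints[k]),
                 sum(cp[(k + 1):length(cp)]))
  }
})

test_that("Monte Carlo Er mean matches the analytic lognormal oracle", {
  # division-form Er = tr * cn / C; for lognormal C the expectation is
  # tr * cn * (1 + cv^2) / mean
  prof <- default_liuye_profile()$metals
  ref <- default_reference()
  for (m in c("Pb", "Hg", "Cd")) {
    row <- prof[prof$metal == m, ]
    cv <- row$cv / 100
    pars <- lnorm_pars(row$mean, cv)
    spec <- dist_spec("lognormal", meanlog = pars$meanlog, sdlog = pars$sdlog)
    res <- run_mc(function(d)
      single_metal_risk(contamination_factor(d$conc, ref$background[[m]]),
                        ref$toxic_response[[m]]),
      list(conc = spec), mc_config(5e4, seed = 12))
    oracle <- ref$toxic_response[[m]] * ref$background[[m]] *
      (1 + cv^2) / row$mean
    se <- stats::sd(res$draws) / sqrt(res$n)
    expect_lt(abs(res$mean - oracle), 3 * se)
  }
})

test_that("doubling the iteration count leaves the mean statistically stable", {
  spec <- dist_spec("lognormal", meanlog = 0, sdlog = 0.5)
  r1 <- run_mc(function(d) d$x, list(x = spec), mc_config(1e4, seed = 14))
  r2 <- run_mc(function(d) d$x, list(x = spec), mc_config(2e4, seed = 14))
  pooled_se <- sqrt(stats::sd(r1$draws)^2 / r1$n + stats::sd(r2$draws)^2 / r2$n)
  expect_lt(abs(r1$mean - r2$mean), 3 * pooled_se)
})

test_that("sensitivity contributions are signed, normalized and detect independence", {
  n <- 1e4
  x1 <- dist_sample(dist_spec("normal", mean = 0, sd = 1), n, seed = 1)
  x2 <- dist_sample(dist_spec("normal", mean = 0, sd = 1), n, seed = 2)
  x3 <- dist_sample(dist_spec("normal", mean = 0, sd = 1), n, seed = 3)

  # single varying input: +/-100%
  s <- sensitivity_contribution(list(a = x1), x1)
  expect_equal(unname(s), 100)
  s <- sensitivity_contribution(list(a = x1), -x1)
  expect_equal(unname(s), -100)

  # identically distributed independent additive inputs: 50/50
  out <- x1 + x2
  s <- sensitivity_contribution(list(a = x1, b = x2), out)
  expect_equal(unname(s[["a"]]), 50, tolerance = 3)
  expect_equal(unname(s[["b"]]), 50, tolerance = 3)
  expect_equal(sum(abs(s)), 100)

  # an independent input contributes ~0
  s3 <- sensitivity_contribution(list(a = x1, b = x2, c = x3), out)
  expect_lt(abs(s3[["c"]]), 3)
  expect_equal(sum(abs(s3)), 100)

  # zero-variance input: contribution 0 with a warning
  expect_warning(
    s0 <- sensitivity_contribution(list(a = x1, p = rep(2, n)), x1),
    "zero variance")
  expect_equal(unname(s0[["p"]]), 0)
  expect_equal(unname(s0[["a"]]), 100)

  expect_error(sensitivity_contribution(list(a = x1), x1[-1]), "equal length")
})

test_that("mc_sensitivity reads the stored input draws of a result", {
  res <- run_mc(function(d) d$x + 0.1 * d$y,
                list(x = dist_spec("normal", mean = 0, sd = 1),
                     y = dist_spec("normal", mean = 0, sd = 1)),
                mc_config(5000, seed = 20))
  s <- mc_sensitivity(res)
  expect_gt(s[["x"]], s[["y"]])
  expect_equal(sum(abs(s)), 100)
})

test_that("configuration guards reject invalid settings", {
  expect_error(mc_config(100), ">= 1000")
  expect_error(mc_config(1e4, 1, ci_level = 1), "ci_level")
})
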