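#' Parametric distribution specification
#'
#' A `dist_spec` is a lightweight container for a parametric distribution:
#' a family tag, its parameters, and the closed support interval the
#' parameters imply. It is the shared currency between the concentration
#' models fitted to survey summary statistics and the exposure-parameter
#' distributions of the health-risk model, and is what the Monte Carlo
#' engine samples from.
#'
#' Supported families and their parameters:
#' * `point`: `value` (a degenerate distribution).
#' * `normal`: `mean`, `sd`.
#' * `lognormal`: `meanlog`, `sdlog` (parameters of log(X)).
#' * `beta_scaled`: `shape1`, `shape2`, `lower`, `upper` — a Beta variable
#'   rescaled onto `[lower, upper]`.
#' * `weibull`: `shape`, `scale`.
#' * `triangular`: `lower`, `mode`, `upper`.
#' * `uniform`: `lower`, `upper`.
#' * `discrete_uniform`: `values` (equally likely finite set).
#'
#' @param family Family tag, one of the set above.
#' @param ... Named numeric parameters for the family.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = -1.9, sdlog = 0.51)
#' dist_spec("triangular", lower = 180, mode = 345, upper = 365)
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, dist_families())
  params <- list(...)
  req <- .family_params[[family]]
  missing <- setdiff(req, names(params))
  if (length(missing) > 0) {
    stop(sprintf("family '%s' requires parameter(s): %s", family,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- params[req]
  .validate_params(family, params)
  structure(list(family = family, params = params,
                 support = .family_support(family, params)),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_families <- function() {
  c("point", "normal", "lognormal", "beta_scaled", "weibull",
    "triangular", "uniform", "discrete_uniform")
}

.family_params <- list(
  point = "value",
  normal = c("mean", "sd"),
  lognormal = c("meanlog", "sdlog"),
  beta_scaled = c("shape1", "shape2", "lower", "upper"),
  weibull = c("shape", "scale"),
  triangular = c("lower", "mode", "upper"),
  uniform = c("lower", "upper"),
  discrete_uniform = "values"
)

.validate_params <- function(family, p) {
  bad <- function(msg) stop(sprintf("invalid %s spec: %s", family, msg), call. = FALSE)
  switch(family,
    point = if (!is.finite(p$value)) bad("value must be finite"),
    normal = if (p$sd <= 0) bad("sd must be > 0"),
    lognormal = if (p$sdlog <= 0) bad("sdlog must be > 0"),
    beta_scaled = {
      if (p$shape1 <= 0 || p$shape2 <= 0) bad("shapes must be > 0")
      if (p$lower >= p$upper) bad("lower must be < upper")
    },
    weibull = if (p$shape <= 0 || p$scale <= 0) bad("shape and scale must be > 0"),
    triangular = {
      if (p$lower > p$mode || p$mode > p$upper) bad("need lower <= mode <= upper")
      if (p$lower >= p$upper) bad("lower must be < upper")
    },
    uniform = if (p$lower >= p$upper) bad("lower must be < upper"),
    discrete_uniform = if (length(p$values) < 1 || anyNA(p$values))
      bad("values must be a non-empty numeric vector")
  )
  invisible(TRUE)
}

.family_support <- function(family, p) {
  switch(family,
    point = c(p$value, p$value),
    normal = c(-Inf, Inf),
    lognormal = c(0, Inf),
    beta_scaled = c(p$lower, p$upper),
    weibull = c(0, Inf),
    triangular = c(p$lower, p$upper),
    uniform = c(p$lower, p$upper),
    discrete_uniform = range(p$values)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- vapply(x$params, function(v) paste(format(v, digits = 6), collapse = ","),
               character(1))
  cat(sprintf("<dist_spec %s(%s)>\n", x$family,
              paste(names(ps), ps, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Analytic mean of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return The analytic expectation of the distribution.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = p$value,
    normal = p$mean,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    beta_scaled = p$lower + (p$upper - p$lower) * p$shape1 / (p$shape1 + p$shape2),
    weibull = p$scale * gamma(1 + 1 / p$shape),
    triangular = (p$lower + p$mode + p$upper) / 3,
    uniform = (p$lower + p$upper) / 2,
    discrete_uniform = mean(p$values)
  )
}

#' Cumulative distribution function of a specification
#'
#' @param spec A [dist_spec()].
#' @param q Numeric vector of quantiles.
#' @return `P(X <= q)` for each element of `q`.
#' @export
dist_cdf <- function(spec, q) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = as.numeric(q >= p$value),
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    beta_scaled = stats::pbeta((q - p$lower) / (p$upper - p$lower),
                               p$shape1, p$shape2),
    weibull = stats::pweibull(q, p$shape, p$scale),
    triangular = .ptri(q, p$lower, p$mode, p$upper),
    uniform = stats::punif(q, p$lower, p$upper),
    discrete_uniform = vapply(q, function(x) mean(p$values <= x), numeric(1))
  )
}

# triangular CDF / inverse CDF (not provided by the installed stack)
.ptri <- function(q, a, c, b) {
  out <- numeric(length(q))
  lo <- q <= a; hi <- q >= b
  left <- !lo & !hi & q <= c
  right <- !lo & !hi & q > c
  out[lo] <- 0; out[hi] <- 1
  out[left] <- (q[left] - a)^2 / ((b - a) * (c - a))
  out[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - c))
  out
}

.qtri <- function(u, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Derive a reproducible substream seed from a root seed and a name
#'
#' Each named random input gets its own substream whose seed depends only on
#' the root seed and a stable hash of the input's name, so adding or removing
#' one input never perturbs the draws of the others.
#'
#' @param seed Integer root seed.
#' @param name Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% m)
}

# run `expr` under a given seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw random samples from a distribution specification
#'
#' Draws are reproducible: identical `(spec, n, seed)` gives identical output.
#' When `seed` is `NULL` the current RNG stream is used (and advanced).
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of `n` draws inside the spec's support.
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  draw <- function() {
    p <- spec$params
    switch(spec$family,
      point = rep(p$value, n),
      normal = stats::rnorm(n, p$mean, p$sd),
      lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
      beta_scaled = p$lower + (p$upper - p$lower) *
        stats::rbeta(n, p$shape1, p$shape2),
      weibull = stats::rweibull(n, p$shape, p$scale),
      triangular = .qtri(stats::runif(n), p$lower, p$mode, p$upper),
      uniform = stats::runif(n, p$lower, p$upper),
      discrete_uniform = sample(p$values, n, replace = TRUE)
    )
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Fit a distribution to summary statistics by moment matching
#'
#' Builds a [dist_spec()] of the requested family whose analytic moments match
#' the supplied summary statistics. This is the bridge from a published table
#' of per-metal min/max/mean/CV values to a samplable concentration model.
#' Closed-form rules:
#' * `lognormal`: `sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2/2`
#'   (so the arithmetic mean and CV are matched exactly);
#' * `normal`: `mean`, `sd` as given;
#' * `uniform`: support `[min, max]`;
#' * `triangular`: mode `c = 3*mean - min - max`, clamped into `[min, max]`;
#' * `beta_scaled`: shapes from the mean/variance of the variable rescaled
#'   onto `[min, max]`;
#' * `weibull`: shape solved numerically from the CV, scale from the mean;
#' * `discrete_uniform`: no finite-set information survives in summary
#'   statistics, so it falls back to the triangular rule (or, with
#'   `discrete_fallback = "lognormal"`, to the lognormal rule).
#'
#' @param family Family tag (see [dist_spec()]).
#' @param stats A list or one-row data frame with `mean` plus `sd` or `cv`
#'   (CV in percent), and `min`/`max` for the bounded families.
#' @param discrete_fallback Stand-in rule for `discrete_uniform`.
#' @return A [dist_spec()].
#' @examples
#' fit_by_moments("lognormal", list(mean = 0.17, cv = 55.07))
#' fit_by_moments("triangular", list(min = 57, mean = 73.71, max = 85.1))
#' @export
fit_by_moments <- function(family, stats,
                           discrete_fallback = c("triangular", "lognormal")) {
  family <- match.arg(family, dist_families())
  discrete_fallback <- match.arg(discrete_fallback)
  s <- as.list(stats)
  m <- s$mean
  if ((is.null(m) || !is.finite(m)) && family != "uniform")
    stop("stats$mean is required", call. = FALSE)
  sd <- s$sd
  if (is.null(sd)) {
    if (is.null(s$cv)) {
      if (family %in% c("normal", "lognormal", "beta_scaled", "weibull"))
        stop("stats must provide sd or cv", call. = FALSE)
      sd <- NA_real_
    } else {
      if (s$cv <= 0) stop("cv must be > 0", call. = FALSE)
      sd <- m * s$cv / 100
    }
  }
  cv <- if (is.null(m)) NA_real_ else sd / m
  need_range <- function() {
    if (is.null(s$min) || is.null(s$max))
      stop(sprintf("family '%s' needs stats$min and stats$max", family),
           call. = FALSE)
  }
  switch(family,
    point = dist_spec("point", value = m),
    normal = dist_spec("normal", mean = m, sd = sd),
    lognormal = {
      if (!is.finite(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
      s2 <- log(1 + cv^2)
      dist_spec("lognormal", meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    uniform = {
      need_range()
      dist_spec("uniform", lower = s$min, upper = s$max)
    },
    triangular = {
      need_range()
      mode <- min(max(3 * m - s$min - s$max, s$min), s$max)
      dist_spec("triangular", lower = s$min, mode = mode, upper = s$max)
    },
    beta_scaled = {
      need_range()
      w <- s$max - s$min
      my <- (m - s$min) / w
      vy <- (sd / w)^2
      if (my <= 0 || my >= 1)
        stop("beta fit infeasible: mean outside (min, max)", call. = FALSE)
      if (vy >= my * (1 - my))
        stop(paste("beta fit infeasible: variance too large for the support;",
                   "consider a triangular or lognormal fit"), call. = FALSE)
      k <- my * (1 - my) / vy - 1
      dist_spec("beta_scaled", shape1 = my * k, shape2 = (1 - my) * k,
                lower = s$min, upper = s$max)
    },
    weibull = {
      if (!is.finite(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
      f <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv^2
      k <- stats::uniroot(f, c(0.08, 400), tol = 1e-12)$root
      dist_spec("weibull", shape = k, scale = m / gamma(1 + 1 / k))
    },
    discrete_uniform = fit_by_moments(discrete_fallback, s)
  )
}

#' Anderson-Darling goodness-of-fit statistic
#'
#' Computes the Anderson-Darling statistic of a sample against a fully
#' specified continuous distribution:
#' `A^2 = -n - (1/n) * sum_{i=1..n} (2i-1) * [log F(x_(i)) + log(1 - F(x_(n+1-i)))]`.
#' Probability-integral values are clipped away from 0 and 1 by `1e-12` to
#' keep the logarithms finite. The statistic is used comparatively for family
#' selection; no p-values are attached.
#'
#' @param samples Numeric vector, `n >= 3` (sorted internally).
#' @param spec A [dist_spec()] with a continuous CDF (not `point` or
#'   `discrete_uniform`).
#' @return The non-negative statistic `A^2`.
#' @examples
#' anderson_darling(c(0.25, 0.5, 0.75), dist_spec("uniform", lower = 0, upper = 1))
#' @export
anderson_darling <- function(samples, spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family %in% c("point", "discrete_uniform"))
    stop("anderson_darling requires a continuous distribution", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  eps <- 1e-12
  u <- pmin(pmax(dist_cdf(spec, x), eps), 1 - eps)
  if (any(u <= 0) || any(u >= 1)) {
    bad <- x[which(u <= 0 | u >= 1)[1]]
    stop(sprintf("degenerate probability integral at sample %g", bad),
         call. = FALSE)
  }
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Select the best-fitting distribution family for a sample
#'
#' Each candidate family is moment-fitted to the sample's own summary
#' statistics (via [fit_by_moments()]) and scored with [anderson_darling()];
#' candidates are returned in ascending order of the statistic, ties broken
#' by their position in `candidates`. The head of the table is the selected
#' family.
#'
#' @param samples Numeric vector of observations.
#' @param candidates Character vector of family tags to try.
#' @param discrete_fallback Passed to [fit_by_moments()].
#' @return A [tibble::tibble()] with columns `family`, `spec` (list column)
#'   and `ad`, sorted ascending by `ad`.
#' @export
select_family <- function(samples, candidates,
                          discrete_fallback = c("triangular", "lognormal")) {
  if (length(candidates) == 0) stop("candidates must be non-empty", call. = FALSE)
  discrete_fallback <- match.arg(discrete_fallback)
  s <- list(min = min(samples), max = max(samples),
            mean = mean(samples), sd = stats::sd(samples))
  fits <- vector("list", length(candidates))
  ad <- rep(NA_real_, length(candidates))
  errs <- character(0)
  for (k in seq_along(candidates)) {
    res <- tryCatch({
      sp <- fit_by_moments(candidates[k], s, discrete_fallback)
      list(spec = sp, ad = anderson_darling(samples, sp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("%s: %s", candidates[k], conditionMessage(res)))
    } else {
      fits[[k]] <- res$spec
      ad[k] <- res$ad
    }
  }
  ok <- !is.na(ad)
  if (!any(ok))
    stop(paste(c("no candidate family could be fitted:", errs),
               collapse = "\n  "), call. = FALSE)
  ord <- order(ad[ok], seq_len(sum(ok)))
  tibble::tibble(family = candidates[ok][ord],
                 spec = fits[ok][ord],
                 ad = ad[ok][ord])
}

#' Serialize / deserialize a distribution specification
#'
#' `dist_to_list()` turns a spec into a plain list `{family, params, support}`
#' suitable for YAML/JSON; `dist_from_list()` inverts it.
#'
#' @param spec A [dist_spec()].
#' @param x A list as produced by `dist_to_list()`.
#' @return A list, or a [dist_spec()].
#' @export
dist_to_list <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  list(family = spec$family, params = spec$params, support = spec$support)
}

#' @rdname dist_to_list
#' @export
dist_from_list <- function(x) {
  do.call(dist_spec, c(list(family = x$family), x$params))
}
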