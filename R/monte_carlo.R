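#' Monte Carlo configuration
#'
#' @param n_iterations Number of random-sampling iterations (default 10,000,
#'   the standard count for stable 95% interval estimates in this genre of
#'   probabilistic risk assessment). At least 1,000 are required for reported
#'   confidence intervals.
#' @param seed Integer root seed; every input's substream derives from it
#'   via [derive_seed()].
#' @param ci_level Confidence level for percentile intervals, in (0, 1).
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_iterations = 10000, seed = 1, ci_level = 0.95) {
  if (n_iterations < 1000)
    stop("n_iterations must be >= 1000 for reported confidence intervals",
         call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), ci_level = ci_level),
            class = "mc_config")
}

#' Run a Monte Carlo propagation
#'
#' Draws `n_iterations` values from every input distribution (each on its own
#' named substream of the root seed, so the draws of one input are unaffected
#' by adding or removing another), evaluates the model on the joint draws,
#' and summarizes the output with its mean, median and percentile confidence
#' interval. Inputs are sampled independently.
#'
#' @param model A function taking a named list of equal-length numeric
#'   vectors (one per input) and returning one numeric output per draw.
#' @param inputs Named list of [dist_spec()] objects.
#' @param config An [mc_config()].
#' @return An object of class `mc_result`: `draws`, `mean`, `median`,
#'   `ci_low`, `ci_high`, `n`, `ci_level`, `seed` and the per-input draw
#'   matrix `input_draws` (for sensitivity analysis).
#' @export
run_mc <- function(model, inputs, config = mc_config()) {
  stopifnot(is.function(model), length(inputs) > 0, !is.null(names(inputs)))
  n <- config$n_iterations
  draws_in <- lapply(names(inputs), function(nm) {
    dist_sample(inputs[[nm]], n, seed = derive_seed(config$seed, nm))
  })
  names(draws_in) <- names(inputs)
  out <- model(draws_in)
  if (!is.numeric(out) || length(out) != n)
    stop("model must return one numeric value per draw", call. = FALSE)
  if (any(!is.finite(out))) {
    i <- which(!is.finite(out))[1]
    tuple <- vapply(draws_in, function(v) v[i], numeric(1))
    stop(sprintf("model failed at draw %d with inputs: %s", i,
                 paste(names(tuple), signif(tuple, 6), sep = "=",
                       collapse = ", ")), call. = FALSE)
  }
  alpha <- (1 - config$ci_level) / 2
  qs <- stats::quantile(out, c(alpha, 1 - alpha), names = FALSE)
  structure(list(draws = out, mean = mean(out), median = stats::median(out),
                 ci_low = qs[1], ci_high = qs[2], n = n,
                 ci_level = config$ci_level, seed = config$seed,
                 input_draws = draws_in),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result n=%d mean=%.4g median=%.4g %g%% CI [%.4g, %.4g]>\n",
              x$n, x$mean, x$median, 100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

.mc_draws <- function(x) {
  if (inherits(x, "mc_result")) x$draws
  else if (is.numeric(x)) x
  else stop("expected an mc_result or a numeric vector", call. = FALSE)
}

#' Empirical class probabilities of Monte Carlo draws
#'
#' Fraction of draws falling in each class of a [classification_scheme()]
#' (upper-closed intervals). Fractions sum to 1 and classes with no draws
#' are reported as 0.
#'
#' @param result An `mc_result` or numeric vector of draws.
#' @param scheme A [classification_scheme()].
#' @return Named numeric vector of fractions, one per class label.
#' @export
class_probabilities <- function(result, scheme) {
  stopifnot(inherits(scheme, "classification_scheme"))
  draws <- .mc_draws(result)
  if (length(draws) == 0) stop("draws must be non-empty", call. = FALSE)
  idx <- findInterval(draws, scheme$breakpoints, left.open = TRUE) + 1L
  counts <- tabulate(idx, nbins = length(scheme$labels))
  stats::setNames(counts / length(draws), scheme$labels)
}

#' Exceedance probability of Monte Carlo draws
#'
#' Fraction of draws strictly greater than a threshold (mirroring the
#' strict "HI > 1" convention of the risk model).
#'
#' @param result An `mc_result` or numeric vector of draws.
#' @param threshold Numeric scalar.
#' @return Fraction in [0, 1].
#' @export
exceedance_probability <- function(result, threshold) {
  draws <- .mc_draws(result)
  if (length(draws) == 0) stop("draws must be non-empty", call. = FALSE)
  mean(draws > threshold)
}

#' Contribution-to-variance sensitivity analysis
#'
#' Signed, normalized squared Spearman rank correlation between each input's
#' draws and the output draws — the standard "contribution to variance"
#' display of commercial risk-simulation tools. For input v with rank
#' correlation `rho_v`, the contribution is
#' `sign(rho_v) * rho_v^2 / sum_w rho_w^2 * 100` percent, so absolute
#' contributions sum to 100. Zero-variance (point) inputs contribute 0, with
#' a warning.
#'
#' @param input_draws Named list of equal-length numeric vectors (e.g. the
#'   `input_draws` of an `mc_result`).
#' @param output_draws Numeric vector of model outputs, same length.
#' @return Named numeric vector of signed contributions in percent.
#' @export
sensitivity_contribution <- function(input_draws, output_draws) {
  stopifnot(is.list(input_draws), length(input_draws) >= 1,
            !is.null(names(input_draws)))
  lens <- vapply(input_draws, length, integer(1))
  if (any(lens != length(output_draws)))
    stop("input and output draws must have equal length", call. = FALSE)
  rho <- vapply(names(input_draws), function(nm) {
    v <- input_draws[[nm]]
    if (stats::sd(v) == 0) {
      warning(sprintf("input '%s' has zero variance; contribution set to 0", nm),
              call. = FALSE)
      return(0)
    }
    stats::cor(v, output_draws, method = "spearman")
  }, numeric(1))
  total <- sum(rho^2)
  if (total == 0) return(stats::setNames(rep(0, length(rho)), names(rho)))
  100 * sign(rho) * rho^2 / total
}

#' @rdname sensitivity_contribution
#' @param result An `mc_result` produced by [run_mc()].
#' @return `mc_sensitivity()` applies the analysis to a result's own stored
#'   input draws.
#' @export
mc_sensitivity <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  sensitivity_contribution(result$input_draws, result$draws)
}
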