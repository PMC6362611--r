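#' Prior distributions for model parameters
#'
#' A prior encodes pre-existing knowledge about a parameter's value and is
#' evaluated on the log scale when forming the posterior. Two built-ins are
#' provided: an interval (box) prior whose log-density is 0 inside the bounds
#' and -Inf outside (unnormalised, so evidence values computed from it are
#' relative), and a normal prior for values known with an experimental
#' uncertainty (e.g. a thickness of 100 +/- 4 Angstrom). Arbitrary
#' distributions can be supplied through `prior_distribution()`.
#'
#' @param lower,upper Interval bounds (`lower <= upper`).
#' @param mean,sd Location and scale of the normal prior (`sd > 0`).
#' @param logpdf Function of one numeric vector returning the log-density.
#' @param sampler Function of `n` returning `n` draws from the distribution.
#' @param lower_support,upper_support Support limits used for bounded
#'   optimisation starting boxes; default the 1e-7 and 1 - 1e-7 quantiles if a
#'   `quantile_fn` is given, else `-Inf`/`Inf`.
#' @param quantile_fn Optional quantile function (used for support limits).
#'
#' @return An object of class `slabs_prior` with elements `kind`, `logpdf`,
#'   `sample`, `lower`, `upper`.
#' @examples
#' pr <- prior_interval(0, 1)
#' pr$logpdf(c(0.5, 2)) # 0, -Inf
#' @name priors
NULL

new_prior <- function(kind, logpdf, sample, lower, upper) {
  structure(list(kind = kind, logpdf = logpdf, sample = sample,
                 lower = lower, upper = upper),
            class = "slabs_prior")
}

#' @rdname priors
#' @export
prior_interval <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (!(lower <= upper)) stop("interval prior requires lower <= upper")
  new_prior(
    "interval",
    logpdf = function(x) ifelse(x >= lower & x <= upper, 0, -Inf),
    sample = function(n) stats::runif(n, lower, upper),
    lower = lower, upper = upper
  )
}

#' @rdname priors
#' @export
prior_uniform <- function(lower, upper) {
  stopifnot(lower < upper)
  new_prior(
    "uniform",
    logpdf = function(x) stats::dunif(x, lower, upper, log = TRUE),
    sample = function(n) stats::runif(n, lower, upper),
    lower = lower, upper = upper
  )
}

#' @rdname priors
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  new_prior(
    "normal",
    logpdf = function(x) stats::dnorm(x, mean, sd, log = TRUE),
    sample = function(n) stats::rnorm(n, mean, sd),
    lower = mean - 38 * sd, upper = mean + 38 * sd
  )
}

#' @rdname priors
#' @export
prior_distribution <- function(logpdf, sampler,
                               lower_support = -Inf, upper_support = Inf,
                               quantile_fn = NULL) {
  stopifnot(is.function(logpdf), is.function(sampler))
  if (!is.null(quantile_fn)) {
    lower_support <- quantile_fn(1e-7)
    upper_support <- quantile_fn(1 - 1e-7)
  }
  new_prior("distribution", logpdf = logpdf, sample = sampler,
            lower = lower_support, upper = upper_support)
}

#' @export
print.slabs_prior <- function(x, ...) {
  cat(sprintf("<prior: %s [%g, %g]>\n", x$kind, x$lower, x$upper))
  invisible(x)
}

prior_logpdf <- function(prior, x) {
  if (is.null(prior)) return(rep(0, length(x)))
  prior$logpdf(x)
}
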