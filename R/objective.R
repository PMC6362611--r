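#' Model-data comparator
#'
#' An objective pairs a reflectivity model with a measured dataset (and an
#' optional fitting-space transform) and exposes the statistics a fit needs:
#' residuals, chi-squared, the Gaussian log-likelihood, the log-prior and
#' the log-posterior. All of chi-squared, residuals and the likelihood are
#' computed consistently in the transformed space.
#'
#' @param model A [reflect_model()] or [mixed_reflect_model()].
#' @param data A [refl_data] dataset.
#' @param transform A [transform_spec()] or its kind (`"none"`, `"logY"`,
#'   `"YX4"`).
#' @param name Label for reports.
#' @return An object of class `slabs_objective`.
#' @export
objective <- function(model, data, transform = "none",
                      name = attr(data, "name") %||% "") {
  stopifnot(inherits(model, "slabs_model"))
  if (!inherits(data, "slabs_data"))
    data <- refl_data(data$q, data$r, data$dr, data$dq)
  structure(list(model = model, data = data,
                 transform = as_transform(transform), name = name),
            class = "slabs_objective", pset_cache = new.env())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine objectives for co-refinement
#'
#' A global objective sums the log-likelihoods of its members; parameters
#' shared between members (by object identity) appear once in the flattened
#' parameter vector and once in the prior, which is what links them across
#' datasets.
#'
#' @param objectives List of `slabs_objective` objects.
#' @return An object of class `slabs_global_objective`.
#' @export
global_objective <- function(objectives) {
  ok <- vapply(objectives, inherits, logical(1), "slabs_objective")
  if (!all(ok)) stop("all members must be slabs_objective objects")
  if (length(objectives) < 1) stop("need at least one objective")
  structure(list(objectives = objectives),
            class = "slabs_global_objective", pset_cache = new.env())
}

#' @export
collect_parameters.slabs_objective <- function(x) collect_parameters(x$model)

#' @export
collect_parameters.slabs_global_objective <- function(x)
  lapply(x$objectives, collect_parameters)

#' Model curve evaluated at the dataset's Q points
#'
#' @param obj An objective.
#' @return Numeric vector (untransformed reflectivity); for a global
#'   objective, a list of vectors, one per member.
#' @export
generative <- function(obj) UseMethod("generative")

#' @export
generative.slabs_objective <- function(obj) {
  dq <- if (has_dq(obj$data)) obj$data$dq
  model_curve(obj$model, obj$data$q, dq = dq)
}

#' @export
generative.slabs_global_objective <- function(obj)
  lapply(obj$objectives, generative)

transformed_triplet <- function(obj) {
  d <- obj$data
  td <- apply_transform(obj$transform, d$q, d$r, d$dr)
  ym <- generative(obj)
  tm <- apply_transform(obj$transform, d$q, ym)
  list(y = td$y, dy = td$dy, ymod = tm$y)
}

#' @export
residuals.slabs_objective <- function(object, ...) {
  tr <- transformed_triplet(object)
  (tr$y - tr$ymod) / tr$dy
}

#' @export
residuals.slabs_global_objective <- function(object, ...)
  unlist(lapply(object$objectives, stats::residuals), use.names = FALSE)

#' Chi-squared of an objective
#'
#' Sum of squared uncertainty-weighted residuals in the transformed space.
#' @param obj An objective or global objective.
#' @return Numeric scalar.
#' @export
chi_squared <- function(obj) sum(stats::residuals(obj)^2)

#' Gaussian log-likelihood
#'
#' Assumes normally distributed measurement uncertainties:
#' `-0.5 * sum((y_n - y_model_n)^2 / s_n^2 + log(2*pi*s_n^2))`, evaluated in
#' the transformed fitting space. A non-finite model value yields `-Inf`
#' with a warning.
#' @param obj An objective or global objective.
#' @return Numeric scalar.
#' @export
log_likelihood <- function(obj) UseMethod("log_likelihood")

#' @export
log_likelihood.slabs_objective <- function(obj) {
  tr <- transformed_triplet(obj)
  if (any(!is.finite(tr$ymod))) {
    warning("non-finite model values; log-likelihood set to -Inf")
    return(-Inf)
  }
  -0.5 * sum(((tr$y - tr$ymod) / tr$dy)^2 + log(2 * pi * tr$dy^2))
}

#' @export
log_likelihood.slabs_global_objective <- function(obj)
  sum(vapply(obj$objectives, log_likelihood, numeric(1)))

#' @export
log_prior.slabs_objective <- function(pset) {
  obj <- pset
  lp <- log_prior(parameters(obj))
  if (!is.finite(lp)) return(-Inf)
  extra <- model_log_prior_extra(obj$model)
  if (!is.finite(extra)) return(-Inf)
  lp + extra
}

#' @export
log_prior.slabs_global_objective <- function(pset) {
  obj <- pset
  lp <- log_prior(parameters(obj)) # shared parameters counted once
  if (!is.finite(lp)) return(-Inf)
  for (member in obj$objectives) {
    extra <- model_log_prior_extra(member$model)
    if (!is.finite(extra)) return(-Inf)
    lp <- lp + extra
  }
  lp
}

#' Log-posterior of an objective
#'
#' `log-prior + log-likelihood` (up to the constant model evidence). When
#' the prior is `-Inf` the likelihood is never evaluated. If `theta` is
#' given, the varying parameters are set from it first.
#'
#' @param obj An objective or global objective.
#' @param theta Optional numeric vector for the varying parameters, in
#'   [flatten_varying()] order.
#' @return Numeric scalar.
#' @export
log_posterior <- function(obj, theta = NULL) {
  if (!is.null(theta)) set_from_vector(parameters(obj), theta)
  lp <- log_prior(obj)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(obj)
}

#' @export
print.slabs_objective <- function(x, ...) {
  cat(sprintf("<objective '%s': %d points, chi2 = %.4g>\n",
              x$name, nrow(x$data), chi_squared(x)))
  invisible(x)
}

#' @export
print.slabs_global_objective <- function(x, ...) {
  cat(sprintf("<global objective: %d datasets, chi2 = %.4g>\n",
              length(x$objectives), chi_squared(x)))
  invisible(x)
}
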