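#' Least-squares / maximum-posterior fitting
#'
#' Minimises the negative log-posterior of an objective over its varying
#' parameters (for box priors this is equivalent to minimising chi-squared
#' inside the bounds). Three solvers are available: a seeded differential
#' evolution global search, L-BFGS-B (both bound-constrained, requiring
#' finite prior support on every varying parameter), and Levenberg-Marquardt
#' on the residual vector (unbounded; a warning is issued if bounds exist).
#' On success the parameter objects are updated in place to the best values.
#'
#' Parameter uncertainties are reported from the curvature at the optimum
#' (inverse Hessian of the negative log-posterior; for Levenberg-Marquardt,
#' the standard (J'J)^-1 estimate scaled by the reduced chi-squared).
#'
#' @param obj An objective or global objective.
#' @param method One of `"differential_evolution"`, `"lbfgsb"`,
#'   `"levenberg_marquardt"`.
#' @param seed Optional integer seed (differential evolution is stochastic;
#'   the same seed reproduces the same fit).
#' @param maxiter Iteration budget for the chosen solver.
#' @param popsize Differential evolution population size (default
#'   `max(20, 10 * n_dim)`).
#' @return An object of class `slabs_fit`: best parameter vector, standard
#'   errors, covariance, chi-squared and log-posterior at the optimum.
#' @examples
#' \donttest{
#' # see the package vignette for a full worked example
#' }
#' @export
fit_objective <- function(obj,
                          method = c("differential_evolution", "lbfgsb",
                                     "levenberg_marquardt"),
                          seed = NULL, maxiter = NULL, popsize = NULL) {
  method <- match.arg(method)
  pset <- parameters(obj)
  vp <- varying_parameters(pset)
  d <- length(vp)
  if (d == 0) stop("no varying parameters to fit")
  if (!is.null(seed)) set.seed(seed)

  start <- flatten_varying(pset)
  lp0 <- log_posterior(obj, start)
  if (!is.finite(lp0))
    stop("objective is non-finite at the starting parameter values; ",
         "check priors and starting points")
  # finite sentinel for prior-vetoed regions: keeps line searches usable
  big <- max(1e12, 1e6 * abs(lp0))
  nll <- function(theta) {
    lp <- log_posterior(obj, theta)
    if (!is.finite(lp)) big else -lp
  }
  bounds <- varying_bounds(pset)

  result <- switch(method,
    differential_evolution = {
      if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)))
        stop("differential evolution requires finite prior bounds on every ",
             "varying parameter")
      de_minimise(nll, bounds$lower, bounds$upper,
                  maxiter = maxiter %||% 150L,
                  popsize = popsize %||% max(20L, 10L * d))
    },
    lbfgsb = {
      if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)))
        stop("lbfgsb requires finite prior bounds on every varying parameter")
      # optimise on the unit box: parameters spanning many orders of
      # magnitude (thicknesses vs backgrounds) get comparable gradient steps
      width <- pmax(bounds$upper - bounds$lower, 1e-300)
      to_unit <- function(th) (th - bounds$lower) / width
      from_unit <- function(u) bounds$lower + u * width
      u0 <- pmin(pmax(to_unit(start), 0), 1)
      res <- stats::optim(u0, function(u) nll(from_unit(u)),
                          method = "L-BFGS-B", lower = 0, upper = 1,
                          control = list(maxit = maxiter %||% 500L,
                                         factr = 1e4,
                                         ndeps = rep(1e-7, length(u0))))
      list(par = from_unit(res$par), value = res$value,
           converged = res$convergence == 0, iters = res$counts[["function"]])
    },
    levenberg_marquardt = {
      if (any(is.finite(bounds$lower)) || any(is.finite(bounds$upper)))
        warning("Levenberg-Marquardt ignores parameter bounds")
      resfun <- function(theta) {
        set_from_vector(pset, theta)
        r <- stats::residuals(obj)
        r[!is.finite(r)] <- 1e150
        r
      }
      res <- minpack.lm::nls.lm(par = unname(start), fn = resfun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = maxiter %||% 200L))
      list(par = res$par, value = nll(res$par),
           converged = res$info %in% 1:4, iters = res$niter,
           lm_hessian = res$hessian, lm_deviance = res$deviance)
    }
  )

  set_from_vector(pset, result$par)
  best <- flatten_varying(pset)
  scales <- ifelse(is.finite(bounds$lower) & is.finite(bounds$upper),
                   (bounds$upper - bounds$lower) / 100,
                   pmax(abs(best), 1e-8) / 100)
  cov <- fit_covariance(result, nll, best, obj, scales)
  set_from_vector(pset, best) # curvature probes must not move the optimum
  stderr <- if (is.null(cov)) rep(NA_real_, d) else sqrt(pmax(diag(cov), 0))

  structure(list(
    par = best,
    stderr = stats::setNames(stderr, names(best)),
    cov = cov,
    chi_squared = chi_squared(obj),
    log_posterior = log_posterior(obj),
    method = method,
    converged = isTRUE(result$converged %||% TRUE),
    iterations = result$iters %||% NA_integer_,
    n_points = n_data_points(obj),
    objective = obj
  ), class = "slabs_fit")
}

n_data_points <- function(obj) {
  if (inherits(obj, "slabs_global_objective"))
    sum(vapply(obj$objectives, function(o) nrow(o$data), numeric(1)))
  else nrow(obj$data)
}

fit_covariance <- function(result, nll, best, obj, scales) {
  d <- length(best)
  if (!is.null(result$lm_hessian)) {
    # (J'J)^-1 scaled by reduced chi2, the usual least-squares estimate
    dof <- max(n_data_points(obj) - d, 1)
    cv <- try(solve(result$lm_hessian) * result$lm_deviance / dof,
              silent = TRUE)
    if (!inherits(cv, "try-error") && all(is.finite(cv))) return(cv)
  }
  # numerical curvature, probed in per-parameter scaled coordinates
  g <- function(u) nll(best + scales * u)
  h <- try(pracma::hessian(g, rep(0, d)), silent = TRUE)
  if (inherits(h, "try-error") || any(!is.finite(h))) return(NULL)
  cv_u <- try(solve(h), silent = TRUE)
  if (inherits(cv_u, "try-error") || any(!is.finite(cv_u))) return(NULL)
  diag(scales, d) %*% cv_u %*% diag(scales, d)
}

# Classic DE/rand/1/bin with reflection at the bounds.
de_minimise <- function(fn, lower, upper, maxiter = 150L, popsize = 20L,
                        f = 0.7, cr = 0.9, tol = 1e-10) {
  d <- length(lower)
  pop <- matrix(stats::runif(popsize * d, lower, upper),
                nrow = popsize, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  iters <- 0L
  for (it in seq_len(maxiter)) {
    iters <- it
    for (i in seq_len(popsize)) {
      idx <- sample(setdiff(seq_len(popsize), i), 3L)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      # reflect back into the box
      lo_bad <- trial < lower
      trial[lo_bad] <- pmin(2 * lower[lo_bad] - trial[lo_bad], upper[lo_bad])
      hi_bad <- trial > upper
      trial[hi_bad] <- pmax(2 * upper[hi_bad] - trial[hi_bad], lower[hi_bad])
      trial <- pmin(pmax(trial, lower), upper)
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      cand <- pop[i, ]
      cand[cross] <- trial[cross]
      cc <- fn(cand)
      if (cc <= cost[i]) {
        pop[i, ] <- cand
        cost[i] <- cc
      }
    }
    if (max(cost) - min(cost) < tol * (abs(min(cost)) + tol)) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], converged = TRUE,
       iters = iters)
}

#' @export
print.slabs_fit <- function(x, ...) {
  cat(sprintf("<fit (%s): chi2 = %.4g over %d points, %d parameters>\n",
              x$method, x$chi_squared, x$n_points, length(x$par)))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.slabs_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par),
                 estimate = unname(x$par),
                 std.error = unname(x$stderr))
}

#' @exportS3Method generics::glance
glance.slabs_fit <- function(x, ...) {
  tibble::tibble(chi.squared = x$chi_squared,
                 reduced.chi.squared =
                   x$chi_squared / max(x$n_points - length(x$par), 1),
                 log.posterior = x$log_posterior,
                 nobs = x$n_points,
                 n.par = length(x$par),
                 method = x$method,
                 converged = x$converged)
}
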