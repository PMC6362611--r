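#' Affine-invariant ensemble MCMC (stretch move)
#'
#' Samples an arbitrary log-probability function with an ensemble of
#' walkers using the affine-invariant stretch move: each walker is updated
#' by stretching towards a walker drawn from the complementary half of the
#' ensemble, with the scale `z` drawn from g(z) proportional to 1/sqrt(z) on
#' `[1/a, a]` and acceptance probability `z^(d-1) * p(prop)/p(cur)`. The
#' two-half update preserves detailed balance and is what makes the sampler
#' usable without tuning a proposal covariance.
#'
#' This is the low-level engine; [sample_mcmc()] wraps it (and its
#' parallel-tempering variant) for objectives.
#'
#' @param log_prob Function: numeric vector of length `d` -> log-density
#'   (may return `-Inf`).
#' @param p0 Numeric matrix `n_walkers x d` of starting positions, all with
#'   finite `log_prob`.
#' @param n_steps Number of ensemble steps to record.
#' @param seed Optional integer seed; the same seed gives an identical
#'   chain.
#' @param a Stretch scale parameter (default 2).
#' @return A list with `samples` (array `n_steps x n_walkers x d`),
#'   `log_prob` (matrix `n_steps x n_walkers`) and `acceptance` (overall
#'   acceptance fraction).
#' @export
mcmc_ensemble <- function(log_prob, p0, n_steps, seed = NULL, a = 2) {
  if (!is.matrix(p0)) p0 <- matrix(p0, ncol = 1)
  k <- nrow(p0)
  d <- ncol(p0)
  if (k < max(2 * d, 4)) stop("need at least max(2*d, 4) walkers")
  if (k %% 2L != 0L) stop("number of walkers must be even")
  if (!is.null(seed)) set.seed(seed)
  lp <- apply(p0, 1, log_prob)
  if (any(!is.finite(lp)))
    stop("all walkers must start at finite log-probability; review priors ",
         "and starting points")
  samples <- array(NA_real_, c(n_steps, k, d))
  lp_store <- matrix(NA_real_, n_steps, k)
  halves <- list(seq_len(k / 2), seq(k / 2 + 1, k))
  n_acc <- 0L
  x <- p0
  for (step in seq_len(n_steps)) {
    for (h in 1:2) {
      move <- halves[[h]]
      other <- halves[[3 - h]]
      for (i in move) {
        j <- other[sample.int(length(other), 1L)]
        z <- ((a - 1) * stats::runif(1) + 1)^2 / a
        prop <- x[j, ] + z * (x[i, ] - x[j, ])
        lp_prop <- log_prob(prop)
        log_alpha <- (d - 1) * log(z) + lp_prop - lp[i]
        if (is.finite(lp_prop) && log(stats::runif(1)) < log_alpha) {
          x[i, ] <- prop
          lp[i] <- lp_prop
          n_acc <- n_acc + 1L
        }
      }
    }
    samples[step, , ] <- x
    lp_store[step, ] <- lp
  }
  list(samples = samples, log_prob = lp_store,
       acceptance = n_acc / (n_steps * k))
}

# Parallel-tempered ensemble sampling. Each temperature runs its own
# stretch-move ensemble against log_prior + beta * log_lik; adjacent
# temperatures attempt walker swaps after every step. The mean
# log-likelihood per temperature feeds a trapezoidal thermodynamic
# integration estimate of the log-evidence over the beta ladder.
mcmc_pt <- function(log_prior_fn, log_lik_fn, p0, betas, n_steps,
                    seed = NULL, a = 2) {
  if (!is.null(seed)) set.seed(seed)
  nt <- length(betas)
  k <- dim(p0)[2]
  d <- dim(p0)[3]
  x <- p0
  lpri <- matrix(NA_real_, nt, k)
  llik <- matrix(NA_real_, nt, k)
  for (t in seq_len(nt)) for (i in seq_len(k)) {
    lpri[t, i] <- log_prior_fn(x[t, i, ])
    llik[t, i] <- log_lik_fn(x[t, i, ])
  }
  if (any(!is.finite(lpri)) || any(!is.finite(llik)))
    stop("all tempered walkers must start at finite log-probability")
  samples <- array(NA_real_, c(n_steps, k, d)) # cold chain only
  lp_store <- matrix(NA_real_, n_steps, k)
  mean_llik <- numeric(nt)
  halves <- list(seq_len(k / 2), seq(k / 2 + 1, k))
  n_acc <- 0L
  for (step in seq_len(n_steps)) {
    for (t in seq_len(nt)) {
      for (h in 1:2) {
        move <- halves[[h]]
        other <- halves[[3 - h]]
        for (i in move) {
          j <- other[sample.int(length(other), 1L)]
          z <- ((a - 1) * stats::runif(1) + 1)^2 / a
          prop <- x[t, j, ] + z * (x[t, i, ] - x[t, j, ])
          pri <- log_prior_fn(prop)
          if (!is.finite(pri)) next
          lik <- log_lik_fn(prop)
          lp_prop <- pri + betas[t] * lik
          lp_cur <- lpri[t, i] + betas[t] * llik[t, i]
          log_alpha <- (d - 1) * log(z) + lp_prop - lp_cur
          if (is.finite(lp_prop) && log(stats::runif(1)) < log_alpha) {
            x[t, i, ] <- prop
            lpri[t, i] <- pri
            llik[t, i] <- lik
            if (t == 1L) n_acc <- n_acc + 1L
          }
        }
      }
    }
    # swap moves between adjacent temperatures
    for (t in seq_len(nt - 1)) {
      for (i in seq_len(k)) {
        log_alpha <- (betas[t] - betas[t + 1]) *
          (llik[t + 1, i] - llik[t, i])
        if (log(stats::runif(1)) < log_alpha) {
          tmp <- x[t, i, ]; x[t, i, ] <- x[t + 1, i, ]; x[t + 1, i, ] <- tmp
          tmp <- lpri[t, i]; lpri[t, i] <- lpri[t + 1, i]
          lpri[t + 1, i] <- tmp
          tmp <- llik[t, i]; llik[t, i] <- llik[t + 1, i]
          llik[t + 1, i] <- tmp
        }
      }
    }
    samples[step, , ] <- x[1, , ]
    lp_store[step, ] <- lpri[1, ] + llik[1, ]
    mean_llik <- mean_llik + rowMeans(llik)
  }
  mean_llik <- mean_llik / n_steps
  ord <- order(betas)
  log_evidence <- pracma::trapz(betas[ord], mean_llik[ord])
  list(samples = samples, log_prob = lp_store,
       acceptance = n_acc / (n_steps * k),
       betas = betas, mean_log_lik = mean_llik,
       log_evidence = log_evidence)
}

#' Sample the posterior of an objective by ensemble MCMC
#'
#' Runs affine-invariant stretch-move sampling of the objective's
#' log-posterior. Walkers are initialised from the parameter priors,
#' falling back to a small multiplicative jitter (1e-4) around the current
#' values when prior draws fail to reach finite posterior density. With
#' `n_temps` set, a geometric temperature ladder with adjacent-temperature
#' swap moves is used (parallel tempering) and a thermodynamic-integration
#' estimate of the log-evidence over the ladder is attached to the chain.
#'
#' @param obj An objective or global objective.
#' @param n_walkers Number of walkers; default `max(2 * n_dim, 100)` (the
#'   examples in the literature commonly use 200).
#' @param n_steps Number of recorded steps.
#' @param seed Optional integer seed for exact reproducibility.
#' @param n_temps Number of temperatures for parallel tempering (`NULL` for
#'   plain ensemble sampling).
#' @param a Stretch scale parameter.
#' @param init Optional `n_walkers x n_dim` matrix of starting positions
#'   (e.g. the last step of a previous chain, to continue sampling).
#' @return An object of class `slabs_chain` with `samples`
#'   (`n_steps x n_walkers x n_dim`), `log_prob`, `acceptance`, parameter
#'   names, and for tempered runs `log_evidence`.
#' @export
sample_mcmc <- function(obj, n_walkers = NULL, n_steps = 500, seed = NULL,
                        n_temps = NULL, a = 2, init = NULL) {
  pset <- parameters(obj)
  vp <- varying_parameters(pset)
  d <- length(vp)
  if (d == 0) stop("no varying parameters to sample")
  if (!is.null(init) && is.null(n_walkers)) n_walkers <- nrow(init)
  if (is.null(n_walkers)) n_walkers <- max(2L * d, 100L)
  if (n_walkers %% 2L) n_walkers <- n_walkers + 1L
  if (n_walkers < 2L * d) stop("need at least 2 * n_dim walkers")
  if (!is.null(seed)) set.seed(seed)

  centre <- flatten_varying(pset)
  lp_fun <- function(theta) log_posterior(obj, theta)
  draw_start <- function() {
    for (try in 1:100) {
      cand <- vapply(seq_along(vp), function(i) {
        p <- vp[[i]]
        if (!is.null(p$prior) && try <= 50) p$prior$sample(1)
        else centre[[i]] * (1 + 1e-4 * stats::rnorm(1)) +
          1e-8 * stats::rnorm(1)
      }, numeric(1))
      if (is.finite(lp_fun(cand))) return(cand)
    }
    stop("could not find a finite-posterior starting point; review priors ",
         "and starting values")
  }

  if (is.null(n_temps)) {
    p0 <- if (!is.null(init)) {
      if (!is.matrix(init) || nrow(init) != n_walkers || ncol(init) != d)
        stop("init must be an n_walkers x n_dim matrix")
      init
    } else {
      matrix(unlist(lapply(seq_len(n_walkers), function(i) draw_start())),
             nrow = n_walkers, byrow = TRUE)
    }
    run <- mcmc_ensemble(lp_fun, p0, n_steps, a = a)
    betas <- NULL
    log_evidence <- NULL
  } else {
    betas <- (1 / sqrt(2))^(seq_len(n_temps) - 1)
    p0 <- array(NA_real_, c(n_temps, n_walkers, d))
    for (t in seq_len(n_temps)) for (i in seq_len(n_walkers))
      p0[t, i, ] <- draw_start()
    pri_fun <- function(theta) {
      set_from_vector(pset, theta)
      log_prior(obj)
    }
    lik_fun <- function(theta) {
      set_from_vector(pset, theta)
      log_likelihood(obj)
    }
    run <- mcmc_pt(pri_fun, lik_fun, p0, betas, n_steps, a = a)
    log_evidence <- run$log_evidence
  }
  set_from_vector(pset, centre) # sampling must not move the parameters
  structure(list(
    samples = run$samples,
    log_prob = run$log_prob,
    acceptance = run$acceptance,
    par_names = names(centre),
    betas = betas,
    mean_log_lik = run$mean_log_lik,
    log_evidence = log_evidence,
    objective = obj
  ), class = "slabs_chain")
}

#' @export
print.slabs_chain <- function(x, ...) {
  dm <- dim(x$samples)
  cat(sprintf(
    "<chain: %d steps x %d walkers x %d parameters, acceptance %.2f%s>\n",
    dm[1], dm[2], dm[3], x$acceptance,
    if (!is.null(x$log_evidence))
      sprintf(", log-evidence %.3f", x$log_evidence) else ""))
  invisible(x)
}

#' Burn, thin and summarise an MCMC chain
#'
#' Discards the first `burn` steps, keeps every `thin`-th step thereafter
#' and flattens the walkers into one sample matrix. Each parameter is
#' summarised by its median and a standard error equal to half of the
#' 15.87-84.13 percentile range (which equals the standard deviation for
#' a normal distribution); percentiles use linear interpolation between
#' order statistics. The objective's varying parameters are updated to the
#' medians. A subset of `n_draws` posterior samples is exported for
#' plotting curve and SLD-profile spreads.
#'
#' @param chain A `slabs_chain` from [sample_mcmc()].
#' @param burn Steps to discard (`< n_steps`).
#' @param thin Keep every `thin`-th step (`>= 1`).
#' @param n_draws Number of exported posterior draws (default 500, capped at
#'   the flattened sample count).
#' @return An object of class `slabs_chain_summary`: `summary` tibble
#'   (median, stderr per parameter), `flat` sample matrix, `draws` matrix.
#' @export
process_chain <- function(chain, burn = 0, thin = 1, n_draws = 500) {
  stopifnot(inherits(chain, "slabs_chain"))
  n_steps <- dim(chain$samples)[1]
  if (burn >= n_steps) stop("burn must be smaller than the number of steps")
  if (thin < 1) stop("thin must be >= 1")
  keep <- seq(burn + 1, n_steps, by = thin)
  d <- dim(chain$samples)[3]
  flat <- do.call(rbind, lapply(seq_len(d), function(j)
    as.vector(chain$samples[keep, , j])))
  flat <- t(flat)
  colnames(flat) <- chain$par_names
  med <- apply(flat, 2, stats::median)
  q16 <- apply(flat, 2, stats::quantile, probs = 0.1587, names = FALSE)
  q84 <- apply(flat, 2, stats::quantile, probs = 0.8413, names = FALSE)
  summary <- tibble::tibble(term = chain$par_names,
                            median = unname(med),
                            std.error = unname((q84 - q16) / 2))
  if (!is.null(chain$objective))
    set_from_vector(parameters(chain$objective), med)
  n_draws <- min(n_draws, nrow(flat))
  draws <- flat[sample.int(nrow(flat), n_draws), , drop = FALSE]
  structure(list(summary = summary, flat = flat, draws = draws,
                 burn = burn, thin = thin, n_kept_steps = length(keep),
                 log_evidence = chain$log_evidence,
                 chain = chain),
            class = "slabs_chain_summary")
}

#' @export
print.slabs_chain_summary <- function(x, ...) {
  cat(sprintf("<chain summary: %d kept steps (burn %d, thin %d), %d samples>\n",
              x$n_kept_steps, x$burn, x$thin, nrow(x$flat)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slabs_chain_summary <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.slabs_chain_summary <- function(x, ...) {
  tibble::tibble(n.samples = nrow(x$flat),
                 n.kept.steps = x$n_kept_steps,
                 burn = x$burn, thin = x$thin,
                 acceptance = x$chain$acceptance,
                 log.evidence = x$log_evidence %||% NA_real_)
}

#' Persist a chain to a plain-text file (and read it back)
#'
#' The file holds a JSON header line (prefixed `#`) with the parameter
#' names and dimensions, followed by one whitespace-delimited row per step
#' and walker. `read_chain()` restores an equivalent `slabs_chain` (without
#' the originating objective).
#'
#' @param chain A `slabs_chain`.
#' @param path File path.
#' @return `write_chain`: `path` invisibly; `read_chain`: a `slabs_chain`.
#' @export
write_chain <- function(chain, path) {
  dm <- dim(chain$samples)
  hdr <- jsonlite::toJSON(list(par_names = chain$par_names,
                               n_steps = dm[1], n_walkers = dm[2],
                               n_dim = dm[3],
                               acceptance = chain$acceptance,
                               log_evidence = chain$log_evidence),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  flat <- matrix(aperm(chain$samples, c(3, 2, 1)), ncol = dm[3],
                 byrow = TRUE) # row order: step-major, then walker
  lp <- as.vector(t(chain$log_prob))
  writeLines(apply(cbind(flat, lp), 1, function(row)
    paste(formatC(row, format = "e", digits = 12), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", lines[1]))
  body <- do.call(rbind, lapply(strsplit(trimws(lines[-1]), "\\s+"),
                                as.numeric))
  d <- hdr$n_dim
  samples <- array(NA_real_, c(hdr$n_steps, hdr$n_walkers, d))
  lp <- matrix(NA_real_, hdr$n_steps, hdr$n_walkers)
  row <- 1L
  for (s in seq_len(hdr$n_steps)) for (w in seq_len(hdr$n_walkers)) {
    samples[s, w, ] <- body[row, seq_len(d)]
    lp[s, w] <- body[row, d + 1L]
    row <- row + 1L
  }
  structure(list(samples = samples, log_prob = lp,
                 acceptance = hdr$acceptance,
                 par_names = hdr$par_names,
                 betas = NULL, mean_log_lik = NULL,
                 log_evidence = hdr$log_evidence,
                 objective = NULL),
            class = "slabs_chain")
}
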