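# A model whose curve is exactly `bkg` everywhere: zero-contrast structure,
# so the objective statistics can be computed by hand.
constant_model <- function(bkg) {
  s <- structure_model(slab(0, 2), slab(10, 2), slab(0, 2))
  reflect_model(s, scale = 1, bkg = bkg, resolution = res_none())
}

test_that("residuals, chi-squared and log-likelihood match hand values", {
  # model == data: all residuals zero
  m <- reflect_model(simple_structure(), bkg = 1e-7)
  d <- generate_dataset(m, q = default_q_grid(50), noise = NULL)
  o <- objective(m, d)
  expect_equal(residuals(o), rep(0, 50))
  expect_equal(chi_squared(o), 0)

  # one point: y = 2, model = 1, sigma = 0.5 -> residual 2, chi2 4
  o1 <- objective(constant_model(1), refl_data(0.1, 2, 0.5))
  expect_equal(residuals(o1), 2)
  expect_equal(chi_squared(o1), 4)

  # one point: y = 1, model = 2, sigma = 1 -> -(1 + ln 2pi)/2
  o2 <- objective(constant_model(2), refl_data(0.1, 1, 1))
  expect_equal(log_likelihood(o2), -0.5 * (1 + log(2 * pi)),
               tolerance = 1e-12)

  # perfect fit with unit uncertainties: -(n/2) ln 2pi
  n <- 7
  o3 <- objective(constant_model(1), refl_data(seq(0.1, 0.7, 0.1),
                                               rep(1, n), rep(1, n)))
  expect_equal(log_likelihood(o3), -(n / 2) * log(2 * pi))
  # doubling every sigma with a perfect fit costs n * ln 2
  o4 <- objective(constant_model(1), refl_data(seq(0.1, 0.7, 0.1),
                                               rep(1, n), rep(2, n)))
  expect_equal(log_likelihood(o3) - log_likelihood(o4), n * log(2))

  # chi2 is the sum of squared residuals on arbitrary synthetic data
  set.seed(5)
  d5 <- generate_dataset(m, q = default_q_grid(40), noise = noise_model(),
                         seed = 5)
  o5 <- objective(m, d5)
  expect_equal(chi_squared(o5), sum(residuals(o5)^2))
})

test_that("log-posterior = log-prior + log-likelihood, -Inf short-circuits", {
  m <- reflect_model(simple_structure(), bkg = 1e-7)
  thick <- m$structure$components[[2]]$thick
  thick$vary <- TRUE
  thick$prior <- prior_interval(5, 30)
  d <- generate_dataset(m, q = default_q_grid(40), noise = noise_model(),
                        seed = 9)
  o <- objective(m, d)

  # out of bounds: -Inf, and the parameter itself reports the violation
  expect_identical(log_posterior(o, 45), -Inf)
  # inside the bounds of a box prior the posterior equals the likelihood
  expect_equal(log_posterior(o, 15), log_likelihood(o))
  # definitional identity at random points, with a normal prior too
  thick$prior <- prior_normal(15, 4)
  set.seed(2)
  for (th in runif(5, 6, 29)) {
    lp <- log_posterior(o, th)
    expect_equal(lp, log_prior(o) + log_likelihood(o), tolerance = 1e-12)
    expect_equal(log_prior(o), dnorm(th, 15, 4, log = TRUE))
  }
})

test_that("component extra priors veto unphysical lipid packing", {
  apm <- parameter(57, "apm", vary = TRUE, prior = prior_interval(10, 100))
  lf <- lipid_leaflet(apm, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 3)
  s <- structure_model(slab(0, 2.07), lf, slab(0, 6.36, rough = 3))
  m <- reflect_model(s, bkg = 1e-7)
  d <- generate_dataset(m, q = default_q_grid(40), noise = noise_model(),
                        seed = 4)
  o <- objective(m, d)
  expect_true(is.finite(log_posterior(o, 57)))
  # apm small enough that V_t > A * t_t: inside the box prior but vetoed
  expect_identical(log_posterior(o, 20), -Inf)
})

test_that("global objectives add likelihoods and share parameters once", {
  shared_thick <- parameter(15, "SiO2 thick", vary = TRUE,
                            prior = prior_interval(5, 30))
  mk <- function(solvent, seed) {
    s <- structure_model(slab(0, 2.07), slab(shared_thick, 3.47, rough = 3),
                         slab(0, solvent, rough = 3))
    m <- reflect_model(s, bkg = 1e-7)
    objective(m, generate_dataset(m, q = default_q_grid(40),
                                  noise = noise_model(), seed = seed))
  }
  o1 <- mk(6.36, 31)
  o2 <- mk(-0.56, 32)
  g <- global_objective(list(o1, o2))
  expect_equal(log_likelihood(g), log_likelihood(o1) + log_likelihood(o2))
  expect_equal(chi_squared(g), chi_squared(o1) + chi_squared(o2))
  # a single-member global objective is that member
  g1 <- global_objective(list(o1))
  expect_equal(log_likelihood(g1), log_likelihood(o1))
  # the shared parameter appears once in theta and once in the prior
  expect_identical(names(flatten_varying(parameters(g))), "SiO2 thick")
  expect_equal(log_prior(g), 0) # one interval prior, not two
  expect_equal(log_posterior(g, 15), log_likelihood(g))
})

test_that("least squares recovers a slab from noise-free data", {
  truth <- c(thick = 120, sld = 4.2, rough = 4)
  s <- structure_model(slab(0, 0), slab(truth["thick"], truth["sld"],
                                        rough = truth["rough"]),
                       slab(0, 6.36, rough = 3))
  m <- reflect_model(s, bkg = 0, resolution = res_constant(0.05))
  d <- generate_dataset(m, q = default_q_grid(100), noise = NULL)
  layer <- s$components[[2]]
  layer$thick$vary <- TRUE
  layer$thick$prior <- prior_interval(60, 200)
  layer$material$sld$vary <- TRUE
  layer$material$sld$prior <- prior_interval(2, 6)
  layer$rough$vary <- TRUE
  layer$rough$prior <- prior_interval(0, 10)
  # start 20% off the generating values
  set_value(layer$thick, 144)
  set_value(layer$material$sld, 5.04)
  set_value(layer$rough, 4.8)
  o <- objective(m, d)
  fit <- fit_objective(o, method = "lbfgsb")
  expect_lt(max(abs(unname(fit$par) - unname(truth)) / truth), 1e-3)
  expect_lt(fit$chi_squared, 1e-2)
})

test_that("the three least-squares methods behave as documented", {
  s <- simple_structure()
  thick <- s$components[[2]]$thick
  thick$vary <- TRUE
  thick$prior <- prior_interval(5, 30)
  m <- reflect_model(s, bkg = 1e-7)
  d <- generate_dataset(m, q = default_q_grid(50), noise = noise_model(),
                        seed = 77)
  o <- objective(m, d)

  # differential evolution is reproducible under a fixed seed
  set_value(thick, 12)
  f1 <- fit_objective(o, method = "differential_evolution", seed = 42,
                      maxiter = 25)
  set_value(thick, 12)
  f2 <- fit_objective(o, method = "differential_evolution", seed = 42,
                      maxiter = 25)
  expect_identical(f1$par, f2$par)

  # Levenberg-Marquardt warns that bounds are ignored, then agrees with a
  # bounded method on this convex problem
  set_value(thick, 12)
  expect_warning(flm <- fit_objective(o, method = "levenberg_marquardt"),
                 "ignores parameter bounds")
  set_value(thick, 12)
  fbg <- fit_objective(o, method = "lbfgsb")
  expect_lt(abs(flm$par - fbg$par) / fbg$par, 1e-3)
  expect_true(all(is.finite(flm$stderr)))

  # no varying parameters is an error
  thick$vary <- FALSE
  expect_error(fit_objective(o), "no varying parameters")
  thick$vary <- TRUE

  # broom-style accessors
  td <- tidy(fbg)
  expect_identical(names(td), c("term", "estimate", "std.error"))
  expect_identical(nrow(td), 1L)
  gl <- glance(fbg)
  expect_true(gl$reduced.chi.squared < 2)
})

test_that("ensemble sampler has correct shape, determinism and targets", {
  # shape and seeded determinism
  lp <- function(x) -0.5 * sum(x^2)
  p0 <- matrix(rnorm(12 * 2, sd = 0.5), 12, 2)
  run1 <- mcmc_ensemble(lp, p0, n_steps = 50, seed = 11)
  run2 <- mcmc_ensemble(lp, p0, n_steps = 50, seed = 11)
  expect_identical(dim(run1$samples), c(50L, 12L, 2L))
  expect_identical(run1$samples, run2$samples)
  expect_true(run1$acceptance > 0.1 && run1$acceptance < 0.95)
  expect_error(mcmc_ensemble(lp, p0[1:3, ], 10), "walkers")
  expect_error(mcmc_ensemble(lp, matrix(Inf, 12, 2), 10), "finite")

  # 1-D Gaussian posterior: median -> mean, stderr -> sd within 3 MC se
  mu <- 1.7; sd_ <- 0.4
  lp1 <- function(x) dnorm(x, mu, sd_, log = TRUE)
  p01 <- matrix(rnorm(20, mu, sd_), 20, 1)
  run <- mcmc_ensemble(lp1, p01, n_steps = 1500, seed = 13)
  chain <- structure(list(samples = run$samples, log_prob = run$log_prob,
                          acceptance = run$acceptance, par_names = "x",
                          objective = NULL), class = "slabs_chain")
  res <- process_chain(chain, burn = 200, thin = 2)
  n_eff <- 2000 # conservative: stretch moves are autocorrelated
  expect_lt(abs(res$summary$median - mu), 3 * sd_ / sqrt(n_eff))
  expect_lt(abs(res$summary$std.error - sd_), 3 * sd_ / sqrt(n_eff))
})

test_that("sampling an objective is reproducible and leaves values alone", {
  s <- simple_structure()
  thick <- s$components[[2]]$thick
  thick$vary <- TRUE
  thick$prior <- prior_interval(10, 20)
  m <- reflect_model(s, bkg = 1e-7)
  d <- generate_dataset(m, q = default_q_grid(40), noise = noise_model(),
                        seed = 19)
  o <- objective(m, d)
  set_value(thick, 15)
  ch1 <- sample_mcmc(o, n_walkers = 10, n_steps = 40, seed = 3)
  expect_identical(dim(ch1$samples), c(40L, 10L, 1L))
  expect_equal(par_value(thick), 15) # sampling must not move the parameters
  ch2 <- sample_mcmc(o, n_walkers = 10, n_steps = 40, seed = 3)
  expect_identical(ch1$samples, ch2$samples)
  # processing updates the parameter to the posterior median
  res <- process_chain(ch1, burn = 20)
  expect_equal(par_value(thick), res$summary$median)
  expect_error(sample_mcmc(o, n_walkers = 1, n_steps = 10), "walkers")
})

test_that("chain processing implements burn, thin and percentile stderr", {
  set.seed(8)
  # normal samples: stderr approximates 1 through the percentile rule
  fake <- structure(list(
    samples = array(rnorm(400 * 50), c(400, 50, 1)),
    log_prob = matrix(0, 400, 50), acceptance = 0.5,
    par_names = "z", objective = NULL), class = "slabs_chain")
  res <- process_chain(fake, burn = 0, thin = 1)
  expect_lt(abs(res$summary$std.error - 1), 0.03)
  expect_lt(abs(res$summary$median), 0.03)

  # constant chain: median is the constant and stderr 0
  const <- fake
  const$samples[] <- 3.25
  resc <- process_chain(const, burn = 10, thin = 5)
  expect_identical(resc$summary$median, 3.25)
  expect_identical(resc$summary$std.error, 0)

  # thinning a 8000-step chain by 400 keeps 20 saved steps
  long <- structure(list(samples = array(0, c(8000, 4, 1)),
                         log_prob = matrix(0, 8000, 4), acceptance = 0.5,
                         par_names = "z", objective = NULL),
                    class = "slabs_chain")
  resl <- process_chain(long, burn = 0, thin = 400)
  expect_identical(resl$n_kept_steps, 20L)
  expect_identical(nrow(resl$flat), 80L) # 20 steps x 4 walkers
  expect_error(process_chain(fake, burn = 400), "burn")
  expect_error(process_chain(fake, thin = 0), "thin")
})

test_that("chains persist to text files and back", {
  set.seed(12)
  ch <- structure(list(samples = array(rnorm(30 * 6 * 2), c(30, 6, 2)),
                       log_prob = matrix(rnorm(180), 30, 6),
                       acceptance = 0.42, par_names = c("a", "b"),
                       log_evidence = -3.2, objective = NULL),
                  class = "slabs_chain")
  f <- withr::local_tempfile(fileext = ".txt")
  write_chain(ch, f)
  ch2 <- read_chain(f)
  expect_equal(ch2$samples, ch$samples, tolerance = 1e-12)
  expect_equal(ch2$log_prob, ch$log_prob, tolerance = 1e-12)
  expect_identical(ch2$par_names, c("a", "b"))
  expect_equal(ch2$log_evidence, -3.2)
})

test_that("parallel tempering recovers an analytic log-evidence", {
  # uniform prior on [-2, 2] with a N(0, 0.5) likelihood: Z = 1/4
  pri <- function(x) dunif(x, -2, 2, log = TRUE)
  lik <- function(x) dnorm(x, 0, 0.5, log = TRUE)
  betas <- (1 / sqrt(2))^(0:11)
  set.seed(6)
  p0 <- array(runif(12 * 16, -2, 2), c(12, 16, 1))
  run <- slabs:::mcmc_pt(pri, lik, p0, betas, n_steps = 400, seed = 6)
  expect_lt(abs(run$log_evidence - log(1 / 4)), 0.35)
  # the cold chain still samples the posterior
  flat <- as.vector(run$samples[-(1:100), , 1])
  post_sd <- 1 / sqrt(1 / 0.5^2) # prior is flat over the bulk
  expect_lt(abs(sd(flat) - post_sd), 0.05)
})
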