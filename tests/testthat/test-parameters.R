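test_that("built-in priors are proper distributions where they claim to be", {
  # normalised priors integrate to 1 by quadrature
  for (pr in list(prior_uniform(-2, 5), prior_normal(3, 0.7))) {
    total <- integrate(function(x) exp(pr$logpdf(x)),
                       pr$lower, pr$upper, rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-6)
  }
  # interval prior: reference constant inside, -Inf outside
  pr <- prior_interval(0, 1)
  expect_identical(pr$logpdf(c(0, 0.5, 1)), c(0, 0, 0))
  expect_identical(pr$logpdf(c(-0.01, 1.01)), c(-Inf, -Inf))
  expect_error(prior_interval(2, 1), "lower <= upper")
  # interval sampling stays inside the bounds
  set.seed(1)
  draws <- prior_interval(-3, -1)$sample(500)
  expect_true(all(draws >= -3 & draws <= -1))
})

test_that("log_prior sums varying-parameter log-densities", {
  p <- parameter(0.5, "p", vary = TRUE, prior = prior_interval(0, 1))
  expect_identical(log_prior(parameters(p)), 0)
  set_value(p, 1.5)
  expect_identical(log_prior(parameters(p)), -Inf)

  a <- parameter(0, "a", vary = TRUE, prior = prior_normal(0, 1))
  b <- parameter(1, "b", vary = TRUE, prior = prior_normal(0, 1))
  expect_equal(log_prior(parameters(a, b)), -log(2 * pi) - 0.5,
               tolerance = 1e-12)
  # fixed parameters contribute nothing
  b$vary <- FALSE
  expect_equal(log_prior(parameters(a, b)), dnorm(0, log = TRUE))
})

test_that("algebraic constraints evaluate lazily and reject cycles", {
  p1 <- parameter(1, "p1")
  p2 <- parameter(2, "p2")
  p3 <- parameter(0, "p3", vary = TRUE)
  set_constraint(p3, p1 + p2)
  expect_equal(par_value(p3), 3)
  expect_false(p3$vary) # constrained parameters stop varying

  # lazy re-evaluation when a dependency changes
  pa <- parameter(1, "pa")
  pb <- parameter(0, "pb")
  set_constraint(pb, 2 * pa)
  expect_equal(par_value(pb), 2)
  set_value(pa, 5)
  expect_equal(par_value(pb), 10)

  # total-thickness style constraint over several parameters
  total <- parameter(100, "T")
  t1 <- parameter(30, "t1")
  t2 <- parameter(20, "t2")
  t3 <- parameter(0, "t3")
  set_constraint(t3, total - t1 - t2)
  expect_equal(par_value(t3), 50)

  # unary functions work in expressions
  ps <- parameter(4, "ps")
  pq <- parameter(0, "pq")
  set_constraint(pq, sqrt(ps) + 1)
  expect_equal(par_value(pq), 3)

  # direct and transitive cycles are refused by name
  expect_error(set_constraint(p1, p3 + 1), "cycle")
  x <- parameter(1, "x"); y <- parameter(1, "y")
  set_constraint(y, x + 1)
  expect_error(set_constraint(x, y * 2), "cycle")
  expect_error(set_value(p3, 7), "constrained")
})

test_that("flattening covers varying parameters once, in stable order", {
  a <- parameter(1, "a", vary = TRUE, prior = prior_interval(0, 10))
  b <- parameter(2, "b")
  c2 <- parameter(3, "c", vary = TRUE, prior = prior_interval(0, 10))
  ps <- parameters(a, b, c2)
  expect_identical(flatten_varying(ps), c(a = 1, c = 3))

  # a parameter shared by two containers appears once (identity dedup)
  shared <- parameter(5, "shared", vary = TRUE,
                      prior = prior_interval(0, 10))
  ps2 <- parameters(list(shared, a), list(shared, b))
  expect_length(ps2, 3)
  expect_identical(names(flatten_varying(ps2)), c("shared", "a"))

  # same name, different object: both kept, with a warning on flatten
  other <- parameter(9, "a", vary = TRUE, prior = prior_interval(0, 10))
  expect_warning(flatten_varying(parameters(a, other)), "duplicated")

  # round trip leaves values untouched, and is an exact inverse
  th <- flatten_varying(ps)
  set_from_vector(ps, th + 1)
  expect_identical(flatten_varying(ps), th + 1)
  set_from_vector(ps, th)
  expect_identical(flatten_varying(ps), th)
  expect_error(set_from_vector(ps, c(1, 2, 3)), "expected 2")
})

test_that("constraint evaluation is deterministic and order-independent", {
  set.seed(7)
  for (rep in 1:20) {
    base <- lapply(1:4, function(i) parameter(runif(1, 1, 5), paste0("b", i)))
    d1 <- parameter(0, "d1"); d2 <- parameter(0, "d2")
    set_constraint(d1, base[[1]] + base[[2]] * base[[3]])
    set_constraint(d2, d1 / base[[4]])
    v_forward <- c(par_value(d1), par_value(d2))
    # evaluating in the opposite order gives identical results
    v_backward <- rev(c(par_value(d2), par_value(d1)))
    expect_identical(v_forward, v_backward)
    expect_equal(v_forward[1],
                 base[[1]]$value + base[[2]]$value * base[[3]]$value)
  }
})

test_that("parameter sets serialise to config records and back", {
  a <- parameter(1.5, "a", vary = TRUE, prior = prior_interval(0, 3))
  b <- parameter(2, "b", vary = TRUE, prior = prior_normal(2, 0.5))
  d <- parameter(0, "d")
  set_constraint(d, a + 2 * b)
  cfg <- params_to_config(parameters(a, b, d))
  rebuilt <- params_from_config(cfg)
  expect_named(rebuilt, c("a", "b", "d"))
  expect_equal(par_value(rebuilt$d), 5.5)
  expect_true(rebuilt$a$vary)
  expect_false(rebuilt$d$vary)
  expect_equal(rebuilt$b$prior$logpdf(2.3), dnorm(2.3, 2, 0.5, log = TRUE))
  # the rebuilt constraint is live, not a frozen value
  set_value(rebuilt$a, 2.5)
  expect_equal(par_value(rebuilt$d), 6.5)
})
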