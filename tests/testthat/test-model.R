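test_that("zero-truncated Poisson mass matches its formula and normalizes", {
  # direct evaluation of mu^k e^-mu / k! / (1 - e^-mu) at k = 2, mu = 2
  expect_equal(truncated_poisson_pmf(2, 2),
               (2^2 * exp(-2) / 2) / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(truncated_poisson_pmf(2, 2), 0.31304, tolerance = 1e-4)
  # mu -> 0: all truncated mass collapses on k = 1
  expect_equal(truncated_poisson_pmf(1, 1e-8), 1, tolerance = 1e-7)
  expect_equal(sum(truncated_poisson_pmf(1:200, 8)), 1, tolerance = 1e-12)
  expect_error(truncated_poisson_pmf(0, 2), "discarded")
  expect_error(truncated_poisson_pmf(2, -1), "positive")
})

test_that("the mixture series agrees with the closed-form product measure", {
  set.seed(3)
  for (mu in c(0.1, 1, 2, 8, 20)) {
    p <- random_simplex()
    params <- model_params(mu, p)
    expect_equal(mixture_category_probs(params),
                 mixture_category_probs_closed_form(params), tolerance = 1e-10)
  }
})

test_that("mixture probabilities hit their analytic limits", {
  # single-clone limit: only singletons, with probability p
  p <- c(0.4, 0.3, 0.2, 0.1)
  f <- mixture_category_probs(model_params(1e-8, p))
  expect_equal(unname(f[1:4]), p, tolerance = 1e-6)
  expect_equal(sum(f[5:15]), 0, tolerance = 1e-6)

  # uniform colors at mu = 2
  f2 <- mixture_category_probs_closed_form(model_params(2, rep(0.25, 4)))
  expect_equal(unname(f2[["G"]]), 0.101536, tolerance = 1e-5)
  expect_equal(unname(f2[["GRYB"]]), 0.027721, tolerance = 1e-4)
  expect_equal(unname(f2[1:4]), rep(f2[["G"]], 4), tolerance = 1e-12)
  expect_equal(unname(f2[5:10]), rep(f2[["GR"]], 6), tolerance = 1e-12)

  # heavy induction saturates all four colors
  expect_gt(mixture_category_probs_closed_form(
    model_params(50, rep(0.25, 4)))[["GRYB"]], 0.999)

  # a color with zero frequency never appears
  f0 <- mixture_category_probs_closed_form(model_params(2, c(1, 0, 0, 0)))
  expect_equal(unname(f0[["G"]]), 1, tolerance = 1e-12)
  expect_equal(sum(f0) , 1, tolerance = 1e-12)
})

test_that("multi-color mass is monotone in the clone-number mean", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  mass <- vapply(seq(0.2, 12, by = 0.2), function(mu) {
    f <- mixture_category_probs_closed_form(model_params(mu, p))
    sum(f[5:15])
  }, 0)
  expect_true(all(diff(mass) > 0))
})

test_that("the log-likelihood is a true multinomial log-probability", {
  # all images in one category: coefficient term vanishes
  counts <- category_counts(c(10, rep(0, 14)))
  params <- model_params(2, c(0.4, 0.2, 0.2, 0.2))
  f <- mixture_category_probs_closed_form(params)
  expect_equal(log_likelihood(counts, params), 10 * log(f[["G"]]),
               tolerance = 1e-12)

  # observed category with zero model probability: sentinel, no error
  imposs <- category_counts(c(5, 0, 0, 0, 3, rep(0, 10)))  # n_GR = 3
  expect_identical(log_likelihood(imposs, model_params(2, c(0.5, 0, 0.25, 0.25))),
                   -Inf)

  # never exceeds the saturated multinomial bound
  set.seed(9)
  for (i in 1:20) {
    sim <- simulate_experiment(mu = runif(1, 0.5, 8), p = random_simplex(),
                               n_images = 200, seed = i)
    n <- sim$counts$counts
    saturated <- dmultinom(n, prob = n / sum(n), log = TRUE)
    ll <- log_likelihood(sim$counts, model_params(runif(1, 0.5, 8), random_simplex()))
    expect_lte(ll, saturated + 1e-9)
  }
})

test_that("the likelihood is invariant under color relabeling", {
  set.seed(21)
  sim <- simulate_experiment(3, c(0.4, 0.3, 0.2, 0.1), 300, seed = 5)
  params <- model_params(2.5, c(0.35, 0.3, 0.2, 0.15))
  for (i in 1:5) {
    perm <- sample(4)
    counts_perm <- permute_category_counts(sim$counts, perm)
    params_perm <- model_params(params$mu, params$p[perm])
    expect_equal(log_likelihood(counts_perm, params_perm),
                 log_likelihood(sim$counts, params), tolerance = 1e-10)
  }
})

test_that("constrained and unconstrained parameterizations are mutually inverse", {
  set.seed(13)
  for (i in 1:25) {
    params <- model_params(exp(runif(1, -3, 3)), random_simplex())
    back <- from_unconstrained(to_unconstrained(params))
    expect_equal(back$mu, params$mu, tolerance = 1e-12)
    expect_equal(back$p, params$p, tolerance = 1e-12)
  }
  # the origin maps to mu = 1, uniform p
  origin <- from_unconstrained(c(0, 0, 0, 0))
  expect_equal(origin$mu, 1)
  expect_equal(unname(origin$p), rep(0.25, 4), tolerance = 1e-12)
  # any finite eta lands strictly inside the parameter space
  for (i in 1:25) {
    eta <- runif(4, -30, 30)
    pars <- from_unconstrained(eta)
    expect_true(pars$mu > 0)
    expect_true(all(pars$p > 0) && abs(sum(pars$p) - 1) < 1e-12)
  }
  expect_error(to_unconstrained(model_params(1, c(1, 0, 0, 0))), "interior")
  expect_error(from_unconstrained(c(0, Inf, 0, 0)), "finite")
})
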