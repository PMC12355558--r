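test_that("starting values are sensible summaries of the counts", {
  # all-singleton data: no multi-color evidence, small starting mu
  singles <- category_counts(c(40, 30, 20, 10, rep(0, 11)))
  g <- initial_guess(singles)
  expect_lte(g$mu, 0.5)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)

  # overwhelmingly four-color data: saturation forces a large starting mu
  quads <- category_counts(c(rep(0, 14), 100))
  expect_gte(initial_guess(quads)$mu, 4)
})

test_that("the MLE recovers parameters from near-exact expected frequencies", {
  counts <- expected_counts(mu = 3, p = c(0.4, 0.2, 0.2, 0.2), n_images = 10000)
  fit <- fit_mle(counts, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params_hat$mu - 3) / 3, 0.02)
  expect_true(all(abs(fit$params_hat$p - c(0.4, 0.2, 0.2, 0.2)) < 0.01))
  # the reported optimum is at least as good as the deterministic start
  expect_gte(fit$loglik, log_likelihood(counts, initial_guess(counts)) - 1e-9)
})

test_that("relabeling colors permutes the estimates and nothing else", {
  sim <- simulate_experiment(3, c(0.4, 0.25, 0.2, 0.15), 400, seed = 8)
  fit <- fit_mle(sim$counts, seed = 2)
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    fit_perm <- fit_mle(permute_category_counts(sim$counts, perm), seed = 2)
    expect_equal(fit_perm$params_hat$mu, fit$params_hat$mu, tolerance = 1e-6)
    expect_equal(fit_perm$loglik, fit$loglik, tolerance = 1e-8)
    expect_equal(unname(fit_perm$params_hat$p), unname(fit$params_hat$p[perm]),
                 tolerance = 1e-6)
  }
})

test_that("single-category data yields a flagged boundary fit, not an error", {
  only_g <- category_counts(c(50, rep(0, 14)))
  fit <- fit_mle(only_g, seed = 1)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(any(fit$boundary_flags))
  expect_true(fit$boundary_flags[["mu"]])   # no co-occurrence evidence: mu at floor
})

test_that("the independent stats4 route reaches the same optimum", {
  skip_if_not_installed("stats4")
  sim <- simulate_experiment(2.5, c(0.5, 0.2, 0.2, 0.1), 300, seed = 14)
  fit <- fit_mle(sim$counts, seed = 3)
  nll <- function(eta1, eta2, eta3, eta4) {
    -log_likelihood(sim$counts, from_unconstrained(c(eta1, eta2, eta3, eta4)))
  }
  eta0 <- to_unconstrained(initial_guess(sim$counts))
  ref <- stats4::mle(nll, start = list(eta1 = eta0[1], eta2 = eta0[2],
                                       eta3 = eta0[3], eta4 = eta0[4]))
  ref_ll <- as.numeric(stats4::logLik(ref))
  expect_gte(fit$loglik, ref_ll - 1e-6)          # never worse than stats4
  expect_lt(abs(fit$loglik - ref_ll), 1e-3)      # and at the same optimum
  ref_params <- from_unconstrained(as.numeric(stats4::coef(ref)))
  expect_equal(fit$params_hat$mu, ref_params$mu, tolerance = 1e-2)
})

test_that("profile intervals bracket the estimate and tighten with sample size", {
  truth_mu <- 4
  truth_p <- c(0.4, 0.2, 0.2, 0.2)
  widths <- vapply(c(100, 400, 1600), function(n) {
    sim <- simulate_experiment(truth_mu, truth_p, n, seed = 100 + n)
    fit <- fit_mle(sim$counts, seed = 1)
    ci <- profile_ci(sim$counts, fit, "mu")
    expect_lte(ci$lower, fit$params_hat$mu)
    expect_gte(ci$upper, fit$params_hat$mu)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("the profile deviance is non-negative everywhere it is evaluated", {
  sim <- simulate_experiment(3, c(0.4, 0.2, 0.2, 0.2), 300, seed = 17)
  fit <- fit_mle(sim$counts, seed = 1)
  for (mu in c(1.5, 2.5, fit$params_hat$mu, 4, 6)) {
    pl <- clonecount:::profile_loglik(sim$counts, "mu", mu, fit)$loglik
    expect_lte(pl, fit$loglik + 1e-6)
  }
  # frequencies can be profiled too
  ci_p <- profile_ci(sim$counts, fit, "p_G")
  expect_lt(ci_p$lower, fit$params_hat$p[["G"]])
  expect_gt(ci_p$upper, fit$params_hat$p[["G"]])
  expect_error(profile_ci(sim$counts, fit, "sigma"), "parameter")
})

test_that("batch fitting is deterministic, ordered, and failure-tolerant", {
  datasets <- simulate_paper_grid(n_images_per_dataset = 80, seed = 5)
  expect_error(fit_all(list()), "non-empty")

  tab <- fit_all(datasets, seed = 9)
  expect_s3_class(tab, "condition_table")
  expect_equal(nrow(tab), 12)
  expect_equal(tab$induction_min, rep(c(30, 60, 120), each = 4))
  expect_equal(tab$stage[1:4], c("early", "early", "late", "late"))
  expect_true(all(is.finite(tab$mu_hat)))
  expect_true(all(is.finite(tab$mu_lo) & is.finite(tab$mu_hi)))

  # bitwise determinism of the whole table
  tab2 <- fit_all(datasets, seed = 9)
  expect_identical(serialize(tab, NULL), serialize(tab2, NULL))

  # a single dataset reduces to fit_mle + profile_ci
  one <- fit_all(datasets[1], seed = 9)
  d <- datasets[[1]]
  seed1 <- clonecount:::with_local_seed(9, sample.int(.Machine$integer.max - 1L, 1))
  fit <- fit_mle(d, seed = seed1)
  ci <- profile_ci(d, fit, "mu")
  expect_equal(one$mu_hat, fit$params_hat$mu)
  expect_equal(one$mu_lo, ci$lower)
  expect_equal(one$mu_hi, ci$upper)
})

test_that("fixing color frequencies from a control dataset still estimates mu", {
  datasets <- simulate_paper_grid(n_images_per_dataset = 120, seed = 31)
  ids <- vapply(datasets, function(d) d$meta$dataset_id, "")
  sub <- datasets[ids %in% c("120_late_clone", "120_late_tumor")]
  tab <- fit_all(sub, seed = 4, fix_p_from = "120_late_clone")
  expect_true(all(tab$status == "ok"))
  # tumor row inherits the control's frequencies exactly
  pc <- unlist(tab[tab$image_class == "clone", c("p_G", "p_R", "p_Y", "p_B")])
  pt <- unlist(tab[tab$image_class == "tumor", c("p_G", "p_R", "p_Y", "p_B")])
  expect_equal(unname(pt), unname(pc), tolerance = 1e-12)
  expect_true(is.finite(tab$mu_hat[tab$image_class == "tumor"]))
})
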