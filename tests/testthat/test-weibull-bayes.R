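# Independent oracles: brute-force posterior normalization on a rate grid,
# quadrature for the superiority probability, Monte Carlo Gamma pairs.
grid_posterior_density <- function(prior, events, censors, lam) {
  k <- prior$shape_k
  loglik <- vapply(lam, function(l)
    sum(log(k) + log(l) + (k - 1) * log(events) - l * events^k) -
      l * sum(censors^k), numeric(1))
  logpost <- stats::dgamma(lam, prior$alpha, rate = prior$beta, log = TRUE) +
    loglik
  w <- exp(logpost - max(logpost))
  w / sum(w * c(diff(lam), 0))
}

quad_prob_superiority <- function(pt, pc) {
  stats::integrate(function(x)
    stats::pgamma(x, pt$alpha_post, rate = pt$beta_post) *
      stats::dgamma(x, pc$alpha_post, rate = pc$beta_post),
    0, Inf, rel.tol = 1e-10)$value
}

test_that("conjugate update accumulates events in alpha and exposure in beta", {
  pr <- prior_spec()
  p0 <- posterior_update(pr, survival_data())
  expect_equal(c(p0$alpha_post, p0$beta_post), c(10, 80))
  p1 <- posterior_update(pr, survival_data(c(2, 4, 6), 5))
  expect_equal(c(p1$alpha_post, p1$beta_post), c(13, 97))
  expect_equal(p1$n_events, 3L)
  expect_equal(p1$n_subjects, 4L)
  p2 <- posterior_update(prior_spec(shape_k = 2), survival_data(3))
  expect_equal(c(p2$alpha_post, p2$beta_post), c(11, 89))
  expect_error(survival_data(c(2, -1)), "positive")
  expect_error(survival_data(numeric(0), 0), "positive")
})

test_that("closed-form posterior matches brute-force normalization", {
  # prior pseudo-event count stays 10 on every dataset
  set.seed(101)
  for (rep in 1:50) {
    k <- sample(c(1, 1, 2, 0.8), 1)
    pr <- prior_spec(shape_k = k)
    ne <- sample(0:6, 1); nc <- sample(0:4, 1)
    ev <- if (ne) round(rweibull(ne, k, 8), 3) + 0.01 else numeric(0)
    cs <- if (nc) round(rweibull(nc, k, 8), 3) + 0.01 else numeric(0)
    po <- posterior_update(pr, survival_data(ev, cs))
    expect_equal(po$alpha_post - po$n_events, 10)
    if (ne == 0) next  # grid likelihood needs at least one event term
    lam <- seq(1e-4, 1.5, length.out = 4000)
    dens <- grid_posterior_density(pr, ev, cs, lam)
    closed <- stats::dgamma(lam, po$alpha_post, rate = po$beta_post)
    tv <- sum(abs(dens - closed) * c(diff(lam), 0)) / 2
    expect_lt(tv, 1e-6)
  }
})

test_that("mean PFS and rate conversions invert each other", {
  expect_equal(mean_pfs(0.125, 1), 8)
  expect_equal(mean_pfs(1, 1), 1)
  expect_equal(mean_pfs(1, 2), gamma(1.5))
  expect_equal(rate_for_mean(8, 1), 0.125)
  expect_equal(rate_for_mean(gamma(1.5), 2), 1)
  for (m in c(0.1, 0.5, 2, 8, 18, 100))
    for (k in c(0.7, 1, 1.6))
      expect_equal(mean_pfs(rate_for_mean(m, k), k), m, tolerance = 1e-10)
  # strictly decreasing in the rate
  expect_true(mean_pfs(0.2) < mean_pfs(0.1))
  expect_error(mean_pfs(0), "positive")
  expect_error(rate_for_mean(-2), "positive")
})

test_that("probability of superiority has its closed Gamma-ratio form", {
  pr <- prior_spec()
  p0 <- posterior_update(pr, survival_data())
  expect_equal(prob_superiority(p0, p0), 0.5)
  # more exposure at equal events means a lower rate, hence superiority
  pt <- list(alpha_post = 10, beta_post = 160, shape_k = 1)
  expect_equal(prob_superiority(pt, p0), pbeta(2 / 3, 10, 10))
  pt2 <- list(alpha_post = 13, beta_post = 97, shape_k = 1)
  expect_equal(prob_superiority(pt2, p0), quad_prob_superiority(pt2, p0),
               tolerance = 1e-6)
  expect_error(prob_superiority(list(alpha_post = 10, beta_post = 80,
                                     shape_k = 2), p0), "shape")
})

test_that("superiority is monotone, complementary, and matches sampling", {
  base <- list(alpha_post = 12, beta_post = 100, shape_k = 1)
  ctrl <- list(alpha_post = 15, beta_post = 110, shape_k = 1)
  # increasing treatment exposure raises superiority; events lower it
  p_beta <- vapply(c(90, 100, 120, 150), function(b)
    prob_superiority(list(alpha_post = 12, beta_post = b, shape_k = 1), ctrl),
    numeric(1))
  expect_true(all(diff(p_beta) > 0))
  p_alpha <- vapply(c(10, 12, 16, 22), function(a)
    prob_superiority(list(alpha_post = a, beta_post = 100, shape_k = 1), ctrl),
    numeric(1))
  expect_true(all(diff(p_alpha) < 0))
  set.seed(202)
  for (i in 1:20) {
    a <- list(alpha_post = runif(1, 10, 40), beta_post = runif(1, 60, 300),
              shape_k = 1)
    b <- list(alpha_post = runif(1, 10, 40), beta_post = runif(1, 60, 300),
              shape_k = 1)
    expect_equal(prob_superiority(a, b) + prob_superiority(b, a), 1,
                 tolerance = 1e-12)
  }
  # paired-draw frequency agrees with the closed form
  n <- 2e5
  dt <- posterior_draws(base, n, seed = 5)
  dc <- posterior_draws(ctrl, n, seed = 6)
  emp <- mean(dt < dc)
  expect_lt(abs(emp - prob_superiority(base, ctrl)), 3 * sqrt(0.25 / n))
})

test_that("posterior draws are reproducible with correct moments", {
  po <- list(alpha_post = 13, beta_post = 97, shape_k = 1)
  expect_identical(posterior_draws(po, 100, seed = 3),
                   posterior_draws(po, 100, seed = 3))
  d <- posterior_draws(po, 1e5, seed = 4)
  se <- sqrt(po$alpha_post / po$beta_post^2 / 1e5)
  expect_lt(abs(mean(d) - po$alpha_post / po$beta_post), 3 * se)
})

test_that("the posterior mean recovers the true rate from large samples", {
  set.seed(77)
  lam_star <- rate_for_mean(8, 1)
  t <- rweibull(2000, 1, lam_star^-1)
  po <- posterior_update(prior_spec(), survival_data(t))
  expect_lt(abs(po$alpha_post / po$beta_post - lam_star) / lam_star, 0.05)
})
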