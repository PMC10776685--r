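test_that("NB pmf: closed-form values, Poisson limit, normalisation", {
  expect_identical(nb_pmf(0, mu = 1, theta = 1), 0.5)
  # theta -> Inf recovers Poisson
  expect_equal(nb_pmf(2, mu = 2, theta = 1e9), exp(-2) * 2^2 / 2,
               tolerance = 1e-6)
  expect_equal(sum(nb_pmf(0:1e5, mu = 50, theta = 3)), 1, tolerance = 1e-10)
  expect_error(nb_pmf(1.5, 1, 1), "integer")
  expect_error(nb_pmf(1, -1, 1), "positive")
  expect_error(nb_pmf(1, 1, 0), "positive")
})

test_that("marginal log-likelihood: degenerate prior and exchangeability", {
  set.seed(2)
  d <- nb_glmm_data(l = 6, ni = 4, sigma = 0.4)
  obs <- glmm_observations(d$r, d$x, d$cell)
  # sigma = 0 equals the sum of independent NB log pmfs exactly
  p <- c(log(500), -0.4, log(5), -Inf)
  mu <- exp(p[1] + p[2] * d$x)
  expect_equal(nb_glmm_marginal_loglik(p, obs),
               sum(dnbinom(d$r, mu = mu, size = 5, log = TRUE)),
               tolerance = 1e-12)
  # relabelling cell lines leaves the likelihood unchanged
  relab <- setNames(sample(unique(d$cell)), unique(d$cell))
  obs2 <- glmm_observations(d$r, d$x, unname(relab[d$cell]))
  p2 <- c(log(500), -0.4, log(5), log(0.5))
  expect_equal(nb_glmm_marginal_loglik(p2, obs),
               nb_glmm_marginal_loglik(p2, obs2), tolerance = 1e-10)
})

test_that("quadrature matches brute-force integration and improves with nodes", {
  set.seed(3)
  r1 <- c(420, 510, 380); r2 <- c(610, 550, 700)
  obs <- glmm_observations(c(r1, r2), rep(c(0, 1), each = 3),
                           rep(c("cA", "cB"), each = 3))
  b0 <- log(500); b <- 0.2; th <- 4; sig <- 0.5
  ref <- trapz_cluster_loglik(r1, exp(b0), th, sig) +
    trapz_cluster_loglik(r2, exp(b0 + b), th, sig)
  p <- c(b0, b, log(th), log(sig))
  expect_equal(nb_glmm_marginal_loglik(p, obs, n_quad = 31), ref,
               tolerance = 1e-6)
  # accuracy is monotone in the number of nodes
  errs <- vapply(c(1, 5, 11, 21), function(q)
    abs(nb_glmm_marginal_loglik(p, obs, n_quad = q) - ref), numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("sigma-zero NB fit matches an independent NB regression oracle", {
  skip_if_not_installed("MASS")
  set.seed(4)
  d <- nb_glmm_data(l = 30, ni = 8, b = -0.5, sigma = 0)
  obs <- glmm_observations(d$r, d$x, d$cell)
  fit <- fit_nb_glmm(obs, sigma_zero = TRUE)
  ref <- MASS::glm.nb(r ~ x, data = data.frame(r = d$r, x = d$x),
                      control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$beta, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-3)
  expect_equal(fit$sigma2, 0)
})

test_that("full fit agrees with glmmTMB (the same Laplace objective)", {
  skip_if_not_installed("glmmTMB")
  set.seed(5)
  d <- nb_glmm_data(l = 24, ni = 6, b = -0.6, sigma = 0.35)
  obs <- glmm_observations(d$r, d$x, d$cell)
  fit <- fit_nb_glmm(obs)
  tmb <- glmmTMB::glmmTMB(r ~ x + (1 | cell), family = glmmTMB::nbinom2,
                          data = data.frame(r = d$r, x = d$x, cell = d$cell))
  expect_equal(fit$beta, unname(glmmTMB::fixef(tmb)$cond[2]), tolerance = 1e-3)
  expect_equal(fit$se_beta, sqrt(stats::vcov(tmb)$cond[2, 2]), tolerance = 1e-3)
  expect_equal(fit$theta, glmmTMB::sigma(tmb), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(tmb)), tolerance = 1e-6)
})

test_that("the fitted optimum dominates nearby parameter points", {
  set.seed(6)
  d <- nb_glmm_data(l = 16, ni = 5, sigma = 0.3)
  obs <- glmm_observations(d$r, d$x, d$cell)
  fit <- fit_nb_glmm(obs)
  par <- c(fit$beta0, fit$beta, log(fit$theta),
           log(max(sqrt(fit$sigma2), 1e-3)))
  for (i in 1:20) {
    pp <- par + rnorm(4, 0, 0.05)
    expect_lte(nb_glmm_marginal_loglik(pp, obs), fit$loglik + 1e-6)
  }
})

test_that("fit input validation", {
  expect_error(glmm_observations(c(1, 2), c(0, 1), c("a", "a")),
               "constant within")
  obs <- glmm_observations(c(5, 5, 5, 5), c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_error(fit_nb_glmm(obs), "degenerate")
  obs1 <- glmm_observations(c(5, 6, 7), c(0, 0, 0), c("a", "a", "b"))
  expect_error(fit_nb_glmm(obs1), "mutant")
})

test_that("one-sided Wald p-values and their monotonicity", {
  expect_equal(wald_one_sided_p(0, 1), 0.5)
  expect_equal(wald_one_sided_p(-1.6448536 * 2, 2), 0.05, tolerance = 1e-6)
  expect_equal(wald_one_sided_p(2, 1), pnorm(2), tolerance = 1e-12)
  expect_error(wald_one_sided_p(1, 0), "positive")
  b <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(wald_one_sided_p(b, 0.7)) > 0))
})

test_that("BH adjustment: textbook cases, permutation invariance", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap_p(0, 5, 5, 10), 1)
  expect_equal(hypergeom_overlap_p(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(hypergeom_overlap_p(6, 5, 5, 10), "inconsistent")
  # brute-force pmf summation over small grids
  for (N in c(8, 12, 20)) for (K in c(3, N %/% 2)) for (n in c(2, N %/% 2)) {
    for (k in 0:min(n, K)) {
      pmf <- vapply(0:min(n, K), function(j)
        choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1))
      expect_equal(hypergeom_overlap_p(k, K, n, N), sum(pmf[(k:min(n, K)) + 1]),
                   tolerance = 1e-12)
    }
  }
})
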