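test_that("the AGQ likelihood collapses to the NB GLM likelihood at sigma2_b = 0", {
  # closed form: one observation y = 0, mu = 1, alpha = 1 -> log((1+1)^-1) = log 0.5
  ll <- nbmm_loglik_agq(0, list(X = matrix(1, 1, 1), subject = factor(1)),
                        beta = 0, alpha = 1, sigma2_b = 0, n_nodes = 7)
  expect_equal(ll, log(0.5))
  expect_equal(ll, -0.6931, tolerance = 1e-4)
  # general case: matches dnbinom exactly
  set.seed(1)
  des <- study_design(3)
  p <- fixed_params(1, beta0 = log(40), alpha = 0.2, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 2)
  y <- sim$counts$counts[1, ]
  beta <- c(log(40), rep(0, 7))
  ll2 <- nbmm_loglik_agq(y, des, beta = beta, alpha = 0.2, sigma2_b = 0)
  expect_equal(ll2, sum(stats::dnbinom(y, size = 5, mu = 40, log = TRUE)))
})

test_that("the AGQ likelihood converges under quadrature refinement", {
  set.seed(2)
  des <- study_design(4)
  p <- fixed_params(1, beta0 = log(150), alpha = 0.3, sigma2_b = 0.5)
  sim <- simulate_dataset(p, des, seed = 3)
  y <- sim$counts$counts[1, ]
  beta <- c(log(150), rep(0, 7))
  ll <- vapply(c(5, 15, 25), function(k)
    nbmm_loglik_agq(y, des, beta = beta, alpha = 0.3, sigma2_b = 0.5,
                    n_nodes = k), numeric(1))
  expect_lt(abs(ll[3] - ll[2]), 1e-6)
  expect_lt(abs(ll[3] - ll[2]), abs(ll[2] - ll[1]) + 1e-12)
})

test_that("a common offset shift is absorbed by the intercept", {
  set.seed(3)
  des <- study_design(3)
  p <- fixed_params(1, beta0 = log(80), alpha = 0.15, sigma2_b = 0.2)
  sim <- simulate_dataset(p, des, seed = 4)
  y <- sim$counts$counts[1, ]
  beta <- c(log(80), 0.1, rep(0, 6))
  l1 <- nbmm_loglik_agq(y, des, offsets = rep(0, length(y)), beta = beta,
                        alpha = 0.15, sigma2_b = 0.2)
  beta2 <- beta
  beta2[1] <- beta[1] - log(2)
  l2 <- nbmm_loglik_agq(y, des, offsets = rep(log(2), length(y)), beta = beta2,
                        alpha = 0.15, sigma2_b = 0.2)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("the one-node AGQ fit reproduces the Laplace fit of glmmTMB", {
  set.seed(4)
  des <- study_design(10)
  p <- fixed_params(1, beta0 = log(400), alpha = 0.1, sigma2_b = 0.3)
  p$beta5 <- 1 / 3; p$beta6 <- 2 / 3; p$beta7 <- 1
  sim <- simulate_dataset(p, des, seed = 5)
  y <- sim$counts$counts[1, ]
  d <- transform(data.frame(y = y, des$samples), time = factor(time))
  tm <- glmmTMB::glmmTMB(y ~ group * time + (1 | subject), data = d,
                         family = glmmTMB::nbinom2)
  # my likelihood evaluated at the glmmTMB solution equals its logLik
  ll <- nbmm_loglik_agq(y, des, beta = glmmTMB::fixef(tm)$cond,
                        alpha = 1 / glmmTMB::sigma(tm),
                        sigma2_b = glmmTMB::VarCorr(tm)$cond$subject[1],
                        n_nodes = 1)
  expect_equal(ll, as.numeric(stats::logLik(tm)), tolerance = 1e-5)
  # and my optimizer reaches the same solution
  fit <- fit_nbmm_agq(y, des, n_nodes = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), unname(glmmTMB::fixef(tm)$cond),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(tm)), tolerance = 1e-4)
})

test_that("AGQ estimates are stable in the number of nodes", {
  set.seed(5)
  des <- study_design(10)
  p <- fixed_params(1, beta0 = log(300), alpha = 0.1, sigma2_b = 0.4)
  sim <- simulate_dataset(p, des, seed = 6)
  y <- sim$counts$counts[1, ]
  f7 <- fit_nbmm_agq(y, des, n_nodes = 7)
  f15 <- fit_nbmm_agq(y, des, n_nodes = 15)
  expect_lt(max(abs(f7$coef - f15$coef)), 1e-3)
})

test_that("with true sigma2_b = 0 the AGQ fit sits near the GLM solution", {
  set.seed(6)
  des <- study_design(10)
  p <- fixed_params(1, beta0 = log(500), alpha = 0.2, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 7)
  y <- sim$counts$counts[1, ]
  fit <- fit_nbmm_agq(y, des)
  d <- transform(data.frame(y = y, des$samples), time = factor(time))
  gl <- MASS::glm.nb(y ~ group * time, data = d)
  expect_lt(fit$sigma2_b, 0.02)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(gl))), 0.1)
})

test_that("pseudo-likelihood matches the NB GLM when sigma2_b = 0 and counts are large", {
  set.seed(7)
  des <- study_design(10)
  p <- fixed_params(1, beta0 = log(2000), alpha = 0.05, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 8)
  y <- sim$counts$counts[1, ]
  fit <- fit_nbmm_pl(y, des)
  d <- transform(data.frame(y = y, des$samples), time = factor(time))
  gl <- MASS::glm.nb(y ~ group * time, data = d)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coef - stats::coef(gl))), 0.02)
})

test_that("pseudo-likelihood and AGQ agree on moderate-count genes", {
  set.seed(8)
  des <- study_design(10)
  G <- 25
  p <- fixed_params(G, beta0 = log(300), alpha = 0.1, sigma2_b = 0.3, seed = 9)
  p <- assign_de_effects(p, 1, seed = 10)
  sim <- simulate_dataset(p, des, seed = 11)
  d7 <- vapply(seq_len(G), function(g) {
    y <- sim$counts$counts[g, ]
    fa <- fit_nbmm_agq(y, des, hessian = FALSE)
    fp <- fit_nbmm_pl(y, des)
    if (fa$converged && fp$converged) abs(fa$coef[8] - fp$coef[8]) else NA_real_
  }, numeric(1))
  expect_lt(stats::median(d7, na.rm = TRUE), 0.05)
})

test_that("degenerate constant-count genes are flagged, never fatal", {
  des <- study_design(3)
  y <- rep(5, nrow(des$X))
  fa <- fit_nbmm_agq(y, des)
  fp <- fit_nbmm_pl(y, des)
  fl <- fit_lmm_reml(log1p(y), des)
  expect_false(fa$converged && !fa$singular)
  expect_false(fp$converged && !fp$singular)
  expect_false(fl$converged && !fl$singular)
})
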