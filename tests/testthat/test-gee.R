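test_that("with one observation per subject GEE equals the Poisson GLM", {
  set.seed(1)
  y <- rpois(12, 20)
  X <- cbind(1, rnorm(12))
  fit <- fit_gee_exchangeable(y, list(X = X, subject = factor(1:12)))
  gl <- stats::glm.fit(X, y, family = stats::poisson())
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), unname(gl$coefficients), tolerance = 1e-7)
  expect_equal(fit$rho, 0)
})

test_that("the intercept-only fit mean-matches and the hand sandwich is 0.125", {
  fit <- fit_gee_exchangeable(c(1, 3), list(X = matrix(1, 2, 1),
                                            subject = factor(1:2)))
  expect_equal(unname(fit$coef), log(2), tolerance = 1e-9)
  # bread 4, meat (1-2)^2 + (3-2)^2 = 2, variance 2/16
  expect_equal(as.vector(fit$robust_cov), 0.125, tolerance = 1e-9)
  # zero residuals -> zero robust covariance
  fz <- fit_gee_exchangeable(c(4, 4), list(X = matrix(1, 2, 1),
                                           subject = factor(1:2)))
  expect_equal(as.vector(fz$robust_cov), 0, tolerance = 1e-12)
})

test_that("the sandwich matches a from-scratch assembly with numeric Jacobians", {
  set.seed(2)
  des <- list(X = cbind(1, rep(c(0, 1), each = 6), rep(c(0, 1), 6)),
              subject = factor(rep(1:3, each = 4)))
  y <- rpois(12, exp(2 + 0.3 * des$X[, 2] + 0.2 * des$X[, 3]))
  fit <- fit_gee_exchangeable(y, des)
  # rebuild bread and meat densely, with D_i = dmu/dbeta by central differences
  p <- 3
  mu_of <- function(beta) exp(as.vector(des$X %*% beta))
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (s in levels(des$subject)) {
    ix <- which(des$subject == s)
    Di <- matrix(0, length(ix), p)
    for (k in 1:p) {
      h <- 1e-6
      bp <- fit$coef; bp[k] <- bp[k] + h
      bm <- fit$coef; bm[k] <- bm[k] - h
      Di[, k] <- (mu_of(bp)[ix] - mu_of(bm)[ix]) / (2 * h)
    }
    mui <- mu_of(fit$coef)[ix]
    ni <- length(ix)
    R <- matrix(fit$rho, ni, ni); diag(R) <- 1
    Vi <- fit$phi * diag(sqrt(mui)) %*% R %*% diag(sqrt(mui))
    Vinv <- solve(Vi)
    ei <- y[ix] - mui
    A <- A + t(Di) %*% Vinv %*% Di
    M <- M + t(Di) %*% Vinv %*% ei %*% t(ei) %*% Vinv %*% Di
  }
  ref <- solve(A) %*% M %*% solve(A)
  expect_equal(fit$robust_cov, ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$naive_cov, solve(A), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the working correlation tracks the residual intraclass correlation", {
  set.seed(3)
  des <- study_design(150)
  p <- fixed_params(1, beta0 = log(100), alpha = 0.01, sigma2_b = 0.2)
  sim <- simulate_dataset(p, des, seed = 4)
  y <- sim$counts$counts[1, ]
  fit <- fit_gee_exchangeable(y, des)
  # brute-force ICC of Pearson residuals
  r <- (y - fit$mu) / sqrt(fit$mu)
  bysub <- split(r, des$subject)
  pairs <- do.call(rbind, lapply(bysub, function(ri) {
    cb <- utils::combn(length(ri), 2)
    cbind(ri[cb[1, ]], ri[cb[2, ]])
  }))
  icc <- mean(pairs[, 1] * pairs[, 2]) / (sum(r^2) / length(r))
  expect_gt(fit$rho, 0.2)
  expect_equal(fit$rho, icc, tolerance = 0.05)
})

test_that("the small-sample correction inflates variances on few-subject toys", {
  set.seed(4)
  for (nsub in c(3, 4, 5)) {
    des <- study_design(n_per_group = nsub)
    des4 <- list(X = des$X[, 1:2], subject = des$subject)  # intercept + group
    p <- fixed_params(1, beta0 = log(60), alpha = 0.05, sigma2_b = 0.1)
    sim <- simulate_dataset(p, des, seed = nsub)
    y <- sim$counts$counts[1, ]
    fit <- fit_gee_exchangeable(y, des4)
    # inflation direction: the leverage adjustment dominates on few subjects
    expect_gt(mean(diag(fit$wl_cov) / diag(fit$robust_cov)), 1)
  }
})

test_that("the small-sample correction vanishes as subjects grow", {
  # iid clusters, intercept-only: pooling is exact and only the (I - H)^-1
  # inflation of order p/K remains
  set.seed(5)
  des1 <- list(X = matrix(1, 800, 1), subject = factor(rep(1:200, each = 4)))
  p <- fixed_params(1, beta0 = log(100), alpha = 0.05, sigma2_b = 0.15)
  simdes <- study_design(100)
  sim <- simulate_dataset(p, simdes, seed = 6)
  y <- sim$counts$counts[1, ]
  fit <- fit_gee_exchangeable(y, des1)
  expect_lt(abs(fit$wl_cov[1, 1] / fit$robust_cov[1, 1] - 1), 0.05)
  # full design: per-coefficient ratios average to 1 across genes
  set.seed(7)
  des <- study_design(100)
  pg <- fixed_params(30, beta0 = log(100), alpha = 0.05, sigma2_b = 0.15,
                     seed = 8)
  simg <- simulate_dataset(pg, des, seed = 9)
  ratios <- sapply(seq_len(30), function(g) {
    f <- fit_gee_exchangeable(simg$counts$counts[g, ], des)
    diag(f$wl_cov) / diag(f$robust_cov)
  })
  mr <- rowMeans(ratios)
  # group and interaction coefficients (the Wald-test targets) agree to 5%;
  # the remaining coefficients carry an O(p/K) pooling term, bounded at 10%
  expect_true(all(abs(mr[c(2, 6, 7, 8)] - 1) < 0.05))
  expect_true(all(abs(mr - 1) < 0.10))
})

test_that("identical subjects pool to the common individual covariance", {
  # 4 identical subjects with identical residuals: the pooled standardized
  # residual covariance equals each subject's own, so the corrected meat is
  # exactly 4 copies of the common per-subject term
  y <- rep(c(2, 6), 4)
  des <- list(X = cbind(1, rep(c(0, 1), 4)), subject = factor(rep(1:4, each = 2)))
  fit <- fit_gee_exchangeable(y, des)
  pieces <- mdseq:::gee_pieces(fit)
  s1 <- pieces$sub[[1]]
  Hi <- s1$Di %*% pieces$Binv %*% t(s1$VinvD)
  ei <- solve(diag(2) - Hi, s1$e)
  own <- tcrossprod(ei / sqrt(s1$mu))          # one subject's matrix
  G1 <- sweep(s1$VinvD, 1, sqrt(s1$mu), "*")
  single_subject_version <- pieces$Binv %*% (4 * t(G1) %*% own %*% G1) %*%
    pieces$Binv
  expect_equal(fit$wl_cov, (single_subject_version +
                              t(single_subject_version)) / 2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("unequal cluster sizes are rejected by the pooled correction", {
  set.seed(6)
  y <- rpois(7, 15)
  des <- list(X = matrix(1, 7, 1), subject = factor(c(1, 1, 1, 2, 2, 3, 3)))
  fit <- fit_gee_exchangeable(y, des)
  expect_error(small_sample_covariance(fit), "equal cluster sizes")
})
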