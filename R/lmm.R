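## Linear mixed model with a single subject random intercept, fitted by REML
## with the variance ratio gamma = sigma2_b / sigma2_e profiled out. Optional
## observation weights (used by the pseudo-likelihood NB fitter) give
## Var(e_ij) = sigma2_e / w_ij.
##
## All per-subject sums use the Woodbury identity on
## V*_i = W_i^{-1} + gamma 11', so one criterion evaluation is a handful of
## crossproducts and never forms an N x N matrix.

lmm_sums <- function(gamma, y, X, subj, w) {
  Xw <- X * w
  Sxx <- crossprod(Xw, X)
  Sxy <- crossprod(Xw, y)
  Syy <- sum(w * y^2)
  ldV <- -sum(log(w))
  s_i <- rowsum(w, subj)
  u <- rowsum(Xw, subj)                 # m x p, rows = subject totals X'w
  a <- rowsum(w * y, subj)
  if (gamma > 0) {
    ci <- as.vector(gamma / (1 + gamma * s_i))
    Sxx <- Sxx - crossprod(u, u * ci)
    Sxy <- Sxy - crossprod(u, a * ci)
    Syy <- Syy - sum(ci * a^2)
    ldV <- ldV + sum(log1p(gamma * s_i))
  }
  list(Sxx = Sxx, Sxy = Sxy, Syy = Syy, ldV = ldV,
       s_i = s_i, u = u, a = a)
}

## -2 REML log-likelihood with sigma2_e profiled out, as a function of gamma.
lmm_profile_crit <- function(gamma, y, X, subj, w, n, p) {
  s <- lmm_sums(gamma, y, X, subj, w)
  ch <- tryCatch(chol(s$Sxx), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), s$Sxy))
  rss <- s$Syy - sum(beta * s$Sxy)
  if (!is.finite(rss) || rss <= 0) return(list(crit = Inf))
  s2e <- rss / (n - p)
  crit <- (n - p) * (1 + log(2 * pi) + log(s2e)) + s$ldV +
    2 * sum(log(diag(ch)))
  list(crit = crit, beta = as.vector(beta), s2e = s2e, sums = s, chol = ch)
}

## -2 REML log-likelihood as a function of theta = (sigma2_b, sigma2_e);
## needed for the variance-parameter covariance behind Satterthwaite DF.
lmm_crit_theta <- function(theta, y, X, subj, w, n, p) {
  s2b <- theta[1]
  s2e <- theta[2]
  if (s2e <= 0 || s2b < 0) return(Inf)
  s <- lmm_sums(s2b / s2e, y, X, subj, w)
  ch <- tryCatch(chol(s$Sxx), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), s$Sxy))
  rss <- s$Syy - sum(beta * s$Sxy)
  if (!is.finite(rss) || rss < 0) return(Inf)
  (n - p) * log(2 * pi) + (n - p) * log(s2e) + s$ldV +
    2 * sum(log(diag(ch))) + rss / s2e
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits y = X beta + b_subject + e with b ~ N(0, sigma2_b) and
#' e ~ N(0, sigma2_e / w) by restricted maximum likelihood, profiling the
#' variance ratio. A fit with the random-intercept variance on the boundary
#' (intraclass fraction below `singular_tol`) is flagged `singular`, the
#' convention this study counts as non-convergence.
#'
#' @param y Numeric response vector (one gene's transformed values).
#' @param design A `study_design`, or a list with elements `X` (design
#'   matrix) and `subject` (factor).
#' @param weights Optional positive observation weights.
#' @param singular_tol Boundary threshold on sigma2_b / (sigma2_b + sigma2_e).
#' @param lgamma_interval Search interval for log(sigma2_b / sigma2_e).
#' @return A list of class `lmm_fit`: `coef`, `coef_cov`, `sigma2_b`,
#'   `sigma2_e`, `loglik` (REML), `converged`, `singular`, `blups`, plus the
#'   internals used for Satterthwaite degrees of freedom.
#' @export
fit_lmm_reml <- function(y, design, weights = NULL, singular_tol = 1e-6,
                         lgamma_interval = c(-13, 13)) {
  di <- fit_inputs(design)
  X <- di$X
  subj <- di$subject
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(subj) == n, n > p)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(all(w > 0), length(w) == n)
  if (stats::var(y) == 0 || qr(X)$rank < p) {
    return(structure(list(coef = rep(NA_real_, p), converged = FALSE,
                          singular = TRUE, method = "lmm"),
                     class = "lmm_fit"))
  }
  f <- function(lg) lmm_profile_crit(exp(lg), y, X, subj, w, n, p)$crit
  opt <- stats::optimize(f, interval = lgamma_interval)
  at0 <- lmm_profile_crit(0, y, X, subj, w, n, p)
  if (at0$crit <= opt$objective) {
    gamma <- 0
    sol <- at0
  } else {
    gamma <- exp(opt$minimum)
    sol <- lmm_profile_crit(gamma, y, X, subj, w, n, p)
  }
  s2e <- sol$s2e
  s2b <- gamma * s2e
  icc <- s2b / (s2b + s2e)
  beta <- sol$beta
  names(beta) <- colnames(X)
  cov <- s2e * chol2inv(sol$chol)
  dimnames(cov) <- list(colnames(X), colnames(X))
  # BLUPs: b_i = gamma * sum_j w_ij r_ij / (1 + gamma s_i)
  r <- y - X %*% beta
  num <- rowsum(w * as.vector(r), subj)
  blups <- as.vector(gamma * num / (1 + gamma * sol$sums$s_i))
  names(blups) <- rownames(num)
  structure(list(
    coef = beta,
    coef_cov = cov,
    sigma2_b = s2b,
    sigma2_e = s2e,
    loglik = -sol$crit / 2,
    converged = is.finite(sol$crit),
    singular = icc < singular_tol,
    n_iter = NA_integer_,
    blups = blups,
    method = "lmm",
    y = y, X = X, subject = subj, weights = w, n = n, p = p,
    cache = new.env(parent = emptyenv())
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: sigma2_b = %.4g, sigma2_e = %.4g, REML loglik = %.3f%s\n",
              x$sigma2_b, x$sigma2_e, x$loglik,
              if (isTRUE(x$singular)) " (singular)" else ""))
  invisible(x)
}

## Coefficient covariance at an arbitrary theta = (s2b, s2e); used to take
## numeric derivatives of contrast variances with respect to the variance
## parameters.
lmm_cov_at <- function(fit, theta) {
  s <- lmm_sums(theta[1] / theta[2], fit$y, fit$X, fit$subject, fit$weights)
  theta[2] * solve(s$Sxx)
}

## Asymptotic covariance of theta-hat = (s2b, s2e): 2 * inverse Hessian of the
## -2 REML log-likelihood. Cached on the fit's environment-free list via attr.
lmm_vcov_theta <- function(fit) {
  theta <- c(fit$sigma2_b, fit$sigma2_e)
  crit <- function(th) lmm_crit_theta(th, fit$y, fit$X, fit$subject,
                                      fit$weights, fit$n, fit$p)
  H <- tryCatch(
    stats::optimHess(theta, crit,
                     control = list(ndeps = pmax(1e-8, theta * 1e-4))),
    error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) return(NULL)
  V
}

#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' Computes the effective denominator degrees of freedom of the F statistic
#' for H0: L beta = 0 from a random-intercept LMM fit. For a single contrast
#' l, DF = 2 (l' C l)^2 / Var(l' C l) with the variance obtained by the delta
#' method over the REML variance parameters; multi-row contrasts are combined
#' through the eigendecomposition of L C L' and the moment-matching rule
#' DF = 2 E / (E - q) with E = sum_m nu_m / (nu_m - 2).
#'
#' When the random-intercept variance is on the boundary the statistic
#' reduces to its ordinary least squares form and the residual DF (n - p) is
#' returned; the same fallback (with a warning) is used if the
#' variance-parameter covariance is not positive definite.
#'
#' @param fit An `lmm_fit` from [fit_lmm_reml()].
#' @param L Contrast matrix (q x p, full row rank) or a single contrast vector.
#' @return Positive denominator degrees of freedom (scalar).
#' @export
satterthwaite_df <- function(fit, L) {
  if (!inherits(fit, "lmm_fit") || !isTRUE(fit$converged))
    stop("satterthwaite_df requires a converged lmm_fit")
  L <- rbind(L)
  q <- nrow(L)
  resid_df <- fit$n - fit$p
  if (fit$singular || fit$sigma2_b <= 0) return(resid_df)
  cache <- fit$cache
  if (!is.null(cache) && !is.null(cache$A)) {
    A <- cache$A
    Cp <- cache$Cp
    Cm <- cache$Cm
    hh <- cache$hh
  } else {
    A <- lmm_vcov_theta(fit)
    if (is.null(A)) {
      warning("variance-parameter covariance not positive definite; ",
              "falling back to residual degrees of freedom")
      return(resid_df)
    }
    theta <- c(fit$sigma2_b, fit$sigma2_e)
    h <- pmax(theta * 1e-4, 1e-8)
    # central-difference coefficient covariances, reused by every contrast row
    Cp <- list(lmm_cov_at(fit, theta + c(h[1], 0)),
               lmm_cov_at(fit, theta + c(0, h[2])))
    Cm <- list(lmm_cov_at(fit, pmax(theta - c(h[1], 0), c(0, 1e-12))),
               lmm_cov_at(fit, pmax(theta - c(0, h[2]), c(0, 1e-12))))
    hh <- c(theta[1] - pmax(theta[1] - h[1], 0),
            theta[2] - pmax(theta[2] - h[2], 1e-12)) + h
    if (!is.null(cache)) {
      cache$A <- A
      cache$Cp <- Cp
      cache$Cm <- Cm
      cache$hh <- hh
    }
  }
  one_df <- function(l) {
    f <- as.vector(t(l) %*% fit$coef_cov %*% l)
    g <- vapply(1:2, function(k)
      (as.vector(t(l) %*% Cp[[k]] %*% l) - as.vector(t(l) %*% Cm[[k]] %*% l)) / hh[k],
      numeric(1))
    den <- as.vector(t(g) %*% A %*% g)
    if (den <= 0) return(Inf)
    2 * f^2 / den
  }
  if (q == 1) {
    nu <- one_df(as.vector(L))
    return(if (is.finite(nu)) max(nu, 1) else resid_df)
  }
  VL <- L %*% fit$coef_cov %*% t(L)
  e <- eigen((VL + t(VL)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  P <- e$vectors[, pos, drop = FALSE]
  contr <- t(P) %*% L                       # rows: independent 1-df contrasts
  nus <- apply(contr, 1, one_df)
  nus <- nus[is.finite(nus)]
  E <- sum(nus[nus > 2] / (nus[nus > 2] - 2))
  if (length(nus) == 0 || E <= q) return(resid_df)
  max(2 * E / (E - q), 1)
}
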