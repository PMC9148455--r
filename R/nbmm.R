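#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights of the n-point Gauss-Hermite rule for integrals against
#' exp(-x^2), computed by the Golub-Welsch eigenvalue method.
#'
#' @param n Number of nodes (>= 1).
#' @return List with numeric vectors `x` (nodes) and `w` (weights).
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Marginal log-likelihood of a NB random-intercept model by adaptive quadrature
#'
#' Evaluates the marginal log-likelihood of counts under a negative binomial
#' model with log link, fixed effects `beta`, per-sample `offsets`, and a
#' subject random intercept with variance `sigma2_b`, integrating each
#' subject's intercept by adaptive Gauss-Hermite quadrature centred at the
#' posterior mode. One node reproduces the Laplace approximation; at
#' `sigma2_b = 0` it equals the plain NB GLM log-likelihood.
#'
#' @param y Integer count vector for one gene.
#' @param design `study_design` or list with `X` and `subject`.
#' @param offsets Per-sample log offsets (default 0).
#' @param beta Fixed-effect coefficients.
#' @param alpha NB dispersion (> 0).
#' @param sigma2_b Random-intercept variance (>= 0).
#' @param n_nodes Number of quadrature nodes (default 11).
#' @return The marginal log-likelihood (scalar).
#' @export
nbmm_loglik_agq <- function(y, design, offsets = NULL, beta, alpha, sigma2_b,
                            n_nodes = 11) {
  stopifnot(alpha > 0, sigma2_b >= 0, n_nodes >= 1)
  di <- fit_inputs(design)
  if (is.null(offsets)) offsets <- rep(0, length(y))
  gh <- gauss_hermite(n_nodes)
  nbmm_agq_loglik_cpp(as.numeric(y), di$X, as.numeric(offsets),
                      as.integer(di$subject) - 1L, nlevels(di$subject),
                      as.numeric(beta), alpha, sigma2_b, gh$x, gh$w)
}

## Moment starting values shared by the NBMM fitters: Poisson GLM coefficients,
## Pearson dispersion, and a between-subject variance from working residuals.
nbmm_start <- function(y, X, subj, offsets) {
  g <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                       offset = offsets))
  beta <- g$coefficients
  beta[!is.finite(beta)] <- 0
  mu <- pmax(exp(as.vector(X %*% beta) + offsets), 1e-8)
  n <- length(y)
  p <- ncol(X)
  alpha <- sum(((y - mu)^2 - mu) / mu^2) / max(n - p, 1)
  alpha <- min(max(alpha, 1e-3), 100)
  d <- log((y + 0.5) / (mu + 0.5))
  s2b <- stats::var(tapply(d, subj, mean))
  s2b <- min(max(s2b, 0.02), 10)
  list(beta = beta, alpha = alpha, s2b = s2b, mu = mu)
}

#' Fit a negative binomial mixed model by adaptive Gauss-Hermite quadrature
#'
#' Maximizes the AGQ marginal likelihood over (beta, log alpha, log sigma2_b)
#' by box-constrained quasi-Newton (the optimization loop runs in compiled
#' code with warm-started posterior modes). The coefficient covariance, when
#' requested, is the corresponding block of the inverse observed information.
#' With `n_nodes = 1` this is the Laplace-approximation fit.
#'
#' @param y Integer count vector for one gene.
#' @param design `study_design` or list with `X` and `subject`.
#' @param offsets Per-sample log offsets (default 0).
#' @param n_nodes Quadrature nodes (default 11).
#' @param max_eval Maximum optimizer iterations.
#' @param singular_tol sigma2_b below this is flagged singular.
#' @param start Optional starting values `list(beta, alpha, s2b)` (e.g. from
#'   a full-model fit when refitting a nested reduced model).
#' @param hessian Compute the observed-information coefficient covariance
#'   (skippable for likelihood-ratio-only workflows).
#' @return A list of class `nbmm_fit`: `coef`, `coef_cov`, `alpha`,
#'   `sigma2_b`, `loglik`, `converged`, `singular`, `n_iter`.
#' @export
fit_nbmm_agq <- function(y, design, offsets = NULL, n_nodes = 11,
                         max_eval = 500, singular_tol = 1e-8, start = NULL,
                         hessian = TRUE) {
  di <- fit_inputs(design)
  X <- di$X
  subj <- di$subject
  p <- ncol(X)
  if (is.null(offsets)) offsets <- rep(0, length(y))
  fail <- function() structure(list(coef = rep(NA_real_, p), converged = FALSE,
                                    singular = FALSE, method = "nbmm-agq"),
                               class = "nbmm_fit")
  if (stats::var(y) == 0) {
    out <- fail()
    out$singular <- TRUE
    return(out)
  }
  if (is.null(start)) {
    start <- tryCatch(nbmm_start(y, X, subj, offsets), error = function(e) NULL)
    if (is.null(start)) return(fail())
  }
  gh <- gauss_hermite(n_nodes)
  si <- as.integer(subj) - 1L
  ns <- nlevels(subj)
  yn <- as.numeric(y)
  offs <- as.numeric(offsets)
  par0 <- c(pmin(pmax(start$beta, -29), 29),
            log(min(max(start$alpha, 2e-6), 900)),
            log(min(max(start$s2b, singular_tol * 2), 45)))
  lower <- c(rep(-30, p), log(1e-6), log(singular_tol))
  upper <- c(rep(30, p), log(1e3), log(50))
  opt <- tryCatch(
    nbmm_agq_fit_cpp(yn, X, offs, si, ns, par0, lower, upper, gh$x, gh$w,
                     as.integer(max_eval)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) return(fail())
  par <- opt$par
  beta <- par[1:p]
  names(beta) <- colnames(X)
  cov <- NULL
  if (hessian) {
    negll <- function(pp) {
      ll <- nbmm_agq_loglik_cpp(yn, X, offs, si, ns, pp[1:p], exp(pp[p + 1]),
                                exp(pp[p + 2]), gh$x, gh$w)
      if (is.finite(ll)) -ll else 1e10
    }
    cov <- tryCatch({
      H <- stats::optimHess(par, negll)
      solve(H)[1:p, 1:p, drop = FALSE]
    }, error = function(e) matrix(NA_real_, p, p))
    dimnames(cov) <- list(colnames(X), colnames(X))
  }
  structure(list(
    coef = beta,
    coef_cov = cov,
    alpha = exp(par[p + 1]),
    sigma2_b = exp(par[p + 2]),
    loglik = -opt$value,
    converged = opt$convergence == 0,
    singular = exp(par[p + 2]) <= singular_tol * 1.01,
    n_iter = opt$fncount,
    n_nodes = n_nodes,
    method = "nbmm-agq"
  ), class = "nbmm_fit")
}

#' @export
print.nbmm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("nbmm_fit (", x$method, "): not converged\n")
    return(invisible(x))
  }
  cat(sprintf("nbmm_fit (%s): alpha = %.4g, sigma2_b = %.4g, loglik = %.3f%s\n",
              x$method, x$alpha, x$sigma2_b, x$loglik,
              if (isTRUE(x$singular)) " (singular)" else ""))
  invisible(x)
}

#' Fit a negative binomial mixed model by pseudo-likelihood
#'
#' Iteratively linearizes the NB GLMM into a weighted linear mixed model:
#' with conditional mean mu = exp(eta + b), the working response is
#' z = eta_linear + (y - mu) / mu with weights w = mu / (1 + alpha mu); a
#' weighted REML random-intercept fit updates (beta, sigma2_b, b), and the
#' dispersion alpha is updated by matching the conditional Pearson chi-square
#' to its degrees of freedom. Iteration stops when the relative change in
#' (beta, sigma2_b, alpha) falls below `tol`. The returned fit carries the
#' final weighted LMM so F tests can use Satterthwaite denominator degrees of
#' freedom.
#'
#' @param y Integer count vector for one gene.
#' @param design `study_design` or list with `X` and `subject`.
#' @param offsets Per-sample log offsets (default 0).
#' @param max_iter Maximum outer iterations (default 200).
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param singular_tol Boundary threshold on the intraclass fraction.
#' @return A list of class `c("nbmm_pl_fit", "lmm_fit")` with `coef`,
#'   `coef_cov`, `alpha`, `sigma2_b`, `converged`, `singular`, `n_iter`, and
#'   the embedded weighted LMM internals.
#' @export
fit_nbmm_pl <- function(y, design, offsets = NULL, max_iter = 200, tol = 1e-8,
                        singular_tol = 1e-6) {
  di <- fit_inputs(design)
  X <- di$X
  subj <- di$subject
  n <- length(y)
  p <- ncol(X)
  if (is.null(offsets)) offsets <- rep(0, n)
  fail <- function(singular = FALSE)
    structure(list(coef = rep(NA_real_, p), converged = FALSE,
                   singular = singular, method = "nbmm-pl"),
              class = c("nbmm_pl_fit", "lmm_fit"))
  if (stats::var(y) == 0) return(fail(singular = TRUE))
  st <- tryCatch(nbmm_start(y, X, subj, offsets), error = function(e) NULL)
  if (is.null(st)) return(fail())
  beta <- st$beta
  alpha <- st$alpha
  s2b <- st$s2b
  b <- rep(0, nlevels(subj))
  lfit <- NULL
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta) + offsets + b[as.integer(subj)]
    mu <- pmax(exp(pmin(eta, 30)), 1e-8)
    z <- eta - offsets + (y - mu) / mu
    w <- mu / (1 + alpha * mu)
    lfit <- fit_lmm_reml(z, list(X = X, subject = subj), weights = w,
                         singular_tol = singular_tol)
    if (!isTRUE(lfit$converged)) return(fail())
    beta_new <- lfit$coef
    s2b_new <- lfit$sigma2_b
    b <- lfit$blups
    # Pearson moment update: solve sum (y-mu)^2 / (mu (1 + a mu)) = n - p
    eta <- as.vector(X %*% beta_new) + offsets + b[as.integer(subj)]
    mu <- pmax(exp(pmin(eta, 30)), 1e-8)
    pear <- function(a) sum((y - mu)^2 / (mu * (1 + a * mu))) - (n - p)
    alpha_new <- if (pear(1e-8) <= 0) 1e-8
      else if (pear(1e4) >= 0) 1e4
      else stats::uniroot(pear, c(1e-8, 1e4), tol = 1e-10)$root
    delta <- max(abs(c(beta_new - beta, s2b_new - s2b, alpha_new - alpha)) /
                   (abs(c(beta, s2b, alpha)) + 1e-4))
    beta <- beta_new
    s2b <- s2b_new
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  out <- lfit
  out$coef <- beta
  out$alpha <- alpha
  out$sigma2_b <- s2b
  out$converged <- converged
  out$n_iter <- iter
  out$method <- "nbmm-pl"
  class(out) <- c("nbmm_pl_fit", "lmm_fit")
  out
}
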