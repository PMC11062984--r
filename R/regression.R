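# Individual-level regressions: beta regression with logit link for the
# relative niche index (a proportion in (0,1)) and a Gamma GLM with
# identity link for absolute ellipse areas (positive, right-skewed). Both
# are fitted by Fisher scoring with step-halving, so the fit trace is
# monotone by construction; standard errors come from the observed
# information (numerical Hessian of the log-likelihood at the optimum).

#' Compress proportions away from the boundary
#'
#' The standard transform \eqn{y' = (y (N - 1) + 0.5)/N}, where N is the
#' number of observations; maps \[0, 1\] into (0, 1). A lone individual has
#' relative niche index exactly 1, which a beta likelihood cannot score.
#'
#' @param y Proportions in \[0, 1\].
#' @return Adjusted proportions strictly inside (0, 1).
#' @export
squeeze_proportions <- function(y) {
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}

.beta_loglik <- function(y, mu, phi) {
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Beta regression with logit link and constant precision
#'
#' Maximum-likelihood fit of \eqn{y_i \sim Beta(\mu_i \phi, (1-\mu_i)\phi)}
#' with \eqn{logit(\mu_i) = x_i^T \beta}, by Fisher scoring alternating
#' beta and phi updates under step-halving (the log-likelihood trace is
#' non-decreasing). Wald standard errors use the observed information.
#'
#' If any response equals 0 or 1 exactly the boundary compression
#' [squeeze_proportions()] is applied (with a message); values outside
#' \[0, 1\] are an error.
#'
#' @param data A data frame containing the model variables.
#' @param formula Model formula, e.g. `relative_index ~ species + n_sections`.
#' @param max_iter Maximum scoring iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return An object of class `beta_reg` with elements `coefficients`
#'   (tidy tibble incl. phi), `loglik`, `trace`, `n`, `converged`,
#'   `family_link = "beta(logit)"`.
#' @export
beta_regression <- function(data, formula, max_iter = 200, tol = 1e-10) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, data = mf)
  if (any(y < 0 | y > 1)) {
    abort("responses must lie in [0, 1]", class = "isoniche_domain_error")
  }
  if (any(y == 0 | y == 1)) {
    inform("boundary responses detected; applying (y*(N-1)+0.5)/N compression")
    y <- squeeze_proportions(y)
  }
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient", class = "isoniche_rank_error")
  }
  n <- length(y)
  p <- ncol(X)
  ystar <- stats::qlogis(y)
  # initial beta from an OLS fit on the logit scale; phi by moments
  beta <- unname(stats::lm.fit(X, ystar)$coefficients)
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  e <- ystar - eta
  sig2 <- sum(e^2) / max(n - p, 1) * (mu * (1 - mu))^2
  phi <- max(mean(mu * (1 - mu) / pmax(sig2, 1e-8)) - 1, 1)
  ll <- .beta_loglik(y, mu, phi)
  trace <- ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # --- beta step (Fisher scoring with step-halving) ---
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    Tm <- mu * (1 - mu)                     # dmu/deta under logit
    score_b <- phi * drop(crossprod(X, Tm * (ystar - mustar)))
    w <- phi * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * Tm^2
    K_bb <- phi * crossprod(X, X * w)
    step <- solve(K_bb, score_b)
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      mu_new <- stats::plogis(drop(X %*% beta_new))
      ll_new <- .beta_loglik(y, mu_new, phi)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { beta_new <- beta; mu_new <- mu; ll_new <- ll; break }
    }
    beta <- beta_new; mu <- mu_new; ll <- ll_new
    # --- phi step (Newton with step-halving) ---
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    score_p <- sum(mu * (ystar - mustar) + log(1 - y) -
                     digamma((1 - mu) * phi) + digamma(phi))
    K_pp <- sum(trigamma(mu * phi) * mu^2 +
                  trigamma((1 - mu) * phi) * (1 - mu)^2 - trigamma(phi))
    dphi <- score_p / K_pp
    lam <- 1
    repeat {
      phi_new <- phi + lam * dphi
      ll_new <- if (phi_new > 0) .beta_loglik(y, mu, phi_new) else -Inf
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { phi_new <- phi; ll_new <- ll; break }
    }
    phi <- phi_new
    ll_prev <- tail(trace, 1)
    ll <- ll_new
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    grad <- sqrt(sum(score_b^2) + score_p^2)
    abort(sprintf("beta regression did not converge (gradient norm %.3g)",
                  grad), class = "isoniche_convergence_error")
  }
  # observed information at the optimum, over (beta, log phi)
  beta <- unname(beta)
  nll <- function(par) {
    mu_ <- stats::plogis(drop(X %*% par[1:p]))
    -.beta_loglik(y, mu_, exp(par[p + 1]))
  }
  H <- optimHess(c(beta, log(phi)), nll)
  V <- solve(H)
  se <- unname(sqrt(diag(V))[1:p])
  se_logphi <- sqrt(diag(V))[p + 1]
  z <- beta / se
  coefs <- tibble(
    term = c(colnames(X), "(phi)"),
    estimate = c(unname(beta), phi),
    std_error = c(se, phi * se_logphi),
    statistic = c(z, NA_real_),
    p_value = c(2 * pnorm(-abs(z)), NA_real_),
    conf_low = c(beta - qnorm(0.975) * se, phi * exp(-qnorm(0.975) * se_logphi)),
    conf_high = c(beta + qnorm(0.975) * se, phi * exp(qnorm(0.975) * se_logphi)))
  structure(list(coefficients = coefs, phi = phi, loglik = ll,
                 trace = trace, n = n, converged = converged,
                 family_link = "beta(logit)", formula = formula),
            class = "beta_reg")
}

#' @export
print.beta_reg <- function(x, ...) {
  cat(sprintf("Beta regression (logit link), n = %d, logLik = %.3f, phi = %.3f\n",
              x$n, x$loglik, x$phi))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @method tidy beta_reg
#' @export
tidy.beta_reg <- function(x, ...) x$coefficients

#' @method glance beta_reg
#' @export
glance.beta_reg <- function(x, ...) {
  tibble(logLik = x$loglik, phi = x$phi, n = x$n,
         iterations = length(x$trace) - 1, converged = x$converged)
}

.gamma_deviance <- function(y, mu) {
  2 * sum(-log(y / mu) + (y - mu) / mu)
}

#' Gamma GLM with identity link
#'
#' Maximum-likelihood fit of a Gamma generalised linear model with identity
#' link, \eqn{E[y_i] = x_i^T \beta}, by Fisher scoring with step-halving:
#' any step that drives a fitted mean non-positive or increases the deviance
#' is halved (and the fit aborts if halving cannot resolve it). Standard
#' errors use the expected information scaled by the Pearson dispersion, and
#' inference is on the t distribution with n - p degrees of freedom.
#'
#' @param data A data frame containing the model variables.
#' @param formula Model formula with a strictly positive response.
#' @param max_iter Maximum scoring iterations.
#' @param tol Convergence tolerance on the relative deviance change.
#' @return An object of class `gamma_glm_id` with `coefficients`, `deviance`,
#'   `trace` (deviance per iteration, non-increasing), `dispersion`, `shape`,
#'   `n`, `converged`, `family_link = "Gamma(identity)"`.
#' @export
gamma_glm_identity <- function(data, formula, max_iter = 100, tol = 1e-10) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, data = mf)
  if (any(y <= 0)) {
    abort("Gamma responses must be strictly positive",
          class = "isoniche_domain_error")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient", class = "isoniche_rank_error")
  }
  n <- length(y)
  p <- ncol(X)
  # start at the intercept-only fit (guaranteed positive means), or OLS if valid
  beta <- unname(stats::lm.fit(X, y)$coefficients)
  if (any(drop(X %*% beta) <= 0)) {
    beta <- rep(0, p)
    has_int <- "(Intercept)" %in% colnames(X)
    beta[if (has_int) which(colnames(X) == "(Intercept)") else 1] <- mean(y)
  }
  mu <- drop(X %*% beta)
  dev <- .gamma_deviance(y, mu)
  trace <- dev
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- 1 / mu^2
    XtDX <- crossprod(X, X * D)
    step <- solve(XtDX, drop(crossprod(X, D * (y - mu))))
    lam <- 1
    ok <- FALSE
    for (h in 1:50) {
      beta_new <- beta + lam * step
      mu_new <- drop(X %*% beta_new)
      if (all(mu_new > 0)) {
        dev_new <- .gamma_deviance(y, mu_new)
        if (dev_new <= dev + 1e-12) { ok <- TRUE; break }
      }
      lam <- lam / 2
    }
    if (!ok) {
      if (max(abs(step)) < 1e-8) { converged <- TRUE; break }
      abort("identity-link fitted means driven non-positive; step-halving failed",
            class = "isoniche_convergence_error")
    }
    improved <- dev - dev_new
    beta <- beta_new; mu <- mu_new; dev <- dev_new
    trace <- c(trace, dev)
    if (improved < tol * (abs(dev) + tol)) { converged <- TRUE; break }
  }
  dispersion <- sum(((y - mu) / mu)^2) / (n - p)
  V <- solve(crossprod(X, X / mu^2)) * dispersion
  se <- unname(sqrt(diag(V)))
  tval <- beta / se
  pv <- 2 * pt(-abs(tval), df = n - p)
  ci <- qt(0.975, df = n - p) * se
  coefs <- tibble(term = colnames(X), estimate = unname(beta),
                  std_error = se, statistic = tval, p_value = pv,
                  conf_low = unname(beta) - ci, conf_high = unname(beta) + ci)
  structure(list(coefficients = coefs, deviance = dev, trace = trace,
                 dispersion = dispersion, shape = 1 / dispersion,
                 fitted = mu, n = n, converged = converged,
                 family_link = "Gamma(identity)", formula = formula),
            class = "gamma_glm_id")
}

#' @importFrom stats pt qt
#' @export
print.gamma_glm_id <- function(x, ...) {
  cat(sprintf("Gamma GLM (identity link), n = %d, deviance = %.4f, dispersion = %.4f\n",
              x$n, x$deviance, x$dispersion))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @method tidy gamma_glm_id
#' @export
tidy.gamma_glm_id <- function(x, ...) x$coefficients

#' @method glance gamma_glm_id
#' @export
glance.gamma_glm_id <- function(x, ...) {
  tibble(deviance = x$deviance, dispersion = x$dispersion, shape = x$shape,
         n = x$n, iterations = length(x$trace) - 1, converged = x$converged)
}
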