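# Zero-truncated negative binomial regression with log link
#
# The response is a positive count y >= 1 modelled as negative binomial with
# untruncated mean mu = exp(X beta) and size (dispersion) parameter theta,
# conditioned on y >= 1: the NB probability is renormalized by 1 - P(0),
# P(0) = (theta / (theta + mu))^theta. Fitting maximizes the exact truncated
# log-likelihood jointly over (beta, log theta) by quasi-Newton (BFGS) with
# analytic gradients, initialized from a Poisson GLM.

ztnb_loglik <- function(par, y, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  mu <- exp(drop(X %*% beta))
  p0 <- dnbinom(0, mu = mu, size = theta)
  sum(dnbinom(y, mu = mu, size = theta, log = TRUE) - log1p(-p0))
}

ztnb_gradient <- function(par, y, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  # d logL / d mu for the truncated NB
  p0 <- (theta / (theta + mu))^theta
  dmu <- (y - mu) * theta / (mu * (theta + mu)) -
    p0 * theta / ((theta + mu) * (1 - p0))
  gbeta <- unname(drop(crossprod(X, dmu * mu)))
  # d logL / d theta
  dtheta <- digamma(y + theta) - digamma(theta) + log(theta) + 1 -
    log(theta + mu) - (y + theta) / (theta + mu) +
    p0 * (log(theta / (theta + mu)) + mu / (theta + mu)) / (1 - p0)
  c(gbeta, sum(dtheta) * theta)  # chain rule for log-theta
}

#' Zero-truncated negative binomial regression
#'
#' Fits a count regression for strictly positive counts (for example the
#' number of distinct phenotypes a genome encodes across the environments
#' where it is viable, which is at least 1 by construction). The counts are
#' modelled as negative binomial with log link for the untruncated mean and
#' a size (inverse-dispersion) parameter `theta`, conditioned on the count
#' being nonzero.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param start Optional starting values `c(beta, log(theta))`; by default
#'   the coefficients of a Poisson fit and `log(theta) = 0`.
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return An object of class `ztnb` with components `coefficients`,
#'   `theta`, `logLik`, `vcov` (Wald, from the observed information of the
#'   joint `(beta, log theta)` problem), `fitted.values` (untruncated mean),
#'   `converged`, `boundary` and the usual bookkeeping.
#' @examples
#' d <- data.frame(x = rep(0:1, each = 50),
#'                 y = pmax(1, rpois(100, 4)))
#' fit <- ztnb(y ~ x, d)
#' coef(fit)
#' @export
ztnb <- function(formula, data, start = NULL, control = list()) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (any(y < 1)) stop("zero-truncated model requires all counts >= 1")
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  p <- ncol(X)
  boundary <- all(y == 1)
  if (is.null(start)) {
    pfit <- suppressWarnings(glm.fit(X, y, family = poisson()))
    start <- c(pfit$coefficients, 0)
  }
  ll0 <- ztnb_loglik(start, y, X)
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-12,
                          fnscale = -1), control)
  opt <- optim(start, ztnb_loglik, ztnb_gradient, y = y, X = X,
               method = "BFGS", control = ctrl)
  est <- unname(opt$par)
  H <- tryCatch(optimHess(est, ztnb_loglik, ztnb_gradient, y = y, X = X),
                error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(-H), error = function(e)
      matrix(NA_real_, p + 1, p + 1))
  else matrix(NA_real_, p + 1, p + 1)
  cf <- setNames(est[seq_len(p)], colnames(X))
  converged <- (opt$convergence == 0) && !boundary
  if (boundary)
    warning("all counts equal 1: boundary fit, size parameter unidentified")
  mu <- exp(drop(X %*% cf))
  dimnames(V) <- list(c(colnames(X), "log_theta"),
                      c(colnames(X), "log_theta"))
  structure(list(
    coefficients = cf,
    theta = exp(est[p + 1]),
    logLik = opt$value,
    logLik_start = ll0,
    vcov_full = V,
    vcov = V[seq_len(p), seq_len(p), drop = FALSE],
    fitted.values = mu,
    y = y, X = X,
    n_obs = length(y),
    converged = converged,
    boundary = boundary,
    call = match.call(),
    formula = formula,
    terms = attr(mf, "terms")
  ), class = "ztnb")
}

#' @export
coef.ztnb <- function(object, ...) object$coefficients

#' @export
vcov.ztnb <- function(object, ...) object$vcov

#' @export
logLik.ztnb <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.ztnb <- function(object, ...) object$n_obs

#' @export
print.ztnb <- function(x, ...) {
  cat("Zero-truncated negative binomial regression (log link)\n")
  cat("Call:", deparse(x$call), "\n\nCoefficients:\n")
  print(round(x$coefficients, 4))
  cat("theta (size):", formatC(x$theta, digits = 4), "  logLik:",
      formatC(x$logLik, digits = 6), "  n:", x$n_obs, "\n")
  if (!x$converged) cat("** fit did not converge **\n")
  invisible(x)
}

#' @export
summary.ztnb <- function(object, ...) {
  wt <- wald_table(object)
  structure(list(call = object$call, table = wt, theta = object$theta,
                 logLik = object$logLik, n_obs = object$n_obs,
                 converged = object$converged), class = "summary.ztnb")
}

#' @export
print.summary.ztnb <- function(x, ...) {
  cat("Zero-truncated negative binomial regression (log link)\n")
  cat("Call:", deparse(x$call), "\n\n")
  tb <- x$table
  tb[, -1] <- lapply(tb[, -1], function(v) signif(v, 4))
  print(tb, row.names = FALSE)
  cat("\ntheta (size):", formatC(x$theta, digits = 4),
      "  logLik:", formatC(x$logLik, digits = 6),
      "  n:", x$n_obs, "\n")
  invisible(x)
}

#' Predict from a zero-truncated negative binomial fit
#'
#' @param object A `ztnb` fit.
#' @param newdata Optional data frame.
#' @param type `"link"` (linear predictor), `"response"` (untruncated mean
#'   `mu`), or `"truncated"` (mean of the zero-truncated distribution,
#'   `mu / (1 - P(0))`).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.ztnb <- function(object, newdata = NULL,
                         type = c("link", "response", "truncated"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X
       else model.matrix(delete.response(terms(object$formula)), newdata)
  eta <- unname(drop(X %*% object$coefficients))
  if (type == "link") return(eta)
  mu <- exp(eta)
  if (type == "response") return(mu)
  p0 <- dnbinom(0, mu = mu, size = object$theta)
  mu / (1 - p0)
}

#' @export
fitted.ztnb <- function(object, ...) object$fitted.values

#' @export
residuals.ztnb <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted.values
  th <- object$theta
  p0 <- dnbinom(0, mu = mu, size = th)
  m_t <- mu / (1 - p0)  # truncated mean
  r <- object$y - m_t
  if (type == "response") return(r)
  # truncated variance
  v <- (mu + mu^2 * (1 + 1 / th)) / (1 - p0) - m_t^2
  r / sqrt(v)
}

#' Simulate from a zero-truncated negative binomial fit
#'
#' Draws by rejection from the untruncated negative binomial until nonzero.
#'
#' @param object A `ztnb` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.ztnb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  th <- object$theta
  out <- lapply(seq_len(nsim), function(i) rztnb(length(mu), mu, th))
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Random zero-truncated negative binomial deviates
#'
#' @param n Number of draws.
#' @param mu Untruncated mean (recycled).
#' @param theta Size parameter.
#' @return Integer vector of counts >= 1.
#' @export
rztnb <- function(n, mu, theta) {
  mu <- rep_len(mu, n)
  y <- rnbinom(n, mu = mu, size = theta)
  while (any(y == 0)) {
    i <- which(y == 0)
    y[i] <- rnbinom(length(i), mu = mu[i], size = theta)
  }
  y
}
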