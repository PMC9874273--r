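# Negative-binomial random-intercept GLMM, fitted by maximising the
# marginal likelihood with adaptive Gauss-Hermite quadrature. NB2
# parameterisation throughout: Var(y) = mu + mu^2/theta, log link, one
# Gaussian random intercept per fish.

log_sum_exp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Per-observation NB2 log-mass at linear predictor eta (+ group intercept b).
nb_logmass <- function(y, eta, theta) {
  dnbinom(y, mu = exp(eta), size = theta, log = TRUE)
}

#' Marginal log-likelihood of the NB random-intercept model
#'
#' Evaluates
#' \deqn{\ell = \sum_g \log \int \prod_{i \in g} \mathrm{NB}(y_i \mid
#'   \mu = e^{x_i\beta + b}, \theta)\, \phi(b; 0, \sigma_b^2)\, db}
#' by adaptive Gauss-Hermite quadrature: per group, the integrand's mode is
#' located by Newton iteration and the quadrature rule is recentred and
#' rescaled by the curvature there. With `sigma_b = 0` the integral
#' degenerates and the independent NB log-masses are summed directly.
#'
#' @param beta Fixed-effect coefficient vector (matches columns of `X`).
#' @param theta NB2 dispersion (> 0).
#' @param sigma_b Random-intercept SD (>= 0).
#' @param y Non-negative integer response vector.
#' @param X Design matrix (rows = observations).
#' @param group Grouping factor/vector (one random intercept per level).
#' @param nodes Number of Gauss-Hermite nodes (default 20).
#' @return The marginal log-likelihood (scalar).
#' @export
nb_glmm_loglik <- function(beta, theta, sigma_b, y, X, group, nodes = 20) {
  if (theta <= 0) abort("`theta` must be positive.")
  if (sigma_b < 0) abort("`sigma_b` must be non-negative.")
  eta0 <- drop(X %*% beta)
  g <- as.integer(factor(group, levels = unique(group)))
  if (sigma_b == 0) {
    ll <- sum(nb_logmass(y, eta0, theta))
    if (!is.finite(ll)) abort("non-finite log-likelihood at the supplied parameters.")
    return(ll)
  }
  G <- max(g)
  # Newton iteration for the per-group conditional mode of b
  b_hat <- numeric(G)
  for (it in 1:50) {
    mu <- exp(eta0 + b_hat[g])
    grad_obs <- y - mu * (y + theta) / (mu + theta)
    hess_obs <- -(y + theta) * theta * mu / (mu + theta)^2
    grad <- rowsum(grad_obs, g)[, 1] - b_hat / sigma_b^2
    hess <- rowsum(hess_obs, g)[, 1] - 1 / sigma_b^2
    step <- grad / hess
    # damp large steps to keep exp() in range
    step <- pmax(pmin(step, 5), -5)
    b_hat <- b_hat - step
    if (max(abs(step)) < 1e-12) break
  }
  curv <- -(rowsum(-(y + theta) * theta * exp(eta0 + b_hat[g]) /
                     (exp(eta0 + b_hat[g]) + theta)^2, g)[, 1] -
              1 / sigma_b^2) # = -h''(b_hat) > 0
  gh <- pracma::gaussHermite(nodes)
  s <- sqrt(2 / curv)
  # log integrand at each (group, node)
  contrib <- matrix(NA_real_, G, nodes)
  for (k in seq_len(nodes)) {
    b_k <- b_hat + s * gh$x[k]
    eta <- eta0 + b_k[g]
    h <- rowsum(nb_logmass(y, eta, theta), g)[, 1] +
      dnorm(b_k, 0, sigma_b, log = TRUE)
    contrib[, k] <- log(gh$w[k]) + gh$x[k]^2 + h
  }
  ll <- sum(log(s) + log_sum_exp(contrib))
  if (!is.finite(ll)) {
    abort(sprintf(
      "non-finite log-likelihood (theta=%.3g, sigma_b=%.3g).", theta, sigma_b
    ))
  }
  ll
}

# Build the fixed-effects design matrix for a model specification.
# Numeric covariates are standardised; the attributes carry the transform
# so coefficients can be reported on the original scale.
nb_glmm_design <- function(data, predictor = NULL, interaction = FALSE) {
  terms <- c()
  if ("species" %in% names(data) &&
      length(unique(as.character(data$species))) > 1) {
    terms <- c(terms, "species")
  }
  terms <- c(terms, "body_length", "treatment", "order")
  if (!is.null(predictor)) terms <- c(terms, predictor)
  if (interaction) {
    if (is.null(predictor)) abort("interaction requires a focal predictor.")
    terms <- c(terms, sprintf("%s:treatment", predictor))
  }
  fml <- stats::reformulate(terms)
  mf <- stats::model.frame(fml, data = droplevels(as.data.frame(data)))
  X <- stats::model.matrix(fml, mf)
  # standardise numeric (non-dummy) columns
  centre <- rep(0, ncol(X))
  scale_ <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))[-1]) {
    v <- X[, j]
    if (length(unique(v)) > 2) {
      centre[j] <- mean(v)
      scale_[j] <- sd(v)
      if (scale_[j] == 0) scale_[j] <- 1
      X[, j] <- (v - centre[j]) / scale_[j]
    }
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1, ncol(X))]]
    abort(paste("rank-deficient design; aliased columns:",
                paste(aliased, collapse = ", ")))
  }
  attr(X, "centre") <- centre
  attr(X, "scale") <- scale_
  X
}

#' Fit the NB random-intercept mixed model
#'
#' Maximises [nb_glmm_loglik()] over \eqn{(\beta, \log\theta, \log\sigma_b)}
#' by BFGS from a deterministic start (Poisson GLM coefficients, a
#' moment-based dispersion and a small positive \eqn{\sigma_b}), so
#' refitting the same data is bit-reproducible. Fixed effects always
#' include species (when more than one is present), body length, treatment
#' and trial order; `predictor` adds one focal morphology variable and
#' `interaction` its interaction with treatment. Numeric covariates are
#' standardised internally and coefficients are reported back on the
#' original scale, with standard errors from the inverse numerical Hessian.
#'
#' @param data Tibble with the response, `fish_id`, `species`,
#'   `body_length`, `treatment`, `order` and any focal predictor column.
#'   Non-integer responses are rounded to integer mm first.
#' @param response Response column name (one of the four behaviour means).
#' @param predictor Focal morphology variable, or `NULL` for the null
#'   model (covariates only).
#' @param interaction Include `predictor x treatment`?
#' @param random_intercept Set `FALSE` to constrain \eqn{\sigma_b = 0}:
#'   the model degenerates to a fixed-effects NB GLM fitted by the same
#'   machinery (useful for boundary checks and as a baseline).
#' @param nodes Gauss-Hermite nodes (default 20).
#' @return Object of class `nb_glmm` with elements `coefficients` (tibble
#'   `term`, `estimate`, `std.error`), `theta`, `sigma_b`, `loglik`, `k`,
#'   `n`, `aicc`, `converged`, `diagnostics`, and the fitting context.
#' @seealso [tidy()], [glance()], [compare_to_null()],
#'   [build_support_table()]
#' @export
nb_glmm <- function(data, response, predictor = NULL, interaction = FALSE,
                    random_intercept = TRUE, nodes = 20) {
  if (!response %in% names(data)) abort(sprintf("no column `%s`.", response))
  keep <- c(response, "fish_id", "species", "body_length", "treatment",
            "order", predictor)
  miss <- setdiff(keep, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  data <- tidyr::drop_na(dplyr::select(data, dplyr::all_of(keep)))
  y <- as.numeric(data[[response]])
  if (any(y < 0)) abort("negative responses are not NB-distributed.")
  y <- round(y) # integer mm so the NB mass is proper
  X <- nb_glmm_design(data, predictor, interaction)
  group <- data$fish_id
  p <- ncol(X)

  # deterministic start: Poisson GLM + moment estimate of theta
  start_fit <- stats::glm.fit(X, y, family = stats::poisson())
  beta0 <- start_fit$coefficients
  mu0 <- pmax(start_fit$fitted.values, 1e-8)
  excess <- mean(((y - mu0)^2 - mu0) / mu0^2)
  theta0 <- 1 / max(excess, 1e-2)
  par0 <- c(beta0, log(theta0), if (random_intercept) log(0.2))

  negll <- function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1])
    sigma_b <- if (random_intercept) exp(par[p + 2]) else 0
    tryCatch(
      -nb_glmm_loglik(beta, theta, sigma_b, y, X, group, nodes),
      error = function(e) .Machine$double.xmax / 1e10
    )
  }
  opt <- optim(par0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  grad <- tryCatch(
    pracma::grad(negll, opt$par, heps = 1e-6),
    error = function(e) rep(NA_real_, length(opt$par))
  )
  hess <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
  vcov_std <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)

  beta_std <- opt$par[seq_len(p)]
  theta_hat <- unname(exp(opt$par[p + 1]))
  sigma_hat <- if (random_intercept) unname(exp(opt$par[p + 2])) else 0
  centre <- attr(X, "centre")
  scale_ <- attr(X, "scale")
  # map standardised coefficients back to the original predictor scale
  A <- diag(1 / scale_)
  A[1, ] <- A[1, ] * 0
  A[1, 1] <- 1
  A[1, -1] <- -centre[-1] / scale_[-1]
  beta_raw <- drop(A %*% beta_std)
  se_raw <- if (!is.null(vcov_std)) {
    V <- A %*% vcov_std[seq_len(p), seq_len(p), drop = FALSE] %*% t(A)
    sqrt(pmax(diag(V), 0))
  } else {
    rep(NA_real_, p)
  }
  k <- p + 1 + as.integer(random_intercept) # fixed effects + theta (+ sigma_b)
  n <- length(y)
  ll <- -opt$value
  converged <- opt$convergence == 0 && is.finite(ll)
  structure(
    list(
      coefficients = tibble::tibble(term = colnames(X),
                                    estimate = beta_raw,
                                    std.error = se_raw),
      theta = theta_hat, sigma_b = sigma_hat,
      loglik = ll, k = k, n = n,
      aicc = aicc(ll, k, n),
      converged = converged,
      diagnostics = list(optim_convergence = opt$convergence,
                         grad_norm = sqrt(sum(grad^2)),
                         counts = opt$counts),
      response = response, predictor = predictor,
      interaction = interaction, random_intercept = random_intercept,
      nodes = nodes,
      par_std = opt$par, X_attr = list(centre = centre, scale = scale_,
                                       colnames = colnames(X))
    ),
    class = "nb_glmm"
  )
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf(
    "<nb_glmm> %s ~ %s%s | n = %d fish-trials, theta = %.3g, sigma_b = %.3g\n",
    x$response, x$predictor %||% "(null model)",
    if (x$interaction) " x treatment" else "", x$n, x$theta, x$sigma_b
  ))
  cat(sprintf("  logLik = %.4f, AICc = %.4f, k = %d%s\n", x$loglik, x$aicc,
              x$k, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nb_glmm <- function(x, ...) {
  dplyr::mutate(
    x$coefficients,
    statistic = .data$estimate / .data$std.error,
    p.value = 2 * stats::pnorm(-abs(.data$statistic))
  )
}

#' @exportS3Method generics::glance
glance.nb_glmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AICc = x$aicc, k = x$k, nobs = x$n,
    theta = x$theta, sigma_b = x$sigma_b, converged = x$converged
  )
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + 2k(k+1)/(n - k - 1)}
#'
#' @param loglik Maximised log-likelihood (or an `nb_glmm` fit, from which
#'   `k` and `n` are taken).
#' @param k Parameter count (fixed effects + dispersion + random-intercept
#'   SD).
#' @param n Observation count.
#' @return AICc value.
#' @export
aicc <- function(loglik, k = NULL, n = NULL) {
  if (inherits(loglik, "nb_glmm")) {
    fit <- loglik
    return(aicc(fit$loglik, fit$k, fit$n))
  }
  if (n <= k + 1) abort("AICc undefined: n must exceed k + 1.")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare a candidate model against its null model
#'
#' The null model keeps every covariate but drops the focal predictor (and
#' any interaction). Support follows the \eqn{\Delta AICc \ge 2} rule:
#' a candidate whose AICc undercuts the null's by two or more units is
#' strongly supported (the boundary value 2.0 is inclusive).
#'
#' @param fit,null_fit `nb_glmm` fits of the same response on the same
#'   rows.
#' @return One-row tibble: `delta_aicc` (`AICc_null - AICc_model`) and
#'   `supported`.
#' @export
compare_to_null <- function(fit, null_fit) {
  stopifnot(inherits(fit, "nb_glmm"), inherits(null_fit, "nb_glmm"))
  if (fit$n != null_fit$n) abort("fits use different observation counts.")
  if (fit$response != null_fit$response) abort("fits model different responses.")
  delta <- null_fit$aicc - fit$aicc
  tibble::tibble(delta_aicc = delta, supported = delta >= 2)
}
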