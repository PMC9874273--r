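# shared small fixture: 20 fish x 2 observations
glmm_fixture <- local({
  set.seed(321)
  G <- 20
  X <- cbind(1, rnorm(2 * G), rep(c(0, 1), G))
  colnames(X) <- c("(Intercept)", "x", "treat")
  beta_true <- c(log(100), -0.3, 0.1)
  b <- rep(rnorm(G, 0, 0.3), each = 2)
  y <- rnbinom(2 * G, mu = exp(drop(X %*% beta_true) + b), size = 6)
  list(y = y, X = X, group = rep(1:G, each = 2), beta = beta_true)
})

test_that("sigma_b = 0 reduces the marginal likelihood to independent NB", {
  fx <- glmm_fixture
  direct <- sum(dnbinom(fx$y, mu = exp(drop(fx$X %*% fx$beta)), size = 6,
                        log = TRUE))
  expect_equal(nb_glmm_loglik(fx$beta, 6, 0, fx$y, fx$X, fx$group), direct)
})

test_that("large theta with sigma_b = 0 approaches the Poisson likelihood", {
  fx <- glmm_fixture
  pois <- sum(dpois(fx$y, exp(drop(fx$X %*% fx$beta)), log = TRUE))
  expect_equal(nb_glmm_loglik(fx$beta, 1e8, 0, fx$y, fx$X, fx$group), pois,
               tolerance = 1e-4)
})

test_that("quadrature matches brute-force trapezoid integration", {
  fx <- glmm_fixture
  set.seed(77)
  for (r in 1:15) {
    beta <- fx$beta + runif(3, -0.2, 0.2)
    theta <- runif(1, 2, 20)
    sb <- runif(1, 0.1, 0.8)
    expect_equal(
      nb_glmm_loglik(beta, theta, sb, fx$y, fx$X, fx$group),
      oracle_marginal_loglik(beta, theta, sb, fx$y, fx$X, fx$group),
      tolerance = 1e-6
    )
  }
})

test_that("likelihood domain errors are raised", {
  fx <- glmm_fixture
  expect_error(nb_glmm_loglik(fx$beta, -1, 0.2, fx$y, fx$X, fx$group),
               "theta")
  expect_error(nb_glmm_loglik(fx$beta, 5, -0.1, fx$y, fx$X, fx$group),
               "sigma_b")
})

test_that("data simulated without random effects recover a plain NB GLM", {
  skip_if_not_installed("MASS")
  sim <- sim_study(101, effect_spec(slopes = c(otic_area = -0.25),
                                    sigma_b = 0, theta = 10),
                   n = c(10, 10, 60))
  free_fit <- nb_glmm(sim$trials, "mean_nn", "otic_area")
  expect_lt(free_fit$sigma_b, 0.1)
  fit <- nb_glmm(sim$trials, "mean_nn", "otic_area",
                 random_intercept = FALSE)
  expect_identical(fit$sigma_b, 0)
  expect_equal(fit$k, free_fit$k - 1L)
  ref <- MASS::glm.nb(
    round(mean_nn) ~ species + body_length + treatment + order + otic_area,
    data = sim$trials
  )
  expect_equal(fit$coefficients$estimate,
               unname(coef(ref))[match(fit$coefficients$term,
                                       names(coef(ref)))],
               tolerance = 1e-3)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("the fitted likelihood agrees with an independent mixed-model fit", {
  skip_if_not_installed("glmmTMB")
  sim <- sim_study(55, effect_spec(slopes = c(otic_area = -0.25),
                                   sigma_b = 0.25, theta = 8),
                   n = c(10, 10, 60))
  fit <- nb_glmm(sim$trials, "mean_nn", "otic_area")
  dat <- dplyr::mutate(sim$trials, y = round(.data$mean_nn))
  ref <- glmmTMB::glmmTMB(
    y ~ species + body_length + treatment + order + otic_area +
      (1 | fish_id),
    family = glmmTMB::nbinom2, data = dat
  )
  refco <- glmmTMB::fixef(ref)$cond
  expect_equal(fit$coefficients$estimate,
               unname(refco)[match(fit$coefficients$term, names(refco))],
               tolerance = 5e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 0.05)
  expect_equal(fit$theta, glmmTMB::sigma(ref), tolerance = 0.02)
})

test_that("refitting identical data is bit-identical", {
  sim <- sim_study(7, n = c(5, 5, 20))
  f1 <- nb_glmm(sim$trials, "mean_nn", "otic_area")
  f2 <- nb_glmm(sim$trials, "mean_nn", "otic_area")
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-100, 5, 50), 210 + 60 / 44)
  expect_lt(abs(aicc(-100, 5, 1e6) - (2 * 100 + 2 * 5)), 1e-3)
  expect_error(aicc(-100, 49, 50), "undefined")
  fit <- structure(list(loglik = -100, k = 5, n = 50), class = "nb_glmm")
  expect_equal(aicc(fit), 210 + 60 / 44)
})

test_that("the support rule is inclusive at exactly two AICc units", {
  mk <- function(aicc_val) structure(
    list(aicc = aicc_val, n = 100, response = "mean_nn"), class = "nb_glmm"
  )
  expect_true(compare_to_null(mk(98), mk(100))$supported)
  expect_false(compare_to_null(mk(98.1), mk(100))$supported)
  expect_equal(compare_to_null(mk(98), mk(100))$delta_aicc, 2)
  bad <- structure(list(aicc = 98, n = 99, response = "mean_nn"),
                   class = "nb_glmm")
  expect_error(compare_to_null(bad, mk(100)), "different observation")
})

test_that("adding the true predictor raises the likelihood every time", {
  for (s in 1:5) {
    sim <- sim_study(400 + s, effect_spec(slopes = c(otic_area = -0.4),
                                          sigma_b = 0.15, theta = 10),
                     n = c(8, 8, 40))
    with_pred <- nb_glmm(sim$trials, "mean_nn", "otic_area")
    without <- nb_glmm(sim$trials, "mean_nn")
    expect_gt(with_pred$loglik, without$loglik)
  }
})

test_that("support decisions are invariant to predictor rescaling", {
  sim <- sim_study(9, effect_spec(slopes = c(otic_area = -0.4)),
                   n = c(8, 8, 40))
  dat <- sim$trials
  fit <- nb_glmm(dat, "mean_nn", "otic_area")
  null_fit <- nb_glmm(dat, "mean_nn")
  dat2 <- dplyr::mutate(dat, otic_area = .data$otic_area * 1000)
  fit2 <- nb_glmm(dat2, "mean_nn", "otic_area")
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "otic_area"],
               fit2$coefficients$estimate[fit2$coefficients$term == "otic_area"] * 1000,
               tolerance = 1e-4)
  expect_identical(compare_to_null(fit, null_fit)$supported,
                   compare_to_null(fit2, null_fit)$supported)
})

test_that("rank-deficient designs fail loudly, naming the aliased column", {
  sim <- sim_study(13, n = c(5, 5, 10))
  dat <- dplyr::mutate(sim$trials, otic_area = .data$body_length)
  expect_error(nb_glmm(dat, "mean_nn", "otic_area"), "aliased.*otic_area")
})
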