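test_that("model spec validates its topology", {
  expect_error(path_model_spec(indicators = c("a", "b", "c"), outcome = "a"),
               "outcome")
  expect_error(path_model_spec(indicators = c("a", "b", "c"),
                               error_cov = list(c("a", "z"))),
               "pairs")
  sp <- path_model_spec(indicators = c("a", "b", "c"),
                        error_cov = list(c("a", "b")))
  expect_length(sp$error_cov, 1)
})

test_that("exact factor-structure covariance is recovered with chisq ~ 0", {
  lambda <- c(0.8, 0.7, 0.6)
  gamma <- 0.5
  psi <- c(1 - lambda^2, 1 - gamma^2)  # unit-variance scaling
  S <- oracle_sem_sigma(lambda, gamma, psi)
  vars <- c("x1", "x2", "x3", "tympanic")
  dimnames(S) <- list(vars, vars)
  fit <- fit_path_model(S, n = 500,
                        model = path_model_spec(indicators = vars[1:3]))
  expect_true(fit$converged)
  expect_equal(unname(fit$loadings), lambda, tolerance = 1e-4)
  expect_equal(fit$gamma, gamma, tolerance = 1e-4)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$df, 4 * 5 / 2 - 8)
  # implied covariance is symmetric PD at the optimum
  expect_lt(max(abs(fit$implied - t(fit$implied))), 1e-12)
  expect_gt(min(eigen(fit$implied, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("parameters are recovered from simulated MVN data at n = 5000", {
  set.seed(501)
  lambda <- c(0.939, 0.857, 0.966, 0.305, 0.613, 0.483)
  gamma <- 0.801
  psi <- c(1 - lambda^2, 1 - gamma^2)
  Sigma <- oracle_sem_sigma(lambda, gamma, psi)
  L <- chol(Sigma)
  X <- matrix(rnorm(5000 * 7), 5000) %*% L
  vars <- c(paste0("x", 1:6), "tympanic")
  colnames(X) <- vars
  fit <- fit_path_model(cov(X), n = 5000,
                        model = path_model_spec(indicators = vars[1:6]))
  expect_true(fit$converged)
  # 3 Monte-Carlo SEs; loading SEs at n = 5000 are well under 0.02
  expect_lt(max(abs(fit$std_loadings - lambda)), 0.05)
  expect_lt(abs(fit$std_gamma - gamma), 0.05)
})

test_that("BFGS path agrees with an independent nlminb fit on random inputs", {
  set.seed(502)
  for (rep in 1:20) {
    cfg <- random_sem_cov(k = 4, perturb = 0.08)
    n <- 300
    fit <- fit_path_model(cfg$S, n, model = path_model_spec(
      indicators = rownames(cfg$S)[1:4]))
    alt <- oracle_fit_sem(cfg$S, n)
    expect_lt(abs(fit$discrepancy - alt$value), 1e-6)
    expect_lt(max(abs(unname(fit$loadings) - alt$lambda)), 1e-3)
    expect_lt(abs(fit$gamma - alt$gamma), 1e-3)
  }
})

test_that("refitting a converged fit's implied covariance gives chisq <= 1e-6", {
  set.seed(503)
  cfg <- random_sem_cov(k = 5, perturb = 0.1)
  model <- path_model_spec(indicators = rownames(cfg$S)[1:5])
  fit <- fit_path_model(cfg$S, 400, model = model)
  refit <- fit_path_model(fit$implied, 400, model = model)
  expect_lt(refit$chisq, 1e-6)
})

test_that("standardized loadings stay in [-1, 1] on correlation inputs", {
  set.seed(504)
  for (rep in 1:10) {
    cfg <- random_sem_cov(k = 5, perturb = 0.05)
    R <- cov2cor(cfg$S)
    fit <- suppressWarnings(
      fit_path_model(R, 300, model = path_model_spec(
        indicators = rownames(R)[1:5])))
    if (!fit$heywood) {
      expect_true(all(abs(fit$std_loadings) <= 1 + 1e-8))
      expect_lte(abs(fit$std_gamma), 1 + 1e-8)
    }
  }
})

test_that("indirect effect is exactly direct times the structural path", {
  set.seed(505)
  cfg <- random_sem_cov(k = 6, perturb = 0.05)
  fit <- fit_path_model(cfg$S, 201, model = path_model_spec(
    indicators = rownames(cfg$S)[1:6]))
  eff <- path_effects(fit, digits = Inf)
  k <- 6
  expect_identical(eff$indirect[1:k], eff$direct[1:k] * eff$direct[k + 1])
  # identity path: gamma = 1 maps direct to indirect unchanged
  fake <- fit
  fake$std_gamma <- 1
  eff1 <- path_effects(fake, digits = Inf)
  expect_identical(eff1$indirect[1:k], eff1$direct[1:k])
})

test_that("degenerate inputs are rejected with clear errors", {
  S <- diag(3)
  dimnames(S) <- list(c("a", "b", "tympanic"), c("a", "b", "tympanic"))
  expect_error(fit_path_model(S[1:2, 1:2], 100,
                              model = path_model_spec(indicators = c("a", "b"))),
               "lacks|size")
  Sbad <- matrix(1, 3, 3, dimnames = dimnames(S))
  expect_error(fit_path_model(Sbad, 100,
                              model = path_model_spec(indicators = c("a", "b"))),
               "positive definite")
  expect_error(fit_path_model(S, 2,
                              model = path_model_spec(indicators = c("a", "b"))),
               "n must exceed")
})

test_that("independence null model has its closed forms", {
  expect_equal(independence_null(diag(4), 100)$chisq, 0)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(independence_null(R, 51)$chisq, -50 * log(1 - 0.6^2),
               tolerance = 1e-12)
  expect_equal(independence_null(diag(7), 201)$df, 21)
  expect_error(independence_null(matrix(1, 2, 2), 100), "singular")
})

test_that("fit indices hit their closed forms and limits", {
  # perfect fit: zero discrepancy
  lambda <- c(0.8, 0.7, 0.6); gamma <- 0.5
  S <- oracle_sem_sigma(lambda, gamma, c(1 - lambda^2, 1 - gamma^2))
  vars <- c("x1", "x2", "x3", "tympanic")
  dimnames(S) <- list(vars, vars)
  fit <- fit_path_model(S, 500, model = path_model_spec(indicators = vars[1:3]))
  idx <- fit_indices(fit)
  expect_equal(idx$cfi, 1, tolerance = 1e-8)
  expect_equal(idx$rmsea, 0, tolerance = 1e-6)
  expect_equal(idx$nfi, 1, tolerance = 1e-8)
  expect_equal(idx$gfi, 1, tolerance = 1e-8)

  # closed-form spot values at chisq = 6.82, df = 5, n = 201
  stub <- structure(list(S = diag(3), implied = diag(3), chisq = 6.82,
                         df = 5, n = 201),
                    class = "path_model_fit")
  idx2 <- fit_indices(stub, null_fit = list(chisq = 800, df = 21))
  expect_equal(idx2$normed_chisq, 1.364, tolerance = 1e-12)
  expect_equal(idx2$rmsea, sqrt(1.82 / 1000), tolerance = 1e-12)
  expect_equal(round(idx2$rmsea, 4), 0.0427)
  expect_equal(idx2$p_value, pchisq(6.82, 5, lower.tail = FALSE))

  # df = 0: undefined indices surface as NaN with a warning
  stub0 <- structure(list(S = diag(3), implied = diag(3), chisq = 0,
                          df = 0, n = 201),
                     class = "path_model_fit")
  expect_warning(idx0 <- fit_indices(stub0, null_fit = list(chisq = 800,
                                                            df = 21)),
                 "df = 0")
  expect_true(is.nan(idx0$rmsea))
  expect_true(is.nan(idx0$normed_chisq))
})

test_that("declared error covariances add free parameters and reduce df", {
  set.seed(506)
  cfg <- random_sem_cov(k = 4, perturb = 0.1)
  vars <- rownames(cfg$S)
  plain <- fit_path_model(cfg$S, 300,
                          model = path_model_spec(indicators = vars[1:4]))
  rich <- fit_path_model(cfg$S, 300, model = path_model_spec(
    indicators = vars[1:4], error_cov = list(c(vars[1], vars[2]))))
  expect_equal(plain$df - rich$df, 1)
  expect_lte(rich$discrepancy, plain$discrepancy + 1e-10)
})
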