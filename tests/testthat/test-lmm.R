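test_that("fit matches a dense multivariate-normal brute-force oracle", {
  inst <- make_lmm_instance(n_subjects = 5, n_obs = 20)
  for (method in c("ML", "REML")) {
    fit <- fit_random_intercept_lmm(inst$X, inst$y, inst$subject, method)
    oracle <- dense_fit(inst$X, inst$y, inst$subject, method)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
    # both optimizers stop within tol of the same flat maximum, so the
    # parameters agree at the optimizer-convergence scale, not machine eps
    expect_lt(max(abs(fit$beta - oracle$beta)), 1e-5)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-5)
    expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
  }
  # the maximized ML loglik equals the explicit block-covariance MVN density
  fit <- fit_random_intercept_lmm(inst$X, inst$y, inst$subject, "ML")
  expect_equal(fit$loglik,
               dense_mvn_loglik(inst$X, inst$y, inst$subject, fit$beta,
                                fit$tau2, fit$sigma2),
               tolerance = 1e-8)
})

test_that("REML equals ML plus the determinant correction at fixed variances", {
  inst <- make_lmm_instance(n_subjects = 5, n_obs = 20, seed = 3)
  lambda <- 2.5
  ml <- dense_profile(lambda, inst$X, inst$y, inst$subject, "ML")
  # at the REML variance scale, l_R = l_ML - 0.5 log|X' V^{-1} X| + (p/2) log 2pi
  reml <- dense_profile(lambda, inst$X, inst$y, inst$subject, "REML")
  sigma2 <- reml$sigma2
  Vl <- dense_V_lambda(inst$subject, lambda)
  Vinv <- solve(sigma2 * Vl)
  A <- t(inst$X) %*% Vinv %*% inst$X
  r <- inst$y - inst$X %*% reml$beta
  l_ml_at <- -0.5 * (length(inst$y) * log(2 * pi) +
                       determinant(sigma2 * Vl, TRUE)$modulus +
                       t(r) %*% Vinv %*% r)
  p <- ncol(inst$X)
  expect_equal(reml$loglik,
               as.numeric(l_ml_at - 0.5 * determinant(A, TRUE)$modulus +
                            (p / 2) * log(2 * pi)),
               tolerance = 1e-8)
})

test_that("balanced one-way REML equals the ANOVA method-of-moments", {
  set.seed(21)
  n <- 50; J <- 4
  subject <- rep(seq_len(n), each = J)
  y <- rnorm(n, 10, 2)[subject] + rnorm(n * J, 0, 1)
  X <- matrix(1, n * J, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_random_intercept_lmm(X, y, subject, "REML")
  grand <- tapply(y, subject, mean)
  msb <- J * sum((grand - mean(y))^2) / (n - 1)
  msw <- sum((y - grand[subject])^2) / (n * (J - 1))
  expect_equal(fit$sigma2, msw, tolerance = 1e-6)
  expect_equal(fit$tau2, (msb - msw) / J, tolerance = 1e-6)
})

test_that("tau2 goes to the zero boundary when there is no subject effect", {
  set.seed(33)
  subject <- rep(1:80, each = 4)
  X <- cbind(1, x = rnorm(320))
  e <- rnorm(320)
  e <- e - ave(e, subject)   # no between-subject variation at all
  y <- drop(X %*% c(2, 1)) + e
  expect_warning(fit <- fit_random_intercept_lmm(X, y, subject, "REML"),
                 "boundary")
  expect_equal(fit$tau2, 0)
  expect_true(fit$boundary)
  expect_equal(blup_intercepts(fit), setNames(rep(0, 80), levels(factor(subject))))
})

test_that("fit agrees with lme4 on a moderate simulated dataset", {
  skip_if_not_installed("lme4")
  d <- simulate_lmm_data(150, 4, tau = 2, sigma = 0.8, seed = 9)
  df <- data.frame(y = d$y, d$X[, -1], subject = d$subject)
  for (reml in c(TRUE, FALSE)) {
    fit <- fit_random_intercept_lmm(d$X, d$y, d$subject,
                                    if (reml) "REML" else "ML")
    lf <- suppressWarnings(lme4::lmer(
      y ~ age + rcs1 + rcs2 + rcs3 + (1 | subject), df, REML = reml))
    expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
    expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
    expect_equal(fit$tau2, unname(unlist(lme4::VarCorr(lf))),
                 tolerance = 1e-4)
  }
})

test_that("fit is invariant to subject ordering and within-subject permutation", {
  d <- simulate_lmm_data(40, 3, tau = 2, sigma = 1, seed = 17)
  fit1 <- fit_random_intercept_lmm(d$X, d$y, d$subject)
  set.seed(1)
  perm <- sample(length(d$y))
  fit2 <- fit_random_intercept_lmm(d$X[perm, ], d$y[perm], d$subject[perm])
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit1$tau2, fit2$tau2, tolerance = 1e-4)
})

test_that("BLUPs match the dense generalized-least-squares oracle", {
  inst <- make_lmm_instance(n_subjects = 5, n_obs = 20, seed = 8)
  fit <- fit_random_intercept_lmm(inst$X, inst$y, inst$subject)
  b <- blup_intercepts(fit)
  oracle <- dense_blup(inst$X, inst$y, inst$subject, fit$beta, fit$tau2,
                       fit$sigma2)
  expect_lt(max(abs(unname(b) - oracle)), 1e-8)
  # shrinkage limit: constant within-subject residual c, large J -> blup -> c
  subject <- rep(1:2, c(400, 400))
  X <- matrix(1, 800, 1)
  y <- c(rep(5 + 3, 400), rep(5 - 3, 400)) + rnorm(800, 0, 1e-3)
  f2 <- fit_random_intercept_lmm(X, y, subject)
  expect_equal(unname(blup_intercepts(f2)), c(3, -3), tolerance = 0.05)
})

test_that("scaled residuals follow their definitions", {
  inst <- make_lmm_instance(n_subjects = 6, n_obs = 30, seed = 4)
  fit <- fit_random_intercept_lmm(inst$X, inst$y, inst$subject)
  b <- blup_intercepts(fit)
  fitted_cond <- drop(inst$X %*% fit$beta) + b[as.integer(factor(inst$subject))]
  r_cond <- scaled_residuals(fit, mode = "conditional")
  expect_equal(unname(r_cond), unname((inst$y - fitted_cond) / sqrt(fit$sigma2)),
               tolerance = 1e-12)
  r_marg <- scaled_residuals(fit, mode = "marginal")
  expect_equal(unname(r_marg),
               unname((inst$y - drop(inst$X %*% fit$beta)) /
                        sqrt(fit$sigma2 + fit$tau2)),
               tolerance = 1e-12)
  # an observation equal to its fitted value has residual 0, and a
  # conditional residual of 2 sigma-hat scales to exactly 2
  y2 <- fitted_cond
  y2[5] <- fitted_cond[5] + 2 * sqrt(fit$sigma2)
  e2 <- (y2 - fitted_cond) / sqrt(fit$sigma2)
  expect_equal(unname(e2[3]), 0)
  expect_equal(unname(e2[5]), 2)
})

test_that("marginal scaled residuals have mean 0 and unit spread under the model", {
  d <- simulate_lmm_data(5000, 4, tau = 2, sigma = 0.8, seed = 31)
  fit <- fit_random_intercept_lmm(d$X, d$y, d$subject)
  r <- scaled_residuals(fit, mode = "marginal")
  expect_lt(abs(mean(r)), 0.02)
  expect_gt(sd(r), 0.97)
  expect_lt(sd(r), 1.03)
  # conditional residuals are shrunken: smaller spread, fewer exceedances
  rc <- scaled_residuals(fit, mode = "conditional")
  expect_lt(sd(rc), sd(r))
  expect_lte(sum(abs(rc) > 3), sum(abs(r) > 3) * 1.5)
})

test_that("studentized residuals refine the marginal residual", {
  d <- simulate_lmm_data(200, 4, tau = 2, sigma = 1, seed = 12)
  fit <- fit_random_intercept_lmm(d$X, d$y, d$subject)
  r_m <- scaled_residuals(fit, mode = "marginal")
  r_i <- scaled_residuals(fit, type = "internally_studentized")
  r_e <- scaled_residuals(fit, type = "externally_studentized")
  # leverage inflation is mild away from the design edges
  expect_true(all(abs(r_i) >= abs(r_m) - 1e-10))
  expect_equal(unname(r_i), unname(r_m), tolerance = 0.05)
  # external studentization: same signs, inflates only large residuals
  expect_true(all(sign(r_e) == sign(r_i) | r_i == 0))
  expect_equal(unname(r_e), unname(r_i), tolerance = 0.02)
  expect_true(all(abs(r_e)[abs(r_i) > 2] >= abs(r_i)[abs(r_i) > 2]))
  # size cap for the leave-one-out mode
  big <- simulate_lmm_data(5100, 2, tau = 1, sigma = 1, seed = 1)
  fbig <- fit_random_intercept_lmm(big$X, big$y, big$subject)
  expect_error(scaled_residuals(fbig, type = "externally_studentized"),
               "size-limit")
})

test_that("longitudinal-outlier flags are strict and nested across cutoffs", {
  r <- c(-6.5, -3.2, -3, 0, 3, 3.2, 4.5, NA)
  f3 <- flag_longitudinal_outliers(r, 3)
  expect_setequal(f3$row, c(1L, 2L, 6L, 7L))
  expect_false(3L %in% f3$row)    # boundary not flagged
  expect_false(5L %in% f3$row)
  f4 <- flag_longitudinal_outliers(r, 4)
  f5 <- flag_longitudinal_outliers(r, 5)
  f6 <- flag_longitudinal_outliers(r, 6)
  expect_true(all(f6$row %in% f5$row))
  expect_true(all(f5$row %in% f4$row))
  expect_true(all(f4$row %in% f3$row))
  expect_error(flag_longitudinal_outliers(r, 0), "invalid config")
  expect_error(flag_longitudinal_outliers(r, -3), "invalid config")
})

test_that("profile likelihood is unimodal in log lambda on test instances", {
  d <- simulate_lmm_data(60, 4, tau = 2, sigma = 1, seed = 44)
  pre <- bivclean:::lmm_precompute(d$X, d$y, d$subject)
  ll <- vapply(seq(log(1e-8), log(1e4), length.out = 120), function(g)
    bivclean:::lmm_profile(exp(g), pre, "REML")$loglik, numeric(1))
  s <- sign(diff(ll))
  expect_lte(sum(diff(s[s != 0]) != 0), 1)  # at most one sign change
})

test_that("model dump serializes the fit", {
  d <- simulate_lmm_data(20, 3, seed = 2)
  fit <- fit_growth_lmm(d$age, d$y, d$subject)
  js <- jsonlite::fromJSON(lmm_dump(fit))
  expect_equal(js$method, "REML")
  expect_equal(js$knots, default_knots("height"))
  expect_equal(js$n_obs, 60)
  path <- withr::local_tempfile(fileext = ".json")
  lmm_dump(fit, path)
  expect_equal(jsonlite::fromJSON(path)$sigma2, fit$sigma2)
})
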