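# Dense-matrix oracles for the random-intercept model. These assemble the
# full N x N covariance and use generic solve()/determinant() calls, fully
# independent of the package's per-subject rank-one identities.

dense_V_lambda <- function(subject, lambda) {
  Z <- stats::model.matrix(~ 0 + factor(subject))
  diag(length(subject)) + lambda * Z %*% t(Z)
}

# profiled (restricted) log-likelihood at lambda, all-dense
dense_profile <- function(lambda, X, y, subject, method = "REML") {
  N <- length(y); p <- ncol(X)
  Vl <- dense_V_lambda(subject, lambda)
  Vinv <- solve(Vl)
  A <- t(X) %*% Vinv %*% X
  # at extreme lambda A is near-singular (the centered intercept collapses);
  # those grid points sit far below the maximum, so skip the rcond check
  beta <- solve(A, t(X) %*% Vinv %*% y, tol = 0)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vinv %*% r)
  ldV <- determinant(Vl, logarithm = TRUE)$modulus
  if (method == "ML") {
    sigma2 <- rss / N
    ll <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + ldV + N)
  } else {
    sigma2 <- rss / (N - p)
    ldA <- determinant(A, logarithm = TRUE)$modulus
    ll <- -0.5 * ((N - p) * log(2 * pi) + (N - p) * log(sigma2) + ldV + ldA +
                    (N - p))
  }
  list(loglik = as.numeric(ll), beta = drop(beta), sigma2 = sigma2)
}

dense_fit <- function(X, y, subject, method = "REML",
                      bounds = c(1e-10, 1e6)) {
  grid <- seq(log(bounds[1]), log(bounds[2]), length.out = 61)
  vals <- vapply(grid, function(g)
    dense_profile(exp(g), X, y, subject, method)$loglik, numeric(1))
  i <- which.max(vals)
  opt <- stats::optimize(function(g)
    dense_profile(exp(g), X, y, subject, method)$loglik,
    interval = c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
    maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  prof <- dense_profile(lambda, X, y, subject, method)
  c(prof, list(lambda = lambda, tau2 = lambda * prof$sigma2))
}

# multivariate-normal log-density with explicitly assembled block covariance
dense_mvn_loglik <- function(X, y, subject, beta, tau2, sigma2) {
  V <- sigma2 * diag(length(y)) + tau2 *
    (stats::model.matrix(~ 0 + factor(subject)) %*%
       t(stats::model.matrix(~ 0 + factor(subject))))
  r <- y - X %*% beta
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# generalized-least-squares BLUP via dense matrices
dense_blup <- function(X, y, subject, beta, tau2, sigma2) {
  Z <- stats::model.matrix(~ 0 + factor(subject))
  V <- sigma2 * diag(length(y)) + tau2 * Z %*% t(Z)
  drop(tau2 * t(Z) %*% solve(V, y - X %*% beta))
}

# small fixture: a few subjects with a well-conditioned Gaussian design, so
# dense and rank-one solves of the same normal equations agree to ~1e-12
# (a raw cubic-spline basis is too collinear to compare solvers at 1e-8)
make_lmm_instance <- function(n_subjects = 5, n_obs = 20, tau = 2, sigma = 1,
                              seed = 11) {
  set.seed(seed)
  subject <- sort(rep_len(seq_len(n_subjects), n_obs))
  X <- cbind("(Intercept)" = 1,
             matrix(stats::rnorm(n_obs * 4), n_obs, 4,
                    dimnames = list(NULL, paste0("x", 1:4))))
  beta <- c(50, 1, -1, 0.5, 0.25)
  y <- drop(X %*% beta) +
    stats::rnorm(n_subjects, 0, tau)[subject] + stats::rnorm(n_obs, 0, sigma)
  list(X = X, y = y, subject = subject, beta = beta)
}

# simple record table builder for pipeline tests
make_records <- function(child_id, sex, age_months, height = NA_real_,
                         weight = NA_real_, birth = as.Date("2012-01-01")) {
  n <- length(child_id)
  data.frame(child_id = as.character(child_id), sex = rep_len(sex, n),
             birth_date = rep_len(birth, n),
             visit_date = rep_len(birth, n) + round(age_months * 30.4375),
             length_height_cm = rep_len(height, n),
             weight_kg = rep_len(weight, n), stringsAsFactors = FALSE)
}
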