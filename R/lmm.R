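# Random-intercept linear mixed model via profiled likelihood.
#
# V_i = sigma^2 (I + lambda 1 1'), lambda = tau^2/sigma^2. For fixed lambda,
# beta and sigma^2 have closed forms through the rank-one Woodbury identity
# (I + lambda 11')^{-1} = I - c 11', c = lambda/(1 + lambda J_i), so one
# likelihood evaluation costs O(N p + n p^2). The profile is maximized over
# log(lambda) by a derivative-free grid + Brent search.

lmm_precompute <- function(X, y, subject) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y),
            length(subject) == length(y))
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete", call. = FALSE)
  subject <- factor(subject)
  if (nlevels(subject) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  p <- ncol(X)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0) || qr(sweep(X, 2, nrm, "/"))$rank < p) {
    stop("design error: X is rank deficient", call. = FALSE)
  }
  list(X = X, y = y, subject = subject,
       XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       S = rowsum(X, subject, reorder = TRUE),           # n x p subject sums
       t = drop(rowsum(y, subject, reorder = TRUE)),     # subject sums of y
       J = as.integer(table(subject)),                   # visits per subject
       n = nlevels(subject), N = length(y), p = p)
}

# profiled (restricted) log-likelihood and GLS pieces at a given lambda
lmm_profile <- function(lambda, pre, method) {
  c_i <- lambda / (1 + lambda * pre$J)
  Sc <- pre$S * sqrt(c_i)
  A <- pre$XtX - crossprod(Sc)                     # X' Vlam^{-1} X
  b <- pre$Xty - drop(crossprod(pre$S, c_i * pre$t))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  # generalized RSS from explicit residuals: e'e - sum c_i (sum_i e)^2.
  # The sufficient-statistic form q - beta'b cancels the large y'y scale and
  # loses enough digits to bias the flat profile maximum by ~1e-6 in lambda
  e <- pre$y - drop(pre$X %*% beta)
  te <- drop(rowsum(e, pre$subject, reorder = TRUE))
  rss <- sum(e^2) - sum(c_i * te^2)
  rss <- max(rss, .Machine$double.xmin)
  logdet_V <- sum(log1p(lambda * pre$J))
  if (method == "ML") {
    sigma2 <- rss / pre$N
    ll <- -0.5 * (pre$N * log(2 * pi) + pre$N * log(sigma2) + logdet_V + pre$N)
  } else {
    df <- pre$N - pre$p
    sigma2 <- rss / df
    ll <- -0.5 * (df * log(2 * pi) + df * log(sigma2) + logdet_V +
                    2 * sum(log(diag(ch))) + df)
  }
  list(loglik = ll, beta = beta, sigma2 = sigma2, A = A, chol = ch)
}

#' Fit a random-intercept linear mixed model
#'
#' Maximizes the (restricted) likelihood of
#' \eqn{Y_i \sim N(X_i\beta, \sigma^2 I + \tau^2 1 1^\top)} over
#' \eqn{(\beta, \sigma^2, \tau^2 \ge 0)}. The variance ratio
#' \eqn{\lambda = \tau^2/\sigma^2} is profiled: \eqn{\beta} and
#' \eqn{\sigma^2} are solved in closed form for each \eqn{\lambda} using
#' per-subject rank-one covariance identities (cost linear in the number of
#' observations), and \eqn{\lambda} is found by a derivative-free search on
#' the log scale over \eqn{[10^{-10}, 10^6]}. \eqn{\tau^2} may converge to
#' the zero boundary, in which case it is reported as exactly 0 with a
#' warning.
#'
#' @param X Design matrix including the intercept column.
#' @param y Outcome vector.
#' @param subject Subject identifiers (coerced to factor); each subject's
#'   rows share one random intercept.
#' @param method `"REML"` (default) or `"ML"`.
#' @param lambda_bounds Search interval for \eqn{\lambda}.
#' @param tol Relative convergence tolerance on \eqn{\lambda}.
#' @param max_eval Cap on profile-likelihood evaluations.
#' @return Object of class `mixed_fit`: `beta`, `tau2`, `sigma2`, `lambda`,
#'   `loglik`, `method`, `n_subjects`, `n_obs`, `converged`, `boundary`,
#'   `n_eval`, and the model frame needed for residuals/BLUPs.
#' @export
fit_random_intercept_lmm <- function(X, y, subject, method = c("REML", "ML"),
                                     lambda_bounds = c(1e-10, 1e6),
                                     tol = 1e-8, max_eval = 200) {
  method <- match.arg(method)
  pre <- lmm_precompute(X, y, subject)
  n_eval <- 0L
  obj <- function(loglam) {
    n_eval <<- n_eval + 1L
    lmm_profile(exp(loglam), pre, method)$loglik
  }
  lo <- log(lambda_bounds[1]); hi <- log(lambda_bounds[2])
  grid <- seq(lo, hi, length.out = 61)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(obj, interval = bracket, maximum = TRUE,
                         tol = max(tol, 1e-10))
  loglam <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  # parabolic polish: Brent stops once objective differences reach the
  # evaluation noise floor, which on a flat maximum leaves log-lambda
  # accurate only to ~1e-6; refitting a local parabola with successively
  # smaller spacing recovers several more digits
  if (loglam > lo && loglam < hi) {
    for (h in c(1e-3, 1e-4, 2e-5)) {
      fl <- obj(loglam - h); fc <- obj(loglam); fr <- obj(loglam + h)
      denom <- fl - 2 * fc + fr
      if (is.finite(denom) && denom < 0) {
        cand <- loglam + h * (fl - fr) / (2 * denom)
        if (abs(cand - loglam) < h && obj(cand) >= fc) loglam <- cand
      }
    }
  }
  lambda <- exp(loglam)
  prof <- lmm_profile(lambda, pre, method)
  boundary <- lambda <= lambda_bounds[1] * (1 + 1e-6) ||
    abs(loglam - lo) < 1e-6
  tau2 <- if (boundary) 0 else lambda * prof$sigma2
  if (boundary) {
    warning("tau2 converged to the zero boundary", call. = FALSE)
  }
  converged <- is.finite(prof$loglik) && n_eval <= max_eval
  if (!converged) {
    warning("profile search did not converge within the evaluation cap",
            call. = FALSE)
  }
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  structure(
    list(beta = beta, tau2 = tau2, sigma2 = prof$sigma2, lambda = lambda,
         loglik = prof$loglik, method = method,
         n_subjects = pre$n, n_obs = pre$N,
         converged = converged, boundary = boundary, n_eval = n_eval,
         data = pre),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s: n_subjects=%d n_obs=%d logLik=%.4f\n",
              x$method, x$n_subjects, x$n_obs, x$loglik))
  cat(sprintf("  tau2=%.6g sigma2=%.6g%s\n", x$tau2, x$sigma2,
              if (x$boundary) " (boundary)" else ""))
  cat("  beta:", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                       collapse = " "), "\n")
  invisible(x)
}

#' Covariance of the fixed-effect estimates
#'
#' \eqn{\widehat{Cov}(\hat\beta) = \hat\sigma^2 (X^\top V_\lambda^{-1} X)^{-1}}
#' evaluated at the fitted variance ratio.
#'
#' @param object A `mixed_fit`.
#' @param ... Unused.
#' @return `p x p` covariance matrix.
#' @export
vcov.mixed_fit <- function(object, ...) {
  prof <- lmm_profile(object$lambda, object$data, object$method)
  v <- object$sigma2 * chol2inv(prof$chol)
  dimnames(v) <- list(names(object$beta), names(object$beta))
  v
}

#' Predicted random intercepts (BLUPs)
#'
#' Shrunken subject-level intercepts
#' \eqn{\hat b_{0i} = \frac{J_i \hat\tau^2}{\hat\sigma^2 + J_i \hat\tau^2}
#' \bar r_i}, where \eqn{\bar r_i} is the subject mean of the marginal
#' residuals \eqn{y_{ij} - x_{ij}^\top\hat\beta}.
#'
#' @param fit A `mixed_fit`.
#' @return Named numeric vector, one entry per subject.
#' @export
blup_intercepts <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  pre <- fit$data
  c_i <- fit$lambda / (1 + fit$lambda * pre$J)
  if (fit$tau2 == 0) c_i <- rep(0, pre$n)
  b <- c_i * (pre$t - drop(pre$S %*% fit$beta))
  names(b) <- levels(pre$subject)
  b
}

#' Scaled and studentized model residuals
#'
#' The default (`mode = "marginal"`, `type = "scaled"`) is the scaled
#' residual \eqn{R_{ij} = e_{ij}/\sqrt{\widehat{Var}(Y_{ij})}} with
#' \eqn{e_{ij} = y_{ij} - x_{ij}^\top\hat\beta} and marginal variance
#' \eqn{\hat\sigma^2 + \hat\tau^2}. `mode = "conditional"` instead subtracts
#' the subject's predicted intercept and scales by \eqn{\hat\sigma};
#' conditional residuals are shrunken, so their spread is below 1 even under
#' a correct model. The studentized types refine the marginal residual:
#' internally studentized divides additionally by \eqn{\sqrt{1-h_{ij}}} with
#' \eqn{h_{ij}} the generalized-least-squares leverage (available up to
#' 1e5 observations); externally studentized rescales each residual with the
#' observation deleted via the standard leave-one-out identity, holding the
#' variance components fixed (up to 1e4 observations).
#'
#' @param fit A `mixed_fit`.
#' @param mode `"marginal"` (default) or `"conditional"`; only used for
#'   `type = "scaled"`.
#' @param type `"scaled"`, `"internally_studentized"`, or
#'   `"externally_studentized"`.
#' @return Numeric vector of residuals, one per observation, in input order.
#' @export
scaled_residuals <- function(fit, mode = c("marginal", "conditional"),
                             type = c("scaled", "internally_studentized",
                                      "externally_studentized")) {
  stopifnot(inherits(fit, "mixed_fit"))
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  pre <- fit$data
  e_marg <- pre$y - drop(pre$X %*% fit$beta)
  if (type == "scaled") {
    if (mode == "conditional") {
      b <- blup_intercepts(fit)
      return((e_marg - b[as.integer(pre$subject)]) / sqrt(fit$sigma2))
    }
    return(e_marg / sqrt(fit$sigma2 + fit$tau2))
  }
  cap <- if (type == "internally_studentized") 1e5 else 1e4
  if (pre$N > cap) {
    stop("size-limit error: ", type, " residuals support at most ", cap,
         " observations", call. = FALSE)
  }
  prof <- lmm_profile(fit$lambda, pre, fit$method)
  Ainv_Xt <- chol2inv(prof$chol)           # (X' Vlam^{-1} X)^{-1}
  v_marg <- fit$sigma2 + fit$tau2
  h <- fit$sigma2 * rowSums((pre$X %*% Ainv_Xt) * pre$X) / v_marg
  r_int <- e_marg / sqrt(v_marg * (1 - h))
  if (type == "internally_studentized") return(r_int)
  nu <- pre$N - pre$p
  r_int * sqrt((nu - 1) / pmax(nu - r_int^2, .Machine$double.eps))
}

#' Flag longitudinal outliers from residuals
#'
#' Flags observations whose residual lies strictly outside `(-cutoff,
#' +cutoff)`. Flag sets are nested across cutoffs because they derive from
#' one residual vector.
#'
#' @param residuals Numeric residual vector (e.g. from
#'   [scaled_residuals()]).
#' @param cutoff Positive cutoff; the study's candidates are 3, 4, 5, 6.
#' @return `data.frame` with columns `row` (observation index) and `value`
#'   (the residual).
#' @export
flag_longitudinal_outliers <- function(residuals, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff <= 0) {
    stop("invalid config: cutoff must be a positive number", call. = FALSE)
  }
  bad <- which(!is.na(residuals) & abs(residuals) > cutoff)
  data.frame(row = bad, value = residuals[bad])
}

#' Fit the growth-trajectory model for one stratum
#'
#' Convenience wrapper: builds the restricted-cubic-spline design in age
#' (intercept + [rcs_basis()]) and fits the random-intercept model.
#'
#' @param age Ages in months.
#' @param y Length/height (cm) or weight (kg).
#' @param subject Child identifiers.
#' @param knots Spline knots; see [default_knots()].
#' @inheritParams fit_random_intercept_lmm
#' @return A `mixed_fit` with the knot vector stored as `$knots`.
#' @export
fit_growth_lmm <- function(age, y, subject, knots = default_knots("height"),
                           method = c("REML", "ML")) {
  X <- cbind("(Intercept)" = 1, rcs_basis(age, knots))
  fit <- fit_random_intercept_lmm(X, y, subject, method = method)
  fit$knots <- knots
  fit
}

#' Serialize a fitted model to JSON
#'
#' @param fit A `mixed_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
lmm_dump <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mixed_fit"))
  obj <- list(method = fit$method, knots = fit$knots,
              beta = as.list(fit$beta), tau2 = fit$tau2, sigma2 = fit$sigma2,
              loglik = fit$loglik, n_subjects = fit$n_subjects,
              n_obs = fit$n_obs, converged = fit$converged,
              boundary = fit$boundary, n_eval = fit$n_eval)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
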