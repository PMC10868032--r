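#' Default spline knots for the growth-trajectory models
#'
#' Knot locations (months) near the inflection points of median child growth
#' curves: five knots for length/height, four for weight.
#'
#' @param measure `"height"` or `"weight"`.
#' @return Numeric vector of knot ages in months.
#' @export
default_knots <- function(measure = c("height", "weight")) {
  measure <- match.arg(measure)
  if (measure == "height") c(2, 6, 12, 24, 58) else c(3, 6, 12, 58)
}

#' Restricted cubic spline basis in age
#'
#' Builds the standard restricted (natural) cubic spline basis with linear
#' tails: column 1 is the linear term `age`; columns `2..K-1` are the
#' truncated-cubic combinations
#' \deqn{C_k(x) = (x-\epsilon_k)_+^3
#'   - (x-\epsilon_{K-1})_+^3 \frac{\epsilon_K-\epsilon_k}{\epsilon_K-\epsilon_{K-1}}
#'   + (x-\epsilon_K)_+^3 \frac{\epsilon_{K-1}-\epsilon_k}{\epsilon_K-\epsilon_{K-1}}}
#' for \eqn{k = 1..K-2}. Every basis column is continuous with continuous
#' first and second derivatives and is linear beyond the boundary knots.
#'
#' @param age Ages in months (non-negative).
#' @param knots Strictly increasing knot vector, length `K >= 3`.
#' @return Matrix with `length(age)` rows and `K - 1` columns named
#'   `age`, `rcs1`, `rcs2`, ...
#' @export
rcs_basis <- function(age, knots) {
  stopifnot(is.numeric(age), is.numeric(knots), length(knots) >= 3)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  if (any(age < 0, na.rm = TRUE)) {
    stop("invalid input: age must be non-negative", call. = FALSE)
  }
  K <- length(knots)
  tp3 <- function(u) pmax(u, 0)^3
  X <- matrix(NA_real_, length(age), K - 1)
  X[, 1] <- age
  denom <- knots[K] - knots[K - 1]
  for (k in seq_len(K - 2)) {
    X[, k + 1] <- tp3(age - knots[k]) -
      tp3(age - knots[K - 1]) * (knots[K] - knots[k]) / denom +
      tp3(age - knots[K]) * (knots[K - 1] - knots[k]) / denom
  }
  colnames(X) <- c("age", paste0("rcs", seq_len(K - 2)))
  X
}
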