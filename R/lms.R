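#' LMS z-score
#'
#' Convert a measurement to a z-score under the LMS (Box-Cox power, median,
#' coefficient of variation) parameterization used by growth references:
#' \deqn{z = \frac{(y/M)^L - 1}{L S}} for \eqn{L \ne 0}, and
#' \eqn{z = \log(y/M)/S} when \eqn{L = 0}.
#'
#' @param y Measurement in the units of `M` (cm or kg). Vectorized; `NA`
#'   propagates.
#' @param L,M,S LMS parameters (recycled against `y`). `M > 0`, `S > 0`.
#' @return Numeric vector of z-scores.
#' @seealso [zscore_to_value()] for the exact inverse.
#' @export
#' @examples
#' lms_zscore(12, L = 1, M = 10, S = 0.1) # 2
lms_zscore <- function(y, L, M, S) {
  stopifnot(is.numeric(y), is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(M <= 0 | S <= 0, na.rm = TRUE)) {
    stop("invalid reference: M and S must be positive", call. = FALSE)
  }
  if (any(y <= 0, na.rm = TRUE)) {
    stop("invalid measurement: y must be positive", call. = FALSE)
  }
  n <- max(length(y), length(L), length(M), length(S))
  y <- rep_len(y, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  z <- ifelse(L == 0, log(y / M) / S, ((y / M)^L - 1) / (L * S))
  z
}

#' Measurement at a given z-score
#'
#' Exact inverse of [lms_zscore()]: \eqn{y = M (1 + L S z)^{1/L}} for
#' \eqn{L \ne 0}, else \eqn{y = M e^{S z}}.
#'
#' @param z Z-score (vectorized).
#' @inheritParams lms_zscore
#' @return Measurement in the units of `M`.
#' @export
zscore_to_value <- function(z, L, M, S) {
  stopifnot(is.numeric(z))
  if (any(M <= 0 | S <= 0, na.rm = TRUE)) {
    stop("invalid reference: M and S must be positive", call. = FALSE)
  }
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  base <- 1 + L * S * z
  if (any(L != 0 & base <= 0, na.rm = TRUE)) {
    stop("invalid z: 1 + L*S*z must be positive when L != 0", call. = FALSE)
  }
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

biv_indicators <- c("HAZ", "WAZ", "BMIZ", "WHZ")
biv_sexes <- c("M", "F")

#' Growth reference table for one indicator and sex
#'
#' A single LMS table: ordered axis values (age in months for HAZ/WAZ/BMIZ,
#' length in cm for WHZ) with the L, M, S parameters at each point.
#'
#' @param indicator One of `"HAZ"`, `"WAZ"`, `"BMIZ"`, `"WHZ"`.
#' @param sex `"M"` or `"F"`.
#' @param axis Strictly increasing non-negative axis values.
#' @param L,M,S LMS parameters at each axis value (`M > 0`, `S > 0`).
#' @return An object of class `growth_reference`.
#' @export
growth_reference <- function(indicator, sex, axis, L, M, S) {
  indicator <- match.arg(indicator, biv_indicators)
  sex <- match.arg(sex, biv_sexes)
  stopifnot(length(axis) >= 2)
  L <- rep_len(L, length(axis))
  M <- rep_len(M, length(axis))
  S <- rep_len(S, length(axis))
  if (any(!is.finite(axis)) || any(axis < 0) || any(diff(axis) <= 0)) {
    stop("axis values must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(M)) || any(M <= 0) || any(!is.finite(S)) || any(S <= 0)) {
    stop("invalid reference: M and S must be positive and finite", call. = FALSE)
  }
  structure(
    list(indicator = indicator, sex = sex,
         axis_kind = if (indicator == "WHZ") "length_cm" else "age_months",
         table = data.frame(axis = axis, L = L, M = M, S = S)),
    class = "growth_reference")
}

ref_key <- function(indicator, sex) paste(indicator, sex, sep = ".")

#' Bundle growth-reference tables into a set
#'
#' @param ... `growth_reference` objects.
#' @return A named list of class `growth_reference_set`, keyed
#'   `"<indicator>.<sex>"`.
#' @export
growth_reference_set <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && is.list(refs[[1]]) &&
      !inherits(refs[[1]], "growth_reference")) {
    refs <- refs[[1]]
  }
  stopifnot(all(vapply(refs, inherits, logical(1), "growth_reference")))
  names(refs) <- vapply(refs, function(r) ref_key(r$indicator, r$sex), character(1))
  if (anyDuplicated(names(refs))) {
    stop("duplicate indicator/sex table in reference set", call. = FALSE)
  }
  structure(refs, class = "growth_reference_set")
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("<growth_reference> %s sex=%s axis=%s [%g, %g], %d points\n",
              x$indicator, x$sex, x$axis_kind,
              min(x$table$axis), max(x$table$axis), nrow(x$table)))
  invisible(x)
}

#' @export
print.growth_reference_set <- function(x, ...) {
  cat("<growth_reference_set>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read a growth reference from delimited text
#'
#' Expected header: `indicator,sex,axis,L,M,S` with `sex` in `{M, F}` and
#' `indicator` in `{HAZ, WAZ, BMIZ, WHZ}`; axis in months (HAZ/WAZ/BMIZ) or
#' cm (WHZ). Official LMS tables laid out this way load unchanged.
#'
#' @param path File path.
#' @return A `growth_reference_set`.
#' @export
read_growth_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator", "sex", "axis", "L", "M", "S")
  if (!all(need %in% names(df))) {
    stop("reference file must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  parts <- split(df, list(df$indicator, df$sex), drop = TRUE)
  refs <- lapply(parts, function(p) {
    p <- p[order(p$axis), ]
    growth_reference(p$indicator[1], p$sex[1], p$axis, p$L, p$M, p$S)
  })
  growth_reference_set(refs)
}

#' Write a growth reference set to delimited text
#'
#' @param refs A `growth_reference_set`.
#' @param path File path.
#' @export
write_growth_reference <- function(refs, path) {
  stopifnot(inherits(refs, "growth_reference_set"))
  rows <- lapply(refs, function(r) {
    data.frame(indicator = r$indicator, sex = r$sex, axis = r$table$axis,
               L = r$table$L, M = r$table$M, S = r$table$S)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate LMS parameters at arbitrary axis values
#'
#' Linear interpolation of each of L, M, S independently between the
#' bracketing table rows; values at tabulated points are returned exactly.
#' Axis values outside the table range yield `NA` rows (the corresponding
#' z-score is treated as absent downstream) unless `strict = TRUE`.
#'
#' @param ref A `growth_reference`.
#' @param x Axis values (months or cm, matching the table's axis kind).
#' @param strict Error on out-of-range `x` instead of returning `NA`.
#' @return `data.frame` with columns `axis`, `L`, `M`, `S`.
#' @export
interpolate_lms <- function(ref, x, strict = FALSE) {
  stopifnot(inherits(ref, "growth_reference"), is.numeric(x))
  tab <- ref$table
  out_of_range <- !is.na(x) & (x < tab$axis[1] | x > tab$axis[nrow(tab)])
  if (strict && any(out_of_range)) {
    stop("axis value outside reference range [", tab$axis[1], ", ",
         tab$axis[nrow(tab)], "]", call. = FALSE)
  }
  interp <- function(col) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !out_of_range
    if (any(ok)) out[ok] <- stats::approx(tab$axis, tab[[col]], xout = x[ok])$y
    out
  }
  data.frame(axis = x, L = interp("L"), M = interp("M"), S = interp("S"))
}

#' Extreme-tail z-score adjustment
#'
#' For weight-based indicators, z-scores beyond |3| are re-expressed on a
#' measurement scale anchored at the reference's 2- and 3-SD curves, mirroring
#' the behaviour of standard growth-reference software: for `z > 3`,
#' `3 + (y - p3)/(p3 - p2)`; for `z < -3`, `-3 + (y - m3)/(m2 - m3)`; otherwise
#' `z` is unchanged.
#'
#' @param z Unadjusted z-score(s).
#' @param y Measurement(s).
#' @param p_neg3,p_neg2,p_pos2,p_pos3 Measurements at z = -3, -2, +2, +3 for
#'   the same reference point (from [zscore_to_value()]).
#' @return Adjusted z-score(s).
#' @export
adjust_extreme_zscore <- function(z, y, p_neg3, p_neg2, p_pos2, p_pos3) {
  n <- length(z)
  y <- rep_len(y, n); p_neg3 <- rep_len(p_neg3, n); p_neg2 <- rep_len(p_neg2, n)
  p_pos2 <- rep_len(p_pos2, n); p_pos3 <- rep_len(p_pos3, n)
  hi <- !is.na(z) & z > 3
  lo <- !is.na(z) & z < -3
  if (any((hi & p_pos3 == p_pos2) | (lo & p_neg2 == p_neg3), na.rm = TRUE)) {
    stop("invalid reference: degenerate boundary spacing in tail adjustment",
         call. = FALSE)
  }
  out <- z
  out[hi] <- 3 + (y[hi] - p_pos3[hi]) / (p_pos3[hi] - p_pos2[hi])
  out[lo] <- -3 + (y[lo] - p_neg3[lo]) / (p_neg2[lo] - p_neg3[lo])
  out
}

# z for one indicator across a mixed-sex record set; NA where the input or
# axis value is unavailable.
zscore_one_indicator <- function(indicator, sex, axis_value, y, refs,
                                 adjust_extreme = TRUE) {
  z <- rep(NA_real_, length(y))
  for (sx in biv_sexes) {
    key <- ref_key(indicator, sx)
    if (is.null(refs[[key]])) next
    idx <- which(!is.na(sex) & sex == sx & !is.na(axis_value) &
                   !is.na(y) & y > 0)
    if (!length(idx)) next
    p <- interpolate_lms(refs[[key]], axis_value[idx])
    ok <- !is.na(p$M)
    if (!any(ok)) next
    zi <- lms_zscore(y[idx][ok], p$L[ok], p$M[ok], p$S[ok])
    if (adjust_extreme && indicator %in% c("WAZ", "BMIZ", "WHZ")) {
      bnd <- lapply(c(-3, -2, 2, 3), function(b)
        zscore_to_value(b, p$L[ok], p$M[ok], p$S[ok]))
      zi <- adjust_extreme_zscore(zi, y[idx][ok],
                                  bnd[[1]], bnd[[2]], bnd[[3]], bnd[[4]])
    }
    z[idx[ok]] <- zi
  }
  z
}

#' Compute growth-standard z-scores for visit records
#'
#' Computes HAZ (length/height-for-age), WAZ (weight-for-age), BMIZ
#' (BMI-for-age, BMI = weight_kg / (length_m)^2) and WHZ (weight-for-length)
#' from a growth reference set. A z-score is `NA` exactly when a required
#' input is missing or the axis value lies outside the reference table.
#'
#' @param records `data.frame` with columns `sex` ("M"/"F"), `age_months`,
#'   `length_height_cm`, `weight_kg`.
#' @param refs A `growth_reference_set`.
#' @param adjust_extreme Apply the extreme-tail adjustment to the
#'   weight-based indicators (WAZ, BMIZ, WHZ); HAZ is never adjusted.
#' @return `data.frame` with columns `haz`, `waz`, `bmiz`, `whz`.
#' @export
compute_zscores <- function(records, refs, adjust_extreme = TRUE) {
  stopifnot(is.data.frame(records), inherits(refs, "growth_reference_set"),
            all(c("sex", "age_months") %in% names(records)))
  len <- if ("length_height_cm" %in% names(records))
    records$length_height_cm else rep(NA_real_, nrow(records))
  wt <- if ("weight_kg" %in% names(records))
    records$weight_kg else rep(NA_real_, nrow(records))
  age <- records$age_months
  age[!is.na(age) & age < 0] <- NA_real_
  bmi <- ifelse(!is.na(len) & len > 0 & !is.na(wt), wt / (len / 100)^2, NA_real_)
  data.frame(
    haz  = zscore_one_indicator("HAZ", records$sex, age, len, refs, FALSE),
    waz  = zscore_one_indicator("WAZ", records$sex, age, wt, refs, adjust_extreme),
    bmiz = zscore_one_indicator("BMIZ", records$sex, age, bmi, refs, adjust_extreme),
    whz  = zscore_one_indicator("WHZ", records$sex, len, wt, refs, adjust_extreme))
}
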