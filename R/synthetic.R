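# Synthetic longitudinal growth data with labelled error injection.
#
# The generator is the trajectory model run forward: for each child,
# Y_ij = median_curve(age_ij) + b_i + e_ij with b_i ~ N(0, tau^2) and
# e_ij ~ N(0, sigma^2). The toy median curves are restricted-cubic-spline
# functions on the default knots, so simulated trajectories satisfy the
# mixed-model mean structure exactly.

.toy_beta <- list(
  height = c(`(Intercept)` = 50, age = 2.3176355, rcs1 = -0.0045256793,
             rcs2 = 0.0077407561, rcs3 = -0.0042029641),
  weight = c(`(Intercept)` = 3.3, age = 0.44349356, rcs1 = 0.00047751841,
             rcs2 = -0.0011238538))

#' Trajectory coefficients of the toy median growth curves
#'
#' Fixed spline coefficients (intercept + [rcs_basis()] columns on
#' [default_knots()]) defining the synthetic median curves: length rises
#' from 50 cm at birth to ~120 cm at 59 months, weight from 3.3 kg to
#' ~18.6 kg, both strictly increasing and decelerating like real median
#' growth.
#'
#' @param measure `"height"` or `"weight"`.
#' @return Named coefficient vector.
#' @export
toy_trajectory_coefficients <- function(measure = c("height", "weight")) {
  .toy_beta[[match.arg(measure)]]
}

#' Toy median growth curve
#'
#' @param age Ages in months.
#' @param measure `"height"` or `"weight"`.
#' @param sex `"M"` or `"F"` (scalar or vector); boys sit a small fixed
#'   offset above girls.
#' @param sex_offset Half-difference between the sexes (cm or kg).
#' @return Median length/height (cm) or weight (kg).
#' @export
toy_median <- function(age, measure = c("height", "weight"), sex = "M",
                       sex_offset = NULL) {
  measure <- match.arg(measure)
  if (is.null(sex_offset)) sex_offset <- if (measure == "height") 0.6 else 0.25
  beta <- .toy_beta[[measure]]
  X <- cbind(1, rcs_basis(age, default_knots(measure)))
  drop(X %*% beta) + ifelse(sex == "M", sex_offset, -sex_offset)
}

#' Build the toy growth reference set
#'
#' Generates LMS tables for all four indicators from the toy median curves:
#' HAZ/WAZ/BMIZ on an age grid (months), WHZ over the implied length range.
#' `L = 1` throughout and constant coefficients of variation. This is a
#' synthetic stand-in with the *structure* of an official reference; its
#' values are generator parameters, not population data.
#'
#' @param s_height,s_weight,s_bmi Coefficients of variation per indicator.
#' @param age_grid Tabulated ages in months.
#' @param whz_grid Tabulated lengths in cm for the WHZ table.
#' @return A `growth_reference_set`.
#' @export
make_toy_reference <- function(s_height = 0.035, s_weight = 0.11,
                               s_bmi = 0.09, age_grid = 0:59,
                               whz_grid = seq(40, 125, by = 1)) {
  refs <- list()
  fine <- seq(0, 59, by = 0.25)
  for (sx in biv_sexes) {
    m_len <- toy_median(age_grid, "height", sx)
    m_wt <- toy_median(age_grid, "weight", sx)
    if (any(diff(m_len) <= 0) || any(diff(m_wt) <= 0)) {
      stop("invalid config: toy median curves must be strictly increasing",
           call. = FALSE)
    }
    m_bmi <- m_wt / (m_len / 100)^2
    # WHZ: median weight at the age where the median length equals the axis
    len_fine <- toy_median(fine, "height", sx)
    age_at_len <- stats::approx(len_fine, fine, xout = whz_grid, rule = 2)$y
    m_whz <- toy_median(age_at_len, "weight", sx)
    refs <- c(refs, list(
      growth_reference("HAZ", sx, age_grid, 1, m_len, s_height),
      growth_reference("WAZ", sx, age_grid, 1, m_wt, s_weight),
      growth_reference("BMIZ", sx, age_grid, 1, m_bmi, s_bmi),
      growth_reference("WHZ", sx, whz_grid, 1, m_whz, s_weight)))
  }
  growth_reference_set(refs)
}

#' Simulation configuration
#'
#' @param n_children Number of children.
#' @param visits `c(min, max)` of the uniform visit-count distribution.
#' @param sex_ratio Probability of male.
#' @param tau_height,sigma_height Between-child intercept SD and visit noise
#'   SD for length/height (cm).
#' @param tau_weight,sigma_weight Same for weight (kg).
#' @param first_visit_max Latest possible first-visit age (months).
#' @param gap_range `c(min, max)` months between consecutive visits.
#' @param round_height,round_weight Recording resolution (cm, kg).
#' @param birth_window Calendar window for birth dates.
#' @param seed Master seed; fixes the full output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_children = 1000, visits = c(2, 8), sex_ratio = 0.5,
                       tau_height = 2, sigma_height = 0.8,
                       tau_weight = 0.5, sigma_weight = 0.25,
                       first_visit_max = 12, gap_range = c(1, 10),
                       round_height = 0.1, round_weight = 0.01,
                       birth_window = as.Date(c("2010-01-01", "2014-12-31")),
                       seed = 1) {
  stopifnot(n_children >= 1, visits[1] >= 2, visits[2] >= visits[1],
            tau_height >= 0, sigma_height > 0,
            tau_weight >= 0, sigma_weight > 0, gap_range[1] > 0)
  structure(as.list(environment()), class = "sim_config")
}

# split one master seed into named substreams so toggling one purpose does
# not perturb the draws of another
split_seed <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate clean longitudinal growth records
#'
#' Draws children with 2+ visits at ages 0-59 months (first visit uniform on
#' `[0, first_visit_max]`, subsequent gaps uniform on `gap_range`, truncated
#' at 59 months) and generates length/height and weight from the toy median
#' curves plus a child-level random intercept and visit-level Gaussian
#' noise. Visit dates are the birth date plus the age rounded to whole days,
#' so ages recomputed from dates match the generating ages to recording
#' precision. Output is a pure function of the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return `list(records, truth)`: records in the pipeline's input layout
#'   (plus `.rid`), truth with one `clean` label per record.
#' @export
simulate_children <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed, 2)

  # stream 1: cohort structure (sex, birth dates, visit ages)
  set.seed(seeds[1])
  n <- config$n_children
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "M", "F")
  J <- sample(seq(config$visits[1], config$visits[2]), n, replace = TRUE)
  birth <- config$birth_window[1] +
    sample.int(as.integer(diff(config$birth_window)) + 1L, n, replace = TRUE) - 1L
  ages <- vector("list", n)
  for (i in seq_len(n)) {
    a <- cumsum(c(stats::runif(1, 0, config$first_visit_max),
                  stats::runif(J[i] - 1, config$gap_range[1],
                               config$gap_range[2])))
    ages[[i]] <- a[a <= 59]
  }
  J_eff <- lengths(ages)
  N <- sum(J_eff)
  child <- rep(seq_len(n), J_eff)
  age_days <- round(unlist(ages) * 30.4375)
  visit_date <- birth[child] + age_days
  age_eff <- age_days / 30.4375

  # stream 2: measurement noise
  set.seed(seeds[2])
  b_len <- stats::rnorm(n, 0, config$tau_height)
  b_wt <- stats::rnorm(n, 0, config$tau_weight)
  len <- toy_median(age_eff, "height", sex[child]) + b_len[child] +
    stats::rnorm(N, 0, config$sigma_height)
  wt <- toy_median(age_eff, "weight", sex[child]) + b_wt[child] +
    stats::rnorm(N, 0, config$sigma_weight)

  records <- data.frame(
    child_id = sprintf("C%06d", child), sex = sex[child],
    birth_date = birth[child], visit_date = visit_date,
    length_height_cm = round(len / config$round_height) * config$round_height,
    weight_kg = round(wt / config$round_weight) * config$round_weight,
    stringsAsFactors = FALSE)
  records$.rid <- seq_len(N)
  truth <- data.frame(.rid = records$.rid, child_id = records$child_id,
                      visit_date = records$visit_date,
                      measure = NA_character_, error_type = "clean",
                      pre_value = NA_real_, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Error-injection specification
#'
#' Per-record injection rates for the error taxonomy of routine data entry:
#' decimal shifts (x10 or /10), heights recorded in metres, transposed
#' digits, swapped height/weight fields, exact duplicate rows, missing
#' fields, and implausible height decreases (a later visit set 3-10 cm
#' below the child's previous height, so the injected drop always violates
#' the -2 cm rule; smaller jitter belongs to the clean noise model).
#'
#' @param decimal_shift,unit_error,digit_transposition,swap_height_weight,duplicate_row,missing_field,height_decrease
#'   Rates in `[0, 1]`; their sum must not exceed 1 (targets are disjoint).
#' @return A list of class `error_spec`.
#' @export
error_spec <- function(decimal_shift = 0, unit_error = 0,
                       digit_transposition = 0, swap_height_weight = 0,
                       duplicate_row = 0, missing_field = 0,
                       height_decrease = 0) {
  rates <- as.list(environment())
  v <- unlist(rates)
  if (any(v < 0) || any(v > 1) || sum(v) > 1) {
    stop("invalid config: rates must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  structure(rates, class = "error_spec")
}

transpose_digits <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  digits <- gsub("[^0-9]", "", s)
  if (nchar(digits) < 2) return(x)
  dot <- regexpr(".", s, fixed = TRUE)
  d <- strsplit(digits, "")[[1]]
  tmp <- d[1]; d[1] <- d[2]; d[2] <- tmp
  out <- paste(d, collapse = "")
  if (dot > 0) {
    out <- paste0(substr(out, 1, dot - 1), ".", substr(out, dot, nchar(out)))
  }
  as.numeric(out)
}

#' Inject labelled errors into clean records
#'
#' Applies each error type of the [error_spec()] to a disjoint random
#' subset of records (count = rate x number of records, rounded). Every
#' injected error is labelled with its type and pre-error value; duplicate
#' rows copy all five key fields exactly and are appended at the end.
#'
#' @param records Clean records (with `.rid`).
#' @param spec An [error_spec()].
#' @param seed Seed for target selection and error magnitudes.
#' @return `list(records, truth)` where truth labels every row (`clean` or
#'   the error type) and records the pre-error value.
#' @export
inject_errors <- function(records, spec = error_spec(), seed = 1) {
  stopifnot(inherits(spec, "error_spec"), !is.null(records$.rid))
  set.seed(as.integer(seed))
  n <- nrow(records)
  truth <- data.frame(.rid = records$.rid, child_id = records$child_id,
                      visit_date = records$visit_date,
                      measure = NA_character_, error_type = "clean",
                      pre_value = NA_real_, stringsAsFactors = FALSE)
  pool <- seq_len(n)
  take <- function(k, from = pool) {
    k <- min(k, length(from))
    idx <- if (k > 0) sort(sample(from, k)) else integer()
    pool <<- setdiff(pool, idx)
    idx
  }
  mark <- function(idx, type, measure, pre) {
    truth$error_type[idx] <<- type
    truth$measure[idx] <<- measure
    truth$pre_value[idx] <<- pre
  }

  idx <- take(round(spec$decimal_shift * n))
  if (length(idx)) {
    meas <- sample(c("height", "weight"), length(idx), replace = TRUE)
    fac <- sample(c(10, 0.1), length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      col <- measure_col(meas[k])
      pre <- records[[col]][idx[k]]
      if (is.na(pre)) next
      records[[col]][idx[k]] <- pre * fac[k]
      mark(idx[k], "decimal_shift", meas[k], pre)
    }
  }

  idx <- take(round(spec$unit_error * n))
  if (length(idx)) {
    pre <- records$length_height_cm[idx]
    records$length_height_cm[idx] <- pre / 100
    mark(idx, "unit_error", "height", pre)
  }

  idx <- take(round(spec$digit_transposition * n))
  if (length(idx)) {
    meas <- sample(c("height", "weight"), length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      col <- measure_col(meas[k])
      pre <- records[[col]][idx[k]]
      if (is.na(pre)) next
      records[[col]][idx[k]] <- transpose_digits(pre)
      mark(idx[k], "digit_transposition", meas[k], pre)
    }
  }

  idx <- take(round(spec$swap_height_weight * n))
  if (length(idx)) {
    pre <- records$length_height_cm[idx]
    records$length_height_cm[idx] <- records$weight_kg[idx]
    records$weight_kg[idx] <- pre
    mark(idx, "swap_height_weight", "both", pre)
  }

  idx <- take(round(spec$missing_field * n))
  if (length(idx)) {
    meas <- sample(c("height", "weight"), length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      col <- measure_col(meas[k])
      pre <- records[[col]][idx[k]]
      records[[col]][idx[k]] <- NA_real_
      mark(idx[k], "missing_field", meas[k], pre)
    }
  }

  # height decrease: target visits with an earlier visit of the same child;
  # the new value sits 3-10 cm below the child's previous height
  ord <- order(records$child_id, records$visit_date)
  pos <- integer(n); pos[ord] <- seq_len(n)
  prev_row <- rep(NA_integer_, n)
  same_child <- c(FALSE, records$child_id[ord][-1] ==
                    records$child_id[ord][-n])
  prev_row[ord[which(same_child)]] <- ord[which(same_child) - 1L]
  eligible <- intersect(pool, which(!is.na(prev_row) &
                                      !is.na(records$length_height_cm)))
  # never target two adjacent visits of one child, so each injected value is
  # computed from an untouched predecessor and always violates the rule
  want <- round(spec$height_decrease * n)
  idx <- integer()
  for (cand in sample(eligible)) {
    if (length(idx) >= want) break
    if (!(prev_row[cand] %in% idx) && !(cand %in% prev_row[idx])) {
      idx <- c(idx, cand)
    }
  }
  idx <- sort(idx)
  pool <- setdiff(pool, idx)
  if (length(idx)) {
    pre <- records$length_height_cm[idx]
    drop_cm <- stats::runif(length(idx), 3, 10)
    records$length_height_cm[idx] <-
      round(records$length_height_cm[prev_row[idx]] - drop_cm, 1)
    mark(idx, "height_decrease", "height", pre)
  }

  k_dup <- round(spec$duplicate_row * n)
  if (k_dup > 0) {
    idx <- sort(pool[sample.int(length(pool), k_dup)])
    copies <- records[idx, , drop = FALSE]
    copies$.rid <- max(records$.rid) + seq_len(k_dup)
    records <- rbind(records, copies)
    truth <- rbind(truth, data.frame(
      .rid = copies$.rid, child_id = copies$child_id,
      visit_date = copies$visit_date, measure = NA_character_,
      error_type = "duplicate_row", pre_value = NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

flag_family <- function(flag_type) {
  ifelse(flag_type == "duplicate", "duplicate",
  ifelse(flag_type %in% c("missing_negative", "out_of_age_range"), "missing",
  ifelse(flag_type == "singleton", "singleton",
  ifelse(grepl("^po_", flag_type), "po",
  ifelse(flag_type == "lo", "lo",
  ifelse(flag_type == "decreasing_height", "decreasing_height", "other"))))))
}

#' Evaluate flags against injected-error truth labels
#'
#' Standard 2x2 metrics of the cleaning against the known contamination:
#' per error type and flag family (duplicate, missing, po, lo,
#' decreasing_height, singleton, plus a `combined` any-flag column),
#' sensitivity = fraction of injected records receiving a flag of that
#' family; per family, specificity and positive predictive value over the
#' clean records.
#'
#' @param flags Flag `data.frame` (e.g. `result$flags` from
#'   [run_pipeline()]).
#' @param truth Truth labels from [inject_errors()].
#' @return `list(by_type, summary)` data frames.
#' @export
evaluate_flags <- function(flags, truth) {
  stopifnot(is.data.frame(flags), is.data.frame(truth))
  if (nrow(flags) && !all(flags$.rid %in% truth$.rid)) {
    stop("alignment error: flags reference records absent from truth",
         call. = FALSE)
  }
  families <- c("duplicate", "missing", "po", "lo", "decreasing_height",
                "singleton", "combined")
  fam <- flag_family(flags$flag_type)
  flagged_by <- lapply(stats::setNames(families, families), function(f) {
    if (f == "combined") unique(flags$.rid)
    else unique(flags$.rid[fam == f])
  })
  types <- unique(truth$error_type)
  by_type <- do.call(rbind, lapply(types, function(ty) {
    rid <- truth$.rid[truth$error_type == ty]
    do.call(rbind, lapply(families, function(f) {
      caught <- sum(rid %in% flagged_by[[f]])
      data.frame(error_type = ty, flag_family = f, n_errors = length(rid),
                 n_caught = caught, sensitivity = caught / length(rid),
                 stringsAsFactors = FALSE)
    }))
  }))
  clean_rid <- truth$.rid[truth$error_type == "clean"]
  err_rid <- truth$.rid[truth$error_type != "clean"]
  summary <- do.call(rbind, lapply(families, function(f) {
    fl <- flagged_by[[f]]
    fp <- sum(clean_rid %in% fl)
    tp <- sum(err_rid %in% fl)
    data.frame(flag_family = f, n_flagged = length(fl), true_positives = tp,
               false_positives = fp,
               ppv = if (length(fl)) tp / length(fl) else NA_real_,
               specificity = 1 - fp / max(length(clean_rid), 1),
               stringsAsFactors = FALSE)
  }))
  list(by_type = by_type, summary = summary)
}

#' Simulate data exactly from the random-intercept spline model
#'
#' Low-level generator for the longitudinal module: visit ages uniform on
#' `age_range`, design = intercept + [rcs_basis()], outcomes
#' `y = X beta + b_subject + e`. Used for parameter-recovery and null
#' flag-rate checks where the fitted model must be exactly the generating
#' model.
#'
#' @param n_subjects Number of subjects.
#' @param visits Visits per subject (scalar or vector of length
#'   `n_subjects`).
#' @param beta True coefficients (intercept + spline columns); defaults to
#'   the toy length/height trajectory.
#' @param knots Spline knots.
#' @param tau,sigma True random-intercept and residual SDs.
#' @param age_range Visit-age range in months.
#' @param seed Seed.
#' @return `list(X, y, subject, age, beta, tau, sigma)`.
#' @export
simulate_lmm_data <- function(n_subjects, visits = 4,
                              beta = toy_trajectory_coefficients("height"),
                              knots = default_knots("height"),
                              tau = 3, sigma = 1, age_range = c(0, 59),
                              seed = 1) {
  set.seed(as.integer(seed))
  J <- rep_len(visits, n_subjects)
  subject <- rep(seq_len(n_subjects), J)
  N <- length(subject)
  age <- stats::runif(N, age_range[1], age_range[2])
  X <- cbind("(Intercept)" = 1, rcs_basis(age, knots))
  stopifnot(ncol(X) == length(beta))
  y <- drop(X %*% beta) + stats::rnorm(n_subjects, 0, tau)[subject] +
    stats::rnorm(N, 0, sigma)
  list(X = X, y = y, subject = subject, age = age, beta = beta,
       tau = tau, sigma = sigma)
}
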