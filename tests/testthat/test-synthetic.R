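test_that("toy reference is monotone, smooth and self-consistent", {
  refs <- make_toy_reference()
  expect_setequal(names(refs),
                  as.vector(outer(c("HAZ", "WAZ", "BMIZ", "WHZ"), c("M", "F"),
                                  paste, sep = ".")))
  # sex-averaged median length at birth is the 50 cm anchor
  expect_equal(mean(c(toy_median(0, "height", "M"),
                      toy_median(0, "height", "F"))), 50)
  ages <- seq(0, 58, by = 0.5)
  expect_true(all(diff(toy_median(ages, "height", "M")) > 0))
  expect_true(all(diff(toy_median(ages, "weight", "F")) > 0))
  # a measurement generated at true z on the reference computes back to z
  for (z_true in c(-2, 0, 2)) {
    p <- interpolate_lms(refs[["WAZ.F"]], 18)
    rec <- data.frame(sex = "F", age_months = 18,
                      length_height_cm = NA_real_,
                      weight_kg = zscore_to_value(z_true, p$L, p$M, p$S))
    expect_equal(compute_zscores(rec, refs)$waz, z_true, tolerance = 1e-9)
  }
})

test_that("simulation is a pure function of the config", {
  cfg <- sim_config(n_children = 100, seed = 77)
  a <- simulate_children(cfg)
  b <- simulate_children(cfg)
  expect_identical(a, b)
  c2 <- simulate_children(sim_config(n_children = 100, seed = 78))
  expect_false(identical(a$records$length_height_cm,
                         c2$records$length_height_cm))
})

test_that("simulated cohorts have the configured structure", {
  sim <- simulate_children(sim_config(n_children = 500, seed = 10))
  r <- sim$records
  r$age <- compute_age_months(r$birth_date, r$visit_date)
  expect_true(all(r$age >= 0 & r$age <= 59))
  expect_true(all(table(r$child_id) >= 2))
  expect_true(all(r$sex %in% c("M", "F")))
  expect_equal(nrow(sim$truth), nrow(r))
  expect_true(all(sim$truth$error_type == "clean"))
  # near-degenerate noise: children sit on the median curve
  tight <- simulate_children(sim_config(n_children = 50, tau_height = 0,
                                        sigma_height = 1e-6,
                                        round_height = 1e-6, seed = 2))
  tr <- tight$records
  tr$age <- compute_age_months(tr$birth_date, tr$visit_date)
  expect_lt(max(abs(tr$length_height_cm -
                      toy_median(tr$age, "height", tr$sex))), 1e-4)
})

test_that("child-mean deviations decompose into tau^2 + sigma^2 / J", {
  cfg <- sim_config(n_children = 5000, tau_height = 2, sigma_height = 0.8,
                    seed = 19)
  sim <- simulate_children(cfg)
  r <- sim$records
  r$age <- compute_age_months(r$birth_date, r$visit_date)
  dev <- r$length_height_cm - toy_median(r$age, "height", r$sex)
  child_mean <- tapply(dev, r$child_id, mean)
  J <- tapply(dev, r$child_id, length)
  expected <- cfg$tau_height^2 + mean(cfg$sigma_height^2 / J)
  expect_equal(var(child_mean), expected, tolerance = 0.05)
})

test_that("error injection is labelled, disjoint and conservative", {
  sim <- simulate_children(sim_config(n_children = 400, seed = 30))
  none <- inject_errors(sim$records, error_spec(), seed = 1)
  expect_identical(none$records, sim$records)
  expect_true(all(none$truth$error_type == "clean"))

  spec <- error_spec(decimal_shift = 0.02, unit_error = 0.01,
                     digit_transposition = 0.01, swap_height_weight = 0.01,
                     duplicate_row = 0.02, missing_field = 0.01,
                     height_decrease = 0.02)
  inj <- inject_errors(sim$records, spec, seed = 2)
  tr <- inj$truth[inj$truth$error_type != "clean", ]
  n0 <- nrow(sim$records)
  counts <- table(tr$error_type)
  for (ty in setdiff(names(spec), "duplicate_row")) {
    expect_equal(unname(counts[ty]), round(spec[[ty]] * n0))
  }
  expect_equal(unname(counts["duplicate_row"]), round(spec$duplicate_row * n0))
  # disjoint targets: each original record carries at most one error
  expect_false(anyDuplicated(tr$.rid) > 0)

  # decimal shifts are exactly x10 or /10 of the labelled pre-error value
  ds <- tr[tr$error_type == "decimal_shift", ]
  now <- inj$records[match(ds$.rid, inj$records$.rid), ]
  val <- ifelse(ds$measure == "height", now$length_height_cm, now$weight_kg)
  ratio <- val / ds$pre_value
  expect_true(all(abs(ratio - 10) < 1e-9 | abs(ratio - 0.1) < 1e-9))

  # duplicates copy the five key fields exactly
  dup <- inj$records[inj$records$.rid %in%
                       tr$.rid[tr$error_type == "duplicate_row"], ]
  key <- function(d) paste(d$child_id, d$birth_date, d$visit_date,
                           d$length_height_cm, d$weight_kg)
  expect_true(all(key(dup) %in% key(sim$records)))

  # injected height decreases always violate the -2 cm rule
  hd <- tr[tr$error_type == "height_decrease", ]
  r <- inj$records
  ord <- order(r$child_id, r$visit_date)
  r <- r[ord, ]
  for (rid in hd$.rid) {
    i <- which(r$.rid == rid)
    expect_equal(r$child_id[i - 1], r$child_id[i])
    expect_lt(r$length_height_cm[i] - r$length_height_cm[i - 1], -2)
  }
  expect_error(error_spec(decimal_shift = 0.9, duplicate_row = 0.2), "sum")
})

test_that("flag evaluation computes the 2x2 metrics", {
  truth <- data.frame(.rid = 1:10, child_id = as.character(1:10),
                      visit_date = as.Date("2012-01-01"),
                      measure = NA, error_type = c(rep("clean", 8),
                                                   "decimal_shift",
                                                   "decimal_shift"),
                      pre_value = NA)
  flags <- data.frame(.rid = c(9L, 10L), child_id = c("9", "10"),
                      visit_date = as.Date("2012-01-01"), measure = "height",
                      flag_type = "po_haz", stage = "population_outliers",
                      value = c(9, -9))
  ev <- evaluate_flags(flags, truth)
  row <- ev$by_type[ev$by_type$error_type == "decimal_shift" &
                      ev$by_type$flag_family == "po", ]
  expect_equal(row$sensitivity, 1)
  expect_equal(ev$summary$specificity[ev$summary$flag_family == "po"], 1)
  expect_equal(ev$summary$ppv[ev$summary$flag_family == "po"], 1)
  # no flags: sensitivity 0, specificity 1
  ev0 <- evaluate_flags(flags[0, ], truth)
  expect_true(all(ev0$by_type$sensitivity[
    ev0$by_type$error_type == "decimal_shift"] == 0))
  expect_true(all(ev0$summary$specificity == 1))
  bad <- flags
  bad$.rid <- c(99L, 100L)
  expect_error(evaluate_flags(bad, truth), "alignment")
})

test_that("fitting the trajectory model on clean simulated data recovers the variances", {
  # single sex: pooling sexes would add the +/-0.6 cm offset variance
  # (0.36 cm^2) to the between-child component, so truth would be 4.36.
  # n sized so that the 5% tolerance is ~2.6 sampling SDs of tau2-hat
  sim <- simulate_children(sim_config(n_children = 6000, tau_height = 2,
                                      sigma_height = 0.8, sex_ratio = 1,
                                      seed = 99))
  r <- sim$records
  r$age <- compute_age_months(r$birth_date, r$visit_date)
  fit <- fit_growth_lmm(r$age, r$length_height_cm, r$child_id,
                        knots = default_knots("height"))
  expect_lt(abs(fit$tau2 - 4) / 4, 0.05)
  expect_lt(abs(fit$sigma2 - 0.64) / 0.64, 0.05)
})

test_that("contamination raises the population-outlier rate monotonically", {
  sim <- simulate_children(sim_config(n_children = 800, seed = 55))
  refs <- make_toy_reference()
  rates <- c(0, 0.01, 0.03, 0.06)
  po_rate <- vapply(rates, function(rt) {
    inj <- inject_errors(sim$records, error_spec(decimal_shift = rt),
                         seed = 56)
    res <- run_pipeline(inj$records, refs,
                        pipeline_config(lo_cutoffs = 3,
                                        decreasing_heights = FALSE))
    sum(grepl("^po_", res$flags$flag_type)) / nrow(inj$records)
  }, numeric(1))
  expect_true(all(diff(po_rate) > 0))
})
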