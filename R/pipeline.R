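#' Age in fractional months between two dates
#'
#' Days between `birth_date` and `visit_date` divided by 30.4375 (the mean
#' Gregorian month). Negative ages (visit before birth) are returned as
#' negative numbers and routed to the missing/negative removal stage by the
#' pipeline rather than raising an error.
#'
#' @param birth_date,visit_date `Date` vectors (or coercible).
#' @param divisor Days per month.
#' @return Numeric vector of ages in months.
#' @export
compute_age_months <- function(birth_date, visit_date, divisor = 30.4375) {
  as.numeric(as.Date(visit_date) - as.Date(birth_date)) / divisor
}

measure_col <- function(measure) {
  switch(measure, height = "length_height_cm", weight = "weight_kg",
         stop("unknown measure: ", measure, call. = FALSE))
}

make_flags <- function(records, idx, measure, flag_type, stage, value) {
  if (!length(idx)) {
    return(data.frame(.rid = integer(), child_id = character(),
                      visit_date = as.Date(character()),
                      measure = character(), flag_type = character(),
                      stage = character(), value = numeric()))
  }
  data.frame(.rid = records$.rid[idx], child_id = records$child_id[idx],
             visit_date = records$visit_date[idx],
             measure = measure, flag_type = flag_type, stage = stage,
             value = value, stringsAsFactors = FALSE)
}

#' Read visit records from delimited text
#'
#' Expected header: `child_id,sex,birth_date,visit_date,length_height_cm,
#' weight_kg`; dates ISO 8601; sex `M`/`F`; empty field = missing.
#'
#' @param path File path.
#' @return `data.frame` with parsed dates and a stable internal record id
#'   column `.rid`.
#' @export
read_growth_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(child_id = "character"))
  need <- c("child_id", "sex", "birth_date", "visit_date",
            "length_height_cm", "weight_kg")
  if (!all(need %in% names(df))) {
    stop("records file must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$birth_date <- as.Date(df$birth_date)
  df$visit_date <- as.Date(df$visit_date)
  df$length_height_cm <- as.numeric(df$length_height_cm)
  df$weight_kg <- as.numeric(df$weight_kg)
  df$.rid <- seq_len(nrow(df))
  df
}

#' Write visit records to delimited text
#'
#' @param records Records `data.frame`.
#' @param path File path.
#' @export
write_growth_records <- function(records, path) {
  cols <- c("child_id", "sex", "birth_date", "visit_date",
            "length_height_cm", "weight_kg")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Remove exact duplicate rows
#'
#' Rows identical on the five-field key (child id, birth date, visit date,
#' length/height, weight) are collapsed to the first occurrence in input
#' order; later copies are flagged `duplicate`. Rows differing in any key
#' field are all kept.
#'
#' @param records Records `data.frame` (with `.rid`).
#' @param stage Stage label for the flags.
#' @return `list(kept, flags)`.
#' @export
remove_duplicates <- function(records, stage = "duplicates") {
  if (!nrow(records)) return(list(kept = records,
                                  flags = make_flags(records, integer(), NA,
                                                     "duplicate", stage, NA)))
  key <- paste(records$child_id, records$birth_date, records$visit_date,
               records$length_height_cm, records$weight_kg, sep = "\r")
  dup <- which(duplicated(key))
  list(kept = records[setdiff(seq_len(nrow(records)), dup), , drop = FALSE],
       flags = make_flags(records, dup, NA_character_, "duplicate", stage,
                          NA_real_))
}

#' Remove records with missing, non-positive or out-of-range values
#'
#' For the given measure stream, flags records with an absent or
#' non-positive measurement, absent/invalid sex, absent dates, or negative
#' age as `missing_negative`, and records with age above `max_age_months`
#' as `out_of_age_range`. Zero measurements are treated as invalid by
#' default (a 0 cm length is physically impossible); set
#' `zero_invalid = FALSE` for a strict "negative only" reading.
#'
#' @param records Records `data.frame` with `age_months`.
#' @param measure `"height"` or `"weight"`.
#' @param max_age_months Upper retention bound (completed study window).
#' @param zero_invalid Treat exact zeros as invalid.
#' @param stage Stage label.
#' @return `list(kept, flags)`.
#' @export
remove_missing_negative <- function(records, measure, max_age_months = 59,
                                    zero_invalid = TRUE,
                                    stage = "missing_negative") {
  val <- records[[measure_col(measure)]]
  bad_val <- is.na(val) | (if (zero_invalid) val <= 0 else val < 0)
  bad_sex <- is.na(records$sex) | !(records$sex %in% biv_sexes)
  bad_age <- is.na(records$age_months) | records$age_months < 0
  invalid <- bad_val | bad_sex | bad_age
  over <- !invalid & records$age_months > max_age_months
  flags <- rbind(
    make_flags(records, which(invalid), measure, "missing_negative", stage,
               val[which(invalid)]),
    make_flags(records, which(over), measure, "out_of_age_range", stage,
               records$age_months[which(over)]))
  list(kept = records[!(invalid | over), , drop = FALSE], flags = flags)
}

#' Remove children contributing a single measurement
#'
#' All records of children with exactly one retained measurement of the
#' measure are flagged `singleton`: such children cannot inform a
#' longitudinal model and would only shrink the residual variance.
#'
#' @inheritParams remove_missing_negative
#' @return `list(kept, flags)`.
#' @export
remove_singletons <- function(records, measure, stage = "singleton") {
  cnt <- table(records$child_id)
  single <- names(cnt)[cnt == 1L]
  idx <- which(records$child_id %in% single)
  list(kept = records[setdiff(seq_len(nrow(records)), idx), , drop = FALSE],
       flags = make_flags(records, idx, measure, "singleton", stage,
                          records[[measure_col(measure)]][idx]))
}

#' Flag implausible decreases in a height series
#'
#' Scans one child's length/height series in age order, keeping a running
#' last-accepted value initialized at the first measurement (assumed
#' correct). A measurement more than 2 cm below the last accepted value is
#' flagged and does not update the running value; small negative
#' differences (measurement/device variation) pass.
#'
#' @param values Length/height measurements in age order.
#' @param ages Optional visit ages; if supplied they must be
#'   non-decreasing, otherwise an ordering error is raised.
#' @param threshold Flagging threshold on the difference (cm); default -2.
#' @return Logical vector, `TRUE` where flagged.
#' @export
flag_decreasing_heights <- function(values, ages = NULL, threshold = -2) {
  if (!is.null(ages)) {
    stopifnot(length(ages) == length(values))
    if (is.unsorted(ages)) {
      stop("ordering error: series must be sorted by age", call. = FALSE)
    }
  }
  n <- length(values)
  flag <- logical(n)
  if (n == 0) return(flag)
  last <- values[1]
  for (j in seq_len(n)[-1]) {
    if (values[j] - last < threshold) {
      flag[j] <- TRUE
    } else {
      last <- values[j]
    }
  }
  flag
}

apply_decreasing_heights <- function(records, threshold = -2,
                                     stage = "decreasing_heights") {
  ord <- order(records$child_id, records$age_months)
  rec <- records[ord, , drop = FALSE]
  flag_sorted <- unlist(lapply(
    split(rec$length_height_cm, rec$child_id, drop = TRUE),
    flag_decreasing_heights, threshold = threshold), use.names = FALSE)
  idx <- ord[flag_sorted]
  list(kept = records[setdiff(seq_len(nrow(records)), idx), , drop = FALSE],
       flags = make_flags(records, idx, "height", "decreasing_height", stage,
                          records$length_height_cm[idx]))
}

stat_row <- function(x, stage, sex, variable) {
  x <- x[!is.na(x)]
  data.frame(stage = stage, sex = sex, variable = variable, n = length(x),
             mean = if (length(x)) mean(x) else NA_real_,
             sd = if (length(x) > 1) stats::sd(x) else NA_real_,
             min = if (length(x)) min(x) else NA_real_,
             max = if (length(x)) max(x) else NA_real_)
}

#' Descriptive statistics for a stage snapshot
#'
#' Per sex: mean, SD, min, max of age, the measurement, the z-score (if
#' supplied), and measurements per child.
#'
#' @param records Stage snapshot `data.frame`.
#' @param measure `"height"` or `"weight"`.
#' @param z Optional z-score vector aligned with `records`.
#' @param stage Stage label.
#' @return `data.frame` with columns `stage,sex,variable,n,mean,sd,min,max`.
#' @export
descriptive_stats <- function(records, measure, z = NULL, stage = "stage") {
  out <- list()
  for (sx in biv_sexes) {
    sel <- !is.na(records$sex) & records$sex == sx
    if (!any(sel)) next
    r <- records[sel, , drop = FALSE]
    out[[length(out) + 1L]] <- stat_row(r$age_months, stage, sx, "age_months")
    out[[length(out) + 1L]] <- stat_row(r[[measure_col(measure)]], stage, sx,
                                        measure_col(measure))
    if (!is.null(z)) {
      out[[length(out) + 1L]] <- stat_row(z[sel], stage, sx, "zscore")
    }
    out[[length(out) + 1L]] <- stat_row(as.numeric(table(r$child_id)), stage,
                                        sx, "measurements_per_child")
  }
  do.call(rbind, out)
}

#' Pipeline configuration
#'
#' @param measures Streams to clean: subset of `c("height", "weight")`.
#' @param po Plausibility cutoffs ([po_cutoffs()]).
#' @param po_dataset_kind `"per_stream"` (HAZ for height, WAZ for weight; the
#'   default) or `"combined"` (all four indicators flag in both streams).
#' @param lo_cutoffs Residual cutoffs; each is applied to the same post-PO
#'   dataset (parallel columns, not sequentially).
#' @param residual_mode,residual_type See [scaled_residuals()].
#' @param method `"REML"` or `"ML"` for the trajectory model.
#' @param knots_height,knots_weight Spline knots per measure.
#' @param decreasing_heights Run the decreasing-heights branch (height
#'   stream, from the post-PO dataset).
#' @param dh_threshold Decreasing-heights threshold in cm.
#' @param adjust_extreme Extreme-tail z adjustment for weight-based
#'   indicators.
#' @param age_divisor Days per month for age computation.
#' @param max_age_months Oldest retained age.
#' @param zero_invalid Treat zero measurements as invalid.
#' @param verbose Log per-stage counts to standard error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(measures = c("height", "weight"),
                            po = po_cutoffs(),
                            po_dataset_kind = c("per_stream", "combined"),
                            lo_cutoffs = c(3, 4, 5, 6),
                            residual_mode = "marginal",
                            residual_type = "scaled",
                            method = "REML",
                            knots_height = default_knots("height"),
                            knots_weight = default_knots("weight"),
                            decreasing_heights = TRUE,
                            dh_threshold = -2,
                            adjust_extreme = TRUE,
                            age_divisor = 30.4375,
                            max_age_months = 59,
                            zero_invalid = TRUE,
                            verbose = FALSE) {
  measures <- match.arg(measures, several.ok = TRUE)
  po_dataset_kind <- match.arg(po_dataset_kind)
  if (any(lo_cutoffs <= 0)) {
    stop("invalid config: lo_cutoffs must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage_count <- function(stream, branch, stage, d_in, d_out) {
  data.frame(stream = stream, branch = branch, stage = stage,
             records_in = nrow(d_in), records_removed = nrow(d_in) - nrow(d_out),
             records_kept = nrow(d_out),
             children_in = length(unique(d_in$child_id)),
             children_kept = length(unique(d_out$child_id)),
             stringsAsFactors = FALSE)
}

pipeline_log <- function(verbose, row) {
  if (verbose) {
    message(sprintf("[%s/%s] %s: in=%d removed=%d kept=%d",
                    row$stream, row$branch, row$stage, row$records_in,
                    row$records_removed, row$records_kept))
  }
}

#' Run the staged cleaning pipeline
#'
#' Orchestrates, per measurement stream: duplicate removal (consolidated
#' five-field key) -> missing/negative/age-range removal -> single-
#' measurement children removal -> z-score computation -> population-outlier
#' removal -> second singleton pass -> sex-stratified spline mixed-model fit
#' -> residual-based longitudinal-outlier flagging at each requested cutoff
#' (each against the same post-PO dataset) -> optional decreasing-heights
#' branch (height stream). Produces full flag and stage accounting,
#' prevalence of stunting/underweight categories at every stage, descriptive
#' statistics, and a flag-proportion-by-age profile. The run is
#' deterministic given the input order.
#'
#' @param records Records `data.frame` (see [read_growth_records()]).
#' @param refs A `growth_reference_set`.
#' @param config A [pipeline_config()].
#' @return Object of class `biv_pipeline`: `cleaned` (per stream: `post_po`,
#'   `post_singleton2`, `lo` per cutoff, `decreasing_heights`), `flags`,
#'   `stage_report`, `prevalence`, `descriptives`, `flags_by_age`, `fits`,
#'   `config`.
#' @export
run_pipeline <- function(records, refs, config = pipeline_config()) {
  stopifnot(is.data.frame(records), inherits(refs, "growth_reference_set"),
            inherits(config, "pipeline_config"))
  if (is.null(records$.rid)) records$.rid <- seq_len(nrow(records))
  records$birth_date <- as.Date(records$birth_date)
  records$visit_date <- as.Date(records$visit_date)
  records$age_months <- ifelse(
    is.na(records$birth_date) | is.na(records$visit_date), NA_real_,
    compute_age_months(records$birth_date, records$visit_date,
                       config$age_divisor))

  all_flags <- list()
  report <- list()
  prevalence <- list()
  descriptives <- list()
  by_age <- list()
  fits <- list()
  cleaned <- list()

  dup <- remove_duplicates(records)
  all_flags$dup <- dup$flags
  rep_row <- stage_count("all", "main", "duplicates", records, dup$kept)
  pipeline_log(config$verbose, rep_row)
  report$dup <- rep_row
  d0 <- dup$kept

  z0 <- compute_zscores(d0, refs, adjust_extreme = config$adjust_extreme)

  for (measure in config$measures) {
    stream_ind <- if (measure == "height") "HAZ" else "WAZ"
    zcol <- tolower(stream_ind)
    kind <- if (config$po_dataset_kind == "combined") "combined"
            else if (measure == "height") "length_height" else "weight"

    mn <- remove_missing_negative(d0, measure,
                                  max_age_months = config$max_age_months,
                                  zero_invalid = config$zero_invalid)
    all_flags[[paste0(measure, "_mn")]] <- mn$flags
    rep_row <- stage_count(measure, "main", "missing_negative", d0, mn$kept)
    pipeline_log(config$verbose, rep_row)
    report[[paste0(measure, "_mn")]] <- rep_row
    d1 <- mn$kept

    s1 <- remove_singletons(d1, measure)
    all_flags[[paste0(measure, "_s1")]] <- s1$flags
    rep_row <- stage_count(measure, "main", "singleton", d1, s1$kept)
    pipeline_log(config$verbose, rep_row)
    report[[paste0(measure, "_s1")]] <- rep_row
    d2 <- s1$kept

    z2 <- z0[match(d2$.rid, d0$.rid), , drop = FALSE]
    po <- flag_population_outliers(z2, kind, config$po)
    po_rows <- sort(unique(po$row))
    if (nrow(po)) {
      all_flags[[paste0(measure, "_po")]] <-
        make_flags(d2, po$row, measure, paste0("po_", tolower(po$indicator)),
                   "population_outliers", po$value)
    }
    d3 <- d2[setdiff(seq_len(nrow(d2)), po_rows), , drop = FALSE]
    rep_row <- stage_count(measure, "main", "population_outliers", d2, d3)
    pipeline_log(config$verbose, rep_row)
    report[[paste0(measure, "_po")]] <- rep_row

    s2 <- remove_singletons(d3, measure, stage = "singleton_post_po")
    all_flags[[paste0(measure, "_s2")]] <- s2$flags
    rep_row <- stage_count(measure, "main", "singleton_post_po", d3, s2$kept)
    pipeline_log(config$verbose, rep_row)
    report[[paste0(measure, "_s2")]] <- rep_row
    d4 <- s2$kept

    # sex-stratified trajectory model on the post-PO dataset
    knots <- if (measure == "height") config$knots_height else config$knots_weight
    resid <- rep(NA_real_, nrow(d4))
    for (sx in biv_sexes) {
      sel <- which(d4$sex == sx)
      if (length(unique(d4$child_id[sel])) < 2) next
      fit <- fit_growth_lmm(d4$age_months[sel], d4[[measure_col(measure)]][sel],
                            d4$child_id[sel], knots = knots,
                            method = config$method)
      fits[[paste(measure, sx, sep = "_")]] <- fit
      resid[sel] <- scaled_residuals(fit, mode = config$residual_mode,
                                     type = config$residual_type)
    }

    lo_sets <- list()
    for (cut in config$lo_cutoffs) {
      lo <- flag_longitudinal_outliers(resid, cut)
      branch <- paste0("lo_cutoff_", cut)
      if (nrow(lo)) {
        all_flags[[paste0(measure, "_", branch)]] <-
          make_flags(d4, lo$row, measure, "lo", branch, lo$value)
      }
      d_lo <- d4[setdiff(seq_len(nrow(d4)), lo$row), , drop = FALSE]
      rep_row <- stage_count(measure, branch, "longitudinal_outliers", d4, d_lo)
      pipeline_log(config$verbose, rep_row)
      report[[paste0(measure, "_", branch)]] <- rep_row
      lo_sets[[as.character(cut)]] <- d_lo
    }

    d_dh <- NULL
    if (measure == "height" && config$decreasing_heights) {
      dh <- apply_decreasing_heights(d4, threshold = config$dh_threshold)
      all_flags[[paste0(measure, "_dh")]] <- dh$flags
      rep_row <- stage_count(measure, "decreasing_heights",
                             "decreasing_heights", d4, dh$kept)
      pipeline_log(config$verbose, rep_row)
      report[[paste0(measure, "_dh")]] <- rep_row
      d_dh <- dh$kept
    }

    # prevalence at each stage (stream indicator)
    zs <- function(d) z0[[zcol]][match(d$.rid, d0$.rid)]
    biv0 <- {
      zi <- z0[[zcol]]
      !is.na(zi) & (zi < config$po[[stream_ind]][1] |
                      zi > config$po[[stream_ind]][2])
    }
    prev <- list(prevalence_table(z0[[zcol]], stream_ind, "initial", biv = biv0))
    add_prev <- function(d, stage) {
      z <- zs(d)
      if (length(z) && any(!is.na(z))) {
        prev[[length(prev) + 1L]] <<- prevalence_table(z, stream_ind, stage)
      }
    }
    add_prev(d3, "post_po")
    add_prev(d4, "post_singleton2")
    for (cut in names(lo_sets)) add_prev(lo_sets[[cut]], paste0("post_lo_", cut))
    if (!is.null(d_dh)) add_prev(d_dh, "post_decreasing_heights")
    prev_df <- do.call(rbind, prev)
    prev_df$stream <- measure
    prevalence[[measure]] <- prev_df

    # descriptive statistics per stage snapshot
    snaps <- c(list(initial = d0, post_missing_negative = d1,
                    post_singleton = d2, post_po = d3, post_singleton2 = d4),
               stats::setNames(lo_sets, paste0("post_lo_", names(lo_sets))))
    if (!is.null(d_dh)) snaps$post_decreasing_heights <- d_dh
    desc <- do.call(rbind, lapply(names(snaps), function(nm) {
      d <- snaps[[nm]]
      if (!nrow(d)) return(NULL)
      descriptive_stats(d, measure, z = zs(d), stage = nm)
    }))
    desc$stream <- measure
    descriptives[[measure]] <- desc

    # flag proportion by age (completed months), per flag family
    bin <- function(d) pmin(floor(d$age_months), config$max_age_months)
    prof <- list()
    add_prof <- function(base, idx_rid, type) {
      bins <- bin(base)
      n_rec <- table(factor(bins, levels = 0:config$max_age_months))
      n_flag <- table(factor(bin(base[base$.rid %in% idx_rid, , drop = FALSE]),
                             levels = 0:config$max_age_months))
      prof[[length(prof) + 1L]] <<- data.frame(
        stream = measure, flag_type = type,
        age_bin = 0:config$max_age_months,
        n_records = as.integer(n_rec), n_flagged = as.integer(n_flag),
        proportion = ifelse(n_rec > 0, as.integer(n_flag) / as.integer(n_rec),
                            NA_real_))
    }
    add_prof(d2, d2$.rid[po_rows], "po")
    for (cut in config$lo_cutoffs) {
      lo_rid <- setdiff(d4$.rid, lo_sets[[as.character(cut)]]$.rid)
      add_prof(d4, lo_rid, paste0("lo_", cut))
    }
    if (!is.null(d_dh)) add_prof(d4, setdiff(d4$.rid, d_dh$.rid),
                                 "decreasing_height")
    by_age[[measure]] <- do.call(rbind, prof)

    cleaned[[measure]] <- list(post_po = d3, post_singleton2 = d4,
                               lo = lo_sets, decreasing_heights = d_dh)
  }

  flags <- do.call(rbind, all_flags)
  rownames(flags) <- NULL
  structure(
    list(cleaned = cleaned, flags = flags,
         stage_report = do.call(rbind, c(report, make.row.names = FALSE)),
         prevalence = do.call(rbind, c(prevalence, make.row.names = FALSE)),
         descriptives = do.call(rbind, c(descriptives, make.row.names = FALSE)),
         flags_by_age = do.call(rbind, c(by_age, make.row.names = FALSE)),
         fits = fits, config = config),
    class = "biv_pipeline")
}

#' @export
print.biv_pipeline <- function(x, ...) {
  cat("<biv_pipeline>\n")
  main <- x$stage_report[x$stage_report$branch == "main", ]
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-7s %-22s in=%-8d removed=%-7d kept=%d\n",
                main$stream[i], main$stage[i], main$records_in[i],
                main$records_removed[i], main$records_kept[i]))
  }
  br <- x$stage_report[x$stage_report$branch != "main", ]
  for (i in seq_len(nrow(br))) {
    cat(sprintf("  %-7s %-22s removed=%d (%.2f%%)\n", br$stream[i],
                br$branch[i], br$records_removed[i],
                100 * br$records_removed[i] / max(br$records_in[i], 1)))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `flags.csv`, `stage_report.json`, `prevalence.csv`,
#' `descriptives.csv`, `flags_by_age.csv` and one `model_<stream>_<sex>.json`
#' per fitted stratum.
#'
#' @param result A `biv_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "biv_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$flags, file.path(dir, "flags.csv"),
                   row.names = FALSE, na = "")
  writeLines(jsonlite::toJSON(result$stage_report, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "stage_report.json"))
  utils::write.csv(result$prevalence, file.path(dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(result$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$flags_by_age, file.path(dir, "flags_by_age.csv"),
                   row.names = FALSE, na = "")
  for (nm in names(result$fits)) {
    lmm_dump(result$fits[[nm]], file.path(dir, paste0("model_", nm, ".json")))
  }
  invisible(dir)
}
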