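#' Plausibility cutoffs for population outliers
#'
#' Open z-score intervals of plausibility per indicator. Defaults are the
#' WHO cutoffs for biologically implausible values: HAZ (-6, +6),
#' WAZ (-6, +5), BMIZ (-5, +5), WHZ (-5, +5). A value equal to a bound is
#' considered plausible (strict inequalities).
#'
#' @param HAZ,WAZ,BMIZ,WHZ Length-2 numeric `c(lower, upper)`.
#' @return Named list of class `po_cutoffs`.
#' @export
po_cutoffs <- function(HAZ = c(-6, 6), WAZ = c(-6, 5),
                       BMIZ = c(-5, 5), WHZ = c(-5, 5)) {
  cut <- list(HAZ = HAZ, WAZ = WAZ, BMIZ = BMIZ, WHZ = WHZ)
  for (nm in names(cut)) {
    ci <- cut[[nm]]
    if (length(ci) != 2 || !is.numeric(ci) || ci[1] >= ci[2]) {
      stop("cutoffs for ", nm, " must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  }
  structure(cut, class = "po_cutoffs")
}

# indicators active per dataset kind
po_active_indicators <- function(dataset_kind) {
  switch(dataset_kind,
         length_height = "HAZ",
         weight = "WAZ",
         combined = biv_indicators,
         stop("unknown dataset_kind: ", dataset_kind, call. = FALSE))
}

#' Flag population outliers against reference cutoffs
#'
#' A record is flagged on an indicator when its z-score lies strictly outside
#' that indicator's plausibility interval. Analyses of length/height and
#' weight are run separately, so the `length_height` kind flags on HAZ only
#' and the `weight` kind on WAZ only; `combined` flags on all four
#' indicators. Absent z-scores never flag.
#'
#' @param z `data.frame` of z-scores as from [compute_zscores()] (columns
#'   `haz`, `waz`, `bmiz`, `whz`; missing columns are treated as absent).
#' @param dataset_kind One of `"length_height"`, `"weight"`, `"combined"`.
#' @param cutoffs A [po_cutoffs()] object.
#' @return `data.frame` with one row per violated (row, indicator) pair:
#'   columns `row` (index into `z`), `indicator`, `value` (the z-score).
#' @export
flag_population_outliers <- function(z, dataset_kind = c("length_height",
                                                         "weight", "combined"),
                                     cutoffs = po_cutoffs()) {
  dataset_kind <- match.arg(dataset_kind)
  stopifnot(is.data.frame(z), inherits(cutoffs, "po_cutoffs"))
  out <- list()
  for (ind in po_active_indicators(dataset_kind)) {
    col <- tolower(ind)
    if (!col %in% names(z)) next
    zi <- z[[col]]
    bad <- which(!is.na(zi) & (zi < cutoffs[[ind]][1] | zi > cutoffs[[ind]][2]))
    if (length(bad)) {
      out[[ind]] <- data.frame(row = bad, indicator = ind, value = zi[bad])
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(), indicator = character(),
                      value = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row, res$indicator), , drop = FALSE]
}

check_finite_z <- function(z) {
  if (any(is.nan(z) | is.infinite(z))) {
    stop("invalid input: z-scores must be finite", call. = FALSE)
  }
}

haz_levels <- c("severe_stunting", "moderate_stunting", "adequate")
waz_levels <- c("severe_underweight", "moderate_underweight", "adequate",
                "overweight")

#' Classify length/height-for-age z-scores
#'
#' Severe stunting: HAZ < -3; moderate stunting: -3 <= HAZ < -2; adequate:
#' HAZ >= -2 (the boundary HAZ = -2 is assigned to adequate, matching the
#' >= -2 convention used for the weight classification).
#'
#' @param z Numeric HAZ values; `NA` yields `NA`, non-finite values error.
#' @return Factor with levels `severe_stunting`, `moderate_stunting`,
#'   `adequate`.
#' @export
classify_haz <- function(z) {
  check_finite_z(z)
  out <- ifelse(is.na(z), NA_character_,
                ifelse(z < -3, "severe_stunting",
                       ifelse(z < -2, "moderate_stunting", "adequate")))
  factor(out, levels = haz_levels)
}

#' Classify weight-for-age z-scores
#'
#' Severe underweight: WAZ < -3; moderate underweight: -3 <= WAZ < -2;
#' adequate: -2 <= WAZ <= +2; overweight: WAZ > +2.
#'
#' @inheritParams classify_haz
#' @return Factor with levels `severe_underweight`, `moderate_underweight`,
#'   `adequate`, `overweight`.
#' @export
classify_waz <- function(z) {
  check_finite_z(z)
  out <- ifelse(is.na(z), NA_character_,
                ifelse(z < -3, "severe_underweight",
                       ifelse(z < -2, "moderate_underweight",
                              ifelse(z <= 2, "adequate", "overweight"))))
  factor(out, levels = waz_levels)
}

#' Prevalence of growth-indicator categories
#'
#' Tabulates category percentages for one indicator at one cleaning stage.
#' By default percentages are over records with a present z-score. When
#' `biv` is supplied (initial-dataset style), separate `BIV` and `Missing`
#' rows are added and percentages are over all records, so the column sums
#' to 100 either way.
#'
#' @param z Numeric z-scores (`NA` = absent).
#' @param indicator `"HAZ"` or `"WAZ"` (selects the classifier).
#' @param stage Stage label for the output.
#' @param biv Optional logical vector marking records flagged as
#'   biologically implausible; those records are excluded from the category
#'   counts and reported in a `BIV` row, and remaining `NA` z in a
#'   `Missing` row.
#' @return `data.frame` with columns `stage`, `indicator`, `category`,
#'   `count`, `percent`.
#' @export
prevalence_table <- function(z, indicator = c("HAZ", "WAZ"), stage = "stage",
                             biv = NULL) {
  indicator <- match.arg(indicator)
  if (!length(z)) stop("empty input: no records to tabulate", call. = FALSE)
  classify <- if (indicator == "HAZ") classify_haz else classify_waz
  if (is.null(biv)) {
    zz <- z[!is.na(z)]
    if (!length(zz)) stop("empty input: no present z-scores", call. = FALSE)
    tab <- table(classify(zz))
    denom <- length(zz)
    cats <- names(tab); counts <- as.integer(tab)
  } else {
    stopifnot(length(biv) == length(z))
    usable <- !biv & !is.na(z)
    tab <- table(classify(z[usable]))
    cats <- c(names(tab), "BIV", "Missing")
    counts <- c(as.integer(tab), sum(biv), sum(!biv & is.na(z)))
    denom <- length(z)
  }
  data.frame(stage = stage, indicator = indicator, category = cats,
             count = counts, percent = 100 * counts / denom,
             stringsAsFactors = FALSE)
}
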