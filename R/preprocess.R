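#' Average 24-hour dietary recalls within person
#'
#' Each participant contributes one or two complete recall days; amounts are
#' averaged over the available days (an unweighted day mean; one-day
#' participants keep their single day unchanged).  Persons with zero complete
#' records are excluded and reported, not errored.
#'
#' @param records Data frame in long day format: a person id column, a day
#'   index column (1 or 2), and one nonnegative amount column per food.
#' @param id_col,day_col Names of the id and day-index columns.
#' @return A list with `amounts` (person x food matrix, row names = ids),
#'   `ids`, and `excluded` (data frame of dropped ids with reasons).
#' @export
average_recalls <- function(records, id_col = "person_id",
                            day_col = "day_index") {
  stopifnot(is.data.frame(records))
  for (col in c(id_col, day_col))
    if (!col %in% names(records))
      stop("column '", col, "' not found in recall records", call. = FALSE)
  foods <- setdiff(names(records), c(id_col, day_col))
  if (!all(records[[day_col]] %in% c(1L, 2L)))
    stop("day_index must be 1 or 2", call. = FALSE)

  complete <- stats::complete.cases(records[foods])
  ids_all <- unique(records[[id_col]])
  rec <- records[complete, , drop = FALSE]
  if (any(table(rec[[id_col]], rec[[day_col]]) > 1))
    stop("a person has more than one record for the same day", call. = FALSE)

  dropped <- setdiff(ids_all, unique(rec[[id_col]]))
  excluded <- data.frame(id = dropped,
                         reason = rep("no complete recall", length(dropped)))
  if (nrow(rec)) {
    means <- aggregate(rec[foods], by = stats::setNames(list(rec[[id_col]]), "id"),
                       FUN = mean)
    means <- means[match(intersect(ids_all, means$id), means$id), , drop = FALSE]
    amounts <- as.matrix(means[foods])
    rownames(amounts) <- means$id
  } else {
    amounts <- matrix(numeric(0), 0, length(foods),
                      dimnames = list(NULL, foods))
  }
  list(amounts = amounts, ids = rownames(amounts), excluded = excluded)
}

#' Fit the 4-level consumption categorization rule
#'
#' For each food, cutpoints are the 1/3 and 2/3 empirical quantiles
#' (inverse-ECDF, i.e. `type = 1`) of the strictly positive amounts pooled over
#' the whole analytic population — not within subgroup.  A column with fewer
#' than 3 distinct positive values is flagged degenerate: positive amounts
#' there map to a single "consumed" level (level 2).
#'
#' @param amounts Nonnegative numeric matrix, persons x foods.
#' @return A `categorization_rule`: data frame with columns `food`, `t1`,
#'   `t2`, `degenerate`.
#' @export
fit_categorization <- function(amounts) {
  amounts <- as.matrix(amounts)
  if (any(amounts < 0, na.rm = TRUE))
    stop("consumption amounts must be nonnegative", call. = FALSE)
  foods <- colnames(amounts)
  if (is.null(foods)) foods <- paste0("food", seq_len(ncol(amounts)))
  rule <- data.frame(food = foods, t1 = NA_real_, t2 = NA_real_,
                     degenerate = FALSE)
  for (j in seq_len(ncol(amounts))) {
    pos <- amounts[, j]
    pos <- pos[!is.na(pos) & pos > 0]
    if (length(unique(pos)) < 3) {
      rule$degenerate[j] <- TRUE
      warning("column '", foods[j],
              "' has fewer than 3 distinct positive values; ",
              "categorizing positives to a single consumed level",
              call. = FALSE)
    } else {
      q <- quantile(pos, c(1, 2) / 3, type = 1, names = FALSE)
      rule$t1[j] <- q[1]; rule$t2[j] <- q[2]
    }
  }
  class(rule) <- c("categorization_rule", "data.frame")
  rule
}

#' Categorize consumption amounts into 4 levels
#'
#' Maps amounts to levels using half-open intervals with closed right
#' endpoints (ties at a cutpoint go to the lower level):
#' `0 -> 1` (none), `(0, t1] -> 2` (low), `(t1, t2] -> 3` (medium),
#' `(t2, Inf) -> 4` (high).  Degenerate foods map all positive amounts to
#' level 2.
#'
#' @param amounts Nonnegative numeric matrix, persons x foods.
#' @param rule A rule from [fit_categorization()], fitted on data with the
#'   same food columns.
#' @param subgroup Optional subgroup vector passed through to the result.
#' @param ... Passed to [consumption_matrix()].
#' @return A [consumption_matrix()] with `d = 4` when `subgroup` is given,
#'   otherwise the integer level matrix.
#' @export
categorize <- function(amounts, rule, subgroup = NULL, ...) {
  amounts <- as.matrix(amounts)
  if (ncol(amounts) != nrow(rule))
    stop("rule covers ", nrow(rule), " foods but data has ", ncol(amounts),
         " columns", call. = FALSE)
  bad <- which(amounts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative amount at row %d, column %d", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  lev <- matrix(1L, nrow(amounts), ncol(amounts),
                dimnames = dimnames(amounts))
  for (j in seq_len(ncol(amounts))) {
    a <- amounts[, j]
    if (rule$degenerate[j]) {
      lev[, j] <- ifelse(a > 0, 2L, 1L)
    } else {
      lev[, j] <- 1L + (a > 0) + (a > rule$t1[j]) + (a > rule$t2[j])
    }
  }
  if (is.null(subgroup)) return(lev)
  consumption_matrix(lev, subgroup, d = 4L, items = rule$food, ...)
}

#' Study eligibility criteria
#'
#' Inclusion filters for the low-income female adult analytic population:
#' female sex, age 20--80 y (both inclusive; surveys commonly top-code age at
#' 80), family poverty-income ratio at or below 1.30, a known race/ethnicity
#' in the analyzed set, not pregnant or lactating, and at least one complete
#' dietary recall.
#'
#' @param sex Required sex value, or `NA` to skip the filter.
#' @param age_min,age_max Inclusive age bounds.
#' @param pir_max Poverty-income ratio ceiling (inclusive).
#' @param races Character vector of allowed race/ethnicity codes, or `NULL`
#'   to accept any non-missing value.
#' @param exclude_pregnant Drop pregnant/lactating participants?
#' @param min_recalls Minimum number of complete recalls.
#' @return An `eligibility_criteria` list.
#' @export
eligibility_criteria <- function(sex = "Female", age_min = 20, age_max = 80,
                                 pir_max = 1.30, races = NULL,
                                 exclude_pregnant = TRUE, min_recalls = 1L) {
  stopifnot(pir_max > 0, age_min <= age_max)
  structure(list(sex = sex, age_min = age_min, age_max = age_max,
                 pir_max = pir_max, races = races,
                 exclude_pregnant = exclude_pregnant,
                 min_recalls = as.integer(min_recalls)),
            class = "eligibility_criteria")
}

#' Apply eligibility criteria to a participant table
#'
#' Filters are applied in a fixed, documented order — sex, age, race/ethnicity
#' known and allowed, income ratio, pregnancy/lactation, diet completeness —
#' and the exclusion tally reports the count removed at each step in that
#' order (a person already removed is not re-counted at a later step).
#' Missing values in a criterion's column fail that criterion.
#'
#' @param covariates Data frame with columns `id`, `sex`, `age`, `race`,
#'   `income_ratio`, `pregnant` (logical), `n_recalls` (columns a skipped
#'   criterion does not use may be absent).
#' @param criteria An [eligibility_criteria()].
#' @return List with `ids` (retained id vector), `kept` (filtered data frame)
#'   and `tally` (named integer vector of exclusions in application order).
#' @export
apply_eligibility <- function(covariates, criteria = eligibility_criteria()) {
  stopifnot(is.data.frame(covariates))
  need <- c("id",
            if (!is.na(criteria$sex) && !is.null(criteria$sex)) "sex",
            "age", "race", "income_ratio",
            if (criteria$exclude_pregnant) "pregnant",
            "n_recalls")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  df <- covariates
  tally <- integer(0)
  drop_step <- function(df, keep, label) {
    keep[is.na(keep)] <- FALSE
    tally[[label]] <<- sum(!keep)
    df[keep, , drop = FALSE]
  }
  if (!is.null(criteria$sex) && !is.na(criteria$sex))
    df <- drop_step(df, df$sex == criteria$sex, "sex")
  df <- drop_step(df, df$age >= criteria$age_min & df$age <= criteria$age_max,
                  "age")
  race_ok <- if (is.null(criteria$races)) !is.na(df$race)
             else df$race %in% criteria$races
  df <- drop_step(df, race_ok, "race_ethnicity")
  df <- drop_step(df, df$income_ratio <= criteria$pir_max, "income")
  if (criteria$exclude_pregnant)
    df <- drop_step(df, !df$pregnant, "pregnancy")
  df <- drop_step(df, df$n_recalls >= criteria$min_recalls, "diet_completeness")
  list(ids = df$id, kept = df, tally = unlist(tally))
}

#' Derive binary cardiovascular risk-factor flags
#'
#' Flag definitions (units as collected: mg/dL for lipids and glucose, mm Hg
#' for blood pressure, kg/m^2 for BMI):
#' * `high_cholesterol`: total cholesterol > 200, or LDL > 150, or
#'   cholesterol-lowering medication;
#' * `obesity`: BMI >= 30 (inclusive);
#' * `hypertension`: mean systolic > 140, or diastolic > 90, or
#'   blood-pressure medication;
#' * `diabetes`: fasting glucose > 126, or diabetes medication;
#' * `current_smoker`: yes to the current-smoking item.
#'
#' Missingness follows three-valued logic: an OR with a known TRUE disjunct is
#' TRUE even when other inputs are missing; a flag whose deciding inputs are
#' all missing is `NA` (the person is kept but excluded from that flag's
#' summaries).
#'
#' @param tbl Data frame with (any of) columns `total_chol`, `ldl`,
#'   `chol_meds`, `bmi`, `sbp`, `dbp`, `bp_meds`, `glucose`, `diabetes_meds`,
#'   `smoker` (logical or 0/1 for the medication/smoking items).
#' @return Data frame of logical flags, one row per input row.
#' @export
derive_risk_flags <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  col <- function(name) if (name %in% names(tbl)) tbl[[name]] else NA
  as_lgl <- function(x) if (is.logical(x)) x else as.logical(x)
  n <- nrow(tbl)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  data.frame(
    high_cholesterol = rep_n(col("total_chol") > 200) |
      rep_n(col("ldl") > 150) | rep_n(as_lgl(col("chol_meds"))),
    obesity = rep_n(col("bmi") >= 30),
    hypertension = rep_n(col("sbp") > 140) | rep_n(col("dbp") > 90) |
      rep_n(as_lgl(col("bp_meds"))),
    diabetes = rep_n(col("glucose") > 126) |
      rep_n(as_lgl(col("diabetes_meds"))),
    current_smoker = rep_n(as_lgl(col("smoker"))))
}

#' Write / read a categorization rule as CSV
#' @param rule A `categorization_rule`.
#' @param path File path.
#' @export
write_rule <- function(rule, path) {
  write.csv(as.data.frame(rule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  rule <- read.csv(path)
  class(rule) <- c("categorization_rule", "data.frame")
  rule
}
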