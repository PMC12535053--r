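#' Covariate schema for subject-level cohort tables
#'
#' A `covariate_schema` is an ordered description of the baseline covariates
#' shared by every cohort in an analysis: for each covariate its name, kind
#' (`"continuous"` or `"binary"`), unit, and allowed range. It also names the
#' outcome the time/event columns refer to (`"3P-MACE"` for trial-style
#' cohorts with adjudicated cardiovascular death, `"modified 3P-MACE"` when
#' all-cause death substitutes cardiovascular death, as in claims-based
#' longitudinal cohorts).
#'
#' @param covariates data.frame with columns `name`, `kind`, `unit`, `lo`,
#'   `hi`. Binary covariates must have `lo = 0`, `hi = 1`.
#' @param outcome outcome label, e.g. `"3P-MACE"` or `"modified 3P-MACE"`.
#' @return An object of class `covariate_schema`.
#' @seealso [default_schema()] for the standard cardiometabolic covariate set.
#' @export
covariate_schema <- function(covariates, outcome = "3P-MACE") {
  stopifnot(is.data.frame(covariates),
            all(c("name", "kind", "unit", "lo", "hi") %in% names(covariates)))
  covariates$name <- as.character(covariates$name)
  covariates$kind <- as.character(covariates$kind)
  if (anyDuplicated(covariates$name))
    stop("duplicate covariate names in schema: ",
         paste(unique(covariates$name[duplicated(covariates$name)]),
               collapse = ", "))
  if (!all(covariates$kind %in% c("continuous", "binary")))
    stop("covariate kind must be 'continuous' or 'binary'")
  bad <- covariates$kind == "binary" &
    (covariates$lo != 0 | covariates$hi != 1)
  if (any(bad))
    stop("binary covariates must have range {0,1}: ",
         paste(covariates$name[bad], collapse = ", "))
  structure(list(covariates = covariates, outcome = outcome),
            class = "covariate_schema")
}

#' Default cardiometabolic covariate schema
#'
#' Continuous covariates: age (years), bmi (kg/m2), hba1c (%),
#' diabetes_duration (years), egfr (mL/min/1.73m2). Binary flags: sex_male,
#' prior_mi_stroke, prior_cvd, heart_failure, hypertension, pad, and
#' medication indicators (metformin, sulphonylurea, insulin, statin,
#' antiplatelet, ras_blocker, beta_blocker, diuretic, ccb, dpp4i).
#'
#' @param outcome outcome label (default `"3P-MACE"`).
#' @return A `covariate_schema`.
#' @export
default_schema <- function(outcome = "3P-MACE") {
  cont <- data.frame(
    name = c("age", "bmi", "hba1c", "diabetes_duration", "egfr"),
    kind = "continuous",
    unit = c("years", "kg/m2", "%", "years", "mL/min/1.73m2"),
    lo   = c(18, 10, 3, 0, 1),
    hi   = c(110, 80, 20, 80, 250),
    stringsAsFactors = FALSE)
  flags <- c("sex_male", "prior_mi_stroke", "prior_cvd", "heart_failure",
             "hypertension", "pad", "metformin", "sulphonylurea", "insulin",
             "statin", "antiplatelet", "ras_blocker", "beta_blocker",
             "diuretic", "ccb", "dpp4i")
  bin <- data.frame(name = flags, kind = "binary", unit = "flag",
                    lo = 0, hi = 1, stringsAsFactors = FALSE)
  covariate_schema(rbind(cont, bin), outcome = outcome)
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> outcome:", x$outcome, "\n")
  cat(nrow(x$covariates), "covariates (",
      sum(x$covariates$kind == "continuous"), "continuous,",
      sum(x$covariates$kind == "binary"), "binary )\n")
  invisible(x)
}

schema_names <- function(schema) schema$covariates$name

schema_kind <- function(schema, name) {
  schema$covariates$kind[match(name, schema$covariates$name)]
}

#' Construct a subject-level cohort table
#'
#' A `cohort_table` is a validated data.frame of subjects from one or more
#' sources (trial arms, a cross-sectional target population, or a
#' longitudinal new-user cohort). Columns: `subject_id` (unique), `source`
#' (label), `arm` (`"treated"`, `"control"`, or `"none"` for cross-sectional
#' rows), the schema covariates, and for longitudinal rows follow-up `time`
#' in years and `event` in {0,1}. `arm == "none"` rows must have missing
#' time/event and vice versa.
#'
#' @param df data.frame with the columns above (`time`/`event` may be absent
#'   for a purely cross-sectional table).
#' @param schema a `covariate_schema`.
#' @param validate check invariants (default TRUE).
#' @return `df` with class `cohort_table` and the schema attached.
#' @export
cohort_table <- function(df, schema = default_schema(), validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) df$time <- NA_real_
  if (!"event" %in% names(df)) df$event <- NA_real_
  df$subject_id <- as.character(df$subject_id)
  df$source <- as.character(df$source)
  df$arm <- as.character(df$arm)
  attr(df, "schema") <- schema
  class(df) <- c("cohort_table", "data.frame")
  if (validate) validate_cohort(df)
  df
}

#' @rdname cohort_table
#' @param x a `cohort_table`.
#' @export
cohort_schema <- function(x) attr(x, "schema")

#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "schema") <- attr(x, "schema")
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}

#' Validate a cohort table against its schema
#'
#' Checks id uniqueness, arm labels, the arm/time-event consistency rule,
#' binary flags in {0,1}, finite continuous values, allowed ranges, positive
#' follow-up times and event flags in {0,1}. Missing covariate values (NA)
#' are allowed here; they are removed by [complete_case_filter()].
#'
#' @param x a `cohort_table`.
#' @return `x` invisibly; stops with an informative error on violation.
#' @export
validate_cohort <- function(x) {
  schema <- cohort_schema(x)
  need <- c("subject_id", "source", "arm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(schema_names(schema), names(x))
  if (length(miss))
    stop("cohort is missing schema covariate column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$subject_id))
    stop("subject_id values are not unique within the table")
  if (!all(x$arm %in% c("treated", "control", "none")))
    stop("arm must be one of 'treated', 'control', 'none'")
  longit <- x$arm != "none"
  if (any(longit & (is.na(x$time) | is.na(x$event))))
    stop("rows with arm 'treated'/'control' must have time and event")
  if (any(!longit & (!is.na(x$time) | !is.na(x$event))))
    stop("rows with arm 'none' must not carry time/event")
  if (any(longit & x$time <= 0, na.rm = TRUE))
    stop("follow-up time must be > 0; offending row(s): ",
         paste(utils::head(x$subject_id[which(longit & x$time <= 0)], 5),
               collapse = ", "))
  bad_ev <- longit & !(x$event %in% c(0, 1))
  if (any(bad_ev, na.rm = TRUE))
    stop("event must be 0 or 1; offending row(s): ",
         paste(utils::head(x$subject_id[which(bad_ev)], 5), collapse = ", "))
  for (j in seq_len(nrow(schema$covariates))) {
    nm <- schema$covariates$name[j]
    v <- x[[nm]]
    ok <- is.na(v)
    if (schema$covariates$kind[j] == "binary") {
      bad <- !ok & !(v %in% c(0, 1))
      if (any(bad))
        stop("binary covariate '", nm, "' outside {0,1}; row(s): ",
             paste(utils::head(x$subject_id[which(bad)], 5), collapse = ", "))
    } else {
      bad <- !ok & !is.finite(v)
      if (any(bad))
        stop("continuous covariate '", nm, "' non-finite; row(s): ",
             paste(utils::head(x$subject_id[which(bad)], 5), collapse = ", "))
      oob <- !ok & (v < schema$covariates$lo[j] | v > schema$covariates$hi[j])
      if (any(oob))
        stop("covariate '", nm, "' outside allowed range [",
             schema$covariates$lo[j], ", ", schema$covariates$hi[j],
             "]; row(s): ",
             paste(utils::head(x$subject_id[which(oob)], 5), collapse = ", "))
    }
  }
  invisible(x)
}

cohort_columns <- function(schema) {
  c("subject_id", "source", "arm", schema_names(schema), "time", "event")
}

#' Read / write a cohort table as delimited text
#'
#' Comma-delimited UTF-8 with a header row; missing values are empty fields;
#' decimal point regardless of locale. The writer emits binary flags and
#' events as integers and continuous values at full double precision so a
#' write/read round trip reproduces the table.
#'
#' @param path file path.
#' @param schema a `covariate_schema` describing the expected columns.
#' @return `read_cohort`: a validated `cohort_table` with row order
#'   preserved. `write_cohort`: `path`, invisibly.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"),
                        na.strings = "")
  need <- c("subject_id", "source", "arm", schema_names(schema))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (nm in c(schema_names(schema), "time", "event"))
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  cohort_table(df, schema = schema)
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema(cohort)
  out <- as.data.frame(cohort)[, cohort_columns(schema)]
  for (j in seq_len(nrow(schema$covariates)))
    if (schema$covariates$kind[j] == "binary") {
      nm <- schema$covariates$name[j]
      out[[nm]] <- as.integer(out[[nm]])
    }
  out$event <- as.integer(out$event)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Complete-case filtering
#'
#' Drops every subject with at least one missing value among the required
#' covariates (complete-case analysis; no imputation is offered).
#'
#' @param cohort a `cohort_table`.
#' @param required covariate names that must be non-missing; defaults to the
#'   full schema covariate list.
#' @return list with `cohort` (filtered table) and `dropped` (number of rows
#'   removed). Errors if no complete cases remain.
#' @export
complete_case_filter <- function(cohort,
                                 required = schema_names(cohort_schema(cohort))) {
  schema <- cohort_schema(cohort)
  bad <- setdiff(required, schema_names(schema))
  if (length(bad))
    stop("required names not in schema: ", paste(bad, collapse = ", "))
  if (length(required) == 0L)
    return(list(cohort = cohort, dropped = 0L))
  keep <- rowSums(is.na(as.data.frame(cohort)[, required, drop = FALSE])) == 0L
  if (!any(keep))
    stop("no complete cases remain after filtering on: ",
         paste(required, collapse = ", "))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- schema
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out, dropped = sum(!keep))
}

#' Descriptive comparison of two cohorts
#'
#' One row per schema covariate: mean (SD) per group for continuous
#' covariates with a two-sample t-test, count (%) per group for binary flags
#' with a chi-square test. Covariates degenerate in both groups (zero
#' variance / single level) are reported with p = 1 and flagged.
#'
#' @param a,b `cohort_table`s sharing a schema.
#' @param covariates covariate names to compare (default: full schema).
#' @return data.frame with columns `covariate`, `kind`, `stat_a`, `stat_b`
#'   (formatted summaries), `mean_a`, `mean_b`, `diff`, `p_value`,
#'   `degenerate`.
#' @export
describe_and_compare <- function(a, b,
                                 covariates = schema_names(cohort_schema(a))) {
  schema <- cohort_schema(a)
  rows <- lapply(covariates, function(nm) {
    kind <- schema_kind(schema, nm)
    va <- a[[nm]]; vb <- b[[nm]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    degenerate <- FALSE
    if (kind == "continuous") {
      if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
        degenerate <- TRUE
        p <- 1
      } else {
        p <- stats::t.test(va, vb)$p.value
      }
      stat_a <- sprintf("%.2f (%.2f)", mean(va), stats::sd(va))
      stat_b <- sprintf("%.2f (%.2f)", mean(vb), stats::sd(vb))
    } else {
      tab <- rbind(c(sum(va == 1), sum(va == 0)),
                   c(sum(vb == 1), sum(vb == 0)))
      if (any(colSums(tab) == 0)) {
        degenerate <- TRUE
        p <- 1
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
      }
      stat_a <- sprintf("%d (%.1f%%)", sum(va == 1), 100 * mean(va))
      stat_b <- sprintf("%d (%.1f%%)", sum(vb == 1), 100 * mean(vb))
    }
    data.frame(covariate = nm, kind = kind, stat_a = stat_a, stat_b = stat_b,
               mean_a = mean(va), mean_b = mean(vb),
               diff = mean(va) - mean(vb), p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
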