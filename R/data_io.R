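#' Read a long-format longitudinal biomarker table
#'
#' Reads a CSV (RFC-4180, header row required) holding one biomarker
#' measurement per row and returns a `longitudinal_data` object with records
#' sorted by (subject, time), preserving the file order of ties.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping the canonical roles
#'   `id`, `time`, `outcome` to column names in the file, e.g.
#'   `c(id = "id", time = "obstime", outcome = "marker")`.
#' @param covariates Character vector of additional column names read as
#'   numeric fixed-effect covariates (entering the fixed design
#'   \eqn{x_i(t)}); default none.
#' @param random_design Labels for the random-effects design \eqn{z_i(t)};
#'   a subset of `"intercept"`, `"time"` plus covariate names.
#'
#' @return A `longitudinal_data` object: a data frame with columns `id`
#'   (character), `time`, `outcome` and any covariates, carrying the
#'   covariate and random-design labels as attributes.
#' @seealso [read_surv_table()], [validate_join()]
#' @export
read_long_table <- function(path,
                            column_map = c(id = "id", time = "time",
                                           outcome = "outcome"),
                            covariates = character(),
                            random_design = c("intercept", "time")) {
  raw <- read_checked_csv(path)
  need <- column_map[c("id", "time", "outcome")]
  check_columns(raw, c(need, covariates), path)
  df <- data.frame(
    id      = as.character(raw[[need[["id"]]]]),
    time    = parse_numeric(raw, need[["time"]]),
    outcome = parse_numeric(raw, need[["outcome"]]),
    stringsAsFactors = FALSE
  )
  for (cv in covariates) df[[cv]] <- parse_numeric(raw, cv)
  if (any(df$id == "" | is.na(df$id)))
    stop_bigjoint("missing subject id in longitudinal table",
                  "bigjoint_parse_error")
  if (any(df$time < 0))
    stop_bigjoint(sprintf("negative time at row %d",
                          which(df$time < 0)[1L]), "bigjoint_value_error")
  new_longitudinal_data(df, covariates, random_design)
}

new_longitudinal_data <- function(df, covariates, random_design) {
  ord <- order(df$id, df$time)          # stable: ties keep file order
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            covariates = covariates,
            random_design = random_design,
            class = c("longitudinal_data", "data.frame"))
}

#' Read a one-row-per-subject survival table
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping `id`, `time` (observed
#'   time, the minimum of event and censoring time) and `event`
#'   (indicator, 1 = event, 0 = censored) to file columns.
#' @param covariates Additional numeric baseline covariate columns
#'   (\eqn{w_i}).
#' @param admin_horizon Optional administrative follow-up limit \eqn{\tau};
#'   observed times must not exceed it.
#'
#' @return A `survival_data` object: a data frame with columns `id`,
#'   `time`, `event` and covariates; one row per subject.
#' @export
read_surv_table <- function(path,
                            column_map = c(id = "id", time = "time",
                                           event = "event"),
                            covariates = character(),
                            admin_horizon = NULL) {
  raw <- read_checked_csv(path)
  need <- column_map[c("id", "time", "event")]
  check_columns(raw, c(need, covariates), path)
  df <- data.frame(
    id    = as.character(raw[[need[["id"]]]]),
    time  = parse_numeric(raw, need[["time"]]),
    event = parse_numeric(raw, need[["event"]]),
    stringsAsFactors = FALSE
  )
  for (cv in covariates) df[[cv]] <- parse_numeric(raw, cv)
  new_survival_data(df, covariates, admin_horizon)
}

new_survival_data <- function(df, covariates, admin_horizon = NULL) {
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop_bigjoint(paste0("duplicated subject id(s): ",
                         paste(dup, collapse = ", ")),
                  "bigjoint_uniqueness_error")
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad))
    stop_bigjoint(sprintf("event indicator outside {0,1} at row %d", bad[1L]),
                  "bigjoint_value_error")
  bad <- which(df$time <= 0)
  if (length(bad))
    stop_bigjoint(sprintf("non-positive observed time at row %d", bad[1L]),
                  "bigjoint_value_error")
  if (!is.null(admin_horizon) && any(df$time > admin_horizon))
    stop_bigjoint("observed time exceeds admin_horizon",
                  "bigjoint_value_error")
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            covariates = covariates,
            admin_horizon = admin_horizon,
            class = c("survival_data", "data.frame"))
}

#' Join and validate the longitudinal and survival tables
#'
#' Checks that the two tables describe the same subjects and that no
#' biomarker record postdates the subject's observed event or censoring
#' time.  Records timed after the observed time are either dropped (with a
#' count reported) or treated as an error, depending on `drop_post_event`.
#' Electronic-health-record extracts routinely contain such post-censoring
#' rows, so the command-line pipeline drops them by default.
#'
#' @param long A [read_long_table()] result.
#' @param surv A [read_surv_table()] result.
#' @param drop_post_event Drop (and count) longitudinal records with
#'   `time > observed_time` instead of erroring.  Default `TRUE`.
#'
#' @return A `validated_dataset`: list with elements `longitudinal`,
#'   `survival`, `n_subjects`, `dropped_records`.
#' @export
validate_join <- function(long, surv, drop_post_event = TRUE) {
  stopifnot(inherits(long, "longitudinal_data"),
            inherits(surv, "survival_data"), is_flag(drop_post_event))
  ids_l <- unique(long$id)
  ids_s <- surv$id
  only_l <- setdiff(ids_l, ids_s)
  only_s <- setdiff(ids_s, ids_l)
  if (length(only_l) || length(only_s))
    stop_bigjoint(paste0("subject ids present in only one table: ",
                         paste(c(only_l, only_s), collapse = ", ")),
                  "bigjoint_mismatch_error")
  obs_time <- setNames(surv$time, surv$id)
  late <- long$time > obs_time[long$id]
  dropped <- sum(late)
  if (dropped > 0) {
    if (!drop_post_event)
      stop_bigjoint(sprintf(
        "%d longitudinal record(s) postdate the observed time (first: subject %s)",
        dropped, long$id[which(late)[1L]]), "bigjoint_consistency_error")
    long <- new_longitudinal_data(as.data.frame(long)[!late, , drop = FALSE],
                                  attr(long, "covariates"),
                                  attr(long, "random_design"))
  }
  if (!all(ids_s %in% unique(long$id)))
    stop_bigjoint("dropping post-event records left a subject with no longitudinal data",
                  "bigjoint_consistency_error")
  structure(list(longitudinal = long, survival = surv,
                 n_subjects = length(ids_s), dropped_records = dropped),
            class = "validated_dataset")
}

#' Restrict a validated dataset to a subject subset
#'
#' @param data A `validated_dataset`.
#' @param ids Character vector of subject ids to keep.
#' @return A `validated_dataset` holding only those subjects.
#' @export
subset_subjects <- function(data, ids) {
  stopifnot(inherits(data, "validated_dataset"))
  ids <- as.character(ids)
  miss <- setdiff(ids, data$survival$id)
  if (length(miss))
    stop_bigjoint(paste0("unknown subject id(s): ",
                         paste(miss, collapse = ", ")),
                  "bigjoint_mismatch_error")
  long <- data$longitudinal
  surv <- data$survival
  long2 <- new_longitudinal_data(
    as.data.frame(long)[long$id %in% ids, , drop = FALSE],
    attr(long, "covariates"), attr(long, "random_design"))
  surv2 <- new_survival_data(
    as.data.frame(surv)[surv$id %in% ids, , drop = FALSE],
    attr(surv, "covariates"), attr(surv, "admin_horizon"))
  structure(list(longitudinal = long2, survival = surv2,
                 n_subjects = length(ids),
                 dropped_records = 0L),
            class = "validated_dataset")
}

#' Write the two tables of a validated dataset as CSV
#'
#' Values are written with full double precision so that a write/read round
#' trip reproduces them.
#'
#' @param data A `validated_dataset`.
#' @param long_path,surv_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, long_path, surv_path) {
  stopifnot(inherits(data, "validated_dataset"))
  fmt <- function(df) {
    out <- as.data.frame(df)
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    out
  }
  write.csv(fmt(data$longitudinal), long_path, row.names = FALSE,
            quote = FALSE)
  write.csv(fmt(data$survival), surv_path, row.names = FALSE, quote = FALSE)
  invisible(c(long_path, surv_path))
}

#' @export
print.validated_dataset <- function(x, ...) {
  cat("Joint dataset:", x$n_subjects, "subjects,",
      nrow(x$longitudinal), "longitudinal records,",
      sum(x$survival$event), "events",
      sprintf("(%d post-event records dropped)\n", x$dropped_records))
  invisible(x)
}

# -- internal CSV plumbing ---------------------------------------------------

read_checked_csv <- function(path) {
  if (!file.exists(path))
    stop_bigjoint(paste0("file not found: ", path), "bigjoint_io_error")
  read.csv(path, colClasses = "character", check.names = FALSE,
           na.strings = NULL)
}

check_columns <- function(raw, cols, path) {
  miss <- setdiff(cols, names(raw))
  if (length(miss))
    stop_bigjoint(paste0("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", ")),
                  "bigjoint_schema_error")
}

parse_numeric <- function(raw, col) {
  x <- raw[[col]]
  bad <- x == "" | x == "NA"
  val <- suppressWarnings(as.numeric(x))
  bad <- bad | is.na(val)
  if (any(bad))
    stop_bigjoint(sprintf("column '%s' is not numeric at row %d",
                          col, which(bad)[1L]), "bigjoint_parse_error")
  val
}
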