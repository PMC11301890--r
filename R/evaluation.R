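#' Predicted-survival matrix for a cohort
#'
#' Container for per-subject predicted survival probabilities
#' \eqn{\hat S_i(t)} on a common evaluation grid (typically from
#' [predict_survival()] with a common landmark, default 0).
#'
#' @param ids Subject ids (rows).
#' @param times Increasing evaluation grid (columns).
#' @param S Matrix of predicted survival probabilities in `[0,1]`,
#'   non-increasing along each row.
#' @return A `risk_matrix` object.
#' @export
risk_matrix <- function(ids, times, S) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == length(ids), ncol(S) == length(times),
            !is.unsorted(times))
  if (any(S < -1e-9 | S > 1 + 1e-9))
    stop_bigjoint("survival probabilities must lie in [0,1]",
                  "bigjoint_value_error")
  if (ncol(S) > 1 && any(S[, -1L, drop = FALSE] -
                         S[, -ncol(S), drop = FALSE] > 1e-9))
    stop_bigjoint("survival probabilities must be non-increasing in time",
                  "bigjoint_value_error")
  dimnames(S) <- list(ids, NULL)
  structure(list(ids = as.character(ids), times = as.numeric(times),
                 S = pmin(pmax(S, 0), 1)),
            class = "risk_matrix")
}

# S_i(t) for all subjects at one time, linear interpolation between grid
# points (constant beyond the ends)
risk_at <- function(risk, t) {
  tm <- risk$times
  if (length(tm) == 1L) return(risk$S[, 1L])
  apply(risk$S, 1L, function(s)
    stats::approx(tm, s, xout = t, rule = 2)$y)
}

default_eval_grid <- function(surv) {
  ev <- surv$time[surv$event == 1]
  unique(as.numeric(quantile(ev, probs = seq(0.1, 0.9, by = 0.1),
                             type = 7, names = FALSE)))
}

#' Time-dependent concordance index
#'
#' At each grid time `t`, over the Harrell-usable pairs truncated at `t`
#' (pairs `(i, j)` with `T_i < T_j`, `delta_i = 1`, `T_i <= t`), the
#' proportion in which the earlier-event subject has the lower predicted
#' survival at `t` (ties count 0.5).  Points with no usable pairs are
#' reported missing.
#'
#' @param risk A [risk_matrix()] covering every subject in `surv`.
#' @param surv A `survival_data`.
#' @param grid Evaluation times; defaults to the deciles of the observed
#'   event times.
#' @return An `evaluation_curve` data frame: `time`, `value`, `n_usable`;
#'   attribute `metric` is `"concordance"`.
#' @export
concordance_over_time <- function(risk, surv, grid = NULL) {
  check_risk_coverage(risk, surv)
  if (is.null(grid)) grid <- default_eval_grid(surv)
  ord <- match(surv$id, risk$ids)
  Tm <- surv$time; dl <- surv$event
  n <- length(Tm)
  earlier <- outer(Tm, Tm, `<`)            # [i, j]: T_i < T_j
  vals <- numeric(length(grid)); npairs <- integer(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    usable <- earlier & (dl == 1) & (Tm <= t)   # recycles over rows: i
    Si <- risk_at(risk, t)[ord]
    lower <- outer(Si, Si, `<`)
    ties <- outer(Si, Si, `==`)
    np <- sum(usable)
    npairs[g] <- np
    vals[g] <- if (np == 0) NA_real_ else
      (sum(lower & usable) + 0.5 * sum(ties & usable)) / np
  }
  new_evaluation_curve(grid, vals, npairs, "concordance")
}

#' Time-dependent prediction error (IPCW Brier score)
#'
#' \eqn{PE(t) = n^{-1}\sum_i \hat w_i(t)\,(1\{T_i > t\} - \hat S_i(t))^2}
#' with inverse-probability-of-censoring weights
#' \eqn{\hat w_i(t) = 1/\hat G(t)} if \eqn{T_i > t};
#' \eqn{1/\hat G(T_i^-)} if \eqn{T_i \le t, \delta_i = 1}; 0 otherwise,
#' where \eqn{\hat G} is the Kaplan--Meier estimate of the censoring
#' distribution.  Grid times where \eqn{\hat G(t) = 0} are reported
#' missing with a warning.
#'
#' @inheritParams concordance_over_time
#' @return An `evaluation_curve` data frame; attribute `metric` is
#'   `"prediction_error"`.
#' @export
prediction_error_over_time <- function(risk, surv, grid = NULL) {
  check_risk_coverage(risk, surv)
  if (is.null(grid)) grid <- default_eval_grid(surv)
  ord <- match(surv$id, risk$ids)
  Tm <- surv$time; dl <- surv$event
  n <- length(Tm)
  G <- if (any(dl == 0)) kaplan_meier(Tm, 1 - dl) else NULL
  Gat <- function(t, left = FALSE)
    if (is.null(G)) rep(1, length(t)) else eval_survival_curve(G, t, left)
  G_Tm_left <- Gat(Tm, left = TRUE)
  vals <- numeric(length(grid)); n_at_risk <- integer(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    Gt <- Gat(t)
    n_at_risk[g] <- sum(Tm > t)
    if (Gt == 0) {
      warning(sprintf("censoring survival is 0 at t = %g; point dropped", t))
      vals[g] <- NA_real_
      next
    }
    Si <- risk_at(risk, t)[ord]
    w <- ifelse(Tm > t, 1 / Gt,
                ifelse(dl == 1, 1 / G_Tm_left, 0))
    vals[g] <- mean(w * ((Tm > t) - Si)^2)
  }
  new_evaluation_curve(grid, vals, n_at_risk, "prediction_error")
}

new_evaluation_curve <- function(time, value, n_usable, metric) {
  structure(data.frame(time = time, value = value, n_usable = n_usable,
                       row.names = NULL),
            metric = metric,
            class = c("evaluation_curve", "data.frame"))
}

check_risk_coverage <- function(risk, surv) {
  stopifnot(inherits(risk, "risk_matrix"), inherits(surv, "survival_data"))
  miss <- setdiff(surv$id, risk$ids)
  if (length(miss))
    stop_bigjoint(paste0("subjects missing from the risk matrix: ",
                         paste(miss, collapse = ", ")),
                  "bigjoint_coverage_error")
}

#' Build a cohort risk matrix from a fitted model
#'
#' Runs [predict_survival()] for every subject from a common landmark
#' (default 0, i.e. baseline predictions using each subject's baseline
#' covariates and biomarker records up to the landmark).
#'
#' @param data A `validated_dataset`.
#' @param fit A `pooled_fit`, `fit_summary` or [joint_parameters()].
#' @param spec A [model_spec()].
#' @param basis The fitting `spline_basis`.
#' @param times Evaluation grid.
#' @param landmark Common landmark (default 0).
#' @param n_draws Random-effect draws per subject (default 300 — the
#'   cohort average is much less noisy than a single curve).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A [risk_matrix()].
#' @export
cohort_risk_matrix <- function(data, fit, spec, basis, times,
                               landmark = 0, n_draws = 300L, seed = 1L) {
  params <- resolve_params(fit, spec, basis)
  ids <- data$survival$id
  grid <- sort(unique(c(landmark, times)))
  S <- matrix(NA_real_, length(ids), length(times))
  for (i in seq_along(ids)) {
    h <- subject_history_from_data_unchecked(data, ids[i], landmark)
    B <- posterior_b_given_history(h, params, spec, basis,
                                   n_draws = n_draws,
                                   seed = derive_seed(seed, i))
    Sd <- conditional_survival_draws(h, params, spec, basis, grid, B)
    S[i, ] <- rowMeans(Sd)[match(times, grid)]
  }
  risk_matrix(ids, times, S)
}

# like subject_history_from_data but tolerates subjects whose observed
# time is at/below the landmark (their history is simply truncated):
# needed when scoring a whole cohort from baseline
subject_history_from_data_unchecked <- function(data, id, landmark) {
  srow <- which(data$survival$id == id)
  wnames <- attr(data$survival, "covariates")
  w <- if (length(wnames))
    unlist(as.data.frame(data$survival)[srow, wnames, drop = FALSE]) else numeric()
  long <- as.data.frame(data$longitudinal)
  rec <- long[long$id == id & long$time <= landmark,
              c("time", "outcome"), drop = FALSE]
  subject_history(id, rec, w, landmark)
}

#' Write an evaluation curve as CSV
#'
#' The metric name is recorded in a leading `#` comment line.
#'
#' @param curve An `evaluation_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# metric: ", attr(curve, "metric")), con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
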