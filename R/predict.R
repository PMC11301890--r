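#' A subject's accrued history up to a landmark time
#'
#' @param subject_id Identifier.
#' @param records Data frame with columns `time` and `outcome`
#'   (biomarker measurements up to the landmark); may have zero rows.
#' @param w Named or plain numeric vector of baseline covariates
#'   \eqn{w_i}.
#' @param landmark Landmark time `s >= 0`; the prediction is conditional
#'   on survival beyond `s`, so all record times must be `<= s`.
#' @return A `subject_history` object.
#' @export
subject_history <- function(subject_id, records, w = numeric(),
                            landmark) {
  stopifnot(landmark >= 0)
  if (nrow(records) && any(records$time > landmark))
    stop_bigjoint("history records postdate the landmark",
                  "bigjoint_value_error")
  structure(list(subject_id = subject_id,
                 records = records[order(records$time), , drop = FALSE],
                 w = w, landmark = landmark),
            class = "subject_history")
}

#' Extract a subject's history from a validated dataset
#'
#' @param data A `validated_dataset`.
#' @param id Subject id present in the data.
#' @param landmark Landmark time; must be strictly below the subject's
#'   observed time (the prediction conditions on being alive at the
#'   landmark).
#' @return A [subject_history()].
#' @export
subject_history_from_data <- function(data, id, landmark) {
  stopifnot(inherits(data, "validated_dataset"))
  srow <- which(data$survival$id == id)
  if (!length(srow))
    stop_bigjoint(paste0("unknown subject id: ", id),
                  "bigjoint_mismatch_error")
  if (data$survival$time[srow] <= landmark)
    stop_bigjoint(sprintf(
      "landmark %g is not before subject %s's observed time %g",
      landmark, id, data$survival$time[srow]), "bigjoint_value_error")
  wnames <- attr(data$survival, "covariates")
  w <- if (length(wnames))
    unlist(as.data.frame(data$survival)[srow, wnames, drop = FALSE]) else numeric()
  long <- as.data.frame(data$longitudinal)
  rec <- long[long$id == id & long$time <= landmark,
              c("time", "outcome"), drop = FALSE]
  subject_history(id, rec, w, landmark)
}

# internal: shared machinery for the subject-level b posterior
history_target <- function(history, params, spec, basis, nodes = 15L) {
  q <- length(spec$random_design)
  s <- history$landmark
  rec <- history$records
  design_at <- function(labels, tvec) {
    out <- matrix(0, length(tvec), length(labels))
    for (j in seq_along(labels))
      out[, j] <- switch(labels[j], intercept = 1, time = tvec,
                         rep(unname(history$w[labels[j]]), length(tvec)))
    out
  }
  Xr <- design_at(spec$fixed_design, rec$time)
  Zr <- design_at(spec$random_design, rec$time)
  wterm <- if (length(params$gamma)) sum(params$gamma * history$w) else 0
  mu_fix <- if (nrow(rec)) drop(Xr %*% params$beta) else numeric()

  # survival-to-landmark factor exp(-H(0, s))
  if (s > 0) {
    gl <- gauss_legendre_rule(nodes)
    sq <- s / 2 * (gl$x + 1)
    wq <- s / 2 * gl$w
    base_q <- log_baseline_hazard(sq, params$baseline, basis) + wterm +
      params$alpha * drop(design_at(spec$fixed_design, sq) %*% params$beta)
    Zq <- design_at(spec$random_design, sq)
  } else {
    base_q <- numeric(); wq <- numeric(); Zq <- matrix(0, 0, q)
  }

  sigma <- params$sigma
  alpha <- params$alpha
  D <- params$D
  cholD <- chol(D)
  student <- spec$re_distribution == "student_t"
  df <- spec$df

  # log target for a matrix of b rows (m x q)
  function(B) {
    pr <- if (student) dmvt0_log(B, D, df) else dmvnorm0_log(B, D)
    ll <- if (nrow(rec)) {
      mu <- matrix(mu_fix, nrow(rec), nrow(B)) + Zr %*% t(B)
      dv <- dnorm(rep(rec$outcome, nrow(B)), as.vector(mu), sigma,
                  log = TRUE)
      colSums(matrix(dv, nrow(rec)))
    } else 0
    Hs <- if (length(wq)) {
      e <- exp(base_q + alpha * (Zq %*% t(B)))
      colSums(wq * e)
    } else 0
    pr + ll - Hs
  }
}

resolve_params <- function(fit, spec, basis) {
  if (inherits(fit, "joint_parameters")) fit
  else params_from_fit(fit, spec, basis)
}

#' Posterior draws of a subject's random effects given their history
#'
#' Random-walk Metropolis targeting
#' \eqn{p(b_i \mid \mathcal{H}_i(s)) \propto p(b_i \mid D)\,
#' \prod_l N(y_{il} \mid \eta_i(t_{il}), \sigma^2)\,
#' \exp\{-H_i(0, s)\}}; the survival-to-landmark factor is included
#' because the prediction conditions on \eqn{T_i > s}.  Population
#' parameters are fixed at their (pooled) posterior means.
#'
#' @param history A [subject_history()].
#' @param fit A `pooled_fit`, `fit_summary`, or [joint_parameters()].
#' @param spec A [model_spec()].
#' @param basis The fitting `spline_basis`.
#' @param n_draws Retained draws (>= 100).
#' @param seed Seed; fixed seed gives identical draws.
#' @param n_burnin Burn-in iterations (default 500).
#' @return An `n_draws x q` matrix of random-effect draws.
#' @export
posterior_b_given_history <- function(history, fit, spec, basis,
                                      n_draws = 2000L, seed = 1L,
                                      n_burnin = 500L) {
  if (n_draws < 100L)
    stop_bigjoint("n_draws must be at least 100", "bigjoint_config_error")
  params <- resolve_params(fit, spec, basis)
  q <- length(spec$random_design)
  target <- history_target(history, params, spec, basis)
  set.seed(seed)
  step <- sqrt(diag(params$D))
  scale <- 2.4 / sqrt(q)
  b <- rep(0, q)
  lt <- target(matrix(b, 1L))
  out <- matrix(NA_real_, n_draws, q)
  nacc <- 0L
  total <- n_burnin + n_draws
  for (it in seq_len(total)) {
    prop <- b + scale * step * rnorm(q)
    ltp <- target(matrix(prop, 1L))
    if (is.finite(ltp) && log(runif(1)) < ltp - lt) {
      b <- prop; lt <- ltp; nacc <- nacc + 1L
    }
    if (it <= n_burnin && it %% 50L == 0L) {
      rate <- nacc / it
      scale <- scale * exp(min(0.25, 2 / sqrt(it)) * (rate - 0.3))
    }
    if (it > n_burnin) out[it - n_burnin, ] <- b
  }
  out
}

#' Dynamic conditional survival prediction for one subject
#'
#' For each random-effect draw \eqn{b}:
#' \eqn{S(u \mid s, b) = \exp\{-H_i(s, u \mid b)\}}; the reported curve is
#' the Monte-Carlo average over draws with equal-tailed 95% pointwise
#' bands.  \eqn{S(s \mid s) = 1} exactly.
#'
#' @inheritParams posterior_b_given_history
#' @param horizon_grid Increasing prediction times, all `>= landmark`.
#' @return A `dynamic_prediction` with a `survival` data frame (`horizon`,
#'   `mean`, `lower`, `upper`).
#' @export
predict_survival <- function(history, fit, spec, basis, horizon_grid,
                             n_draws = 2000L, seed = 1L) {
  s <- history$landmark
  if (any(horizon_grid < s))
    stop_bigjoint("horizon times must not precede the landmark",
                  "bigjoint_order_error")
  if (is.unsorted(horizon_grid))
    stop_bigjoint("horizon grid must be increasing", "bigjoint_order_error")
  params <- resolve_params(fit, spec, basis)
  B <- posterior_b_given_history(history, params, spec, basis,
                                 n_draws = n_draws, seed = seed)
  S <- conditional_survival_draws(history, params, spec, basis,
                                  horizon_grid, B)
  qs <- apply(S, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(subject_id = history$subject_id, landmark = s,
                 survival = data.frame(horizon = horizon_grid,
                                       mean = rowMeans(S),
                                       lower = qs[1L, ], upper = qs[2L, ]),
                 b_draws = B),
            class = "dynamic_prediction")
}

# per-draw conditional survival matrix: length(grid) x nrow(B)
conditional_survival_draws <- function(history, params, spec, basis,
                                       horizon_grid, B, nodes = 15L) {
  s <- history$landmark
  q <- ncol(B)
  gl <- gauss_legendre_rule(nodes)
  m <- length(horizon_grid)
  design_at <- function(labels, tvec) {
    out <- matrix(0, length(tvec), length(labels))
    for (j in seq_along(labels))
      out[, j] <- switch(labels[j], intercept = 1, time = tvec,
                         rep(unname(history$w[labels[j]]), length(tvec)))
    out
  }
  wterm <- if (length(params$gamma)) sum(params$gamma * history$w) else 0
  S <- matrix(1, m, nrow(B))
  live <- horizon_grid > s
  if (any(live)) {
    tq <- lapply(horizon_grid[live], function(u)
      list(x = (u - s) / 2 * (gl$x + 1) + s, w = (u - s) / 2 * gl$w))
    allx <- unlist(lapply(tq, `[[`, "x"))
    allw <- unlist(lapply(tq, `[[`, "w"))
    grp <- rep(seq_along(tq), each = length(gl$x))
    base <- log_baseline_hazard(allx, params$baseline, basis) + wterm +
      params$alpha *
      drop(design_at(spec$fixed_design, allx) %*% params$beta)
    Zq <- design_at(spec$random_design, allx)
    E <- exp(base + params$alpha * (Zq %*% t(B)))    # (mG) x ndraw
    H <- rowsum(allw * E, grp)                        # m_live x ndraw
    S[live, ] <- exp(-H)
  }
  S
}

#' Dynamic biomarker-trajectory prediction for one subject
#'
#' Per random-effect draw, the expected biomarker (identity link) is
#' \eqn{\eta_i(t) = x(t)'\hat\beta + z(t)'b}; the mean and equal-tailed
#' 95% bands across draws are returned on the requested time grid.
#'
#' @inheritParams posterior_b_given_history
#' @param time_grid Evaluation times (>= 0).
#' @return A data frame `time`, `mean`, `lower`, `upper`.
#' @export
predict_trajectory <- function(history, fit, spec, basis, time_grid,
                               n_draws = 2000L, seed = 1L) {
  stopifnot(all(time_grid >= 0))
  params <- resolve_params(fit, spec, basis)
  B <- posterior_b_given_history(history, params, spec, basis,
                                 n_draws = n_draws, seed = seed)
  design_at <- function(labels, tvec) {
    out <- matrix(0, length(tvec), length(labels))
    for (j in seq_along(labels))
      out[, j] <- switch(labels[j], intercept = 1, time = tvec,
                         rep(unname(history$w[labels[j]]), length(tvec)))
    out
  }
  eta <- drop(design_at(spec$fixed_design, time_grid) %*% params$beta) +
    design_at(spec$random_design, time_grid) %*% t(B)
  eta <- matrix(eta, length(time_grid))
  qs <- apply(eta, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(time = time_grid, mean = rowMeans(eta),
             lower = qs[1L, ], upper = qs[2L, ])
}

#' Write dynamic predictions as tidy CSV
#'
#' @param pred A `dynamic_prediction` (optionally with a `trajectory`
#'   element attached).
#' @param path Output CSV (columns: subject_id, landmark, horizon, mean,
#'   lower, upper, kind).
#' @param trajectory Optional [predict_trajectory()] result to append
#'   with `kind = "trajectory"`.
#' @return Invisibly, `path`.
#' @export
write_prediction <- function(pred, path, trajectory = NULL) {
  stopifnot(inherits(pred, "dynamic_prediction"))
  sv <- cbind(subject_id = pred$subject_id, landmark = pred$landmark,
              pred$survival, kind = "survival")
  out <- sv
  if (!is.null(trajectory)) {
    tr <- data.frame(subject_id = pred$subject_id,
                     landmark = pred$landmark,
                     horizon = trajectory$time, mean = trajectory$mean,
                     lower = trajectory$lower, upper = trajectory$upper,
                     kind = "trajectory")
    out <- rbind(out, tr)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
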