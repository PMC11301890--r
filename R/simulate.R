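#' Configuration for the joint-data simulator
#'
#' The generator draws, per subject, random effects \eqn{b_i} (intercept and
#' slope) from a zero-mean normal or Student-t distribution with covariance
#' `D`, builds the trajectory
#' \eqn{\eta_i(t) = x_i(t)'\beta + z_i(t)'b_i} with \eqn{x = z = (1, t)},
#' and gives the subject the hazard
#' \eqn{h_i(t) = \exp(\log h_0 + \gamma' w_i + \alpha\,\eta_i(t))}
#' with a *constant* true log baseline hazard, so that closed-form checks
#' exist.  Event times are drawn by inverting the cumulative hazard;
#' censoring is the minimum of an exponential time and the administrative
#' horizon.  Biomarker values are observed with Gaussian noise on a fixed
#' visit grid, at visits strictly before the observed time (the baseline
#' visit at 0 is always kept).
#'
#' @param n_subjects Number of subjects.
#' @param beta Fixed effects (intercept, time slope).
#' @param D 2x2 symmetric positive-definite random-effects covariance.
#' @param sigma Residual standard deviation (> 0).
#' @param gamma Log-hazard ratios of the baseline covariates; one
#'   independent standard-normal covariate per element is generated.
#' @param alpha Association: scale on the current linear predictor in the
#'   hazard.
#' @param log_h0 Constant true log baseline hazard.
#' @param censor_rate Exponential censoring rate; 0 disables random
#'   censoring.
#' @param admin_horizon Administrative follow-up limit \eqn{\tau} (may be
#'   `Inf`).
#' @param visit_times Increasing visit grid starting at 0.
#' @param re_distribution `"normal"` or `"student_t"` random effects.
#' @param df Degrees of freedom for Student-t random effects (> 2).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects,
                       beta = c(0.5, 0.3),
                       D = diag(c(0.4, 0.04)),
                       sigma = 0.3,
                       gamma = 0.4,
                       alpha = 0.6,
                       log_h0 = -0.7,
                       censor_rate = 0.25,
                       admin_horizon = 3,
                       visit_times = seq(0, 2.75, by = 0.25),
                       re_distribution = c("normal", "student_t"),
                       df = 4L,
                       seed = 1L) {
  re_distribution <- match.arg(re_distribution)
  if (length(visit_times) == 0)
    stop_bigjoint("empty visit schedule", "bigjoint_config_error")
  if (visit_times[1L] != 0 || is.unsorted(visit_times, strictly = TRUE))
    stop_bigjoint("visit_times must be strictly increasing and start at 0",
                  "bigjoint_config_error")
  if (!isSymmetric(unname(D)) || any(eigen(D, symmetric = TRUE,
                                           only.values = TRUE)$values <= 0))
    stop_bigjoint("D must be symmetric positive-definite",
                  "bigjoint_config_error")
  if (sigma <= 0 || censor_rate < 0 || admin_horizon <= 0 ||
      n_subjects < 1 || length(beta) != 2L)
    stop_bigjoint("invalid simulation configuration",
                  "bigjoint_config_error")
  if (re_distribution == "student_t" && df <= 2)
    stop_bigjoint("Student-t df must exceed 2 for a finite covariance",
                  "bigjoint_config_error")
  structure(list(n_subjects = as.integer(n_subjects), beta = beta, D = D,
                 sigma = sigma, gamma = gamma, alpha = alpha,
                 log_h0 = log_h0, censor_rate = censor_rate,
                 admin_horizon = admin_horizon, visit_times = visit_times,
                 re_distribution = re_distribution, df = df,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a joint longitudinal--survival dataset with known truth
#'
#' @param config A [sim_config()].
#' @return A `joint_simulation` list: `longitudinal`
#'   (a `longitudinal_data`), `survival` (a `survival_data`), and `truth`
#'   (the generating parameter values, plus the drawn random effects).
#' @examples
#' sim <- simulate_joint_dataset(sim_config(50, seed = 42))
#' table(sim$survival$event)
#' @export
simulate_joint_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  k <- length(config$gamma)
  W <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("w", seq_len(k))))
  if (config$re_distribution == "normal") {
    b <- rmvnorm_chol(n, c(0, 0), config$D)
  } else {
    lam <- rgamma(n, config$df / 2, rate = config$df / 2)
    b <- rmvnorm_chol(n, c(0, 0), config$D) / sqrt(lam)
  }
  u <- runif(n)
  event_time <- vapply(seq_len(n), function(i)
    invert_survival_time(list(w = W[i, ], b = b[i, ]), config, u[i]),
    numeric(1))
  cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  cens <- pmin(cens, config$admin_horizon)
  obs_time <- pmin(event_time, cens)
  delta <- as.numeric(event_time <= cens)
  # guard: everything must end at a finite time; an infinite event time with
  # infinite horizon and no censoring cannot be represented
  if (any(!is.finite(obs_time)))
    stop_bigjoint("subject with infinite observed time; set a finite admin_horizon or censor_rate",
                  "bigjoint_config_error")

  ids <- sprintf("s%0*d", nchar(n), seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    tt <- config$visit_times[config$visit_times < obs_time[i]]
    if (length(tt) == 0) tt <- 0           # mandatory baseline visit
    data.frame(id = ids[i], time = tt,
               eta = config$beta[1] + config$beta[2] * tt +
                 b[i, 1] + b[i, 2] * tt,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long$outcome <- long$eta + rnorm(nrow(long), 0, config$sigma)
  truth_eta <- long$eta
  long$eta <- NULL

  long_obj <- new_longitudinal_data(long[, c("id", "time", "outcome")],
                                    character(),
                                    c("intercept", "time"))
  surv_df <- data.frame(id = ids, time = obs_time, event = delta,
                        stringsAsFactors = FALSE)
  for (j in seq_len(k)) surv_df[[colnames(W)[j]]] <- W[, j]
  surv_obj <- new_survival_data(surv_df, colnames(W),
                                if (is.finite(config$admin_horizon))
                                  config$admin_horizon else NULL)
  truth <- structure(list(beta = config$beta, D = config$D,
                          sigma = config$sigma, gamma = config$gamma,
                          alpha = config$alpha, log_h0 = config$log_h0,
                          b = b, ids = ids, true_eta = truth_eta),
                     class = "true_parameters")
  structure(list(longitudinal = long_obj, survival = surv_obj,
                 truth = truth, config = config),
            class = "joint_simulation")
}

#' Invert a subject's cumulative hazard to draw an event time
#'
#' Solves \eqn{H_i(t^*) = -\log u} where \eqn{H_i} is the integral of the
#' subject's hazard from 0, by bracketing and root refinement to absolute
#' tolerance 1e-8.  Returns `Inf` when the cumulative hazard over the whole
#' search window (ten administrative horizons) never reaches the target.
#'
#' @param subject_state List with elements `w` (baseline covariates) and
#'   `b` (random intercept and slope).
#' @param config A [sim_config()].
#' @param u Uniform(0,1) draw.
#' @return The event time, or `Inf`.
#' @export
invert_survival_time <- function(subject_state, config, u) {
  stopifnot(u > 0, u < 1)
  target <- -log(u)
  cc <- config$log_h0 + sum(config$gamma * subject_state$w) +
    config$alpha * (config$beta[1] + subject_state$b[1])
  dd <- config$alpha * (config$beta[2] + subject_state$b[2])
  H <- function(t) {
    # exact integral of exp(cc + dd s) on [0, t]
    if (abs(dd) < 1e-12) exp(cc) * t else exp(cc) * expm1(dd * t) / dd
  }
  t_max <- if (is.finite(config$admin_horizon))
    10 * config$admin_horizon else 1e8
  if (H(t_max) < target) return(Inf)
  uniroot(function(t) H(t) - target, lower = 0, upper = t_max,
          tol = 1e-8)$root
}

#' Write a simulated dataset to disk
#'
#' Writes the longitudinal and survival CSVs in the package's table dialect
#' plus a YAML sidecar with the generating (true) parameter values.
#'
#' @param sim A [simulate_joint_dataset()] result.
#' @param dir Output directory (created if absent).
#' @param basename File stem; default `"sim"`.
#' @return Invisibly, the three paths written.
#' @export
write_simulation <- function(sim, dir, basename = "sim") {
  stopifnot(inherits(sim, "joint_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- file.path(dir, paste0(basename, "_long.csv"))
  sp <- file.path(dir, paste0(basename, "_surv.csv"))
  yp <- file.path(dir, paste0(basename, "_truth.yaml"))
  vd <- validate_join(sim$longitudinal, sim$survival)
  write_dataset(vd, lp, sp)
  tr <- sim$truth
  yaml::write_yaml(list(beta = as.numeric(tr$beta),
                        D = as.numeric(tr$D), sigma = tr$sigma,
                        gamma = as.numeric(tr$gamma), alpha = tr$alpha,
                        log_h0 = tr$log_h0,
                        seed = sim$config$seed), yp)
  invisible(c(lp, sp, yp))
}
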