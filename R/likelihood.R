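#' Model specification for the joint model
#'
#' Only the Gaussian/identity-link longitudinal family is implemented end
#' to end; the family/link fields are an extension seam.  The association
#' structure is the current value of the linear predictor,
#' \eqn{\alpha\,\eta_i(t)}, entering the log hazard.
#'
#' @param fixed_design Labels building \eqn{x_i(t)}: `"intercept"`,
#'   `"time"`, plus optional longitudinal covariate names (treated as
#'   time-constant per subject in the hazard integrand).
#' @param random_design Labels building \eqn{z_i(t)}; default random
#'   intercept and slope.
#' @param family,link Longitudinal family and link; only
#'   `"gaussian"`/`"identity"`.
#' @param association Association structure; only `"current_value"`.
#' @param re_distribution Random-effects law: `"normal"` or `"student_t"`.
#' @param df Student-t degrees of freedom (fixed, not estimated).
#' @return A `model_spec` object.
#' @export
model_spec <- function(fixed_design = c("intercept", "time"),
                       random_design = c("intercept", "time"),
                       family = "gaussian", link = "identity",
                       association = "current_value",
                       re_distribution = c("normal", "student_t"),
                       df = 4L) {
  re_distribution <- match.arg(re_distribution)
  if (family != "gaussian" || link != "identity")
    stop_bigjoint("only the gaussian/identity longitudinal model is supported",
                  "bigjoint_config_error")
  if (association != "current_value")
    stop_bigjoint("only the current-value association is supported",
                  "bigjoint_config_error")
  structure(list(fixed_design = fixed_design,
                 random_design = random_design,
                 family = family, link = link, association = association,
                 re_distribution = re_distribution, df = as.integer(df)),
            class = "model_spec")
}

#' Prior specification
#'
#' Zero-mean normal priors on all fixed-dimension coefficients
#' (\eqn{\beta, \gamma, \alpha} and the baseline-hazard coefficients), an
#' inverse-Wishart prior on the random-effects covariance `D`, and an
#' inverse-gamma prior on the residual variance \eqn{\sigma^2}.  The
#' random-effects density \eqn{\sum_i \log p(b_i \mid D)} is accounted here
#' as part of the prior, keeping the likelihood conditional on the
#' \eqn{b_i}.
#'
#' @param normal_sd_fixed Prior standard deviation of the normal priors.
#' @param D_df,D_scale Inverse-Wishart degrees of freedom and scale matrix
#'   (defaults: dimension + 1 and the identity, set at use time when
#'   `D_df`/`D_scale` are `NULL`).
#' @param sigma2_shape,sigma2_rate Inverse-gamma hyperparameters for
#'   \eqn{\sigma^2}.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(normal_sd_fixed = 10,
                       D_df = NULL, D_scale = NULL,
                       sigma2_shape = 0.01, sigma2_rate = 0.01) {
  stopifnot(normal_sd_fixed > 0, sigma2_shape > 0, sigma2_rate > 0)
  structure(list(normal_sd_fixed = normal_sd_fixed, D_df = D_df,
                 D_scale = D_scale, sigma2_shape = sigma2_shape,
                 sigma2_rate = sigma2_rate),
            class = "prior_spec")
}

#' Joint-model parameter container
#'
#' @param beta Fixed effects.
#' @param b Matrix of subject random effects (subjects in the survival
#'   table's id order).
#' @param D Random-effects covariance (symmetric positive-definite).
#' @param sigma Residual standard deviation (> 0).
#' @param gamma Survival covariate log-hazard ratios.
#' @param alpha Association parameter.
#' @param baseline A [baseline_coefs()].
#' @return A `joint_parameters` object.
#' @export
joint_parameters <- function(beta, b, D, sigma, gamma, alpha, baseline) {
  if (sigma <= 0) stop_bigjoint("sigma must be positive",
                                "bigjoint_domain_error")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop_bigjoint("D must be positive-definite", "bigjoint_domain_error")
  structure(list(beta = beta, b = b, D = D, sigma = sigma, gamma = gamma,
                 alpha = alpha, baseline = baseline),
            class = "joint_parameters")
}

#' Linear predictor of the longitudinal submodel
#'
#' \eqn{\eta = x'\beta + z'b}.
#'
#' @param x,beta Fixed design vector and coefficients.
#' @param z,b Random design vector and subject effects.
#' @return Scalar linear predictor.
#' @export
linear_predictor <- function(x, z, beta, b) {
  if (length(x) != length(beta) || length(z) != length(b))
    stop_bigjoint("design/coefficient dimension mismatch",
                  "bigjoint_shape_error")
  sum(x * beta) + sum(z * b)
}

#' Longitudinal Gaussian log-likelihood
#'
#' \eqn{\sum_{il} \log N(y_{il} \mid \eta_i(t_{il}), \sigma^2)},
#' conditional on the random effects held in `params`.
#'
#' @param data A `validated_dataset`.
#' @param params A [joint_parameters()].
#' @param spec A [model_spec()].
#' @return Scalar log-likelihood.
#' @export
longitudinal_loglik <- function(data, params, spec) {
  if (params$sigma <= 0)
    stop_bigjoint("sigma must be positive", "bigjoint_domain_error")
  md <- build_model_data(data, spec)
  sum(long_loglik_subj(md, params$beta, params$sigma, params$b))
}

#' Survival log-likelihood of the proportional-hazards submodel
#'
#' \eqn{\sum_i \delta_i\{\log h_0(T_i) + \gamma'w_i + \alpha\eta_i(T_i)\}
#' - H_i(0, T_i)}, with the cumulative hazard by Gauss--Legendre
#' quadrature.
#'
#' @inheritParams longitudinal_loglik
#' @param basis A `spline_basis` for the log baseline hazard.
#' @return Scalar log-likelihood.
#' @export
survival_loglik <- function(data, params, spec, basis) {
  md <- build_model_data(data, spec, basis)
  sum(surv_loglik_subj(md, params$beta, params$gamma, params$alpha,
                       params$baseline$intercept,
                       params$baseline$spline_coefs, params$b))
}

#' Log prior density of the joint-model parameters
#'
#' Normal priors on \eqn{\beta, \gamma, \alpha} and the baseline
#' coefficients; inverse-Wishart on `D`; inverse-gamma on \eqn{\sigma^2};
#' plus the random-effects density \eqn{\sum_i \log p(b_i \mid D)}
#' (multivariate normal, or Student-t with the spec's fixed df).
#' Returns `-Inf` for out-of-support values instead of erroring, so the
#' sampler can reject.
#'
#' @inheritParams longitudinal_loglik
#' @param priors A [prior_spec()].
#' @return Scalar log prior density (unnormalized posterior contribution).
#' @export
log_prior <- function(params, priors, spec) {
  if (params$sigma <= 0) return(-Inf)
  q <- ncol(params$b)
  ev <- eigen(params$D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(-Inf)
  sdf <- priors$normal_sd_fixed
  fixed <- c(params$beta, params$gamma, params$alpha,
             params$baseline$intercept, params$baseline$spline_coefs)
  lp <- sum(dnorm(fixed, 0, sdf, log = TRUE))
  D_df <- if (is.null(priors$D_df)) q + 1 else priors$D_df
  D_scale <- if (is.null(priors$D_scale)) diag(q) else priors$D_scale
  lp <- lp + ldiwish(params$D, D_df, D_scale)
  lp <- lp + ldinvgamma(params$sigma^2, priors$sigma2_shape,
                        priors$sigma2_rate)
  if (nrow(params$b) > 0) {
    lp <- lp + if (spec$re_distribution == "normal")
      sum(dmvnorm0_log(params$b, params$D))
    else sum(dmvt0_log(params$b, params$D, spec$df))
  }
  lp
}

#' Unnormalized log posterior kernel
#'
#' The sum of [longitudinal_loglik()], [survival_loglik()] and
#' [log_prior()]; `-Inf` propagates for out-of-support parameters.
#'
#' @inheritParams survival_loglik
#' @param priors A [prior_spec()].
#' @return Scalar unnormalized log posterior.
#' @export
log_posterior <- function(data, params, priors, spec, basis) {
  lp <- log_prior(params, priors, spec)
  if (!is.finite(lp)) return(-Inf)
  lp + longitudinal_loglik(data, params, spec) +
    survival_loglik(data, params, spec, basis)
}

ldiwish <- function(D, df, S) {
  q <- nrow(D)
  cholD <- chol(D)
  ldetD <- 2 * sum(log(diag(cholD)))
  ldetS <- determinant(S, logarithm = TRUE)$modulus
  lmvgamma <- sum(lgamma((df + 1 - seq_len(q)) / 2)) +
    q * (q - 1) / 4 * log(pi)
  as.numeric(df / 2 * ldetS - df * q / 2 * log(2) - lmvgamma -
               (df + q + 1) / 2 * ldetD -
               0.5 * sum(diag(S %*% chol2inv(cholD))))
}

ldinvgamma <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

# -- internal precomputed model structure -----------------------------------
#
# Everything the sampler touches per iteration is laid out as flat vectors
# and matrices here, once, so that likelihood evaluations are vectorized
# across subjects (and across quadrature nodes for the survival part).

build_model_data <- function(data, spec, basis = NULL, nodes = 15L) {
  stopifnot(inherits(data, "validated_dataset"))
  surv <- data$survival
  long <- data$longitudinal
  ids <- surv$id
  n <- length(ids)
  Ti <- surv$time
  delta <- surv$event
  wnames <- attr(surv, "covariates")
  W <- if (length(wnames))
    as.matrix(as.data.frame(surv)[, wnames, drop = FALSE]) else
      matrix(0, n, 0)

  si <- match(long$id, ids)
  # time-constant covariate value per subject (first record), used when a
  # longitudinal covariate appears in the hazard integrand design
  first_row <- match(ids, long$id)
  design_cols <- function(labels, tvec, subj_idx) {
    out <- matrix(0, length(tvec), length(labels))
    colnames(out) <- labels
    for (j in seq_along(labels)) {
      lab <- labels[j]
      out[, j] <- switch(lab,
        intercept = 1,
        time = tvec,
        long[[lab]][first_row][subj_idx])
    }
    out
  }
  X <- design_cols(spec$fixed_design, long$time, si)
  Z <- design_cols(spec$random_design, long$time, si)

  md <- list(ids = ids, n = n, Ti = Ti, delta = delta, W = W,
             y = long$outcome, si = si, X = X, Z = Z,
             p = ncol(X), q = ncol(Z), N = nrow(long),
             spec = spec)
  if (!is.null(basis)) {
    gl <- gauss_legendre_rule(nodes)
    G <- length(gl$x)
    Snodes <- outer(Ti / 2, gl$x + 1)          # n x G
    Wq <- outer(Ti / 2, gl$w)
    sflat <- as.vector(Snodes)                 # subject varies fastest
    rep_i <- rep(seq_len(n), times = G)
    Bfull_T <- bspline_basis(Ti, basis)
    Bfull_n <- bspline_basis(sflat, basis)
    md$basis <- basis
    md$G <- G
    md$Wq_flat <- as.vector(Wq)
    md$rep_i <- rep_i
    md$Bred_T <- Bfull_T[, -1L, drop = FALSE]
    md$Bred_n <- Bfull_n[, -1L, drop = FALSE]
    md$X_T <- design_cols(spec$fixed_design, Ti, seq_len(n))
    md$Z_T <- design_cols(spec$random_design, Ti, seq_len(n))
    md$X_n <- design_cols(spec$fixed_design, sflat, rep_i)
    md$Z_n <- design_cols(spec$random_design, sflat, rep_i)
  }
  md
}

# Per-subject longitudinal Gaussian log-likelihood (length-n vector).
long_loglik_subj <- function(md, beta, sigma, b) {
  eta <- drop(md$X %*% beta) + rowSums(md$Z * b[md$si, , drop = FALSE])
  contrib <- dnorm(md$y, eta, sigma, log = TRUE)
  out <- numeric(md$n)
  agg <- rowsum(contrib, md$si)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Per-subject survival log-likelihood (length-n vector).
surv_loglik_subj <- function(md, beta, gamma, alpha, g0int, g0coef, b) {
  wterm <- if (ncol(md$W)) drop(md$W %*% gamma) else numeric(md$n)
  eta_T <- drop(md$X_T %*% beta) + rowSums(md$Z_T * b)
  loghaz_T <- g0int + drop(md$Bred_T %*% g0coef) + wterm + alpha * eta_T
  eta_n <- drop(md$X_n %*% beta) +
    rowSums(md$Z_n * b[md$rep_i, , drop = FALSE])
  haz_n <- exp(g0int + drop(md$Bred_n %*% g0coef) + wterm[md$rep_i] +
                 alpha * eta_n)
  H <- rowSums(matrix(md$Wq_flat * haz_n, md$n, md$G))
  md$delta * loghaz_T - H
}
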