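#' MCMC sampler configuration
#'
#' @param n_iter Total iterations.
#' @param n_burnin Burn-in iterations discarded (< `n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed; a fixed seed gives bit-identical draws.
#' @param step_scales Optional named list of initial random-walk proposal
#'   scales for the blocks `b`, `beta`, `gamma`, `alpha`, `baseline`.
#' @param adapt Adapt proposal scales during burn-in (Robbins--Monro,
#'   targeting acceptance 0.25 for vector blocks and 0.44 for scalars);
#'   adaptation is frozen after burn-in to preserve detailed balance.
#' @param store_re Also store per-subject random-effect draws (memory
#'   heavy; off by default).
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(n_iter = 4000L, n_burnin = 1000L, thin = 1L,
                        seed = 1L, step_scales = NULL, adapt = TRUE,
                        store_re = FALSE) {
  if (n_burnin < 0 || n_iter <= n_burnin || thin < 1)
    stop_bigjoint("need n_iter > n_burnin >= 0 and thin >= 1",
                  "bigjoint_config_error")
  sc <- list(b = 0.8, beta = 0.05, gamma = 0.1, alpha = 0.1,
             baseline = 0.1)
  if (!is.null(step_scales)) sc[names(step_scales)] <- step_scales
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), step_scales = sc,
                 adapt = isTRUE(adapt), store_re = isTRUE(store_re)),
            class = "mcmc_config")
}

#' Initial parameter values from simple moment estimators
#'
#' Fixed effects from pooled ordinary least squares of the outcome on the
#' fixed design; random effects at zero; `D` diagonal from per-subject
#' OLS-residual moments (floored at 0.01); residual standard deviation
#' from the pooled residuals; survival coefficients and association at
#' zero; baseline-hazard intercept at the log crude event rate
#' (events / total follow-up time) with zero spline coefficients.
#'
#' @param data A `validated_dataset`.
#' @param spec A [model_spec()].
#' @param basis A `spline_basis`.
#' @return A [joint_parameters()] object.
#' @export
initialize_parameters <- function(data, spec, basis) {
  md <- build_model_data(data, spec)
  if (sum(md$delta) == 0)
    stop_bigjoint("no events in the data; the survival submodel cannot be initialized — supply more data",
                  "bigjoint_init_error")
  fit <- lm.fit(md$X, md$y)
  beta <- unname(fit$coefficients)
  beta[is.na(beta)] <- 0
  res <- md$y - drop(md$X %*% beta)
  sigma <- max(sd(res), 0.01)
  if (!is.finite(sigma)) sigma <- 0.01

  dvar <- numeric(md$q)
  for (j in seq_len(md$q)) {
    lab <- spec$random_design[j]
    if (lab == "intercept") {
      m <- tapply(res, md$si, mean)
      dvar[j] <- var(as.numeric(m))
    } else if (lab == "time") {
      sl <- tapply(seq_along(res), md$si, function(ix) {
        tt <- md$Z[ix, j]
        if (length(unique(tt)) < 2) return(NA_real_)
        sum((tt - mean(tt)) * (res[ix] - mean(res[ix]))) /
          sum((tt - mean(tt))^2)
      })
      dvar[j] <- var(as.numeric(sl), na.rm = TRUE)
    }
    if (!is.finite(dvar[j]) || dvar[j] < 0.01) dvar[j] <- 0.01
  }
  D <- diag(dvar, md$q)

  g0int <- log(sum(md$delta) / sum(md$Ti))
  joint_parameters(
    beta = beta,
    b = matrix(0, md$n, md$q),
    D = D, sigma = sigma,
    gamma = rep(0, ncol(md$W)),
    alpha = 0,
    baseline = baseline_coefs(g0int, rep(0, n_basis(basis) - 1L)))
}

#' Fit the joint model on one data chunk by Metropolis-within-Gibbs
#'
#' Each iteration updates: (i) every subject's random-effect block by a
#' joint random-walk Metropolis step on its own conditional; (ii)
#' \eqn{\beta}, \eqn{\gamma}, \eqn{\alpha} and the baseline-hazard
#' coefficients in separate random-walk blocks against the log posterior;
#' (iii) `D` by a conjugate inverse-Wishart draw given the random effects
#' (with per-subject inverse-gamma mixing draws under Student-t effects);
#' (iv) \eqn{\sigma^2} by a conjugate inverse-gamma draw given the
#' residuals.
#'
#' @param data A `validated_dataset` with at least one event.
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()].
#' @param basis A `spline_basis` (shared across chunks in
#'   [fit_big()]).
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_draws` object: retained draw matrix (one named
#'   column per scalar parameter, including the lower triangle of `D`),
#'   block acceptance rates, posterior mean of the random effects, and the
#'   configuration snapshot.
#' @export
fit_mcmc <- function(data, spec = model_spec(), priors = prior_spec(),
                     basis, mcmc = mcmc_config()) {
  md <- build_model_data(data, spec, basis)
  init <- initialize_parameters(data, spec, basis)
  set.seed(mcmc$seed)

  n <- md$n; q <- md$q; p <- md$p; k <- ncol(md$W)
  nb <- n_basis(basis) - 1L
  D_df <- if (is.null(priors$D_df)) q + 1 else priors$D_df
  D_scale <- if (is.null(priors$D_scale)) diag(q) else priors$D_scale
  sdf <- priors$normal_sd_fixed
  student <- spec$re_distribution == "student_t"

  beta <- init$beta; b <- init$b; D <- init$D; sigma <- init$sigma
  gamma <- init$gamma; alpha <- init$alpha
  g0int <- init$baseline$intercept; g0coef <- init$baseline$spline_coefs
  lam <- rep(1, n)

  ll_long <- long_loglik_subj(md, beta, sigma, b)
  ll_surv <- surv_loglik_subj(md, beta, gamma, alpha, g0int, g0coef, b)
  jit <- 0L
  while (!all(is.finite(c(ll_long, ll_surv))) && jit < 100L) {
    beta <- beta + rnorm(p, 0, 0.01)
    g0int <- g0int + rnorm(1, 0, 0.01)
    ll_long <- long_loglik_subj(md, beta, sigma, b)
    ll_surv <- surv_loglik_subj(md, beta, gamma, alpha, g0int, g0coef, b)
    jit <- jit + 1L
  }
  if (!all(is.finite(c(ll_long, ll_surv))))
    stop_bigjoint("log posterior not finite at initialization after 100 jitter attempts",
                  "bigjoint_divergence_error")

  # random-effects prior terms, given D (and mixing weights under Student-t)
  Dinv <- chol2inv(chol(D))
  re_quad <- rowSums((b %*% Dinv) * b)
  re_logdetD <- determinant(D, logarithm = TRUE)$modulus[1]
  re_prior <- -0.5 * q * log(2 * pi) - 0.5 * re_logdetD +
    0.5 * q * log(lam) - 0.5 * lam * re_quad

  sc <- mcmc$step_scales
  blocks <- c("b", "beta", if (k > 0) "gamma", "alpha", "baseline")
  acc <- setNames(numeric(length(blocks)), blocks)
  trials <- acc
  batch_acc <- acc; batch_n <- acc; batch_no <- 0L

  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  par_names <- c(paste0("beta_", spec$fixed_design),
                 if (k > 0) paste0("gamma_", colnames(md$W)),
                 "alpha", "sigma", "gamma0_0", paste0("gamma0_", seq_len(nb)),
                 d_lower_names(q))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  b_draws <- if (mcmc$store_re) array(NA_real_, c(n_keep, n, q)) else NULL
  b_mean <- matrix(0, n, q)
  keep_i <- 0L

  fixed_lp <- function(x) sum(dnorm(x, 0, sdf, log = TRUE))

  for (iter in seq_len(mcmc$n_iter)) {
    ## (i) subject random effects, all blocks in parallel
    step_b <- sc$b * sqrt(diag(D))
    bp <- b + matrix(rnorm(n * q), n, q) %*% diag(step_b, q)
    ll_long_p <- long_loglik_subj(md, beta, sigma, bp)
    ll_surv_p <- surv_loglik_subj(md, beta, gamma, alpha, g0int, g0coef, bp)
    quad_p <- rowSums((bp %*% Dinv) * bp)
    re_prior_p <- -0.5 * q * log(2 * pi) - 0.5 * re_logdetD +
      0.5 * q * log(lam) - 0.5 * lam * quad_p
    lr <- (ll_long_p + ll_surv_p + re_prior_p) -
      (ll_long + ll_surv + re_prior)
    ok <- log(runif(n)) < lr
    if (any(ok)) {
      b[ok, ] <- bp[ok, , drop = FALSE]
      ll_long[ok] <- ll_long_p[ok]; ll_surv[ok] <- ll_surv_p[ok]
      re_prior[ok] <- re_prior_p[ok]; re_quad[ok] <- quad_p[ok]
    }
    batch_acc["b"] <- batch_acc["b"] + mean(ok); batch_n["b"] <- batch_n["b"] + 1
    acc["b"] <- acc["b"] + mean(ok); trials["b"] <- trials["b"] + 1

    ## Student-t mixing weights
    if (student) {
      lam <- rgamma(n, (spec$df + q) / 2, rate = (spec$df + re_quad) / 2)
      re_prior <- -0.5 * q * log(2 * pi) - 0.5 * re_logdetD +
        0.5 * q * log(lam) - 0.5 * lam * re_quad
    }

    ## (ii) fixed-dimension blocks
    # beta: affects both submodels
    bprop <- beta + sc$beta * rnorm(p)
    llp <- long_loglik_subj(md, bprop, sigma, b)
    lsp <- surv_loglik_subj(md, bprop, gamma, alpha, g0int, g0coef, b)
    lr <- sum(llp + lsp) - sum(ll_long + ll_surv) +
      fixed_lp(bprop) - fixed_lp(beta)
    ok1 <- is.finite(lr) && log(runif(1)) < lr
    if (ok1) { beta <- bprop; ll_long <- llp; ll_surv <- lsp }
    batch_acc["beta"] <- batch_acc["beta"] + ok1
    batch_n["beta"] <- batch_n["beta"] + 1
    acc["beta"] <- acc["beta"] + ok1; trials["beta"] <- trials["beta"] + 1

    # gamma: survival only
    if (k > 0) {
      gprop <- gamma + sc$gamma * rnorm(k)
      lsp <- surv_loglik_subj(md, beta, gprop, alpha, g0int, g0coef, b)
      lr <- sum(lsp) - sum(ll_surv) + fixed_lp(gprop) - fixed_lp(gamma)
      ok1 <- is.finite(lr) && log(runif(1)) < lr
      if (ok1) { gamma <- gprop; ll_surv <- lsp }
      batch_acc["gamma"] <- batch_acc["gamma"] + ok1
      batch_n["gamma"] <- batch_n["gamma"] + 1
      acc["gamma"] <- acc["gamma"] + ok1
      trials["gamma"] <- trials["gamma"] + 1
    }

    # alpha: survival only
    aprop <- alpha + sc$alpha * rnorm(1)
    lsp <- surv_loglik_subj(md, beta, gamma, aprop, g0int, g0coef, b)
    lr <- sum(lsp) - sum(ll_surv) + fixed_lp(aprop) - fixed_lp(alpha)
    ok1 <- is.finite(lr) && log(runif(1)) < lr
    if (ok1) { alpha <- aprop; ll_surv <- lsp }
    batch_acc["alpha"] <- batch_acc["alpha"] + ok1
    batch_n["alpha"] <- batch_n["alpha"] + 1
    acc["alpha"] <- acc["alpha"] + ok1; trials["alpha"] <- trials["alpha"] + 1

    # baseline-hazard coefficients (intercept + spline block)
    g0prop <- c(g0int, g0coef) + sc$baseline * rnorm(nb + 1L)
    lsp <- surv_loglik_subj(md, beta, gamma, alpha, g0prop[1L],
                            g0prop[-1L], b)
    lr <- sum(lsp) - sum(ll_surv) +
      fixed_lp(g0prop) - fixed_lp(c(g0int, g0coef))
    ok1 <- is.finite(lr) && log(runif(1)) < lr
    if (ok1) { g0int <- g0prop[1L]; g0coef <- g0prop[-1L]; ll_surv <- lsp }
    batch_acc["baseline"] <- batch_acc["baseline"] + ok1
    batch_n["baseline"] <- batch_n["baseline"] + 1
    acc["baseline"] <- acc["baseline"] + ok1
    trials["baseline"] <- trials["baseline"] + 1

    ## (iii) conjugate D | b (, lam)
    S_post <- D_scale + crossprod(b, b * lam)
    D <- riwish1(D_df + n, S_post)
    Dinv <- chol2inv(chol(D))
    re_quad <- rowSums((b %*% Dinv) * b)
    re_logdetD <- determinant(D, logarithm = TRUE)$modulus[1]
    re_prior <- -0.5 * q * log(2 * pi) - 0.5 * re_logdetD +
      0.5 * q * log(lam) - 0.5 * lam * re_quad

    ## (iv) conjugate sigma^2 | residuals
    eta_obs <- drop(md$X %*% beta) + rowSums(md$Z * b[md$si, , drop = FALSE])
    ssr <- sum((md$y - eta_obs)^2)
    sigma <- sqrt(1 / rgamma(1, priors$sigma2_shape + md$N / 2,
                             rate = priors$sigma2_rate + ssr / 2))
    ll_long <- long_loglik_subj(md, beta, sigma, b)

    ## adaptation during burn-in
    if (mcmc$adapt && iter <= mcmc$n_burnin && iter %% 50L == 0L) {
      batch_no <- batch_no + 1L
      step <- min(0.25, 1 / sqrt(batch_no))
      for (bl in blocks) {
        if (batch_n[bl] == 0) next
        rate <- batch_acc[bl] / batch_n[bl]
        target <- if (bl == "alpha") 0.44 else 0.25
        sc[[bl]] <- sc[[bl]] * exp(step * (rate - target))
      }
      batch_acc[] <- 0; batch_n[] <- 0
    }

    ## storage
    if (iter > mcmc$n_burnin &&
        (iter - mcmc$n_burnin) %% mcmc$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- c(beta, if (k > 0) gamma, alpha, sigma,
                           g0int, g0coef, D[lower.tri(D, diag = TRUE)])
      if (mcmc$store_re) b_draws[keep_i, , ] <- b
      b_mean <- b_mean + b
    }
  }
  b_mean <- b_mean / n_keep

  structure(list(draws = draws,
                 b_mean = b_mean,
                 b_draws = b_draws,
                 acceptance = acc / pmax(trials, 1),
                 seed = mcmc$seed,
                 spec = spec, basis = basis, priors = priors,
                 mcmc = mcmc,
                 ids = md$ids,
                 n_subjects = md$n, n_records = md$N),
            class = "posterior_draws")
}

d_lower_names <- function(q) {
  idx <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  sprintf("D_%d_%d", idx[, 1], idx[, 2])
}

#' Posterior summary of a draw matrix
#'
#' Column means, standard deviations, equal-tailed 95% interval bounds and
#' a crude effective sample size (initial-positive-sequence estimate) per
#' scalar parameter.
#'
#' @param draws A `posterior_draws` object (>= 10 retained draws).
#' @return A `fit_summary`: data frame with columns `parameter`, `mean`,
#'   `sd`, `q2.5`, `q97.5`, `ess`, carrying `n_subjects` and `n_records`
#'   as attributes.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- draws$draws
  if (nrow(m) < 10L)
    stop_bigjoint("need at least 10 retained draws to summarize",
                  "bigjoint_summary_error")
  qs <- apply(m, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2L, sd),
                    q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                    ess = apply(m, 2L, ess_ips),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n_subjects = draws$n_subjects,
            n_records = draws$n_records,
            class = c("fit_summary", "data.frame"))
}

# initial-positive-sequence effective sample size
ess_ips <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  ac <- as.numeric(stats::acf(x, lag.max = min(n - 1L, 200L),
                              plot = FALSE)$acf)[-1L]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Write posterior draws to CSV with a YAML metadata sidecar
#'
#' @param draws A `posterior_draws`.
#' @param csv_path Draw matrix destination (one column per parameter).
#' @param yaml_path Metadata destination (seed, sampler settings,
#'   model spec).
#' @return Invisibly, the two paths.
#' @export
write_draws <- function(draws, csv_path, yaml_path) {
  stopifnot(inherits(draws, "posterior_draws"))
  write.csv(as.data.frame(draws$draws), csv_path, row.names = FALSE)
  yaml::write_yaml(list(seed = draws$seed,
                        n_iter = draws$mcmc$n_iter,
                        n_burnin = draws$mcmc$n_burnin,
                        thin = draws$mcmc$thin,
                        re_distribution = draws$spec$re_distribution,
                        acceptance = as.list(round(draws$acceptance, 4)),
                        n_subjects = draws$n_subjects),
                   yaml_path)
  invisible(c(csv_path, yaml_path))
}
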