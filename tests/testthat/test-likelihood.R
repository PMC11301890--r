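make_basis01 <- function(tmax = 3) spline_basis(numeric(), c(0, tmax))

test_that("linear predictor is the bilinear sum with strict dimension checks", {
  expect_equal(linear_predictor(c(1, 2), c(1, 2), c(0, 0), c(0, 0)), 0)
  expect_equal(linear_predictor(c(1, 2), c(1, 2), c(0.5, 1),
                                c(0.1, -0.2)), 2.2)
  expect_equal(linear_predictor(c(1, 2), c(1, 2), c(0.5, 1), c(0.1, -0.2)),
               linear_predictor(c(1, 2), c(1, 2), c(0.1, -0.2), c(0.5, 1)))
  expect_error(linear_predictor(c(1, 2), c(1), c(0.5, 1, 2), c(0.1)),
               class = "bigjoint_shape_error")
})

test_that("longitudinal log-likelihood is an additive sum of normal densities", {
  # one subject, one observation, zero residual, sigma = 1
  long <- bigjoint:::new_longitudinal_data(
    data.frame(id = "1", time = 0, outcome = 0.5),
    character(), c("intercept", "time"))
  surv <- bigjoint:::new_survival_data(
    data.frame(id = "1", time = 1, event = 1), character())
  vd <- validate_join(long, surv)
  spec <- model_spec()
  basis <- make_basis01()
  par1 <- joint_parameters(beta = c(0.5, 0), b = matrix(0, 1, 2),
                           D = diag(2), sigma = 1, gamma = numeric(),
                           alpha = 0,
                           baseline = baseline_coefs(0, rep(0, 3)))
  expect_equal(longitudinal_loglik(vd, par1, spec), -0.5 * log(2 * pi))

  # independent density-sum oracle on a 5-record fixture
  fx <- sim_fixture(5, seed = 2)
  tr <- fx$sim$truth
  par <- joint_parameters(beta = tr$beta, b = tr$b, D = tr$D,
                          sigma = tr$sigma, gamma = tr$gamma,
                          alpha = tr$alpha,
                          baseline = baseline_coefs(tr$log_h0,
                                                    rep(0, n_basis(fx$basis) - 1)))
  lg <- fx$vd$longitudinal
  i <- match(lg$id, fx$vd$survival$id)
  mu <- tr$beta[1] + tr$beta[2] * lg$time + tr$b[i, 1] + tr$b[i, 2] * lg$time
  oracle <- sum(-0.5 * log(2 * pi * tr$sigma^2) -
                  (lg$outcome - mu)^2 / (2 * tr$sigma^2))
  expect_equal(longitudinal_loglik(fx$vd, par, model_spec()), oracle,
               tolerance = 1e-12)
  par_bad <- par; par_bad$sigma <- -1
  expect_error(longitudinal_loglik(fx$vd, par_bad, spec),
               class = "bigjoint_domain_error")
})

test_that("survival log-likelihood matches exponential closed forms and the dense-grid oracle", {
  long <- bigjoint:::new_longitudinal_data(
    data.frame(id = "1", time = 0, outcome = 0),
    character(), c("intercept", "time"))
  basis <- make_basis01(1)
  spec <- model_spec()
  mk <- function(event) {
    surv <- bigjoint:::new_survival_data(
      data.frame(id = "1", time = 1, event = event), character())
    validate_join(long, surv)
  }
  par <- joint_parameters(beta = c(0, 0), b = matrix(0, 1, 2),
                          D = diag(2), sigma = 1, gamma = numeric(),
                          alpha = 0,
                          baseline = baseline_coefs(log(2), rep(0, 3)))
  expect_equal(survival_loglik(mk(1), par, spec, basis), log(2) - 2,
               tolerance = 1e-10)
  expect_equal(survival_loglik(mk(0), par, spec, basis), -2,
               tolerance = 1e-10)

  # 10-subject fixture against delta*log h - H with trapezoid H
  fx <- sim_fixture(10, seed = 4)
  tr <- fx$sim$truth
  par10 <- truth_params(fx$sim, fx$basis, n_re = 10)
  sv <- fx$vd$survival
  oracle <- 0
  for (i in seq_len(10)) {
    eta_T <- tr$beta[1] + tr$beta[2] * sv$time[i] + tr$b[i, 1] +
      tr$b[i, 2] * sv$time[i]
    wterm <- tr$gamma * sv$w1[i]
    logh <- tr$log_h0 + wterm + tr$alpha * eta_T
    H <- trapezoid_hazard(function(s)
      exp(tr$log_h0 + wterm + tr$alpha *
            (tr$beta[1] + tr$b[i, 1] + (tr$beta[2] + tr$b[i, 2]) * s)),
      0, sv$time[i])
    oracle <- oracle + sv$event[i] * logh - H
  }
  expect_equal(survival_loglik(fx$vd, par10, model_spec(), fx$basis),
               oracle, tolerance = 1e-6)
})

test_that("log prior combines hand-verifiable normal, inverse-Wishart and inverse-gamma terms", {
  basis <- make_basis01()
  spec <- model_spec()
  pr1 <- prior_spec(normal_sd_fixed = 1)
  mkpar <- function(b) joint_parameters(
    beta = c(0, 0), b = b, D = diag(2), sigma = 1, gamma = 0, alpha = 0,
    baseline = baseline_coefs(0, rep(0, 3)))
  p0 <- mkpar(matrix(0, 0, 2))
  n_fixed <- 2 + 1 + 1 + 1 + 3          # beta, gamma, alpha, intercept, spline
  # independent hand-coded prior formulas
  ldiw <- function(D, df, S) {
    q <- nrow(D)
    df / 2 * log(det(S)) - df * q / 2 * log(2) -
      (sum(lgamma((df + 1 - 1:q) / 2)) + q * (q - 1) / 4 * log(pi)) -
      (df + q + 1) / 2 * log(det(D)) - 0.5 * sum(diag(S %*% solve(D)))
  }
  ldig <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  expected <- n_fixed * (-0.5 * log(2 * pi)) + ldiw(diag(2), 3, diag(2)) +
    ldig(1, 0.01, 0.01)
  expect_equal(log_prior(p0, pr1, spec), expected, tolerance = 1e-12)

  # doubling the prior sd lowers each fixed-effect density at 0 by log 2
  pr2 <- prior_spec(normal_sd_fixed = 2)
  expect_equal(log_prior(p0, pr1, spec) - log_prior(p0, pr2, spec),
               n_fixed * log(2), tolerance = 1e-12)

  # each zero random effect under D = I contributes -(q/2) log(2 pi)
  p2 <- mkpar(matrix(0, 3, 2))
  expect_equal(log_prior(p2, pr1, spec) - log_prior(p0, pr1, spec),
               3 * (-log(2 * pi)), tolerance = 1e-12)

  # out-of-support sigma gives -Inf
  p_bad <- p0; p_bad$sigma <- -0.1
  expect_identical(log_prior(p_bad, pr1, spec), -Inf)
})

test_that("log posterior is the sum of its parts and tracks the likelihood under flat priors", {
  fx <- sim_fixture(50, seed = 6)
  spec <- model_spec()
  pr <- prior_spec()
  par <- truth_params(fx$sim, fx$basis, n_re = 50)
  lp <- log_posterior(fx$vd, par, pr, spec, fx$basis)
  expect_true(is.finite(lp))
  expect_equal(lp, log_prior(par, pr, spec) +
                 longitudinal_loglik(fx$vd, par, spec) +
                 survival_loglik(fx$vd, par, spec, fx$basis))

  # flat-prior limit: posterior differences equal likelihood differences
  pr_flat <- prior_spec(normal_sd_fixed = 1e9)
  par2 <- par; par2$beta <- par$beta + c(0.1, -0.05); par2$alpha <- 0.3
  dpost <- log_posterior(fx$vd, par2, pr_flat, spec, fx$basis) -
    log_posterior(fx$vd, par, pr_flat, spec, fx$basis)
  dlik <- (longitudinal_loglik(fx$vd, par2, spec) +
             survival_loglik(fx$vd, par2, spec, fx$basis)) -
    (longitudinal_loglik(fx$vd, par, spec) +
       survival_loglik(fx$vd, par, spec, fx$basis))
  expect_equal(dpost, dlik, tolerance = 1e-8)
})

test_that("log posterior is invariant to subject relabelling", {
  fx <- sim_fixture(20, seed = 12)
  spec <- model_spec(); pr <- prior_spec()
  par <- truth_params(fx$sim, fx$basis, n_re = 20)
  lp1 <- log_posterior(fx$vd, par, pr, spec, fx$basis)

  # relabel ids so the sort order reverses; permute b rows to match
  old_ids <- fx$vd$survival$id
  new_ids <- setNames(sprintf("z%03d", rev(seq_along(old_ids))), old_ids)
  long <- as.data.frame(fx$vd$longitudinal)
  long$id <- unname(new_ids[long$id])
  surv <- as.data.frame(fx$vd$survival)
  surv$id <- unname(new_ids[surv$id])
  vd2 <- validate_join(
    bigjoint:::new_longitudinal_data(long, character(),
                                     c("intercept", "time")),
    bigjoint:::new_survival_data(surv, "w1"))
  par2 <- par
  par2$b <- par$b[match(vd2$survival$id, unname(new_ids[old_ids])), ]
  lp2 <- log_posterior(vd2, par2, pr, spec, fx$basis)
  expect_equal(lp1, lp2, tolerance = 1e-12)
})

test_that("with alpha = 0 the longitudinal and survival blocks separate", {
  fx <- sim_fixture(20, seed = 12)
  spec <- model_spec(); pr <- prior_spec()
  par <- truth_params(fx$sim, fx$basis, n_re = 20)
  par$alpha <- 0
  base_long <- longitudinal_loglik(fx$vd, par, spec)
  par_g <- par; par_g$gamma <- par$gamma + 0.3
  par_g$baseline$intercept <- par$baseline$intercept - 0.2
  expect_identical(longitudinal_loglik(fx$vd, par_g, spec), base_long)
  base_surv <- survival_loglik(fx$vd, par, spec, fx$basis)
  par_b <- par; par_b$beta <- par$beta + 0.2; par_b$sigma <- 0.5
  expect_equal(survival_loglik(fx$vd, par_b, spec, fx$basis), base_surv)
})

test_that("posterior differences in one subject's b match the conjugate normal conditional", {
  fx <- sim_fixture(20, seed = 12)
  spec <- model_spec(); basis <- fx$basis
  pr <- prior_spec()
  par <- truth_params(fx$sim, basis, n_re = 20)
  par$alpha <- 0                          # decouples b from the hazard
  lg <- as.data.frame(fx$vd$longitudinal)
  id1 <- fx$vd$survival$id[1]
  r <- lg[lg$id == id1, ]
  X <- cbind(1, r$time); Z <- X
  post <- conjugate_b_posterior(r$outcome, X, Z, par$beta, par$sigma,
                                par$D)
  lpost_at <- function(bv) {
    p <- par; p$b[1, ] <- bv
    log_posterior(fx$vd, p, pr, spec, basis)
  }
  ldens <- function(bv) {
    d <- bv - post$mean
    -0.5 * drop(t(d) %*% solve(post$cov) %*% d)
  }
  b_try <- list(c(0, 0), c(0.3, -0.1), c(-0.5, 0.2))
  lp <- vapply(b_try, lpost_at, numeric(1))
  ld <- vapply(b_try, ldens, numeric(1))
  expect_equal(lp - lp[1], ld - ld[1], tolerance = 1e-8)
})
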