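basis01 <- function(tmax = 3) spline_basis(numeric(), c(0, tmax))

# population parameters with no association and a unit-free hazard
null_params <- function(log_h0 = log(2), D = diag(c(0.4, 0.04)),
                        sigma = 0.3, beta = c(0.5, 0.3), tmax = 3) {
  joint_parameters(beta = beta, b = matrix(0, 0, 2), D = D, sigma = sigma,
                   gamma = numeric(), alpha = 0,
                   baseline = baseline_coefs(log_h0, rep(0, 3)))
}

test_that("with no history and no association the b posterior is the prior", {
  par <- null_params()
  h <- subject_history("x", data.frame(time = numeric(),
                                       outcome = numeric()),
                       w = numeric(), landmark = 0)
  B <- posterior_b_given_history(h, par, model_spec(), basis01(),
                                 n_draws = 4000, seed = 3)
  for (j in 1:2)
    expect_lt(abs(mean(B[, j])), 3 * sqrt(par$D[j, j] / 4000) *
                sqrt(50))   # allow for MCMC autocorrelation
  expect_lt(abs(sd(B[, 1]) / sqrt(par$D[1, 1]) - 1), 0.2)
})

test_that("the b sampler reproduces the closed-form Gaussian conditional", {
  par <- null_params()
  rec <- data.frame(time = c(0, 0.5, 1, 1.5),
                    outcome = c(0.9, 1.3, 1.1, 1.6))
  h <- subject_history("x", rec, w = numeric(), landmark = 1.5)
  B <- posterior_b_given_history(h, par, model_spec(), basis01(),
                                 n_draws = 5000, seed = 4)
  X <- cbind(1, rec$time)
  post <- conjugate_b_posterior(rec$outcome, X, X, par$beta, par$sigma,
                                par$D)
  expect_lt(max(abs(colMeans(B) - post$mean)), 0.05)
  expect_lt(max(abs(apply(B, 2, sd) / sqrt(diag(post$cov)) - 1)), 0.10)

  B2 <- posterior_b_given_history(h, par, model_spec(), basis01(),
                                  n_draws = 5000, seed = 4)
  expect_identical(B, B2)
  expect_error(posterior_b_given_history(h, par, model_spec(), basis01(),
                                         n_draws = 50),
               class = "bigjoint_config_error")
})

test_that("conditional survival is exact in the constant-hazard limit and 1 at the landmark", {
  par <- null_params(log_h0 = log(2))
  h <- subject_history("x", data.frame(time = 0, outcome = 0.6),
                       w = numeric(), landmark = 0.5)
  pred <- predict_survival(h, par, model_spec(), basis01(10),
                           horizon_grid = c(0.5, 1.0, 1.5),
                           n_draws = 300, seed = 5)
  expect_identical(pred$survival$mean[1], 1)
  # alpha = 0: hazard is exactly 2 regardless of b
  expect_equal(pred$survival$mean[2], exp(-1), tolerance = 1e-6)
  expect_equal(pred$survival$mean[3], exp(-2), tolerance = 1e-6)
  expect_error(predict_survival(h, par, model_spec(), basis01(),
                                horizon_grid = c(0.2, 1)),
               class = "bigjoint_order_error")
})

test_that("per-draw survival matches a dense-grid oracle with association", {
  fx <- sim_fixture(30, seed = 7)
  par <- truth_params(fx$sim, fx$basis)
  id_long <- fx$vd$survival$id[which(fx$vd$survival$time > 2)][1]
  h <- subject_history_from_data(fx$vd, id_long, 0.6)
  grid <- c(0.6, 1.2, 2.0)
  B <- posterior_b_given_history(h, par, model_spec(), fx$basis,
                                 n_draws = 200, seed = 6)
  S <- bigjoint:::conditional_survival_draws(h, par, model_spec(),
                                             fx$basis, grid, B)
  expect_equal(S[1, ], rep(1, 200))
  # oracle: dense trapezoid integral of the hazard for 20 draws
  w1 <- h$w[["w1"]]
  for (d in seq_len(20)) {
    haz <- function(s) exp(par$baseline$intercept + par$gamma * w1 +
                             par$alpha * (par$beta[1] + B[d, 1] +
                                            (par$beta[2] + B[d, 2]) * s))
    for (g in 2:3)
      expect_equal(S[g, d],
                   exp(-trapezoid_hazard(haz, 0.6, grid[g], npts = 2e4)),
                   tolerance = 1e-4)
  }
  # survival means are non-increasing along the horizon
  expect_true(all(diff(rowMeans(S)) <= 0))
})

test_that("chained landmarks telescope with shared draws", {
  fx <- sim_fixture(30, seed = 7)
  par <- truth_params(fx$sim, fx$basis)
  id_long <- fx$vd$survival$id[order(fx$vd$survival$time, decreasing = TRUE)][2]
  h <- subject_history_from_data(fx$vd, id_long, 0.4)
  B <- posterior_b_given_history(h, par, model_spec(), fx$basis,
                                 n_draws = 100, seed = 2)
  s <- 0.4; s2 <- 1.0; u <- 1.8
  S_direct <- bigjoint:::conditional_survival_draws(
    h, par, model_spec(), fx$basis, c(s2, u), B)
  # S(u|s) = S(s2|s) * exp(-H(s2, u)) with the same b
  h2 <- h; h2$landmark <- s2
  S_tail <- bigjoint:::conditional_survival_draws(
    h2, par, model_spec(), fx$basis, u, B)
  expect_equal(S_direct[2, ], S_direct[1, ] * S_tail[1, ],
               tolerance = 1e-8)
})

test_that("survival means stay monotone across a cohort", {
  fx <- sim_fixture(50, seed = 15)
  par <- truth_params(fx$sim, fx$basis)
  grid <- seq(0, 2.5, by = 0.5)
  risk <- cohort_risk_matrix(fx$vd, par, model_spec(), fx$basis, grid,
                             n_draws = 150, seed = 3)
  expect_true(all(risk$S >= 0 & risk$S <= 1))
  expect_true(all(apply(risk$S, 1, function(s) all(diff(s) <= 1e-9))))
})

test_that("trajectory prediction collapses to the fixed curve for degenerate effects and widens with extrapolation", {
  par_d <- joint_parameters(beta = c(0.5, 0.3), b = matrix(0, 0, 2),
                            D = diag(c(1e-10, 1e-10)), sigma = 0.3,
                            gamma = numeric(), alpha = 0,
                            baseline = baseline_coefs(0, rep(0, 3)))
  h <- subject_history("x", data.frame(time = 0, outcome = 0.4),
                       w = numeric(), landmark = 0.2)
  grid <- c(0, 0.5, 1, 2)
  tr <- predict_trajectory(h, par_d, model_spec(), basis01(), grid,
                           n_draws = 200, seed = 1)
  expect_equal(tr$mean, 0.5 + 0.3 * grid, tolerance = 1e-3)

  # with real effects the band beyond the data is at least as wide
  fx <- sim_fixture(30, seed = 7)
  par <- truth_params(fx$sim, fx$basis)
  id_long <- fx$vd$survival$id[which(fx$vd$survival$time > 2)][1]
  h2 <- subject_history_from_data(fx$vd, id_long, 0.6)
  tr2 <- predict_trajectory(h2, par, model_spec(), fx$basis,
                            c(0.5, 2.5), n_draws = 1000, seed = 2)
  w05 <- tr2$upper[1] - tr2$lower[1]
  w25 <- tr2$upper[2] - tr2$lower[2]
  expect_gte(w25, w05)
})

test_that("trajectory bands cover the true subject curves at observed times", {
  fx <- sim_fixture(60, seed = 31)
  par <- truth_params(fx$sim, fx$basis)
  sv <- fx$vd$survival
  covered <- 0L; total <- 0L
  ids <- head(sv$id[sv$time > 1], 30)
  for (id in ids) {
    i <- match(id, fx$sim$truth$ids)
    h <- subject_history_from_data(fx$vd, id, 1)
    tt <- h$records$time
    if (!length(tt)) next
    tr <- predict_trajectory(h, par, model_spec(), fx$basis, tt,
                             n_draws = 400,
                             seed = bigjoint:::derive_seed(9, i))
    eta_true <- fx$sim$truth$beta[1] + fx$sim$truth$beta[2] * tt +
      fx$sim$truth$b[i, 1] + fx$sim$truth$b[i, 2] * tt
    covered <- covered + sum(tr$lower <= eta_true & eta_true <= tr$upper)
    total <- total + length(tt)
  }
  expect_gte(covered / total, 0.85)
})

test_that("history extraction validates landmarks and prediction files are tidy", {
  fx <- sim_fixture(30, seed = 7)
  i1 <- which(fx$vd$survival$time > 1)[1]
  id <- fx$vd$survival$id[i1]
  Tobs <- fx$vd$survival$time[i1]
  err <- expect_error(subject_history_from_data(fx$vd, id, Tobs + 1),
                      class = "bigjoint_value_error")
  expect_match(conditionMessage(err), id)

  par <- truth_params(fx$sim, fx$basis)
  h <- subject_history_from_data(fx$vd, id, 0.3)
  pred <- predict_survival(h, par, model_spec(), fx$basis,
                           c(0.3, 1, 2), n_draws = 150, seed = 1)
  tr <- predict_trajectory(h, par, model_spec(), fx$basis, c(0, 1, 2),
                           n_draws = 150, seed = 1)
  p <- tempfile(fileext = ".csv")
  write_prediction(pred, p, tr)
  out <- read.csv(p)
  expect_setequal(unique(out$kind), c("survival", "trajectory"))
  expect_true(all(out$lower <= out$upper))
})
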