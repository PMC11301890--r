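# Shared fixtures, built in code at test time.

write_temp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

# tiny three-subject dataset with fully controlled values
tiny_dataset <- function() {
  long <- bigjoint:::new_longitudinal_data(
    data.frame(id = c("1", "1", "2", "2", "3"),
               time = c(0, 0.5, 0, 1, 0),
               outcome = c(1.0, 1.2, 0.8, 1.5, 0.4),
               stringsAsFactors = FALSE),
    character(), c("intercept", "time"))
  surv <- bigjoint:::new_survival_data(
    data.frame(id = c("1", "2", "3"), time = c(1, 2, 1.5),
               event = c(1, 0, 1), stringsAsFactors = FALSE),
    character())
  validate_join(long, surv)
}

# simulated fixture with the generator's default ground truth, cached per
# (n, seed) so multiple test files can share it
.sim_cache <- new.env(parent = emptyenv())
sim_fixture <- function(n = 200, seed = 1) {
  key <- paste0(n, "_", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_joint_dataset(sim_config(n, seed = seed))
    vd <- validate_join(sim$longitudinal, sim$survival)
    basis <- place_knots(vd$survival$time[vd$survival$event == 1], 2,
                         max_time = max(vd$survival$time))
    .sim_cache[[key]] <- list(sim = sim, vd = vd, basis = basis)
  }
  .sim_cache[[key]]
}

# ground-truth joint_parameters for a simulation (constant log baseline
# hazard represented exactly by intercept-only spline coefficients)
truth_params <- function(sim, basis, n_re = NULL) {
  tr <- sim$truth
  b <- if (is.null(n_re)) matrix(0, 0, 2) else tr$b[seq_len(n_re), , drop = FALSE]
  joint_parameters(beta = tr$beta, b = b, D = tr$D, sigma = tr$sigma,
                   gamma = tr$gamma, alpha = tr$alpha,
                   baseline = baseline_coefs(tr$log_h0,
                                             rep(0, n_basis(basis) - 1L)))
}

# independent dense-trapezoid cumulative hazard oracle
trapezoid_hazard <- function(f, t0, t1, npts = 1e5) {
  s <- seq(t0, t1, length.out = npts)
  h <- f(s)
  sum((h[-1] + h[-npts]) / 2 * diff(s))
}

# independently coded Cox-de Boor recursion (test oracle)
cox_de_boor <- function(t, knots, i, d) {
  if (d == 0) {
    # right-closed at the final interval so the last basis reaches 1
    hi <- knots[i + 1]
    if ((t >= knots[i] && t < hi) ||
        (t == hi && hi == knots[length(knots)])) 1 else 0
  } else {
    a <- 0
    if (knots[i + d] > knots[i])
      a <- (t - knots[i]) / (knots[i + d] - knots[i]) *
        cox_de_boor(t, knots, i, d - 1)
    b <- 0
    if (knots[i + d + 1] > knots[i + 1])
      b <- b + (knots[i + d + 1] - t) /
        (knots[i + d + 1] - knots[i + 1]) *
        cox_de_boor(t, knots, i + 1, d - 1)
    a + b
  }
}

oracle_bspline <- function(t, basis) {
  d <- basis$degree
  knots <- c(rep(basis$boundary[1], d + 1), basis$interior_knots,
             rep(basis$boundary[2], d + 1))
  nb <- length(knots) - d - 1
  vapply(seq_len(nb), function(i) cox_de_boor(t, knots, i, d), numeric(1))
}

# closed-form Gaussian posterior of b for the conjugate (alpha = 0) case:
# b | y ~ N(V Z' (y - X beta) / sigma^2, V), V = (Z'Z/sigma^2 + D^-1)^-1
conjugate_b_posterior <- function(y, X, Z, beta, sigma, D) {
  V <- solve(crossprod(Z) / sigma^2 + solve(D))
  m <- drop(V %*% crossprod(Z, y - X %*% beta)) / sigma^2
  list(mean = m, cov = V)
}
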