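#' Place interior knots for the baseline-hazard B-spline
#'
#' Interior knots sit at the q/(Q+1) quantiles (q = 1..Q, type-7 rule) of
#' the observed *event* times; boundary knots at 0 and the maximum observed
#' time.  Degree 3 (cubic) by default.
#'
#' @param event_times Observed times of subjects with an event
#'   (\eqn{\delta = 1}); for `Q = 0` any positive times.
#' @param Q Number of interior knots (>= 0).
#' @param max_time Upper boundary knot; defaults to `max(event_times)`.
#'   Pass the overall maximum observed (event or censoring) time when
#'   available.
#' @param degree Spline degree, default 3.
#' @return A `spline_basis` object.
#' @export
place_knots <- function(event_times, Q, max_time = max(event_times),
                        degree = 3L) {
  if (Q < 0) stop_bigjoint("Q must be >= 0", "bigjoint_config_error")
  if (length(unique(event_times)) < Q + 2)
    stop_bigjoint("too few distinct event times for the requested knots",
                  "bigjoint_degenerate_error")
  interior <- if (Q > 0)
    as.numeric(quantile(event_times, probs = seq_len(Q) / (Q + 1),
                        type = 7, names = FALSE))
  else numeric(0)
  new_spline_basis(interior, c(0, max_time), degree)
}

#' Construct a B-spline basis from explicit knots
#'
#' @param interior_knots Strictly increasing interior knots (may be
#'   empty).
#' @param boundary Length-2 increasing boundary.
#' @param degree Spline degree (default 3).
#' @return A `spline_basis` object.
#' @export
spline_basis <- function(interior_knots, boundary, degree = 3L) {
  new_spline_basis(interior_knots, boundary, degree)
}

new_spline_basis <- function(interior_knots, boundary, degree = 3L) {
  if (boundary[1L] >= boundary[2L])
    stop_bigjoint("boundary knots must be increasing",
                  "bigjoint_config_error")
  if (length(interior_knots) &&
      (is.unsorted(interior_knots, strictly = TRUE) ||
       any(interior_knots <= boundary[1L]) ||
       any(interior_knots >= boundary[2L])))
    stop_bigjoint("interior knots must be strictly increasing inside the boundary",
                  "bigjoint_config_error")
  structure(list(interior_knots = as.numeric(interior_knots),
                 boundary = as.numeric(boundary),
                 degree = as.integer(degree)),
            class = "spline_basis")
}

#' Number of B-spline basis functions of a basis
#' @param basis A `spline_basis`.
#' @return Q + degree + 1.
#' @export
n_basis <- function(basis) {
  length(basis$interior_knots) + basis$degree + 1L
}

#' Evaluate the clamped B-spline basis
#'
#' Returns all `Q + degree + 1` basis values at each time, computed by the
#' Cox--de Boor recursion on the clamped (boundary-repeated) knot vector.
#' Times outside the boundary are clamped to it, so the basis (and hence
#' the log baseline hazard) is constant beyond the last knot — this keeps
#' dynamic-prediction horizons beyond the data range well behaved.
#'
#' @param t Numeric vector of evaluation times (>= 0).
#' @param basis A `spline_basis`.
#' @return A `length(t) x n_basis(basis)` matrix of nonnegative values,
#'   each row summing to 1.
#' @export
bspline_basis <- function(t, basis) {
  stopifnot(inherits(basis, "spline_basis"))
  b0 <- basis$boundary[1L]; b1 <- basis$boundary[2L]
  tt <- pmin(pmax(t, b0), b1)
  knots <- c(rep(b0, basis$degree + 1L), basis$interior_knots,
             rep(b1, basis$degree + 1L))
  splines::splineDesign(knots, tt, ord = basis$degree + 1L,
                        outer.ok = FALSE)
}

#' Baseline-hazard coefficient container
#'
#' The log baseline hazard is
#' \eqn{\log h_0(t) = \gamma_0^0 + \sum_q \gamma_0^q B_q(t)}.  Because the
#' clamped basis satisfies partition of unity, a free intercept plus the
#' full basis is rank-deficient; the first basis function is dropped for
#' identifiability, leaving `n_basis(basis) - 1` free spline coefficients
#' alongside the intercept.
#'
#' @param intercept Scalar \eqn{\gamma_0^0}.
#' @param spline_coefs Numeric vector of length `n_basis(basis) - 1`.
#' @return A `baseline_coefs` object.
#' @export
baseline_coefs <- function(intercept, spline_coefs) {
  stopifnot(is.finite(intercept), all(is.finite(spline_coefs)))
  structure(list(intercept = intercept,
                 spline_coefs = as.numeric(spline_coefs)),
            class = "baseline_coefs")
}

#' Log baseline hazard at given times
#'
#' @param t Numeric vector of times (>= 0).
#' @param coefs A [baseline_coefs()].
#' @param basis A `spline_basis`.
#' @return Numeric vector \eqn{\log h_0(t)}.
#' @export
log_baseline_hazard <- function(t, coefs, basis) {
  B <- bspline_basis(t, basis)
  if (length(coefs$spline_coefs) != ncol(B) - 1L)
    stop_bigjoint("spline coefficient length does not match the basis",
                  "bigjoint_shape_error")
  drop(coefs$intercept + B[, -1L, drop = FALSE] %*% coefs$spline_coefs)
}

#' Cumulative hazard over an interval by Gauss--Legendre quadrature
#'
#' Integrates \eqn{\exp(\log h_0(s) + w + \alpha \eta(s))} over
#' `[t0, t1]` with a fixed-node Gauss--Legendre rule (15 nodes by
#' default, the standard choice in joint-model software).
#'
#' @param linear_predictor_fn Function of time returning \eqn{\eta(s)}
#'   (vectorized).
#' @param w_term Scalar covariate contribution \eqn{\gamma' w_i}.
#' @param alpha Association parameter.
#' @param coefs A [baseline_coefs()].
#' @param basis A `spline_basis`.
#' @param t0,t1 Interval limits, `0 <= t0 <= t1`.
#' @param nodes Number of quadrature nodes.
#' @return The nonnegative cumulative hazard; 0 when `t0 == t1`.
#' @export
cumulative_hazard <- function(linear_predictor_fn, w_term, alpha, coefs,
                              basis, t0, t1, nodes = 15L) {
  if (t1 < t0)
    stop_bigjoint("t1 must not precede t0", "bigjoint_order_error")
  if (t1 == t0) return(0)
  gl <- gauss_legendre_rule(nodes)
  s <- (t1 - t0) / 2 * gl$x + (t1 + t0) / 2
  w <- (t1 - t0) / 2 * gl$w
  sum(w * exp(log_baseline_hazard(s, coefs, basis) + w_term +
                alpha * linear_predictor_fn(s)))
}

#' Kaplan--Meier estimator of the survival function
#'
#' Product-limit estimate from right-censored data, evaluated
#' right-continuously (the product runs over event times \eqn{t_i \le t}).
#'
#' @param times Positive observed times.
#' @param events 0/1 event indicators (1 = event).
#' @return A `survival_curve`: list with `times` (distinct event times),
#'   `survival` (non-increasing, starting from 1 at time 0), and `n_risk`,
#'   `n_event` at each time.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0)
    stop_bigjoint("empty survival input", "bigjoint_empty_error")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep]),
            class = "survival_curve")
}

#' Evaluate a survival curve as a right-continuous step function
#'
#' @param curve A `survival_curve`.
#' @param t Query times.
#' @param left If `TRUE`, evaluate the left limit \eqn{S(t^-)} instead
#'   (used for inverse-censoring weights at event times).
#' @return Survival probabilities at `t`.
#' @export
eval_survival_curve <- function(curve, t, left = FALSE) {
  stopifnot(inherits(curve, "survival_curve"))
  tms <- curve$times; sv <- curve$survival
  idx <- if (left) findInterval(t, tms, left.open = TRUE)
  else findInterval(t, tms)
  c(1, sv)[idx + 1L]
}

#' Write a survival curve to a two-column CSV
#' @param curve A `survival_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survival_curve <- function(curve, path) {
  write.csv(data.frame(time = curve$times, survival = curve$survival),
            path, row.names = FALSE)
  invisible(path)
}
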