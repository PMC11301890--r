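#' Partition subject ids into fitting chunks
#'
#' Ids are shuffled under `seed` and sliced into consecutive chunks of
#' `chunk_size`; a final chunk smaller than `max(min_chunk, chunk_size/2)`
#' is merged into its predecessor.  Chunks are disjoint partitions, not
#' bootstrap subsamples.
#'
#' @param ids Subject identifiers.
#' @param chunk_size Target subjects per chunk (>= `min_chunk`).
#' @param seed Shuffle seed.
#' @param min_chunk Minimum viable chunk size floor (default 20).
#' @return A `chunk_partition`: list of disjoint id vectors whose union is
#'   `ids`.
#' @export
split_subjects <- function(ids, chunk_size, seed, min_chunk = 20L) {
  if (chunk_size < min_chunk)
    stop_bigjoint(sprintf("chunk_size %d below the minimum viable chunk (%d)",
                          chunk_size, min_chunk), "bigjoint_config_error")
  n <- length(ids)
  set.seed(seed)
  shuffled <- ids[sample.int(n)]
  K <- ceiling(n / chunk_size)
  chunks <- split(shuffled, rep(seq_len(K), each = chunk_size,
                                length.out = n))
  if (K > 1 && length(chunks[[K]]) < max(min_chunk, chunk_size / 2)) {
    chunks[[K - 1L]] <- c(chunks[[K - 1L]], chunks[[K]])
    chunks[[K]] <- NULL
  }
  structure(unname(chunks), chunk_size = chunk_size, seed = seed,
            class = "chunk_partition")
}

#' Pool chunk fits by mean and combined standard error
#'
#' Pooled mean is the simple average of the chunk posterior means; pooled
#' variance is \eqn{K^{-2}\sum_k s_k^2} (independent-chunk combination),
#' which reproduces full-data \eqn{1/\sqrt{n}} scaling when chunks are
#' independent.
#'
#' @param chunks List of `chunk_fit` objects (from [fit_big()] internals
#'   or built via [chunk_fit()]).
#' @return A `pooled_fit` data frame: `parameter`, `mean`, `se`, with
#'   pooling metadata in attributes.
#' @export
pool_mean_se <- function(chunks) {
  pars <- check_chunks(chunks)
  K <- length(chunks)
  M <- vapply(chunks, function(ch) ch$summary$mean, numeric(length(pars)))
  S <- vapply(chunks, function(ch) ch$summary$sd, numeric(length(pars)))
  M <- matrix(M, ncol = K); S <- matrix(S, ncol = K)
  new_pooled_fit(pars, rowMeans(M), sqrt(rowSums(S^2)) / K,
                 K, chunks, "mean_se")
}

#' Pool chunk fits by precision weighting
#'
#' With \eqn{H_k} the inverse of chunk `k`'s posterior covariance of the
#' scalar parameters: pooled \eqn{\theta = (\sum_k H_k)^{-1}\sum_k H_k
#' m_k}; pooled covariance \eqn{(\sum_k H_k)^{-1}}.  This mirrors
#' information-matrix updating across groups.  A singular chunk covariance
#' is an error (no silent regularization).
#'
#' @param chunks List of `chunk_fit` objects, each carrying a `cov`
#'   matrix.
#' @return A `pooled_fit` data frame (also carries the pooled covariance
#'   as attribute `cov`).
#' @export
pool_precision_weighted <- function(chunks) {
  pars <- check_chunks(chunks)
  p <- length(pars)
  Hsum <- matrix(0, p, p)
  Hm <- numeric(p)
  for (kk in seq_along(chunks)) {
    ch <- chunks[[kk]]
    if (is.null(ch$cov))
      stop_bigjoint(sprintf("chunk %d carries no parameter covariance", kk),
                    "bigjoint_pooling_error")
    H <- tryCatch(solve(ch$cov), error = function(e) NULL)
    if (is.null(H))
      stop_bigjoint(sprintf("singular parameter covariance in chunk %d", kk),
                    "bigjoint_pooling_error")
    Hsum <- Hsum + H
    Hm <- Hm + drop(H %*% ch$summary$mean)
  }
  Vpool <- solve(Hsum)
  theta <- drop(Vpool %*% Hm)
  out <- new_pooled_fit(pars, theta, sqrt(diag(Vpool)),
                        length(chunks), chunks, "precision_weighted")
  attr(out, "cov") <- Vpool
  out
}

#' Bundle one chunk's results for pooling
#'
#' @param index Chunk index.
#' @param summary A `fit_summary`.
#' @param cov Optional posterior covariance matrix of the scalar
#'   parameters (required for [pool_precision_weighted()]).
#' @param draws Optional `posterior_draws` reference.
#' @return A `chunk_fit` object.
#' @export
chunk_fit <- function(index, summary, cov = NULL, draws = NULL) {
  structure(list(index = index, summary = summary, cov = cov,
                 draws = draws), class = "chunk_fit")
}

check_chunks <- function(chunks) {
  if (length(chunks) < 1L)
    stop_bigjoint("need at least one chunk", "bigjoint_pooling_error")
  pars <- chunks[[1L]]$summary$parameter
  for (ch in chunks[-1L])
    if (!identical(ch$summary$parameter, pars))
      stop_bigjoint(paste0("chunk parameter lists differ: ",
                           paste(symdiff_chr(pars, ch$summary$parameter),
                                 collapse = ", ")),
                    "bigjoint_pooling_error")
  pars
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

new_pooled_fit <- function(pars, mean, se, K, chunks, method) {
  structure(data.frame(parameter = pars, mean = mean, se = se,
                       row.names = NULL, stringsAsFactors = FALSE),
            K = K, pooling_method = method,
            chunk_summaries = lapply(chunks, `[[`, "summary"),
            class = c("pooled_fit", "data.frame"))
}

#' Fit a joint model to a large cohort by divide and conquer
#'
#' Validates the two tables, places the baseline-hazard spline knots once
#' on the *full* event-time set (so the baseline coefficients are
#' commensurable across chunks), partitions subjects, fits each chunk by
#' [fit_mcmc()] with a chunk-derived seed, and pools the chunk summaries.
#' A chunk that happens to contain no events is merged with the next chunk
#' before fitting.
#'
#' @param long A `longitudinal_data`.
#' @param surv A `survival_data`.
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()] (its seed is ignored; chunk seeds are
#'   `seed + chunk index`).
#' @param chunk_size Subjects per chunk.
#' @param pooling_method `"mean_se"` (default) or `"precision_weighted"`.
#' @param seed Master seed for the shuffle and the chunk fits.
#' @param Q Interior knots of the baseline-hazard spline (default 2).
#' @param min_chunk Minimum viable chunk size (default 20).
#' @param drop_post_event Passed to [validate_join()].
#' @param verbose Log one line per chunk.
#' @return A `pooled_fit` with per-chunk summaries, the shared basis and
#'   the partition attached as attributes.
#' @export
fit_big <- function(long, surv, spec = model_spec(),
                    priors = prior_spec(), mcmc = mcmc_config(),
                    chunk_size, pooling_method = c("mean_se",
                                                   "precision_weighted"),
                    seed = 1L, Q = 2L, min_chunk = 20L,
                    drop_post_event = TRUE, verbose = FALSE) {
  pooling_method <- match.arg(pooling_method)
  vd <- validate_join(long, surv, drop_post_event = drop_post_event)
  ev_times <- vd$survival$time[vd$survival$event == 1]
  basis <- place_knots(ev_times, Q, max_time = max(vd$survival$time))
  part <- split_subjects(vd$survival$id, chunk_size,
                         seed = derive_seed(seed, 0L),
                         min_chunk = min_chunk)

  # merge event-free chunks forward before fitting
  groups <- list(); pending <- character()
  for (ids_k in part) {
    ids_k <- c(pending, ids_k); pending <- character()
    ev <- sum(vd$survival$event[vd$survival$id %in% ids_k])
    if (ev == 0) pending <- ids_k else groups[[length(groups) + 1L]] <- ids_k
  }
  if (length(pending)) {
    if (!length(groups))
      stop_bigjoint("no events in any chunk; cannot fit the survival submodel",
                    "bigjoint_init_error")
    groups[[length(groups)]] <- c(groups[[length(groups)]], pending)
  }

  chunks <- vector("list", length(groups))
  for (kk in seq_along(groups)) {
    sub <- subset_subjects(vd, groups[[kk]])
    mc <- mcmc
    mc$seed <- as.integer(seed + kk)
    dr <- fit_mcmc(sub, spec, priors, basis, mc)
    sm <- summarize_draws(dr)
    if (verbose)
      message(sprintf("chunk %d: n=%d events=%d accept(b)=%.2f",
                      kk, sub$n_subjects, sum(sub$survival$event),
                      dr$acceptance[["b"]]))
    chunks[[kk]] <- chunk_fit(kk, sm, cov = cov(dr$draws))
  }
  pooled <- if (pooling_method == "mean_se") pool_mean_se(chunks)
  else pool_precision_weighted(chunks)
  attr(pooled, "basis") <- basis
  attr(pooled, "spec") <- spec
  attr(pooled, "partition") <- groups
  attr(pooled, "chunk_size") <- chunk_size
  attr(pooled, "seed") <- seed
  attr(pooled, "n_subjects") <- vd$n_subjects
  pooled
}

#' Reconstruct point-value joint parameters from a fit
#'
#' Maps the named scalar parameters of a `pooled_fit` or `fit_summary`
#' (posterior means) back into a [joint_parameters()] container with zero
#' random effects, for use in dynamic prediction.
#'
#' @param fit A `pooled_fit` or `fit_summary`.
#' @param spec A [model_spec()].
#' @param basis The `spline_basis` used in fitting.
#' @return A [joint_parameters()] object (with `b` a 0-row matrix).
#' @export
params_from_fit <- function(fit, spec, basis) {
  est <- setNames(fit$mean, fit$parameter)
  q <- length(spec$random_design)
  beta <- unname(est[paste0("beta_", spec$fixed_design)])
  gnames <- grep("^gamma_[^0]", names(est), value = TRUE)
  gamma <- unname(est[gnames])
  nb <- n_basis(basis) - 1L
  D <- matrix(0, q, q)
  idx <- which(lower.tri(D, diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- est[[sprintf("D_%d_%d", idx[r, 1], idx[r, 2])]]
    D[idx[r, 1], idx[r, 2]] <- v
    D[idx[r, 2], idx[r, 1]] <- v
  }
  joint_parameters(
    beta = beta, b = matrix(0, 0, q), D = D,
    sigma = est[["sigma"]], gamma = gamma, alpha = est[["alpha"]],
    baseline = baseline_coefs(est[["gamma0_0"]],
                              unname(est[paste0("gamma0_",
                                                seq_len(nb))])))
}

#' Write a pooled fit (and its chunk summaries) to CSV plus YAML metadata
#'
#' @param fit A `pooled_fit`.
#' @param csv_path Pooled estimates destination.
#' @param yaml_path Metadata destination.
#' @param chunk_csv_path Optional destination for the per-chunk summaries
#'   (long format with a `chunk` column).
#' @return Invisibly, the paths written.
#' @export
write_pooled_fit <- function(fit, csv_path, yaml_path,
                             chunk_csv_path = NULL) {
  stopifnot(inherits(fit, "pooled_fit"))
  write.csv(as.data.frame(fit), csv_path, row.names = FALSE)
  yaml::write_yaml(list(K = attr(fit, "K"),
                        chunk_size = attr(fit, "chunk_size"),
                        pooling_method = attr(fit, "pooling_method"),
                        seed = attr(fit, "seed"),
                        n_subjects = attr(fit, "n_subjects")), yaml_path)
  paths <- c(csv_path, yaml_path)
  if (!is.null(chunk_csv_path)) {
    sm <- attr(fit, "chunk_summaries")
    tall <- do.call(rbind, lapply(seq_along(sm), function(kk)
      cbind(chunk = kk, as.data.frame(sm[[kk]]))))
    write.csv(tall, chunk_csv_path, row.names = FALSE)
    paths <- c(paths, chunk_csv_path)
  }
  invisible(paths)
}
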