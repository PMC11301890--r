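# Internal helpers shared across modules.

# Cached Gauss-Legendre rules keyed by node count.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

# Deterministic sub-seed derivation: keeps derived seeds in 32-bit range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000003 + offset) %% 2147483647L)
}

stop_bigjoint <- function(msg, class) {
  stop(structure(class = c(class, "bigjoint_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Multivariate normal draws via Cholesky (deterministic given the RNG state).
rmvnorm_chol <- function(n, mean, sigma) {
  q <- length(mean)
  L <- chol(sigma)
  z <- matrix(rnorm(n * q), n, q)
  sweep(z %*% L, 2L, mean, `+`)
}

# log density of N(x; 0, sigma) for rows of a matrix
dmvnorm0_log <- function(x, sigma) {
  q <- ncol(x)
  L <- chol(sigma)
  half <- backsolve(L, t(x), transpose = TRUE)   # q x n
  quad <- colSums(half^2)
  -0.5 * q * log(2 * pi) - sum(log(diag(L))) - 0.5 * quad
}

# log density of multivariate Student-t with location 0, scale matrix sigma
dmvt0_log <- function(x, sigma, df) {
  q <- ncol(x)
  L <- chol(sigma)
  half <- backsolve(L, t(x), transpose = TRUE)
  quad <- colSums(half^2)
  lgamma((df + q) / 2) - lgamma(df / 2) - 0.5 * q * log(df * pi) -
    sum(log(diag(L))) - 0.5 * (df + q) * log1p(quad / df)
}

# Inverse-Wishart draw: if X ~ Wishart(df, solve(scale)) then solve(X) ~ IW(df, scale)
riwish1 <- function(df, scale) {
  W <- rWishart(1L, df, solve(scale))[, , 1L]
  solve(W)
}
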