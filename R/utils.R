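#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a list of string
# labels (e.g. region id + trait name). Polynomial string hash mod 2^31 - 1,
# so adding a trait or region never perturbs the streams of existing ones.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), as.character, character(1))
  h <- as.double(seed %% 2147483647L)
  for (s in parts) {
    for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Factor F with t(F) %*% F = R, for multivariate-normal sampling. Cholesky
# when R is positive definite; eigenvalue-clipped factor otherwise.
ld_factor <- function(R) {
  F <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(F)) {
    ee <- eigen(R, symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    F <- sqrt(ev) * t(ee$vectors)
    message("LD matrix not positive definite; sampling with eigenvalue-clipped factor")
  }
  F
}

# n draws from Normal(mu, R). `factor` may carry a precomputed ld_factor(R).
rmvn_ld <- function(n, mu, R, factor = NULL) {
  if (is.null(factor)) factor <- ld_factor(R)
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p) %*% factor
  sweep(z, 2, mu, "+")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
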