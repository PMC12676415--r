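#' Construct a synthetic LD (correlation) matrix
#'
#' Builds the local linkage-disequilibrium correlation matrix used by the
#' fine-mapping, imputation and TWAS stages. Three structures are supported:
#' first-order autoregressive (`R[i,j] = rho^|i-j|`, the usual stand-in for
#' decaying LD along a chromosome), block-diagonal (within-block correlation
#' `rho`, zero across blocks), and identity.
#'
#' @param p Number of variants (>= 1).
#' @param structure One of `"ar1"`, `"block"`, `"identity"`.
#' @param rho Pairwise correlation in `[0, 1)`. Ignored for `"identity"`.
#' @param n_blocks Number of equally sized blocks for `structure = "block"`.
#' @param variant_ids Optional character vector of variant identifiers used as
#'   dimnames; defaults to `v0001 ...`.
#' @return A `p x p` symmetric positive semi-definite matrix with unit
#'   diagonal and variant ids as dimnames.
#' @examples
#' make_ld(3, "ar1", rho = 0.5)
#' @export
make_ld <- function(p, structure = c("ar1", "block", "identity"), rho = 0,
                    n_blocks = 4, variant_ids = NULL) {
  structure <- match.arg(structure)
  if (p < 1) stop("p must be >= 1")
  if (structure != "identity" && (rho < 0 || rho >= 1)) {
    stop("rho must lie in [0, 1)")
  }
  R <- switch(structure,
    identity = diag(p),
    ar1 = rho^abs(outer(seq_len(p), seq_len(p), "-")),
    block = {
      blk <- rep(seq_len(n_blocks), length.out = p)
      blk <- sort(blk)
      M <- (outer(blk, blk, "==")) * rho
      diag(M) <- 1
      M
    }
  )
  if (is.null(variant_ids)) {
    variant_ids <- sprintf("v%04d", seq_len(p))
  }
  dimnames(R) <- list(variant_ids, variant_ids)
  R
}

#' Validate an LD matrix
#'
#' Checks symmetry, unit diagonal and positive semi-definiteness up to a
#' tolerance of `-1e-8` on the smallest eigenvalue.
#'
#' @param R Matrix to validate.
#' @return `R`, invisibly; stops on violation.
#' @export
validate_ld <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("LD matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD matrix is not positive semi-definite (min eigenvalue ",
                            format(min(ev)), ")")
  invisible(R)
}
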