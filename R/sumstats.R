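#' Construct a summary-statistics table
#'
#' One trait's per-variant GWAS or molecular-QTL association table. The
#' pipeline consumes z-scores plus the local LD matrix; `beta` and `se` are
#' kept for schema fidelity with the convention `se = 1/sqrt(n)` and
#' `beta = z * se`, so that `beta/se == z` holds exactly.
#'
#' @param trait Trait name.
#' @param variant_id Character vector of unique variant identifiers.
#' @param z Numeric z-score vector.
#' @param n Per-variant sample size (scalar or vector).
#' @param chrom,pos Chromosome and 1-based position.
#' @param ref,alt Reference / alternate alleles.
#' @param maf Minor allele frequency in `[0, 0.5]`.
#' @param beta,se Effect size per alt allele and its standard error; derived
#'   from `z` and `n` when omitted.
#' @return A `data.frame` with columns `trait, variant_id, chrom, pos, ref,
#'   alt, beta, se, z, maf, n`.
#' @export
sumstats <- function(trait, variant_id, z, n = 10000,
                     chrom = 1L, pos = seq_along(variant_id),
                     ref = "A", alt = "G", maf = 0.25,
                     beta = NULL, se = NULL) {
  p <- length(variant_id)
  se <- if (is.null(se)) 1 / sqrt(rep_len(n, p)) else rep_len(se, p)
  beta <- if (is.null(beta)) z * se else rep_len(beta, p)
  ss <- data.frame(
    trait = trait, variant_id = as.character(variant_id),
    chrom = rep_len(chrom, p), pos = rep_len(pos, p),
    ref = rep_len(ref, p), alt = rep_len(alt, p),
    beta = beta, se = se, z = z,
    maf = rep_len(maf, p), n = rep_len(n, p),
    stringsAsFactors = FALSE
  )
  validate_sumstats(ss)
}

#' Validate a summary-statistics table
#'
#' Enforces unique variant ids, `maf` in `[0, 0.5]`, positive `se` and the
#' identity `|z - beta/se| <= 1e-6` wherever both are present.
#'
#' @param ss A summary-statistics `data.frame`.
#' @return `ss` invisibly-validated (returned visibly for piping).
#' @export
validate_sumstats <- function(ss) {
  need <- c("trait", "variant_id", "beta", "se", "z", "maf", "n")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop("sumstats missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$variant_id)) stop("duplicate variant_ids in sumstats")
  if (any(ss$maf < 0 | ss$maf > 0.5, na.rm = TRUE)) stop("maf must lie in [0, 0.5]")
  if (any(ss$se <= 0, na.rm = TRUE)) stop("se must be positive")
  ok <- is.finite(ss$z) & is.finite(ss$beta) & is.finite(ss$se)
  if (any(abs(ss$z[ok] - ss$beta[ok] / ss$se[ok]) > 1e-6)) {
    stop("z and beta/se disagree beyond 1e-6")
  }
  ss
}

#' Read / write the tab-separated summary-statistics dialect
#'
#' Columns: `variant_id, chrom, pos, ref, alt, beta, se, z, maf, n` plus a
#' leading `trait` column, with header, tab-separated.
#'
#' @param path File path.
#' @param ss Table to write.
#' @return `read_sumstats` returns the validated `data.frame`.
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(variant_id = "character"))
  validate_sumstats(ss)
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dense LD matrix with a variant-index sidecar
#'
#' The matrix file is whitespace-delimited with no header; the sidecar
#' (`<path>.vars`) lists one variant id per line in matrix order.
#'
#' @param R LD matrix with variant ids as dimnames.
#' @param path Matrix file path.
#' @return `read_ld` returns the matrix with dimnames restored.
#' @export
write_ld <- function(R, path) {
  utils::write.table(R, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(R), paste0(path, ".vars"))
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  R <- as.matrix(utils::read.table(path, sep = "\t"))
  ids <- readLines(paste0(path, ".vars"))
  dimnames(R) <- list(ids, ids)
  validate_ld(R)
  R
}
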