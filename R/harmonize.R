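# Summary-statistics QC and harmonization against the LD reference: allele
# alignment (with strand flips for unambiguous pairs), variant filters,
# z/LD-consistency outlier removal, and LD-based imputation of missing or
# removed z-scores.

STRAND_COMP <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Align allele orientation to an LD reference panel
#'
#' Variants whose `(ref, alt)` are swapped relative to the reference have `z`
#' and `beta` negated and alleles swapped; unambiguous pairs are additionally
#' reconciled by strand complement (flip, and flip-plus-swap with negation).
#' Variants with missing alleles or alleles that cannot be reconciled are
#' dropped with reason `allele_mismatch`. Idempotent on its own output.
#'
#' @param ss Summary-statistics table.
#' @param reference `data.frame` with columns `variant_id`, `ref`, `alt`
#'   giving the panel orientation.
#' @return The aligned table, with dropped variant ids in
#'   `attr(, "dropped")`.
#' @export
align_alleles <- function(ss, reference) {
  m <- match(ss$variant_id, reference$variant_id)
  r_ref <- reference$ref[m]
  r_alt <- reference$alt[m]
  a1 <- toupper(ss$ref); a2 <- toupper(ss$alt)
  valid <- !is.na(m) & !is.na(a1) & !is.na(a2) &
    a1 %in% names(STRAND_COMP) & a2 %in% names(STRAND_COMP) &
    !is.na(r_ref) & !is.na(r_alt)
  f1 <- unname(STRAND_COMP[a1]); f2 <- unname(STRAND_COMP[a2])
  ambig <- is_ambiguous_pair(a1, a2)

  keep_same <- valid & a1 == r_ref & a2 == r_alt
  keep_swap <- valid & a1 == r_alt & a2 == r_ref & !keep_same
  # strand flips only for unambiguous pairs (flip of A/T or C/G is degenerate)
  keep_flip <- valid & !ambig & !keep_same & !keep_swap &
    f1 == r_ref & f2 == r_alt
  keep_flipswap <- valid & !ambig & !keep_same & !keep_swap & !keep_flip &
    f1 == r_alt & f2 == r_ref
  keep <- keep_same | keep_swap | keep_flip | keep_flipswap
  flip_sign <- keep_swap | keep_flipswap

  out <- ss[keep, , drop = FALSE]
  fs <- flip_sign[keep]
  out$z[fs] <- -out$z[fs]
  out$beta[fs] <- -out$beta[fs]
  out$ref <- r_ref[keep]
  out$alt <- r_alt[keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- ss$variant_id[!keep]
  out
}

#' Variant quality-control filter
#'
#' Drops strand-ambiguous variants (A/T or C/G), variants with MAF strictly
#' below `maf_min`, missingness strictly above `miss_max` (an absent
#' `missingness` column is treated as 0), and duplicated variant ids (all
#' copies after the first). Retained records are never altered.
#'
#' @param ss Summary-statistics table.
#' @param maf_min MAF lower bound (default 0.0025; strict inequality).
#' @param miss_max Missingness upper bound (default 0.01).
#' @return `list(sumstats =, report =)` where `report` is a named count
#'   vector over reasons `ambiguous, maf, missingness, duplicate`.
#' @export
qc_filter <- function(ss, maf_min = 0.0025, miss_max = 0.01) {
  missingness <- if ("missingness" %in% names(ss)) ss$missingness else 0
  drop_amb <- is_ambiguous_pair(toupper(ss$ref), toupper(ss$alt))
  drop_maf <- !drop_amb & ss$maf < maf_min
  drop_miss <- !drop_amb & !drop_maf & missingness > miss_max
  drop_dup <- !drop_amb & !drop_maf & !drop_miss & duplicated(ss$variant_id)
  keep <- !(drop_amb | drop_maf | drop_miss | drop_dup)
  report <- c(ambiguous = sum(drop_amb), maf = sum(drop_maf),
              missingness = sum(drop_miss), duplicate = sum(drop_dup))
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- ss$variant_id[!keep]
  list(sumstats = out, report = report)
}

#' Detect variants with z-scores inconsistent with the LD structure
#'
#' For each variant the leave-one-out conditional expectation
#' `E[z_i | z_-i]` and variance under `z ~ Normal(0, R)` are computed from
#' the precision matrix of `R + ridge * I` (whose conditioning blocks equal
#' the ridge-regularized leave-one-out blocks exactly); variants whose
#' standardized conditional residual exceeds `t_max` are flagged.
#'
#' @param z z-score vector.
#' @param R LD matrix over the same index.
#' @param t_max Outlier threshold on the standardized residual (default 4).
#' @param ridge Ridge added to the diagonal before inversion.
#' @param v_floor Floor on the conditional variance.
#' @return Integer vector of flagged indices (empty when `length(z) < 3`).
#' @export
detect_ld_outliers <- function(z, R, t_max = 4.0, ridge = 1e-6,
                               v_floor = 1e-4) {
  p <- length(z)
  if (p < 3) return(integer(0))
  stopifnot(nrow(R) == p)
  Om <- solve(R + diag(ridge, p))
  d <- diag(Om)
  resid <- as.vector(Om %*% z) / d        # z_i - E[z_i | z_-i]
  v <- pmax(1 / d, v_floor)
  which(abs(resid) / sqrt(v) > t_max)
}

#' Impute missing z-scores from LD
#'
#' Reconstructs missing z-scores from observed ones and the LD matrix:
#' `zhat_m = R[m, obs] %*% pinv(R[obs, obs]) %*% z_obs`, with imputation
#' quality `q_m = R[m, obs] %*% pinv(R[obs, obs]) %*% R[obs, m]`. The
#' pseudoinverse truncates singular values below `rcond` times the largest.
#' A variant is retained as imputed only if `q > quality_min` and it has at
#' least `min_neighbors` observed variants with `|r| >= r_floor`.
#'
#' @param z_obs Observed z-scores (length of `obs_idx`).
#' @param R LD matrix over the full variant index.
#' @param obs_idx Indices of observed variants within `R`.
#' @param rcond Relative condition-number cutoff for the pseudoinverse
#'   (default 0.01).
#' @param quality_min Minimum imputation quality (default 0.6).
#' @param min_neighbors Minimum count of informative observed neighbors
#'   (default 5).
#' @param r_floor `|r|` threshold defining an informative neighbor
#'   (default 0.2).
#' @return `list(z = full-length vector with accepted imputations filled
#'   (others `NA` at missing positions), quality = full-length quality
#'   vector, imputed = indices accepted)`.
#' @export
impute_z <- function(z_obs, R, obs_idx, rcond = 0.01, quality_min = 0.6,
                     min_neighbors = 5, r_floor = 0.2) {
  p <- nrow(R)
  if (!length(obs_idx)) stop("obs_idx must be nonempty")
  miss_idx <- setdiff(seq_len(p), obs_idx)
  z <- rep(NA_real_, p)
  z[obs_idx] <- z_obs
  quality <- rep(NA_real_, p)
  quality[obs_idx] <- 1
  if (!length(miss_idx)) {
    return(list(z = z, quality = quality, imputed = integer(0)))
  }
  Roo <- R[obs_idx, obs_idx, drop = FALSE]
  Rmo <- R[miss_idx, obs_idx, drop = FALSE]
  Pinv <- MASS::ginv(Roo, tol = rcond)
  W <- Rmo %*% Pinv
  zhat <- as.vector(W %*% z_obs)
  q <- rowSums(W * Rmo)
  neighbors <- rowSums(abs(Rmo) >= r_floor)
  ok <- q > quality_min & neighbors >= min_neighbors
  z[miss_idx[ok]] <- zhat[ok]
  quality[miss_idx] <- q
  list(z = z, quality = quality, imputed = miss_idx[ok])
}

#' Harmonize one trait's summary statistics against an LD reference
#'
#' Runs the full QC chain once, in order: allele alignment, variant filters,
#' z/LD-consistency outlier removal, then LD-based imputation of all variants
#' in the reference index that lack a usable z-score (dropped or absent).
#'
#' @param ss Summary-statistics table.
#' @param ld LD matrix whose dimnames define the reference variant index.
#' @param reference Optional allele reference table (`variant_id, ref, alt`);
#'   when `NULL`, alignment is skipped (alleles assumed panel-oriented).
#' @param maf_min,miss_max,t_max,rcond,quality_min,min_neighbors,r_floor
#'   Stage thresholds, see [qc_filter()], [detect_ld_outliers()],
#'   [impute_z()].
#' @return `list(z = named z vector over the LD index (`NA` where
#'   unrecoverable), sumstats = retained records, report = QC report)` where
#'   `report` has `counts` (named drop counts, incl. `allele_mismatch` and
#'   `ld_outlier`) and `imputed` (`data.frame(variant_id, quality)`).
#' @export
harmonize_sumstats <- function(ss, ld, reference = NULL,
                               maf_min = 0.0025, miss_max = 0.01,
                               t_max = 4.0, rcond = 0.01, quality_min = 0.6,
                               min_neighbors = 5, r_floor = 0.2) {
  ref_ids <- colnames(ld)
  n_in <- nrow(ss)
  counts <- c(allele_mismatch = 0L, ambiguous = 0L, maf = 0L,
              missingness = 0L, duplicate = 0L, ld_outlier = 0L)
  if (!is.null(reference)) {
    ss <- align_alleles(ss, reference)
    counts["allele_mismatch"] <- length(attr(ss, "dropped"))
  }
  qc <- qc_filter(ss, maf_min = maf_min, miss_max = miss_max)
  counts[names(qc$report)] <- counts[names(qc$report)] + qc$report
  ss <- qc$sumstats
  # restrict to the LD index ("not shared with the LD reference removed")
  shared <- ss$variant_id %in% ref_ids
  counts["allele_mismatch"] <- counts["allele_mismatch"] + sum(!shared)
  ss <- ss[shared, , drop = FALSE]

  idx <- match(ss$variant_id, ref_ids)
  z_full <- rep(NA_real_, length(ref_ids))
  z_full[idx] <- ss$z
  obs <- which(!is.na(z_full))
  out_rel <- detect_ld_outliers(z_full[obs], ld[obs, obs, drop = FALSE],
                                t_max = t_max)
  counts["ld_outlier"] <- length(out_rel)
  if (length(out_rel)) {
    drop_ids <- ref_ids[obs[out_rel]]
    ss <- ss[!ss$variant_id %in% drop_ids, , drop = FALSE]
    obs <- obs[-out_rel]
  }
  imp <- if (length(obs) < length(ref_ids) && length(obs) > 0) {
    impute_z(z_full[obs], ld, obs, rcond = rcond, quality_min = quality_min,
             min_neighbors = min_neighbors, r_floor = r_floor)
  } else {
    list(z = z_full, quality = ifelse(is.na(z_full), NA_real_, 1),
         imputed = integer(0))
  }
  z <- stats::setNames(imp$z, ref_ids)
  report <- list(
    counts = counts,
    n_input = n_in, n_retained = nrow(ss), n_imputed = length(imp$imputed),
    imputed = data.frame(variant_id = ref_ids[imp$imputed],
                         quality = imp$quality[imp$imputed],
                         stringsAsFactors = FALSE)
  )
  list(z = z, sumstats = ss, report = report)
}
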