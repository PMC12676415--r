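# Weight-based transcriptome-wide association: burden z-score
# z_twas = (w' z) / sqrt(w' R w) of a gene's predicted molecular level
# against a trait, with the model-retention and significance rules applied
# downstream of externally trained (or synthetically emulated) weights.

#' TWAS burden association for one weight model
#'
#' Aligns the weight vector, z-scores and LD on their common variant index
#' (variants present in the summary statistics but absent from the weights
#' contribute zero weight; weight variants absent from the harmonized
#' summary statistics are dropped) and computes
#' `z_twas = (w' z) / sqrt(w' R w)` with `p = 2 * pnorm(-|z_twas|)`.
#' Results with `w' R w < v_floor` are marked unstable and not retained.
#'
#' @param weights `data.frame` with columns `variant_id, weight` (plus
#'   `gene_id, context, cv_r2, cv_p` carried through if present).
#' @param ss Harmonized summary statistics (or any table with `variant_id`,
#'   `z`).
#' @param R LD matrix over the summary-statistics index.
#' @param trait Trait label for the output row.
#' @param v_floor Degeneracy guard on `w' R w` (default 1e-8).
#' @return A one-row `data.frame` (`gene_id, context, trait, model_tag,
#'   cv_r2, z_twas, p_twas, retained`), or `NULL` when the weight/variant
#'   intersection is empty.
#' @export
twas_assoc <- function(weights, ss, R, trait = NA_character_,
                       v_floor = 1e-8) {
  common <- intersect(weights$variant_id, ss$variant_id)
  if (!length(common)) {
    message("twas_assoc: empty weight/variant intersection for gene ",
            weights$gene_id[1] %||% "?")
    return(NULL)
  }
  w <- weights$weight[match(common, weights$variant_id)]
  z <- ss$z[match(common, ss$variant_id)]
  ii <- match(common, colnames(R))
  Rww <- as.numeric(t(w) %*% R[ii, ii, drop = FALSE] %*% w)
  unstable <- Rww < v_floor
  z_twas <- if (unstable) NA_real_ else sum(w * z) / sqrt(Rww)
  data.frame(
    gene_id = weights$gene_id[1] %||% NA_character_,
    context = weights$context[1] %||% NA_character_,
    trait = trait,
    model_tag = weights$model_tag[1] %||% "weights",
    cv_r2 = weights$cv_r2[1] %||% NA_real_,
    cv_p = weights$cv_p[1] %||% NA_real_,
    z_twas = z_twas,
    p_twas = if (unstable) NA_real_ else 2 * stats::pnorm(-abs(z_twas)),
    retained = !unstable,
    stringsAsFactors = FALSE)
}

#' Filter weight models and select the best per gene and context
#'
#' Retains robust models (`cv_r2 > r2_min` and `cv_p < cv_p_max`, both
#' strict) and flags, per gene x context, the best-performing model
#' (highest `cv_r2`) among those retained.
#'
#' @param models `data.frame` with one row per model and columns `gene_id,
#'   context, cv_r2, cv_p` (e.g. unique model rows of a long weight table).
#' @param r2_min Cross-validation R^2 floor (default 0.01).
#' @param cv_p_max Cross-validation p-value ceiling (default 0.05).
#' @return `models` with logical columns `retained` and `best` added.
#' @export
filter_models <- function(models, r2_min = 0.01, cv_p_max = 0.05) {
  models$retained <- models$cv_r2 > r2_min & models$cv_p < cv_p_max
  models$best <- FALSE
  key <- paste(models$gene_id, models$context, sep = "\r")
  for (k in unique(key[models$retained])) {
    sel <- which(key == k & models$retained)
    models$best[sel[which.max(models$cv_r2[sel])]] <- TRUE
  }
  models
}

#' Apply the TWAS significance rules
#'
#' A result is significant if its p-value passes (1) the fixed global
#' threshold (`p < alpha_fixed`, default 2.5e-6), and/or (2) Bonferroni
#' correction at 0.05 over `m` retained tests. `mode = "either"` (default)
#' applies both rules and flags a result significant when either passes.
#'
#' @param results TWAS results table with `p_twas` and `retained` columns.
#' @param mode `"fixed"`, `"bonferroni"`, or `"either"`.
#' @param alpha_fixed Fixed threshold (default 2.5e-6).
#' @param m Bonferroni family size; defaults to the number of retained tests
#'   within each trait in `results`.
#' @return `results` with a logical `significant` column (always `FALSE`
#'   where not retained).
#' @export
twas_significance <- function(results, mode = c("either", "fixed", "bonferroni"),
                              alpha_fixed = 2.5e-6, m = NULL) {
  mode <- match.arg(mode)
  results$significant <- FALSE
  if (!any(results$retained)) {
    warning("no retained TWAS tests; significance not assigned")
    return(results)
  }
  sig_fixed <- results$retained & !is.na(results$p_twas) &
    results$p_twas < alpha_fixed
  m_trait <- if (is.null(m)) {
    stats::ave(as.numeric(results$retained), results$trait, FUN = sum)
  } else rep(m, nrow(results))
  sig_bonf <- results$retained & !is.na(results$p_twas) & m_trait > 0 &
    results$p_twas < 0.05 / pmax(m_trait, 1)
  results$significant <- switch(mode,
    fixed = sig_fixed,
    bonferroni = sig_bonf,
    either = sig_fixed | sig_bonf)
  results
}
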