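# Credible-set Mendelian randomization: per credible set, PIP-weighted Wald
# ratios of outcome effects to standardized exposure effects; gene-level
# effects by fixed-effect inverse-variance-weighted meta-analysis across
# credible sets, with Cochran's Q / I^2 heterogeneity and the significance
# gate (>= 1 credible set, cPIP > 0.9, p < 0.05, I^2 < 0.5).

#' Select MR instruments from a fine-mapping fit
#'
#' Instruments are the highest-coverage credible sets whose cumulative
#' posterior inclusion probability (cPIP) exceeds `cpip_min`.
#'
#' @param fm A `susie_fit` for the exposure (molecular trait).
#' @param cpip_min cPIP gate (default 0.5, strict).
#' @return List of credible sets (possibly empty).
#' @export
select_instruments <- function(fm, cpip_min = 0.5) {
  css <- Filter(function(cs) cs$coverage == max(fm$coverages),
                fm$credible_sets)
  Filter(function(cs) cs$cPIP > cpip_min, css)
}

#' Credible-set level causal-effect estimate
#'
#' Per member variant `v`: the exposure effect is standardized by its
#' standard error, `b*_v = beta_exp,v / se_exp,v = z_exp,v`; the Wald ratio
#' is `theta_v = beta_out,v / b*_v` with first-order standard error
#' `se_out,v / |b*_v|`. Ratios are combined with normalized PIP weights
#' `a_v = PIP_v / sum(PIP)`: `theta_cs = sum(a_v theta_v)` and, by default,
#' `se_cs = sqrt(sum(a_v^2 se_v^2))` (within-set ratios treated as
#' independent given the set; `se_mode = "conservative"` uses
#' `sum(a_v se_v)` instead). Variants with `|b*_v| < z_floor` are excluded
#' as weak instruments; the estimate is therefore per SD of the genetically
#' predicted exposure.
#'
#' @param cs A credible set (from [credible_sets()]), with member `variants`
#'   and a fit-level PIP available via `pip`.
#' @param pip Named PIP vector for the exposure fit.
#' @param exposure,outcome Harmonized summary-statistics tables covering the
#'   set's variants (members absent from either are dropped).
#' @param z_floor Weak-instrument guard on `|z_exp|` (default 2).
#' @param se_mode `"independent"` (default) or `"conservative"`.
#' @return A one-row `data.frame` (`cs_id, theta, se_theta, cPIP,
#'   n_variants`), or `NULL` when no usable variant remains.
#' @export
cs_ratio_estimate <- function(cs, pip, exposure, outcome, z_floor = 2,
                              se_mode = c("independent", "conservative")) {
  se_mode <- match.arg(se_mode)
  vs <- intersect(intersect(cs$variants, exposure$variant_id),
                  outcome$variant_id)
  if (!length(vs)) return(NULL)
  ie <- match(vs, exposure$variant_id)
  io <- match(vs, outcome$variant_id)
  bstar <- exposure$beta[ie] / exposure$se[ie]
  strong <- abs(bstar) >= z_floor
  if (!all(strong)) {
    message("cs_ratio_estimate: ", sum(!strong),
            " weak instrument variant(s) excluded (|z| < ", z_floor, ")")
  }
  if (!any(strong)) return(NULL)
  vs <- vs[strong]; ie <- ie[strong]; io <- io[strong]
  bstar <- bstar[strong]
  theta_v <- outcome$beta[io] / bstar
  se_v <- outcome$se[io] / abs(bstar)
  a <- pip[vs] / sum(pip[vs])
  theta <- sum(a * theta_v)
  se <- if (se_mode == "independent") sqrt(sum(a^2 * se_v^2)) else
    sum(a * se_v)
  data.frame(cs_id = cs$cs_id, theta = theta, se_theta = se,
             cPIP = cs$cPIP, n_variants = length(vs),
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted meta-analysis across credible sets
#'
#' Pools credible-set estimates with weights `w_k = 1/se_k^2`:
#' `theta_meta = sum(w_k theta_k) / sum(w_k)`,
#' `se_meta = 1/sqrt(sum(w_k))`, `p = 2 Phi(-|theta/se|)`; heterogeneity by
#' Cochran's `Q = sum(w_k (theta_k - theta_meta)^2)` and
#' `I^2 = max(0, (Q - (k-1))/Q)` (0 when `Q = 0` or a single set).
#'
#' @param estimates `data.frame` of credible-set estimates (rows from
#'   [cs_ratio_estimate()]).
#' @param gene_id,context,trait Labels carried into the result.
#' @return An object of class `mr_result` (one-row `data.frame` with
#'   `theta_meta, se_meta, p_meta, Q, I2, n_cs, max_cPIP`), or `NULL` for
#'   empty input.
#' @export
ivw_meta <- function(estimates, gene_id = NA_character_,
                     context = NA_character_, trait = NA_character_) {
  if (is.null(estimates) || nrow(estimates) == 0) return(NULL)
  w <- 1 / estimates$se_theta^2
  theta <- sum(w * estimates$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (estimates$theta - theta)^2)
  k <- nrow(estimates)
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  out <- data.frame(
    gene_id = gene_id, context = context, trait = trait,
    theta_meta = theta, se_meta = se,
    p_meta = 2 * stats::pnorm(-abs(theta / se)),
    Q = Q, I2 = I2, n_cs = k, max_cPIP = max(estimates$cPIP),
    stringsAsFactors = FALSE)
  class(out) <- c("mr_result", class(out))
  out
}

#' Apply the MR significance gate
#'
#' Significant iff at least one credible set is present, `max_cPIP >
#' cpip_min`, `p_meta < p_max`, and `I2 < i2_max`.
#'
#' @param result An `mr_result` (or rows of several).
#' @param p_max Meta-analytic p-value ceiling (default 0.05).
#' @param cpip_min cPIP gate (default 0.9, strict).
#' @param i2_max Heterogeneity ceiling (default 0.5).
#' @return `result` with a logical `significant` column.
#' @export
mr_significance <- function(result, p_max = 0.05, cpip_min = 0.9,
                            i2_max = 0.5) {
  result$significant <- result$n_cs >= 1 & result$max_cPIP > cpip_min &
    result$p_meta < p_max & result$I2 < i2_max
  result
}

#' Gene-level credible-set MR from a fine-mapping fit
#'
#' Convenience wrapper chaining [select_instruments()],
#' [cs_ratio_estimate()] per instrument, [ivw_meta()] and
#' [mr_significance()].
#'
#' @inheritParams cs_ratio_estimate
#' @inheritParams mr_significance
#' @param fm Exposure `susie_fit`.
#' @param gene_id,context,trait Labels.
#' @param cpip_instrument Instrument cPIP gate (default 0.5).
#' @return An `mr_result` with `significant`, or `NULL` when no instrument
#'   yields an estimate.
#' @export
mr_gene <- function(fm, exposure, outcome, gene_id = NA_character_,
                    context = NA_character_, trait = NA_character_,
                    cpip_instrument = 0.5, z_floor = 2,
                    se_mode = "independent", p_max = 0.05,
                    cpip_min = 0.9, i2_max = 0.5) {
  inst <- select_instruments(fm, cpip_min = cpip_instrument)
  if (!length(inst)) return(NULL)
  est <- do.call(rbind, lapply(inst, cs_ratio_estimate, pip = fm$pip,
                               exposure = exposure, outcome = outcome,
                               z_floor = z_floor, se_mode = se_mode))
  res <- ivw_meta(est, gene_id = gene_id, context = context, trait = trait)
  if (is.null(res)) return(NULL)
  mr_significance(res, p_max = p_max, cpip_min = cpip_min, i2_max = i2_max)
}

#' @export
print.mr_result <- function(x, ...) {
  cat("Credible-set MR (fixed-effect IVW across credible sets)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
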