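# Shared fixtures: all built in code at test time.

# a minimal susie_fit-shaped object for unit-testing downstream consumers
fake_fit <- function(alpha, V = rep(1, nrow(alpha)), variant_ids = NULL,
                     coverages = c(0.95, 0.70, 0.50), cs = list(),
                     pip = NULL, trait = "t", region_id = "r") {
  p <- ncol(alpha)
  variant_ids <- variant_ids %||% sprintf("v%04d", seq_len(p))
  keep <- V > 0
  if (is.null(pip)) {
    pip <- if (any(keep)) {
      1 - apply(1 - alpha[keep, , drop = FALSE], 2, prod)
    } else rep(0, p)
  }
  structure(list(alpha = alpha, mu = alpha, V = V,
                 pip = stats::setNames(pip, variant_ids),
                 variant_ids = variant_ids, coverages = coverages,
                 credible_sets = cs, skipped = FALSE, trait = trait,
                 region_id = region_id), class = "susie_fit")
}

fake_cs <- function(variants, cs_id = "E1_C95", effect = 1L,
                    coverage = 0.95, alpha = NULL, cPIP = NULL) {
  list(cs_id = cs_id, effect = effect, coverage = coverage,
       variants = variants,
       alpha = alpha %||% rep(1 / length(variants), length(variants)),
       cumulative_alpha = sum(alpha %||% rep(1 / length(variants),
                                             length(variants))),
       purity = 1, cPIP = cPIP %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds for test replicates
tseed <- function(...) genetier:::derive_seed(20260922L, ...)
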