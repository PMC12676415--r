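# Evidence integration: colocalization-by-xQTL intersection at the variant
# level, putative-causal-gene selection in multi-gene loci, and the 3-tier
# grading of candidate genes across imaging-endophenotype (DNE) traits and
# disease endpoints.

# union of 95/70/50% credible-set members plus non-member variants with
# PIP >= pip_floor, per fine-mapping fit
candidate_xqtl_variants <- function(fm, pip_floor = 0.25) {
  cs_vars <- unique(unlist(lapply(fm$credible_sets, `[[`, "variants")))
  union(cs_vars, names(fm$pip)[fm$pip >= pip_floor])
}

#' Colocalization-prioritized gene flags
#'
#' Intersects colocalized variants (CoS members) with candidate fine-mapped
#' xQTL variants per molecular context: a gene is coloc-prioritized for a
#' GWAS trait when any CoS variant of a trait set containing that trait lies
#' among the gene's candidate xQTL variants in some context. Candidate xQTL
#' variants per context are the union of credible-set members at all
#' coverage levels plus non-member variants with PIP at or above
#' `pip_floor`.
#'
#' @param coloc_results List of `coloc_result` objects (external or CLPP).
#' @param xqtl_fits Nested named list `context -> region_id -> susie_fit`
#'   of xQTL fine-mapping results.
#' @param ann Annotation list with `gene_variants` (named list gene ->
#'   variant ids) and `genes` (`data.frame` with `gene_id`, `region_id`).
#' @param pip_floor PIP threshold for non-credible-set variants
#'   (default 0.25).
#' @param xqtl_traits Trait names that are molecular contexts (excluded from
#'   the GWAS-trait flags; defaults to `names(xqtl_fits)`).
#' @return `data.frame(gene_id, trait, context, variant_id, cos_id)` of
#'   provenance-bearing coloc flags (possibly 0 rows).
#' @export
coloc_xqtl_genes <- function(coloc_results, xqtl_fits, ann,
                             pip_floor = 0.25, xqtl_traits = NULL) {
  xqtl_traits <- xqtl_traits %||% names(xqtl_fits)
  known_genes <- names(ann$gene_variants)
  warned <- FALSE
  rows <- list()
  for (res in coloc_results) {
    gwas_traits <- setdiff(res$trait_set, xqtl_traits)
    cos_vars <- unique(unlist(lapply(res$cos, `[[`, "variants")))
    if (!length(cos_vars) || !length(gwas_traits)) next
    for (cx in names(xqtl_fits)) {
      fits <- xqtl_fits[[cx]]
      fm <- fits[[res$region_id]]
      if (is.null(fm)) next
      cand <- intersect(cos_vars, candidate_xqtl_variants(fm, pip_floor))
      if (!length(cand)) next
      for (g in known_genes) {
        hit <- intersect(cand, ann$gene_variants[[g]])
        if (!length(hit)) next
        for (tr in gwas_traits) {
          cos_id <- res$cos[[1]]$cos_id %||% NA_character_
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, trait = tr, context = cx,
            variant_id = hit, cos_id = cos_id, stringsAsFactors = FALSE)
        }
      }
      orphan <- setdiff(cand, unique(unlist(ann$gene_variants)))
      if (length(orphan) && !warned) {
        message("coloc_xqtl_genes: ", length(orphan),
                " colocalized variant(s) map to no annotated gene")
        warned <- TRUE
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), trait = character(0),
                      context = character(0), variant_id = character(0),
                      cos_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Putative causal gene selection within a region
#'
#' Among genes with eligible TWAS results (retained, significant, robust
#' models) in a region and molecular context, selects the gene containing
#' the top-PIP variant within the widest available credible-set tier
#' (searched 95% then 70% then 50%; PIP ties broken by ascending position);
#' then reports the region's smallest-GWAS-p variant as the putative causal
#' variant and its containing gene as the final target. Returns no selection
#' when no eligible TWAS result exists.
#'
#' @param twas TWAS results table (with `gene_id, context, retained,
#'   significant`) already restricted or restrictable to the region.
#' @param fm The context's `susie_fit` for this region.
#' @param gwas GWAS summary statistics for the region (p-values recomputed
#'   from z where needed).
#' @param ann Annotation list (see [coloc_xqtl_genes()]).
#' @param region_id Region label.
#' @param context Molecular context label.
#' @return One-row `data.frame(region_id, context, selected_gene,
#'   top_pip_variant, causal_variant, causal_gene)` or `NULL`.
#' @export
pcg_select <- function(twas, fm, gwas, ann, region_id,
                       context = NA_character_) {
  elig <- twas[twas$retained & twas$significant &
                 (is.na(twas$context) | twas$context == context), ,
               drop = FALSE]
  elig_genes <- intersect(unique(elig$gene_id),
                          ann$genes$gene_id[ann$genes$region_id == region_id])
  if (!length(elig_genes)) return(NULL)
  gene_of <- function(v) {
    hits <- names(ann$gene_variants)[vapply(ann$gene_variants,
                                            function(gv) v %in% gv,
                                            logical(1))]
    hits <- intersect(hits, ann$genes$gene_id[ann$genes$region_id == region_id])
    if (length(hits)) hits[1] else NA_character_
  }
  selected <- NA_character_; top_variant <- NA_character_
  for (cov in sort(fm$coverages, decreasing = TRUE)) {
    css <- Filter(function(cs) cs$coverage == cov, fm$credible_sets)
    members <- unique(unlist(lapply(css, `[[`, "variants")))
    if (!length(members)) next
    mi <- match(members, fm$variant_ids)
    ord <- members[order(-fm$pip[members], mi)]
    for (v in ord) {
      g <- gene_of(v)
      if (!is.na(g) && g %in% elig_genes) {
        selected <- g; top_variant <- v
        break
      }
    }
    if (!is.na(selected)) break
  }
  if (is.na(selected)) return(NULL)
  pval <- 2 * stats::pnorm(-abs(gwas$z))
  causal_variant <- gwas$variant_id[order(pval, gwas$pos)][1]
  causal_gene <- gene_of(causal_variant)
  data.frame(region_id = region_id, context = context,
             selected_gene = selected, top_pip_variant = top_variant,
             causal_variant = causal_variant,
             causal_gene = if (is.na(causal_gene)) selected else causal_gene,
             stringsAsFactors = FALSE)
}

#' Build a gene-evidence ledger
#'
#' Combines TWAS, colocalization and MR outputs into a per (gene, trait,
#' context) flag table annotated with trait categories.
#'
#' @param twas TWAS results with `significant` flags.
#' @param coloc_flags Output of [coloc_xqtl_genes()].
#' @param mr MR results with `significant` flags (may be `NULL`).
#' @param trait_categories Named character vector trait -> category
#'   (`DNE`, `AD`, `Aging`, `PD`).
#' @return `data.frame(gene_id, trait, category, context, twas_sig,
#'   coloc_sig, mr_sig)` with one row per observed combination.
#' @export
gene_evidence <- function(twas, coloc_flags, mr = NULL, trait_categories) {
  key <- function(d) paste(d$gene_id, d$trait, d$context, sep = "\r")
  all_keys <- unique(c(
    if (nrow(twas)) key(twas[twas$significant, , drop = FALSE]),
    if (nrow(coloc_flags)) key(coloc_flags),
    if (!is.null(mr) && nrow(mr)) key(mr[mr$significant, , drop = FALSE])
  ))
  if (!length(all_keys)) {
    return(data.frame(gene_id = character(0), trait = character(0),
                      category = character(0), context = character(0),
                      twas_sig = logical(0), coloc_sig = logical(0),
                      mr_sig = logical(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(all_keys, "\r"))
  ev <- data.frame(gene_id = parts[, 1], trait = parts[, 2],
                   context = parts[, 3], stringsAsFactors = FALSE)
  ev$category <- unname(trait_categories[ev$trait])
  tk <- if (nrow(twas)) key(twas[twas$significant, , drop = FALSE]) else character(0)
  ck <- if (nrow(coloc_flags)) key(coloc_flags) else character(0)
  mk <- if (!is.null(mr) && nrow(mr)) key(mr[mr$significant, , drop = FALSE]) else character(0)
  ev$twas_sig <- all_keys %in% tk
  ev$coloc_sig <- all_keys %in% ck
  ev$mr_sig <- all_keys %in% mk
  ev
}

#' Assign evidence tiers to genes
#'
#' Grades genes by integrated TWAS and colocalization evidence across DNE
#' traits and disease endpoints: Tier 1 = TWAS and colocalization evidence
#' in DNE and in the endpoint categories; Tier 2 = TWAS and colocalization
#' in DNE but TWAS-only endpoint support; Tier 3 = TWAS or colocalization in
#' DNE with TWAS-only endpoint support. Genes lacking DNE evidence or
#' endpoint evidence are unassigned; each gene receives the best (lowest)
#' tier it satisfies. `endpoint_mode` controls whether the endpoint
#' requirement must hold in all endpoint categories or in at least one
#' (default `"any"`). With `mr_as_endpoint_evidence`, a significant MR
#' result substitutes for endpoint TWAS support.
#'
#' @param evidence Output of [gene_evidence()].
#' @param endpoint_mode `"any"` or `"all"`.
#' @param endpoint_categories Categories treated as endpoints (default AD
#'   and Aging; PD is accepted as a label but excluded by default).
#' @param mr_as_endpoint_evidence Logical (default `FALSE`).
#' @return `data.frame(gene_id, tier, justification)`, `tier` in
#'   `{1, 2, 3, NA}` (NA = unassigned), plus the per-category evidence
#'   columns used.
#' @export
assign_tiers <- function(evidence, endpoint_mode = c("any", "all"),
                         endpoint_categories = c("AD", "Aging"),
                         mr_as_endpoint_evidence = FALSE) {
  endpoint_mode <- match.arg(endpoint_mode)
  genes <- unique(evidence$gene_id)
  out <- lapply(genes, function(g) {
    ev <- evidence[evidence$gene_id == g, , drop = FALSE]
    agg <- function(cat, col) any(ev[[col]][ev$category %in% cat], na.rm = TRUE)
    dne_t <- agg("DNE", "twas_sig")
    dne_c <- agg("DNE", "coloc_sig")
    ep_flags <- lapply(endpoint_categories, function(cat) {
      tw <- agg(cat, "twas_sig")
      if (mr_as_endpoint_evidence) tw <- tw || agg(cat, "mr_sig")
      c(twas = tw, coloc = agg(cat, "coloc_sig"))
    })
    comb <- if (endpoint_mode == "any") {
      c(twas = any(vapply(ep_flags, `[[`, TRUE, "twas")),
        both = any(vapply(ep_flags, function(f) f[["twas"]] && f[["coloc"]],
                          logical(1))))
    } else {
      c(twas = all(vapply(ep_flags, `[[`, TRUE, "twas")),
        both = all(vapply(ep_flags, function(f) f[["twas"]] && f[["coloc"]],
                          logical(1))))
    }
    tier <- NA_integer_
    just <- character(0)
    if (dne_t && dne_c && comb[["both"]]) {
      tier <- 1L; just <- "TWAS+coloc in DNE and endpoints"
    } else if (dne_t && dne_c && comb[["twas"]]) {
      tier <- 2L; just <- "TWAS+coloc in DNE, TWAS-only endpoints"
    } else if ((dne_t || dne_c) && comb[["twas"]]) {
      tier <- 3L; just <- "TWAS or coloc in DNE, TWAS-only endpoints"
    }
    data.frame(gene_id = g, tier = tier,
               dne_twas = dne_t, dne_coloc = dne_c,
               endpoint_twas = comb[["twas"]],
               endpoint_twas_coloc = comb[["both"]],
               justification = if (length(just)) just else "unassigned",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
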