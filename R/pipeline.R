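# End-to-end orchestration: simulate -> harmonize -> fine-map -> coloc ->
# TWAS -> MR -> prioritize -> enrichment, from a single declarative
# configuration with deterministic seeding, stage TSV outputs and scoring
# against the generator's truth tables.

#' Pipeline run configuration
#'
#' Aggregates every stage threshold with its default (MAF 0.0025,
#' missingness 0.01, outlier t 4, imputation rcond 0.01 / quality 0.6 /
#' neighbors 5, L schedule 5/10/5, skip PIP 0.025, coverages 95/70/50%,
#' purity 0.5, CLPP 0.01, candidate PIP floor 0.25, TWAS alpha 2.5e-6, CV
#' R^2 0.01, CV p 0.05, MR cPIP gates 0.5 and 0.9, MR p 0.05, I^2 0.5, FDR
#' 0.1) around a [sim_config()]. Unknown keys are rejected (they do not
#' match a formal argument).
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param out_dir Output directory for stage TSVs (created if needed).
#' @param maf_min,miss_max,t_max,rcond,quality_min,min_neighbors,r_floor
#'   Harmonization thresholds.
#' @param L_init,L_max,L_step,skip_pip,coverages,purity_min Fine-mapping.
#' @param clpp_min,cos_coverage Colocalization.
#' @param pip_floor Candidate-variant PIP floor for coloc/xQTL intersection.
#' @param r2_min,cv_p_max,twas_alpha,twas_mode TWAS retention/significance.
#' @param mr_cpip_instrument,mr_cpip,mr_p,i2_max,mr_z_floor,mr_se_mode MR.
#' @param fdr_max Enrichment FDR threshold.
#' @param endpoint_mode,mr_as_endpoint_evidence Tiering options.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = NULL,
                       maf_min = 0.0025, miss_max = 0.01, t_max = 4.0,
                       rcond = 0.01, quality_min = 0.6, min_neighbors = 5,
                       r_floor = 0.2,
                       L_init = 5, L_max = 10, L_step = 5,
                       skip_pip = 0.025, coverages = c(0.95, 0.70, 0.50),
                       purity_min = 0.5,
                       clpp_min = 0.01, cos_coverage = 0.95,
                       pip_floor = 0.25,
                       r2_min = 0.01, cv_p_max = 0.05,
                       twas_alpha = 2.5e-6, twas_mode = "either",
                       mr_cpip_instrument = 0.5, mr_cpip = 0.9,
                       mr_p = 0.05, i2_max = 0.5, mr_z_floor = 2,
                       mr_se_mode = "independent",
                       fdr_max = 0.1,
                       endpoint_mode = "any",
                       mr_as_endpoint_evidence = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  cfg <- as.list(environment())
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            skip_pip >= 0, skip_pip <= 1,
            all(coverages > 0 & coverages <= 1),
            pip_floor >= 0, pip_floor <= 1,
            twas_alpha > 0, twas_alpha < 1,
            mr_cpip > 0, mr_cpip <= 1, mr_p > 0, mr_p <= 1,
            i2_max >= 0, i2_max <= 1, fdr_max > 0, fdr_max <= 1)
  cfg$endpoint_mode <- match.arg(endpoint_mode, c("any", "all"))
  cfg$twas_mode <- match.arg(twas_mode, c("either", "fixed", "bonferroni"))
  structure(cfg, class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic study
#'
#' Executes the stages in order (simulate, harmonize, fine-map, CLPP
#' colocalization, TWAS, MR, prioritization, enrichment), writes every
#' stage's TSV plus a run report to `out_dir`, and scores the run against
#' the generator's truth tables. Outputs are byte-identical across runs
#' with the same configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, the artifact bundle: all stage objects, the score
#'   table and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir %||% file.path(tempdir(), "genetier_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  sim <- simulate_study(config$sim)
  traits <- config$sim$traits
  regions <- names(sim$ld)
  gwas_traits <- traits$name[traits$role != "xqtl_context"]
  contexts <- traits$name[traits$role == "xqtl_context"]
  trait_categories <- stats::setNames(traits$category, traits$name)

  # ---- harmonize: per trait x region, then restrict each region to the
  # variants harmonized in every trait so all stages share one index
  harm <- list(); qc_rows <- list()
  for (tr in traits$name) {
    harm[[tr]] <- list()
    for (rid in regions) {
      h <- harmonize_sumstats(
        sim$sumstats[[tr]][[rid]], sim$ld[[rid]],
        maf_min = config$maf_min, miss_max = config$miss_max,
        t_max = config$t_max, rcond = config$rcond,
        quality_min = config$quality_min,
        min_neighbors = config$min_neighbors, r_floor = config$r_floor)
      harm[[tr]][[rid]] <- h
      qc_rows[[length(qc_rows) + 1]] <- data.frame(
        trait = tr, region_id = rid, t(h$report$counts),
        n_input = h$report$n_input, n_retained = h$report$n_retained,
        n_imputed = h$report$n_imputed, stringsAsFactors = FALSE)
    }
  }
  common_idx <- list()
  for (rid in regions) {
    ok <- rep(TRUE, ncol(sim$ld[[rid]]))
    for (tr in traits$name) ok <- ok & !is.na(harm[[tr]][[rid]]$z)
    common_idx[[rid]] <- which(ok)
  }
  paths["qc"] <- write_tsv(do.call(rbind, qc_rows),
                           file.path(out_dir, "qc_report.tsv"))

  # ---- fine-map every trait x region on the common index
  fits <- list()
  fm_rows <- list()
  for (tr in traits$name) {
    fits[[tr]] <- list()
    for (rid in regions) {
      ci <- common_idx[[rid]]
      R <- sim$ld[[rid]][ci, ci, drop = FALSE]
      z <- harm[[tr]][[rid]]$z[ci]
      fit <- susie_rss(z, R, L_init = config$L_init, L_max = config$L_max,
                       L_step = config$L_step, skip_pip = config$skip_pip,
                       coverages = config$coverages,
                       purity_min = config$purity_min,
                       trait = tr, region_id = rid)
      fits[[tr]][[rid]] <- fit
      fm_rows[[length(fm_rows) + 1]] <- finemap_table(fit)
    }
  }
  paths["finemap"] <- write_tsv(do.call(rbind, fm_rows),
                                file.path(out_dir, "finemap.tsv"))

  # ---- colocalization: each GWAS trait against each molecular context
  coloc_results <- list()
  for (rid in regions) {
    for (tr in gwas_traits) {
      for (cx in contexts) {
        pair <- list(fits[[tr]][[rid]], fits[[cx]][[rid]])
        names(pair) <- c(tr, cx)
        coloc_results[[length(coloc_results) + 1]] <- clpp_coloc(
          pair, clpp_min = config$clpp_min,
          cos_coverage = config$cos_coverage, region_id = rid)
      }
    }
  }
  paths["coloc"] <- file.path(out_dir, "coloc.tsv")
  write_cos_table(coloc_results, paths["coloc"])

  # ---- TWAS: every retained weight model against every GWAS trait
  wkey <- paste(sim$weights$gene_id, sim$weights$context, sep = "\r")
  models <- sim$weights[!duplicated(wkey),
                        c("gene_id", "context", "region_id", "cv_r2", "cv_p")]
  models <- filter_models(models, r2_min = config$r2_min,
                          cv_p_max = config$cv_p_max)
  twas_rows <- list()
  for (mi in seq_len(nrow(models))) {
    g <- models$gene_id[mi]; cx <- models$context[mi]
    rid <- models$region_id[mi]
    wsub <- sim$weights[sim$weights$gene_id == g & sim$weights$context == cx, ]
    ci <- common_idx[[rid]]
    R <- sim$ld[[rid]][ci, ci, drop = FALSE]
    for (tr in gwas_traits) {
      zt <- harm[[tr]][[rid]]$z[ci]
      sst <- data.frame(variant_id = colnames(R), z = unname(zt),
                        stringsAsFactors = FALSE)
      row <- twas_assoc(wsub, sst, R, trait = tr)
      if (is.null(row)) next
      row$retained <- row$retained && models$retained[mi]
      row$best <- models$best[mi]
      row$region_id <- rid
      twas_rows[[length(twas_rows) + 1]] <- row
    }
  }
  twas <- do.call(rbind, twas_rows)
  twas <- twas_significance(twas, mode = config$twas_mode,
                            alpha_fixed = config$twas_alpha)
  paths["twas"] <- write_tsv(twas, file.path(out_dir, "twas.tsv"))

  # ---- MR: each context (exposure) against each GWAS trait (outcome)
  gene_of_region <- function(v, rid) {
    gg <- sim$annotation$genes$gene_id[sim$annotation$genes$region_id == rid]
    for (g in gg) if (v %in% sim$annotation$gene_variants[[g]]) return(g)
    gg[1]
  }
  mr_rows <- list()
  for (rid in regions) {
    for (cx in contexts) {
      fm <- fits[[cx]][[rid]]
      inst <- select_instruments(fm, cpip_min = config$mr_cpip_instrument)
      if (!length(inst)) next
      best_cs <- inst[[which.max(vapply(inst, `[[`, 0, "cPIP"))]]
      gid <- gene_of_region(best_cs$variants[1], rid)
      for (tr in gwas_traits) {
        res <- mr_gene(fm, sim$sumstats[[cx]][[rid]],
                       sim$sumstats[[tr]][[rid]],
                       gene_id = gid, context = cx, trait = tr,
                       cpip_instrument = config$mr_cpip_instrument,
                       z_floor = config$mr_z_floor,
                       se_mode = config$mr_se_mode, p_max = config$mr_p,
                       cpip_min = config$mr_cpip, i2_max = config$i2_max)
        if (is.null(res)) next
        res$region_id <- rid
        mr_rows[[length(mr_rows) + 1]] <- as.data.frame(res)
      }
    }
  }
  mr <- if (length(mr_rows)) do.call(rbind, mr_rows) else NULL
  paths["mr"] <- write_tsv(
    mr %||% data.frame(gene_id = character(0)),
    file.path(out_dir, "mr.tsv"))

  # ---- prioritization
  xqtl_fits <- stats::setNames(lapply(contexts, function(cx) fits[[cx]]),
                               contexts)
  coloc_flags <- coloc_xqtl_genes(coloc_results, xqtl_fits, sim$annotation,
                                  pip_floor = config$pip_floor,
                                  xqtl_traits = contexts)
  evidence <- gene_evidence(twas, coloc_flags, mr, trait_categories)
  tiers <- if (nrow(evidence)) {
    assign_tiers(evidence, endpoint_mode = config$endpoint_mode,
                 mr_as_endpoint_evidence = config$mr_as_endpoint_evidence)
  } else {
    data.frame(gene_id = character(0), tier = integer(0),
               justification = character(0))
  }
  pcg_rows <- list()
  for (rid in regions) {
    for (cx in contexts) {
      ci <- common_idx[[rid]]
      gsub <- sim$sumstats[[gwas_traits[1]]][[rid]]
      gsub <- gsub[match(colnames(sim$ld[[rid]])[ci], gsub$variant_id), ]
      sel <- pcg_select(twas[twas$region_id == rid, , drop = FALSE],
                        fits[[cx]][[rid]], gsub, sim$annotation, rid,
                        context = cx)
      if (!is.null(sel)) pcg_rows[[length(pcg_rows) + 1]] <- sel
    }
  }
  pcg <- if (length(pcg_rows)) do.call(rbind, pcg_rows) else
    data.frame(region_id = character(0), context = character(0),
               selected_gene = character(0), causal_gene = character(0))
  paths["evidence"] <- write_tsv(evidence, file.path(out_dir, "evidence.tsv"))
  paths["tiers"] <- write_tsv(tiers, file.path(out_dir, "tiers.tsv"))
  paths["pcg"] <- write_tsv(pcg, file.path(out_dir, "pcg.tsv"))

  # ---- enrichment over the prioritized gene union
  query <- sort(unique(c(tiers$gene_id[!is.na(tiers$tier)],
                         pcg$causal_gene)))
  background <- unique(c(unlist(sim$gene_sets), sim$annotation$genes$gene_id))
  enr <- if (length(query)) {
    ora(query, sim$gene_sets, background, fdr_max = config$fdr_max)
  } else {
    data.frame(set_id = character(0), k = integer(0), p_hyper = numeric(0),
               fdr = numeric(0), significant = logical(0))
  }
  paths["enrichment"] <- write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  bundle <- list(config = config, sim = sim, harmonized = harm,
                 fits = fits, coloc = coloc_results, twas = twas, mr = mr,
                 evidence = evidence, tiers = tiers, pcg = pcg,
                 enrichment = enr, paths = paths, out_dir = out_dir)
  score <- score_run(bundle, sim$truth)
  bundle$score <- score
  paths["score"] <- write_tsv(score, file.path(out_dir, "score.tsv"))
  bundle$paths <- paths

  report <- c(
    "genetier pipeline run",
    sprintf("regions: %d  traits: %d  contexts: %d",
            length(regions), length(gwas_traits), length(contexts)),
    sprintf("seed: %d", config$sim$seed),
    sprintf("finemap fits: %d  coloc results: %d  twas tests: %d  mr results: %d",
            length(regions) * nrow(traits), length(coloc_results),
            nrow(twas), if (is.null(mr)) 0L else nrow(mr)),
    sprintf("tiers: %s", paste(utils::capture.output(
      print(table(tiers$tier, useNA = "ifany"))), collapse = " | ")),
    "scores:",
    sprintf("  %s = %.4f", score$metric, score$value))
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(bundle)
}

#' Score a pipeline run against the generator's truth tables
#'
#' Emits recall of planted causal variants in the highest-coverage credible
#' sets, CoS hit rate and precision, TWAS power on causal-variant genes and
#' type-I rate on decoys, MR bias against the true gene-trait effects, and
#' tier-1 recall for planted genes versus decoys.
#'
#' @param bundle Artifact bundle from [run_pipeline()].
#' @param truth Truth tables from [simulate_study()] (defaults to the
#'   bundle's own).
#' @return `data.frame(metric, value, n)`.
#' @export
score_run <- function(bundle, truth = NULL) {
  truth <- truth %||% bundle$sim$truth
  if (is.null(truth)) stop("no truth tables available for scoring")
  met <- function(metric, value, n) data.frame(
    metric = metric, value = value, n = n, stringsAsFactors = FALSE)
  rows <- list()

  tc <- truth$causal
  hit <- logical(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    fit <- bundle$fits[[tc$trait[i]]][[tc$region_id[i]]]
    if (is.null(fit)) next
    top <- Filter(function(cs) cs$coverage == max(fit$coverages),
                  fit$credible_sets)
    hit[i] <- any(vapply(top, function(cs) tc$variant_id[i] %in% cs$variants,
                         logical(1)))
  }
  rows[[1]] <- met("causal_recall_cs95", mean(hit), nrow(tc))

  cos_all <- unlist(lapply(bundle$coloc, function(res)
    lapply(res$cos, `[[`, "variants")), recursive = FALSE)
  if (!is.null(truth$shared)) {
    sh_hit <- vapply(seq_len(nrow(truth$shared)), function(i) {
      any(vapply(cos_all, function(v) truth$shared$variant_id[i] %in% v,
                 logical(1)))
    }, logical(1))
    rows[[length(rows) + 1]] <- met("cos_hit_rate", mean(sh_hit),
                                    nrow(truth$shared))
    if (length(cos_all)) {
      prec <- vapply(cos_all, function(v)
        any(truth$shared$variant_id %in% v), logical(1))
      rows[[length(rows) + 1]] <- met("cos_precision", mean(prec),
                                      length(cos_all))
    }
  }

  tw <- bundle$twas
  if (!is.null(tw) && nrow(tw)) {
    targets <- truth$target_genes$gene_id
    is_t <- tw$gene_id %in% targets
    if (any(is_t)) rows[[length(rows) + 1]] <-
      met("twas_power", mean(tw$significant[is_t]), sum(is_t))
    if (any(!is_t)) rows[[length(rows) + 1]] <-
      met("twas_type1", mean(tw$significant[!is_t]), sum(!is_t))
  }

  if (!is.null(bundle$mr) && !is.null(truth$gene_effects)) {
    ge <- truth$gene_effects
    m <- merge(bundle$mr, ge, by = c("gene_id", "context", "trait"))
    if (nrow(m)) rows[[length(rows) + 1]] <-
      met("mr_bias", mean(m$theta_meta - m$theta_true), nrow(m))
  }

  ti <- bundle$tiers
  if (!is.null(ti) && nrow(ti)) {
    targets <- truth$target_genes$gene_id
    t_rows <- ti[ti$gene_id %in% targets, , drop = FALSE]
    d_rows <- ti[!ti$gene_id %in% targets, , drop = FALSE]
    rows[[length(rows) + 1]] <- met(
      "tier1_recall",
      if (length(targets)) sum(!is.na(t_rows$tier) & t_rows$tier == 1) /
        length(targets) else NA_real_, length(targets))
    rows[[length(rows) + 1]] <- met(
      "decoy_tier1_rate",
      if (nrow(d_rows)) mean(!is.na(d_rows$tier) & d_rows$tier == 1) else 0,
      nrow(d_rows))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
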