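# Synthetic-data generator: the statistical structure every downstream stage
# assumes. z-scores follow the RSS model z ~ Normal(R %*% lambda, R) given the
# local LD matrix R and a sparse vector of non-centralities lambda; traits that
# share a planted causal variant use the same index; xQTL weight models equal
# the planted molecular effect vectors plus Gaussian noise.

#' Simulation configuration
#'
#' Defines the study conditions for [simulate_study()]: region geometry, LD
#' structure, the trait panel (imaging endophenotypes, disease endpoints and
#' molecular-QTL contexts), the planted causal architecture, weight noise and
#' the master seed. Defaults describe a small multi-trait study with one
#' shared causal variant per region across all traits.
#'
#' @param n_regions Number of LD regions.
#' @param variants_per_region Variants per region (>= 2).
#' @param ld_structure One of `"ar1"`, `"block"`, `"identity"`.
#' @param ld_rho Correlation parameter in `[0, 1)`.
#' @param traits `data.frame` with columns `name`, `role` (one of `dne`,
#'   `endpoint`, `xqtl_context`), `category` (`DNE`, `AD`, `Aging`, `PD`, or
#'   `NA` for molecular contexts) and `n` (GWAS/xQTL sample size).
#' @param causal_plan Optional list, one element per region, each a named list
#'   `trait -> list(idx =, ncp =)`. `NULL` plants one causal variant per
#'   region shared by every trait at non-centrality `ncp`.
#' @param ncp Default planted non-centrality (z-score scale) when
#'   `causal_plan` is `NULL`.
#' @param genes_per_region Genes annotated per region (first gene contains the
#'   planted causal variant; the rest are decoys).
#' @param gene_size Number of cis variants per gene.
#' @param weight_noise_sd SD of the Gaussian noise added to planted molecular
#'   effect vectors to form TWAS weights.
#' @param target_cv_r2,decoy_cv_r2 Cross-validation R^2 assigned to weight
#'   models of causal-variant genes and decoy genes.
#' @param target_cv_p,decoy_cv_p Cross-validation p-values likewise.
#' @param maf_low_frac Fraction of non-causal variants planted below the MAF
#'   QC threshold (to exercise the filter).
#' @param ambig_frac Fraction of non-causal variants given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param n_filler_genes Background-only gene ids added to the gene universe
#'   for enrichment analysis.
#' @param n_gene_sets,gene_set_size Gene-set collection geometry; one set is
#'   planted enriched for the causal-variant genes.
#' @param seed Master seed; per-(region, trait) streams are derived from it by
#'   stable hashing so adding a trait never perturbs existing traits.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 3,
                       variants_per_region = 100,
                       ld_structure = "ar1",
                       ld_rho = 0.9,
                       traits = default_traits(),
                       causal_plan = NULL,
                       ncp = 6,
                       genes_per_region = 2,
                       gene_size = 20,
                       weight_noise_sd = 0.05,
                       target_cv_r2 = 0.15, target_cv_p = 1e-4,
                       decoy_cv_r2 = 0.005, decoy_cv_p = 0.5,
                       maf_low_frac = 0.02,
                       ambig_frac = 0.02,
                       n_filler_genes = 200,
                       n_gene_sets = 20, gene_set_size = 25,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    variants_per_region = as.integer(variants_per_region),
    ld_structure = match.arg(ld_structure, c("ar1", "block", "identity")),
    ld_rho = ld_rho, traits = traits, causal_plan = causal_plan, ncp = ncp,
    genes_per_region = as.integer(genes_per_region),
    gene_size = as.integer(gene_size),
    weight_noise_sd = weight_noise_sd,
    target_cv_r2 = target_cv_r2, target_cv_p = target_cv_p,
    decoy_cv_r2 = decoy_cv_r2, decoy_cv_p = decoy_cv_p,
    maf_low_frac = maf_low_frac, ambig_frac = ambig_frac,
    n_filler_genes = as.integer(n_filler_genes),
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size = as.integer(gene_set_size),
    seed = as.integer(seed)
  )
  if (cfg$variants_per_region < 2) stop("variants_per_region must be >= 2")
  if (cfg$ld_structure != "identity" && (ld_rho < 0 || ld_rho >= 1)) {
    stop("ld_rho must lie in [0, 1)")
  }
  if (cfg$weight_noise_sd < 0) stop("weight_noise_sd must be nonnegative")
  stopifnot(all(c("name", "role", "category", "n") %in% names(traits)))
  bad <- setdiff(traits$role, c("dne", "endpoint", "xqtl_context"))
  if (length(bad)) stop("unknown trait roles: ", paste(bad, collapse = ", "))
  if (!is.null(causal_plan)) {
    if (length(causal_plan) != cfg$n_regions) {
      stop("causal_plan must have one element per region")
    }
    for (rp in causal_plan) {
      for (tr in names(rp)) {
        if (!tr %in% traits$name) stop("causal_plan names unknown trait: ", tr)
        idx <- rp[[tr]]$idx
        ncps <- rp[[tr]]$ncp
        if (any(idx < 1 | idx > cfg$variants_per_region)) {
          stop("causal index out of region bounds")
        }
        if (!all(is.finite(ncps))) stop("non-centrality values must be finite")
      }
    }
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_traits <- function() {
  data.frame(
    name = c("DNE1", "DNE2", "AD", "Aging", "eQTL_DLPFC", "pQTL_DLPFC"),
    role = c("dne", "dne", "endpoint", "endpoint", "xqtl_context", "xqtl_context"),
    category = c("DNE", "DNE", "AD", "Aging", NA, NA),
    n = c(33000, 33000, 100000, 100000, 2000, 2000),
    stringsAsFactors = FALSE
  )
}

# Random ref/alt pairs from {A,C,G,T}; a given fraction strand-ambiguous
# (A/T or C/G), drawn from the current RNG stream.
assign_alleles <- function(p, ambig_frac = 0) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(bases, p, replace = TRUE)
  alt <- character(p)
  amb <- stats::runif(p) < ambig_frac
  for (i in seq_len(p)) {
    alt[i] <- if (amb[i]) comp[[ref[i]]] else {
      sample(setdiff(bases, c(ref[i], comp[[ref[i]]])), 1)
    }
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Simulate one trait's z-scores under the RSS model
#'
#' Draws `z ~ Normal(R %*% lambda, R)` where `lambda` is zero except at the
#' planted causal indices, then fills `beta`, `se`, `maf` and alleles to give
#' a schema-complete summary-statistics table (`se = 1/sqrt(n)`,
#' `beta = z * se`).
#'
#' @param ld LD matrix (variant ids in dimnames).
#' @param causal Named numeric vector of non-centralities; names are variant
#'   indices (coercible to integer) or variant ids present in `ld`.
#' @param n Sample size.
#' @param trait Trait name.
#' @param seed Optional seed (sets the global RNG stream).
#' @param chrom,pos_offset Coordinates for the emitted table.
#' @param maf Optional MAF vector; default Uniform(0.01, 0.5).
#' @param alleles Optional `data.frame(ref, alt)`; default random unambiguous
#'   pairs.
#' @param factor Optional precomputed `t(F) %*% F = R` factor for repeated
#'   sampling against the same LD matrix.
#' @return A summary-statistics `data.frame` (see [sumstats()]).
#' @export
simulate_trait_z <- function(ld, causal = numeric(0), n = 10000,
                             trait = "trait", seed = NULL,
                             chrom = 1L, pos_offset = 0L,
                             maf = NULL, alleles = NULL, factor = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(ld)
  lambda <- numeric(p)
  if (length(causal)) {
    if (!all(is.finite(causal))) stop("non-centrality values must be finite")
    nm <- names(causal)
    idx <- suppressWarnings(as.integer(nm))
    if (anyNA(idx)) idx <- match(nm, colnames(ld))
    if (anyNA(idx) || any(idx < 1 | idx > p)) stop("invalid causal indices")
    lambda[idx] <- causal
  }
  mu <- if (length(causal)) as.vector(ld %*% lambda) else numeric(p)
  z <- rmvn_ld(1, mu, ld, factor)[1, ]
  if (is.null(maf)) maf <- stats::runif(p, 0.01, 0.5)
  if (is.null(alleles)) alleles <- assign_alleles(p)
  sumstats(trait, colnames(ld), z, n = n, chrom = chrom,
           pos = pos_offset + seq_len(p), ref = alleles$ref,
           alt = alleles$alt, maf = maf)
}

#' Simulate a complete multi-trait, multi-context study
#'
#' Generates per-region LD matrices, GWAS and xQTL summary statistics with
#' planted shared causal variants, TWAS weight models derived from the planted
#' molecular effects plus noise, gene annotations, gene-set collections with
#' one planted enriched set, and truth tables sufficient to score every
#' downstream stage.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_study` with elements `config`, `ld` (per
#'   region), `sumstats` (per trait, per region), `weights` (long-format
#'   table), `annotation` (gene table + gene -> variant map), `gene_sets`
#'   (named list), and `truth` (tables `causal`, `shared`, `gene_effects`,
#'   `target_genes`, `enriched_sets`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$variants_per_region
  regions <- sprintf("region%02d", seq_len(config$n_regions))
  traits <- config$traits
  gwas_traits <- traits$name[traits$role != "xqtl_context"]
  contexts <- traits$name[traits$role == "xqtl_context"]

  ld <- list()
  ss <- stats::setNames(vector("list", nrow(traits)), traits$name)
  for (tr in traits$name) ss[[tr]] <- list()
  weights <- list()
  genes <- list(); gene_variants <- list()
  truth_causal <- list(); truth_shared <- list(); truth_effects <- list()
  target_genes <- list()

  for (r in seq_along(regions)) {
    rid <- regions[r]
    vids <- sprintf("%s_v%04d", rid, seq_len(p))
    R <- make_ld(p, config$ld_structure, config$ld_rho, variant_ids = vids)
    ld[[rid]] <- R
    fac <- ld_factor(R)

    # region-level plan (drawn from the region stream, not any trait stream)
    set.seed(derive_seed(config$seed, rid, "plan"))
    plan <- config$causal_plan[[r]]
    if (is.null(plan)) {
      shared_idx <- sample(seq(config$gene_size, p - config$gene_size), 1)
      plan <- stats::setNames(
        rep(list(list(idx = shared_idx, ncp = config$ncp)), nrow(traits)),
        traits$name
      )
    }
    causal_idx_all <- sort(unique(unlist(lapply(plan, `[[`, "idx"))))
    # QC victims planted away from causal variants
    free <- setdiff(seq_len(p), causal_idx_all)
    n_low <- round(config$maf_low_frac * p)
    low_maf_idx <- if (n_low > 0) sample(free, min(n_low, length(free))) else integer(0)
    free2 <- setdiff(free, low_maf_idx)
    n_amb <- round(config$ambig_frac * p)
    amb_idx <- if (n_amb > 0) sample(free2, min(n_amb, length(free2))) else integer(0)
    maf_region <- stats::runif(p, 0.01, 0.5)
    maf_region[low_maf_idx] <- stats::runif(length(low_maf_idx), 5e-4, 2e-3)
    alleles <- assign_alleles(p, ambig_frac = 0)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    alleles$alt[amb_idx] <- comp[alleles$ref[amb_idx]]

    # genes: first gene contains the shared causal variant, others are decoys
    gsz <- config$gene_size
    anchor <- if (length(causal_idx_all)) causal_idx_all[1] else 1L
    t_start <- max(1, min(anchor - floor(gsz / 2), p - gsz + 1))
    cand_starts <- seq(1, max(1, p - gsz + 1), by = gsz)
    cand_starts <- cand_starts[cand_starts + gsz - 1 < t_start |
                               cand_starts > t_start + gsz - 1]
    g_starts <- c(t_start, utils::head(cand_starts, config$genes_per_region - 1))
    if (length(g_starts) < config$genes_per_region) {
      stop("region too small for the requested genes_per_region")
    }
    for (k in seq_len(config$genes_per_region)) {
      gid <- sprintf("%s_gene%d", rid, k)
      sel <- seq(g_starts[k], length.out = gsz)
      sel <- sel[sel >= 1 & sel <= p]
      genes[[gid]] <- data.frame(gene_id = gid, region_id = rid,
                                 tss = min(sel), stringsAsFactors = FALSE)
      gene_variants[[gid]] <- vids[sel]
      if (k == 1) {
        target_genes[[length(target_genes) + 1]] <- data.frame(
          gene_id = gid, region_id = rid,
          causal_variant = vids[anchor], stringsAsFactors = FALSE)
      }
    }

    # per-(region, trait) streams: adding a trait never perturbs the others
    for (ti in seq_len(nrow(traits))) {
      tr <- traits$name[ti]
      tp <- plan[[tr]]
      causal <- if (is.null(tp)) numeric(0) else {
        stats::setNames(rep_len(tp$ncp, length(tp$idx)), tp$idx)
      }
      ssr <- simulate_trait_z(
        R, causal, n = traits$n[ti], trait = tr,
        seed = derive_seed(config$seed, rid, tr),
        chrom = r, pos_offset = (r - 1L) * 10L * p,
        maf = maf_region, alleles = alleles, factor = fac
      )
      ss[[tr]][[rid]] <- ssr
      if (length(causal)) {
        truth_causal[[length(truth_causal) + 1]] <- data.frame(
          region_id = rid, trait = tr, variant_id = vids[tp$idx],
          index = tp$idx, ncp = rep_len(tp$ncp, length(tp$idx)),
          stringsAsFactors = FALSE)
      }
    }

    # shared-variant trait sets
    idx_map <- lapply(plan, function(tp) if (is.null(tp)) integer(0) else tp$idx)
    for (ix in causal_idx_all) {
      who <- names(idx_map)[vapply(idx_map, function(v) ix %in% v, logical(1))]
      if (length(who) >= 2) {
        truth_shared[[length(truth_shared) + 1]] <- data.frame(
          region_id = rid, variant_id = vids[ix],
          trait_set = paste(sort(who), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }

    # TWAS weights: planted molecular effect vector + Normal(0, sd^2) noise
    # restricted to each gene's cis variants
    for (cx in contexts) {
      set.seed(derive_seed(config$seed, rid, cx, "weights"))
      cx_idx <- idx_map[[cx]]
      for (k in seq_len(config$genes_per_region)) {
        gid <- sprintf("%s_gene%d", rid, k)
        gvars <- gene_variants[[gid]]
        e <- numeric(length(gvars))
        hit <- intersect(vids[cx_idx], gvars)
        is_target <- length(hit) > 0
        e[match(hit, gvars)] <- 1
        w <- e + stats::rnorm(length(gvars), 0, config$weight_noise_sd)
        if (all(w == 0)) w[1] <- 1e-8  # at least one nonzero weight
        weights[[length(weights) + 1]] <- data.frame(
          gene_id = gid, context = cx, region_id = rid, variant_id = gvars,
          weight = w,
          cv_r2 = if (is_target) config$target_cv_r2 else config$decoy_cv_r2,
          cv_p = if (is_target) config$target_cv_p else config$decoy_cv_p,
          stringsAsFactors = FALSE)
      }
    }

    # true gene -> GWAS-trait effects (beta scale) for MR scoring
    for (cx in contexts) {
      cx_idx <- idx_map[[cx]]
      if (!length(cx_idx)) next
      for (tr in gwas_traits) {
        tr_idx <- idx_map[[tr]]
        shared_ix <- intersect(cx_idx, tr_idx)
        if (!length(shared_ix)) next
        n_out <- traits$n[traits$name == tr]
        ncp_exp <- plan[[cx]]$ncp[match(shared_ix[1], plan[[cx]]$idx)]
        ncp_out <- plan[[tr]]$ncp[match(shared_ix[1], plan[[tr]]$idx)]
        truth_effects[[length(truth_effects) + 1]] <- data.frame(
          region_id = rid, gene_id = sprintf("%s_gene1", rid), context = cx,
          trait = tr, theta_true = (ncp_out / sqrt(n_out)) / ncp_exp,
          stringsAsFactors = FALSE)
      }
    }
  }

  ann <- list(genes = do.call(rbind, genes), gene_variants = gene_variants)

  # gene sets with one planted enriched set over the causal-variant genes
  universe <- c(ann$genes$gene_id,
                sprintf("bg%04d", seq_len(config$n_filler_genes)))
  favored <- vapply(target_genes, function(d) d$gene_id, character(1))
  set.seed(derive_seed(config$seed, "gene_sets"))
  gs <- simulate_gene_sets(universe, favored, n_sets = config$n_gene_sets,
                           set_size = config$gene_set_size)

  structure(list(
    config = config, ld = ld, sumstats = ss,
    weights = do.call(rbind, weights), annotation = ann,
    gene_sets = gs$sets,
    truth = list(
      causal = do.call(rbind, truth_causal),
      shared = if (length(truth_shared)) do.call(rbind, truth_shared) else NULL,
      gene_effects = if (length(truth_effects)) do.call(rbind, truth_effects) else NULL,
      target_genes = do.call(rbind, target_genes),
      enriched_sets = gs$enriched
    )
  ), class = "sim_study")
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Null sets are uniform draws from the universe; the planted set includes
#' each favored gene with probability `enrich_fold` times the baseline
#' inclusion probability, producing the stated fold over-representation in
#' expectation.
#'
#' @param universe Character vector of background gene ids.
#' @param favored Genes the planted set is enriched for.
#' @param n_sets,set_size Collection geometry.
#' @param enrich_fold Fold over-representation of favored genes.
#' @return `list(sets = named list, enriched = name of the planted set)`.
#' @export
simulate_gene_sets <- function(universe, favored, n_sets = 20, set_size = 25,
                               enrich_fold = 4) {
  N <- length(universe)
  sets <- list()
  for (k in seq_len(n_sets)) {
    sets[[sprintf("GS%02d", k)]] <- sample(universe, min(set_size, N))
  }
  q <- min(1, enrich_fold * set_size / N)
  planted <- universe[stats::runif(N) < ifelse(universe %in% favored, q, 0)]
  fill <- sample(setdiff(universe, c(planted, favored)),
                 max(0, set_size - length(planted)))
  enriched_id <- sprintf("GS%02d", n_sets)
  sets[[enriched_id]] <- c(planted, fill)
  list(sets = sets, enriched = enriched_id)
}

#' Simulate an exposure/outcome pair for Mendelian-randomization calibration
#'
#' One region with a single planted instrument: exposure z-scores are drawn
#' from `Normal(R lambda, R)` with `lambda[causal] = b_star`; outcome
#' z-scores from `Normal(R (gamma * lambda), R)`, i.e. the outcome effect is
#' `gamma` per unit of standardized exposure effect, propagated through LD,
#' plus correlated noise. On the beta scale the true causal effect is
#' `gamma / sqrt(n_out)`.
#'
#' @param p,rho Region size and AR(1) correlation.
#' @param b_star Instrument strength (exposure non-centrality).
#' @param gamma True causal effect on the z-score scale (0 = null).
#' @param n_exp,n_out Exposure and outcome sample sizes.
#' @param causal_idx Instrument position (default mid-region).
#' @param seed Optional seed.
#' @return `list(exposure, outcome, ld, causal_idx, theta_true)` with
#'   `theta_true` on the outcome beta scale.
#' @export
simulate_mr_pair <- function(p = 50, rho = 0.5, b_star = 8, gamma = 0,
                             n_exp = 10000, n_out = 50000,
                             causal_idx = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- make_ld(p, "ar1", rho)
  if (is.null(causal_idx)) causal_idx <- ceiling(p / 2)
  fac <- ld_factor(R)
  causal_exp <- stats::setNames(b_star, causal_idx)
  exposure <- simulate_trait_z(R, causal_exp, n = n_exp, trait = "exposure",
                               factor = fac)
  causal_out <- stats::setNames(gamma * b_star, causal_idx)
  outcome <- simulate_trait_z(R, if (gamma != 0) causal_out else
                              stats::setNames(0, causal_idx),
                              n = n_out, trait = "outcome", factor = fac)
  list(exposure = exposure, outcome = outcome, ld = R,
       causal_idx = causal_idx, theta_true = gamma / sqrt(n_out))
}
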