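ext_coloc <- function(variants, trait_set = c("DNE1", "eQTL"),
                      region_id = "r1", vcp = 0.5) {
  structure(list(trait_set = trait_set, region_id = region_id,
                 vcp = stats::setNames(rep(vcp, length(variants)), variants),
                 cos = list(list(cos_id = "c1", variants = variants,
                                 vcp = stats::setNames(rep(vcp, length(variants)),
                                                       variants))),
                 source = "external"), class = "coloc_result")
}

ids6 <- sprintf("v%04d", 1:6)
ann1 <- list(genes = data.frame(gene_id = c("G1", "G2"), region_id = "r1",
                                tss = c(1, 5), stringsAsFactors = FALSE),
             gene_variants = list(G1 = ids6[1:3], G2 = ids6[4:6]))

test_that("colocalized variants inside xQTL credible sets flag their genes", {
  fm <- fake_fit(rbind(c(0, 0, 0.8, 0.1, 0.1, 0)), variant_ids = ids6,
                 cs = list(fake_cs(ids6[3], coverage = 0.70)))
  fl <- coloc_xqtl_genes(list(ext_coloc(ids6[3])),
                         list(eQTL = list(r1 = fm)), ann1,
                         xqtl_traits = "eQTL")
  expect_equal(fl$gene_id, "G1")
  expect_equal(fl$trait, "DNE1")
  expect_equal(fl$variant_id, ids6[3])
})

test_that("the PIP >= 0.25 rescue applies outside credible sets, strictly", {
  fm_30 <- fake_fit(rbind(c(0, 0, 0.3, 0.7, 0, 0)), variant_ids = ids6,
                    cs = list(fake_cs(ids6[4])))
  fl <- coloc_xqtl_genes(list(ext_coloc(ids6[3])),
                         list(eQTL = list(r1 = fm_30)), ann1,
                         xqtl_traits = "eQTL")
  expect_equal(fl$gene_id, "G1")   # PIP 0.3 outside any CS still counts

  fm_20 <- fake_fit(rbind(c(0, 0, 0.2, 0.8, 0, 0)), variant_ids = ids6,
                    cs = list(fake_cs(ids6[4])))
  fl2 <- coloc_xqtl_genes(list(ext_coloc(ids6[3])),
                          list(eQTL = list(r1 = fm_20)), ann1,
                          xqtl_traits = "eQTL")
  expect_equal(nrow(fl2), 0L)      # PIP 0.2 below the floor
})

test_that("putative-causal-gene selection follows top PIP within the CS tiers", {
  gwas <- sumstats("DNE1", ids6, z = c(1, 1, 5, 2, 1, 1))
  twas <- data.frame(gene_id = c("G1", "G2"), context = "eQTL",
                     region_id = "r1", retained = TRUE, significant = TRUE,
                     stringsAsFactors = FALSE)
  fm <- fake_fit(rbind(c(0, 0.9, 0.05, 0.05, 0, 0)), variant_ids = ids6,
                 cs = list(fake_cs(ids6[2], coverage = 0.95,
                                   alpha = 0.9)))
  sel <- pcg_select(twas, fm, gwas, ann1, "r1", context = "eQTL")
  expect_equal(sel$selected_gene, "G1")     # top-PIP variant v2 lies in G1
  expect_equal(sel$causal_variant, ids6[3]) # smallest GWAS p in region
  expect_equal(sel$causal_gene, "G1")

  only_g2 <- twas[twas$gene_id == "G2", ]
  fm2 <- fake_fit(rbind(c(0, 0, 0, 0.9, 0.05, 0)), variant_ids = ids6,
                  cs = list(fake_cs(ids6[4], coverage = 0.95, alpha = 0.9)))
  sel2 <- pcg_select(only_g2, fm2, gwas, ann1, "r1", context = "eQTL")
  expect_equal(sel2$selected_gene, "G2")    # singleton eligibility

  none <- twas; none$significant <- FALSE
  expect_null(pcg_select(none, fm, gwas, ann1, "r1", context = "eQTL"))
})

ev_row <- function(gene, trait, category, twas = FALSE, coloc = FALSE,
                   mr = FALSE) {
  data.frame(gene_id = gene, trait = trait, category = category,
             context = "cx", twas_sig = twas, coloc_sig = coloc,
             mr_sig = mr, stringsAsFactors = FALSE)
}

combo_evidence <- function(bits) {
  # bits: dne_t, dne_c, ad_t, ad_c, ag_t, ag_c
  rbind(ev_row("G", "DNE1", "DNE", bits[1], bits[2]),
        ev_row("G", "AD", "AD", bits[3], bits[4]),
        ev_row("G", "Aging", "Aging", bits[5], bits[6]))
}

test_that("tier assignment equals the hand-coded truth table over all 2^6 combos", {
  oracle <- function(b) {
    dne_t <- b[1]; dne_c <- b[2]
    ep_t_all <- b[3] && b[5]
    ep_both_all <- (b[3] && b[4]) && (b[5] && b[6])
    if (dne_t && dne_c && ep_both_all) return(1L)
    if (dne_t && dne_c && ep_t_all) return(2L)
    if ((dne_t || dne_c) && ep_t_all) return(3L)
    NA_integer_
  }
  for (code in 0:63) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:5), 1L))
    got <- assign_tiers(combo_evidence(bits), endpoint_mode = "all")
    expect_equal(got$tier, oracle(bits),
                 info = paste("combo", paste(as.integer(bits), collapse = "")))
  }
})

test_that("adding evidence never worsens a gene's tier", {
  set.seed(tseed("tier-mono"))
  rank_of <- function(tier) if (is.na(tier)) 4L else tier
  for (i in 1:40) {
    bits <- runif(6) < 0.5
    off <- which(!bits)
    if (!length(off)) next
    more <- bits; more[sample(off, 1)] <- TRUE
    t1 <- assign_tiers(combo_evidence(bits), endpoint_mode = "all")$tier
    t2 <- assign_tiers(combo_evidence(more), endpoint_mode = "all")$tier
    expect_lte(rank_of(t2), rank_of(t1))
  }
})

test_that("tier examples: full support, TWAS-only endpoints, no DNE evidence", {
  full <- rbind(ev_row("G", "DNE1", "DNE", TRUE, TRUE),
                ev_row("G", "AD", "AD", TRUE, TRUE),
                ev_row("G", "Aging", "Aging", TRUE, TRUE))
  expect_equal(assign_tiers(full, endpoint_mode = "all")$tier, 1L)

  t2 <- rbind(ev_row("G", "DNE1", "DNE", TRUE, TRUE),
              ev_row("G", "AD", "AD", TRUE, FALSE))
  expect_equal(assign_tiers(t2, endpoint_mode = "any")$tier, 2L)

  noDNE <- ev_row("G", "AD", "AD", TRUE, TRUE)
  expect_true(is.na(assign_tiers(noDNE, endpoint_mode = "any")$tier))
})

test_that("MR evidence can substitute for endpoint TWAS when enabled", {
  ev <- rbind(ev_row("G", "DNE1", "DNE", TRUE, TRUE),
              ev_row("G", "AD", "AD", FALSE, FALSE, mr = TRUE))
  expect_true(is.na(assign_tiers(ev, endpoint_mode = "any")$tier))
  got <- assign_tiers(ev, endpoint_mode = "any",
                      mr_as_endpoint_evidence = TRUE)
  expect_equal(got$tier, 2L)
})

test_that("gene_evidence merges flags with provenance-consistent categories", {
  twas <- data.frame(gene_id = "G1", context = "eQTL", trait = "DNE1",
                     significant = TRUE, retained = TRUE)
  fl <- data.frame(gene_id = "G1", trait = "AD", context = "eQTL",
                   variant_id = "v1", cos_id = "c1")
  ev <- gene_evidence(twas, fl, NULL,
                      trait_categories = c(DNE1 = "DNE", AD = "AD"))
  expect_equal(nrow(ev), 2L)
  expect_true(ev$twas_sig[ev$trait == "DNE1"])
  expect_true(ev$coloc_sig[ev$trait == "AD"])
  expect_equal(sort(ev$category), c("AD", "DNE"))
})
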