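test_that("null simulation has zero mean z within Monte-Carlo error", {
  R <- make_ld(6, "ar1", rho = 0.7)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("null-mean"))
  zs <- t(vapply(1:1000, function(i) {
    simulate_trait_z(R, factor = fac)$z
  }, numeric(6)))
  mc_se <- apply(zs, 2, sd) / sqrt(1000)
  expect_true(all(abs(colMeans(zs)) <= 4 * mc_se))
})

test_that("expected z equals R %*% lambda (identity and AR(1) cases)", {
  I6 <- make_ld(6, "identity")
  set.seed(tseed("mean-id"))
  zs <- t(vapply(1:2000, function(i) {
    simulate_trait_z(I6, c("1" = 6))$z
  }, numeric(6)))
  expect_equal(mean(zs[, 1]), 6, tolerance = 0.1)
  expect_lt(abs(mean(zs[, 2])), 0.1)

  R <- make_ld(6, "ar1", rho = 0.9)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("mean-ar1"))
  zs <- t(vapply(1:2000, function(i) {
    simulate_trait_z(R, c("1" = 6), factor = fac)$z
  }, numeric(6)))
  # oracle: direct matrix-vector product gives E[z_2] = 0.9 * 6 = 5.4
  lambda <- c(6, rep(0, 5))
  expect_equal(unname((R %*% lambda)[2]), 5.4)
  expect_equal(mean(zs[, 2]), 5.4, tolerance = 0.15)
})

test_that("empirical covariance of simulated z matches R entrywise", {
  R <- make_ld(5, "ar1", rho = 0.8)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("cov"))
  zs <- genetier:::rmvn_ld(6000, rep(0, 5), R, fac)
  emp <- cov(zs)
  # MC-SE of a correlation entry is about (1 - r^2)/sqrt(n)
  mc_se <- (1 - R^2) / sqrt(6000) + 1e-3
  expect_true(all(abs(emp - R) <= 4 * mc_se + 0.05))
})

test_that("summary-statistics schema is internally consistent", {
  R <- make_ld(10, "ar1", rho = 0.5)
  ss <- simulate_trait_z(R, c("3" = 4), n = 5000, seed = tseed("schema"))
  expect_equal(ss$z, ss$beta / ss$se, tolerance = 1e-9)
  expect_true(all(ss$maf >= 0 & ss$maf <= 0.5))
  expect_false(anyDuplicated(ss$variant_id) > 0)
  expect_equal(ss$se, rep(1 / sqrt(5000), 10))
})

test_that("traits sharing a planted causal variant use the same index", {
  cfg <- sim_config(n_regions = 1, variants_per_region = 60, seed = 5)
  study <- simulate_study(cfg)
  tc <- study$truth$causal
  expect_equal(length(unique(tc$variant_id)), 1L)
  expect_setequal(tc$trait, cfg$traits$name)
  expect_true(!is.null(study$truth$shared))
  expect_equal(study$truth$shared$variant_id, unique(tc$variant_id))
})

test_that("zero weight noise reproduces the planted effect vectors exactly", {
  cfg <- sim_config(n_regions = 1, variants_per_region = 60,
                    weight_noise_sd = 0, seed = 5)
  study <- simulate_study(cfg)
  w <- study$weights
  tg <- study$truth$target_genes
  wt <- w[w$gene_id == tg$gene_id[1], ]
  for (cx in unique(wt$context)) {
    ww <- wt[wt$context == cx, ]
    expect_equal(sum(ww$weight != 0), 1L)
    expect_equal(ww$variant_id[ww$weight == 1], tg$causal_variant[1])
  }
})

test_that("per-(region, trait) streams: adding a trait leaves others unchanged", {
  tr4 <- default_traits()[1:4, ]
  tr5 <- default_traits()[1:5, ]
  s4 <- simulate_study(sim_config(n_regions = 2, variants_per_region = 40,
                                  traits = tr4, genes_per_region = 1, seed = 9))
  s5 <- simulate_study(sim_config(n_regions = 2, variants_per_region = 40,
                                  traits = tr5, genes_per_region = 1, seed = 9))
  for (tr in tr4$name) {
    expect_equal(s4$sumstats[[tr]][["region01"]]$z,
                 s5$sumstats[[tr]][["region01"]]$z)
  }
})

test_that("null regions engage the fine-mapping skip rule", {
  R <- make_ld(200, "ar1", rho = 0.9)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("null-skip"))
  res <- vapply(1:100, function(i) {
    fit <- susie_rss(simulate_trait_z(R, factor = fac)$z, R)
    c(n_cs = length(fit$credible_sets), skipped = fit$skipped)
  }, numeric(2))
  # strong-LD noise clusters produce a rare spurious set (~1% of regions);
  # the rest yield no set, via the skip rule or the purity filter
  expect_gte(mean(res["n_cs", ] == 0), 0.97)
  expect_gte(mean(res["skipped", ]), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(variants_per_region = 1), "variants_per_region")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(weight_noise_sd = -1), "weight_noise_sd")
  expect_error(
    sim_config(n_regions = 1, variants_per_region = 10,
               causal_plan = list(list(DNE1 = list(idx = 50, ncp = 5)))),
    "bounds")
  expect_error(
    sim_config(n_regions = 1, variants_per_region = 10,
               causal_plan = list(list(DNE1 = list(idx = 2, ncp = Inf)))),
    "finite")
})

test_that("sumstats TSV dialect round-trips", {
  R <- make_ld(8, "ar1", rho = 0.3)
  ss <- simulate_trait_z(R, c("2" = 3), seed = tseed("io"))
  path <- withr::local_tempfile()
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$z, ss$z, tolerance = 1e-9)
  expect_equal(back$variant_id, ss$variant_id)
})
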