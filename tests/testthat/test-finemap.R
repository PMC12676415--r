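# closed-form single-effect posterior: uniform prior over variants, Normal
# prior on the effect, Bayes factor per variant, grid-maximized prior
# variance — computed directly from the formula as an oracle for L = 1
single_effect_oracle <- function(z, grid = c(0, 0.01, 0.04, 0.16, 0.64, 2.56)) {
  p <- length(z)
  best_ll <- -Inf; best <- NULL
  for (V in grid) {
    bf <- if (V == 0) rep(1, p) else
      sqrt(1 / (1 + V)) * exp(0.5 * z^2 * V / (1 + V))
    ll <- log(mean(bf))
    # a nonzero prior variance must beat the null by 0.1 log-lik units
    margin <- if (!is.null(best) && best$V == 0 && V > 0) 0.1 else 1e-12
    if (ll > best_ll + margin) {
      best_ll <- ll
      best <- list(V = V, alpha = bf / sum(bf))
    }
  }
  best
}

test_that("a single-variant region gets PIP 1 and a credible set at every coverage", {
  R <- matrix(1, 1, 1, dimnames = list("v1", "v1"))
  fit <- susie_rss(c(v1 = 10), R)
  expect_equal(unname(fit$pip), 1, tolerance = 1e-9)
  covs <- vapply(fit$credible_sets, `[[`, 0, "coverage")
  expect_setequal(covs, c(0.95, 0.70, 0.50))
  expect_true(all(vapply(fit$credible_sets, function(cs)
    identical(cs$variants, "v1"), logical(1))))
})

test_that("independent variants separate cleanly (closed-form check)", {
  R <- make_ld(2, "identity")
  fit <- susie_rss(c(10, 0), R)
  expect_gte(unname(fit$pip[1]), 0.99)
  expect_lte(unname(fit$pip[2]), 0.01)
  cs95 <- Filter(function(cs) cs$coverage == 0.95, fit$credible_sets)
  expect_equal(cs95[[1]]$variants, "v0001")
})

test_that("null z-scores engage the skip rule", {
  R <- make_ld(50, "ar1", rho = 0.8)
  fit <- susie_rss(rep(0, 50), R)
  expect_true(fit$skipped)
  expect_length(fit$credible_sets, 0L)
})

test_that("L = 1 matches the brute-force single-effect posterior", {
  set.seed(tseed("ser-oracle"))
  for (rep in 1:5) {
    R <- make_ld(20, "ar1", rho = 0.7)
    z <- simulate_trait_z(R, c("10" = 4), factor = genetier:::ld_factor(R))$z
    fit <- susie_rss(z, R, L_init = 1, L_max = 1)
    oracle <- single_effect_oracle(z)
    expect_equal(unname(fit$alpha[1, ]), oracle$alpha, tolerance = 1e-6)
    expect_equal(fit$V[1], oracle$V)
    expect_equal(unname(fit$pip), oracle$alpha, tolerance = 1e-6)
  }
})

test_that("the PIP identity and alpha normalization hold", {
  set.seed(tseed("pip-identity"))
  R <- make_ld(60, "ar1", rho = 0.9)
  fac <- genetier:::ld_factor(R)
  for (rep in 1:5) {
    z <- simulate_trait_z(R, stats::setNames(c(5, 4), c(10, 45)),
                          factor = fac)$z
    fit <- susie_rss(z, R)
    expect_equal(unname(rowSums(fit$alpha)), rep(1, fit$L_used),
                 tolerance = 1e-6)
    keep <- fit$V > 0
    pip_ref <- 1 - apply(1 - fit$alpha[keep, , drop = FALSE], 2, prod)
    expect_equal(unname(fit$pip), pip_ref, tolerance = 1e-9)
    expect_true(all(fit$pip >= 0 & fit$pip <= 1))
  }
})

test_that("the exact single-effect log-likelihood is non-decreasing over iterations", {
  set.seed(tseed("objective"))
  R <- make_ld(40, "ar1", rho = 0.9)
  z <- simulate_trait_z(R, c("20" = 5), factor = genetier:::ld_factor(R))$z
  fit <- susie_rss(z, R, L_init = 1, L_max = 1)
  expect_true(all(diff(fit$objective) >= -1e-10))
})

test_that("credible sets are minimal prefixes at each coverage", {
  alpha <- rbind(c(0.97, 0.02, 0.01))
  fit <- fake_fit(alpha)
  R <- make_ld(3, "ar1", rho = 0.9)
  cs <- credible_sets(fit, R)
  c95 <- Filter(function(s) s$coverage == 0.95, cs)[[1]]
  expect_equal(c95$variants, "v0001")

  alpha2 <- rbind(c(0.5, 0.3, 0.2))
  cs2 <- credible_sets(fake_fit(alpha2), R, coverages = 0.70)
  expect_equal(cs2[[1]]$variants, c("v0001", "v0002"))
  expect_equal(cs2[[1]]$cumulative_alpha, 0.8)
})

test_that("sets failing the purity threshold are discarded", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.1
  dimnames(R) <- list(c("v0001", "v0002"), c("v0001", "v0002"))
  fit <- fake_fit(rbind(c(0.5, 0.5)), variant_ids = c("v0001", "v0002"))
  expect_length(credible_sets(fit, R, coverages = 0.95), 0L)
  expect_length(credible_sets(fit, R, purity_min = 0.05, coverages = 0.95), 1L)
})

test_that("diagnostics report fallbacks, correlated set pairs and region classes", {
  R <- make_ld(4, "ar1", rho = 0.95)
  ids <- colnames(R)
  no_cs <- fake_fit(rbind(c(0.3, 0.1, 0.05, 0.05)), V = 1, cs = list(),
                    pip = c(0.3, 0.1, 0.05, 0.05), region_id = "rA")
  two_cs <- fake_fit(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), V = c(1, 1),
                     cs = list(fake_cs(ids[1], "E1_C95", 1),
                               fake_cs(ids[2], "E2_C95", 2)),
                     region_id = "rB")
  one_cs <- fake_fit(rbind(c(1, 0, 0, 0)), V = 1,
                     cs = list(fake_cs(ids[4], "E1_C95", 1)),
                     region_id = "rC")
  d <- cs_diagnostics(list(rA = no_cs, rB = two_cs, rC = one_cs),
                      list(rA = R, rB = R, rC = R))
  expect_equal(d$fallback$variant_id, ids[1])  # top-PIP variant retained
  expect_equal(d$regions$class, c("none", "multi", "single"))
  expect_true(d$cs_pairs$flagged[1])           # r = 0.95 > 0.8
  expect_equal(d$cs_pairs$max_abs_r[1], 0.95)
})

test_that("fine-mapping fit methods behave like a model object", {
  R <- make_ld(30, "ar1", rho = 0.8)
  z <- simulate_trait_z(R, c("15" = 6), seed = tseed("methods"),
                        factor = genetier:::ld_factor(R))$z
  fit <- susie_rss(z, R)
  b <- coef(fit)
  expect_length(b, 30)
  expect_equal(unname(which.max(abs(b))), 15, tolerance = 2)
  expect_equal(unname(residuals(fit)), unname(z - as.vector(R %*% b)),
               tolerance = 1e-9)
  expect_output(print(fit), "fine-mapping")
  tab <- finemap_table(fit)
  expect_setequal(tab$variant_id, colnames(R))
})
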