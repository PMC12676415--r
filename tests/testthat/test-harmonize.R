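make_ss <- function(z, ref, alt, maf = 0.25, ids = NULL) {
  p <- length(z)
  sumstats("t", ids %||% sprintf("s%03d", seq_len(p)), z,
           ref = ref, alt = alt, maf = maf)
}

test_that("allele swap negates z and identity leaves it unchanged", {
  ss <- make_ss(c(2, 1.5), ref = c("A", "A"), alt = c("G", "G"))
  ref <- data.frame(variant_id = ss$variant_id,
                    ref = c("G", "A"), alt = c("A", "G"))
  out <- align_alleles(ss, ref)
  expect_equal(out$z, c(-2, 1.5))
  expect_equal(out$ref, c("G", "A"))
  expect_equal(out$alt, c("A", "G"))
})

test_that("allele reconciliation matches an exhaustive enumeration oracle", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  grid <- expand.grid(a1 = bases, a2 = bases, r1 = bases, r2 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$a1 != grid$a2 & grid$r1 != grid$r2, ]
  # oracle: list the orientations that reconcile, with their sign
  oracle <- function(a1, a2, r1, r2) {
    ambig <- paste(a1, a2) %in% c("A T", "T A", "C G", "G C")
    if (a1 == r1 && a2 == r2) return(1)
    if (a1 == r2 && a2 == r1) return(-1)
    if (!ambig && comp[a1] == r1 && comp[a2] == r2) return(1)
    if (!ambig && comp[a1] == r2 && comp[a2] == r1) return(-1)
    return(0)  # dropped
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ss <- make_ss(2, ref = g$a1, alt = g$a2)
    ref <- data.frame(variant_id = ss$variant_id, ref = g$r1, alt = g$r2)
    out <- align_alleles(ss, ref)
    exp_sign <- oracle(g$a1, g$a2, g$r1, g$r2)
    if (exp_sign == 0) {
      expect_equal(nrow(out), 0L)
      expect_equal(attr(out, "dropped"), ss$variant_id)
    } else {
      expect_equal(out$z, exp_sign * 2)
      expect_equal(out$ref, g$r1)
      expect_equal(out$alt, g$r2)
    }
  }
})

test_that("align_alleles is idempotent on its own output", {
  set.seed(tseed("align-idem"))
  ss <- make_ss(rnorm(20), ref = sample(c("A", "C"), 20, TRUE),
                alt = sample(c("G", "T"), 20, TRUE))
  ref <- data.frame(variant_id = ss$variant_id,
                    ref = sample(c("A", "C", "G", "T"), 20, TRUE),
                    alt = sample(c("A", "C", "G", "T"), 20, TRUE))
  ref <- ref[ref$ref != ref$alt, ]
  once <- align_alleles(ss, ref)
  twice <- align_alleles(once, ref)
  attr(once, "dropped") <- attr(twice, "dropped") <- NULL
  expect_equal(twice, once)
})

test_that("QC drops ambiguous variants and applies the strict MAF bound", {
  ss <- make_ss(c(1, 1, 1, 1),
                ref = c("A", "A", "A", "A"), alt = c("T", "G", "G", "G"),
                maf = c(0.3, 0.002, 0.0025, 0.3))
  out <- qc_filter(ss)
  expect_equal(out$report[["ambiguous"]], 1L)
  expect_equal(out$report[["maf"]], 1L)
  expect_setequal(out$sumstats$variant_id, c("s003", "s004"))
})

test_that("clean input passes QC unchanged and duplicates are removed", {
  ss <- make_ss(c(1, 2), ref = c("A", "C"), alt = c("G", "T"))
  out <- qc_filter(ss)
  expect_equal(out$sumstats, ss, ignore_attr = TRUE)
  expect_true(all(out$report == 0))

  dup <- rbind(ss, ss[1, ])
  out2 <- qc_filter(dup)
  expect_equal(out2$report[["duplicate"]], 1L)
  expect_equal(nrow(out2$sumstats), 2L)
})

test_that("consistent signals pass the z/LD outlier check, isolated ones fail", {
  R <- make_ld(30, "ar1", rho = 0.9)
  lambda <- numeric(30); lambda[15] <- 6
  z <- as.vector(R %*% lambda)           # noise-free, perfectly consistent
  expect_length(detect_ld_outliers(z, R), 0L)

  I5 <- make_ld(5, "identity")
  z2 <- c(0.5, 5, 0.1, -0.3, 0.2)        # E[z_i | z_-i] = 0 under identity
  expect_equal(unname(detect_ld_outliers(z2, I5)), 2L)
  expect_length(detect_ld_outliers(c(1, 2), make_ld(2, "identity")), 0L)
})

test_that("sign-corrupted variants in strong LD are flagged reliably", {
  R <- make_ld(50, "ar1", rho = 0.95)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("outlier-sim"))
  flagged <- vapply(1:100, function(i) {
    z <- simulate_trait_z(R, c("25" = 6), factor = fac)$z
    z[25] <- -z[25]
    25 %in% detect_ld_outliers(z, R)
  }, logical(1))
  expect_gte(mean(flagged), 0.90)
})

test_that("imputation handles the identity, perfect-proxy and zero-information cases", {
  R <- make_ld(4, "identity")
  out <- impute_z(c(1, 2, 3, 4), R, 1:4)
  expect_equal(out$z, c(1, 2, 3, 4))
  expect_length(out$imputed, 0L)

  Rp <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  out2 <- impute_z(4, Rp, obs_idx = 2, min_neighbors = 1)
  expect_equal(out2$z[1], 4, tolerance = 1e-8)
  expect_equal(out2$quality[1], 1, tolerance = 1e-8)

  out3 <- impute_z(c(4, 1, 0), make_ld(4, "identity"), obs_idx = 2:4,
                   min_neighbors = 1)
  expect_true(is.na(out3$z[1]))
  expect_lt(out3$quality[1], 0.6)
})

test_that("imputation quality is bounded and accurate under strong LD", {
  R <- make_ld(100, "ar1", rho = 0.9)
  fac <- genetier:::ld_factor(R)
  set.seed(tseed("impute-sim"))
  cors <- c(); quals <- c()
  for (i in 1:20) {
    z <- simulate_trait_z(R, c("50" = 5), factor = fac)$z
    mask <- sample(100, 10)
    obs <- setdiff(1:100, mask)
    out <- impute_z(z[obs], R, obs)
    quals <- c(quals, out$quality[mask])
    got <- out$z[mask]
    keep <- !is.na(got)
    if (sum(keep) >= 3) cors <- c(cors, cor(got[keep], z[mask][keep]))
  }
  expect_true(all(quals >= 0 & quals <= 1 + 1e-8))
  expect_gte(mean(cors), 0.8)
})

test_that("the harmonization chain reports counts that add up", {
  R <- make_ld(80, "ar1", rho = 0.9)
  cfg <- sim_config(n_regions = 1, variants_per_region = 80,
                    maf_low_frac = 0.05, ambig_frac = 0.05, seed = 11)
  study <- simulate_study(cfg)
  ss <- study$sumstats$DNE1$region01
  h <- harmonize_sumstats(ss, study$ld$region01)
  expect_gte(h$report$counts[["ambiguous"]], 1)
  expect_gte(h$report$counts[["maf"]], 1)
  expect_equal(h$report$n_input - sum(h$report$counts), h$report$n_retained)
  # retained records identical to their input rows
  kept <- merge(h$sumstats, ss, by = "variant_id")
  expect_equal(kept$z.x, kept$z.y)
})
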