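test_that("generators are deterministic given scenario and seed", {
  scn <- scenario_library("null", seed = 3)
  p1 <- simulate_reference_panel(scn, seed = 12)
  p2 <- simulate_reference_panel(scn, seed = 12)
  expect_identical(p1$dosage, p2$dosage)
  g1 <- simulate_protein_gwas(scn, seed = 12)
  g2 <- simulate_protein_gwas(scn, seed = 12)
  expect_identical(g1$A$data, g2$A$data)
  o1 <- simulate_outcome_gwas(scn, seed = 12)
  o2 <- simulate_outcome_gwas(scn, seed = 12)
  expect_identical(o1$data, o2$data)
  g3 <- simulate_protein_gwas(scn, seed = 13)
  expect_false(identical(g1$A$data$beta, g3$A$data$beta))
})

test_that("realised allele frequencies track their targets at n = 10,000", {
  scn <- sim_scenario(n_blocks = 2, block_size = 10, n_causal_cis = 1,
                      panel_n = 10000, seed = 6)
  panel <- simulate_reference_panel(scn)
  f_hat <- colMeans(panel$dosage) / 2
  expect_true(all(abs(f_hat - scn$variants$maf) < 0.03))
})

test_that("LD structure follows the block-AR(1) model with attenuation", {
  # independent blocks: cross-block |r| below sampling noise
  scn0 <- sim_scenario(n_blocks = 2, block_size = 5, rho = 0,
                       n_causal_cis = 1, panel_n = 10000, seed = 10)
  R0 <- ld_corr(simulate_reference_panel(scn0), scn0$variants$key)
  off <- R0[upper.tri(R0)]
  expect_true(all(abs(off) < 0.05))
  # rho = 0.9 adjacent pairs: dichotomisation attenuates the latent
  # correlation; compare against an analytic oracle for the dosage
  # correlation of a thresholded bivariate normal
  dosage_corr_oracle <- function(rho, f1, f2) {
    upper_quadrant <- function(a, b) {
      stats::integrate(function(z)
        dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2),
                         lower.tail = FALSE),
        lower = a, upper = Inf, rel.tol = 1e-10)$value
    }
    thr <- function(f) qnorm(c((1 - f)^2, (1 - f)^2 + 2 * f * (1 - f)))
    a <- thr(f1); b <- thr(f2)
    e12 <- sum(vapply(1:2, function(i) vapply(1:2, function(j)
      upper_quadrant(a[i], b[j]), 0.0), numeric(2)))
    (e12 - 4 * f1 * f2) /
      sqrt(4 * f1 * (1 - f1) * f2 * (1 - f2))
  }
  scn9 <- sim_scenario(n_blocks = 1, block_size = 10, rho = 0.9,
                       n_causal_cis = 1, panel_n = 10000, seed = 11)
  R9 <- ld_corr(simulate_reference_panel(scn9), scn9$variants$key)
  adj <- diag(R9[1:9, 2:10])
  f <- scn9$variants$maf
  expected <- vapply(1:9, function(i)
    dosage_corr_oracle(0.9, f[i], f[i + 1]), 0.0)
  expect_true(all(abs(adj - expected) < 0.05))
  # attenuation is real: realised r sits clearly below the latent rho
  expect_true(all(adj < 0.9 & adj > 0.5))
})

test_that("a 5% variance-explained pQTL reaches genome-wide significance
           at n = 20,000", {
  scn <- sim_scenario(n_blocks = 1, block_size = 6, n_causal_cis = 1,
                      causal_ve = 0.05, ve_spread = c(1, 1),
                      nA = 20000, seed = 14)
  ci <- scn$causal_idx
  p <- vapply(1:20, function(s) {
    gw <- simulate_protein_gwas(scn, seed = s)
    gw$A$data$pval[match(scn$variants$key[ci], gw$A$data$key)]
  }, 0.0)
  expect_gte(mean(p < 5e-8), 0.99)
})

test_that("null variants have uniform p-values and analytic SEs", {
  scn <- sim_scenario(n_blocks = 2, block_size = 5, n_causal_cis = 1,
                      causal_ve = 0.03, nA = 4000, nB = 1000, seed = 15)
  null_idx <- 10L  # last variant of the second (causal-free) block
  stats <- vapply(1:120, function(s) {
    gw <- simulate_protein_gwas(scn, seed = 3000 + s)
    d <- gw$A$data[match(scn$variants$key[null_idx], gw$A$data$key), ]
    c(d$pval, d$se, d$eaf)
  }, numeric(3))
  ks <- stats::ks.test(stats[1, ], "punif")
  expect_gt(ks$p.value, 0.01)
  # se close to 1/sqrt(n var(g)) at the null (protein variance is 1)
  se_analytic <- 1 / sqrt(4000 * 2 * stats[3, ] * (1 - stats[3, ]))
  expect_true(all(abs(stats[2, ] / se_analytic - 1) < 0.10))
})

test_that("the two cohorts give concordant effects at the causal variant", {
  scn <- scenario_library("null", seed = 16)
  ci <- scn$causal_idx[1]
  key <- scn$variants$key[ci]
  z <- vapply(1:50, function(s) {
    gw <- simulate_protein_gwas(scn, seed = 500 + s)
    a <- gw$A$data[match(key, gw$A$data$key), ]
    b <- gw$B$data[match(key, gw$B$data$key), ]
    heterogeneity_z(a$beta, a$se, b$beta, b$se)
  }, 0.0)
  expect_gte(mean(abs(z) < 3), 0.98)
})

test_that("binary outcomes give logistic summaries at the case fraction", {
  scn <- sim_scenario(n_blocks = 1, block_size = 6, n_causal_cis = 1,
                      causal_ve = 0.05, theta = 0.5, n_out = 4000,
                      outcome_type = "binary", case_fraction = 0.2,
                      seed = 17)
  out <- simulate_outcome_gwas(scn, seed = 17)
  expect_equal(out$trait_type, "binary")
  expect_true(all(out$data$se > 0))
  # the causal variant should show a positive log-odds association
  ci <- scn$causal_idx
  d <- out$data[match(scn$variants$key[ci], out$data$key), ]
  expect_gt(d$beta / d$se, 2)
})

test_that("the quantitative outcome recovers theta through the ratio", {
  scn <- scenario_library("causal", seed = 18)
  est <- vapply(1:30, function(s)
    mr_replicate(scn, seed = 700 + s)$results$estimate[1], 0.0)
  expect_lt(abs(mean(est) - 0.3), 3 * sd(est) / sqrt(length(est)))
})

test_that("the scenario library is closed over its names", {
  for (nm in c("null", "causal", "causal_shared", "causal_distinct",
               "underpowered_outcome", "pleiotropy_balanced",
               "pleiotropy_directional")) {
    scn <- scenario_library(nm, seed = 2)
    expect_s3_class(scn, "sim_scenario")
  }
  expect_equal(scenario_library("null")$theta, 0)
  shared <- scenario_library("causal_shared")
  expect_equal(shared$theta, 0.3)
  expect_length(shared$causal_idx, 1L)
  distinct <- scenario_library("causal_distinct")
  expect_false(is.na(distinct$outcome_variant))
  expect_length(scenario_library("multi_aptamer"), 5L)
  expect_error(scenario_library("nope"), "unknown scenario")
})
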