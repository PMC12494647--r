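test_that("the significance union is strict and cross-study", {
  dfA <- make_assoc_df(3, pval = c(1e-9, 5e-8, 0.2))
  dfB <- make_assoc_df(3, pval = c(0.3, 5e-8, 4e-8))
  a <- make_ss(dfA)
  b <- make_ss(dfB, study = "studyB")
  keys <- significant_union(a, b)
  expect_setequal(keys, a$data$key[c(1, 3)])  # 5e-8 exactly is excluded
})

test_that("cross-replication requires p < 0.05 and a consistent direction", {
  base <- list(effect_allele = "A", other_allele = "G", eaf = 0.3,
               key = "1:100:A:G")
  disc <- modifyList(base, list(beta = 0.30, pval = 1e-10, se = 0.02))
  expect_true(cross_replicate(disc, modifyList(base, list(
    beta = 0.05, pval = 0.03, se = 0.02))))
  expect_false(cross_replicate(disc, modifyList(base, list(
    beta = -0.05, pval = 0.001, se = 0.02))))
  expect_false(cross_replicate(disc, modifyList(base, list(
    beta = 0.05, pval = 0.05, se = 0.02))))  # exactly 0.05 is strict
  expect_false(cross_replicate(disc, modifyList(base, list(
    beta = 0, pval = 0.01, se = 0.02))))
  # swapped alleles are aligned before comparing directions
  swapped <- modifyList(base, list(effect_allele = "G", other_allele = "A",
                                   beta = -0.05, pval = 0.03, se = 0.02))
  expect_true(cross_replicate(disc, swapped))
  expect_error(cross_replicate(disc, modifyList(base, list(
    effect_allele = "A", other_allele = "C", beta = 0.1, pval = 0.01,
    se = 0.02))), "allele")
})

test_that("the heterogeneity z-statistic is the paired difference in SE units", {
  expect_equal(heterogeneity_z(0.5, 0.1, 0.2, 0.1), 0.3 / sqrt(0.02))
  expect_equal(round(heterogeneity_z(0.5, 0.1, 0.2, 0.1), 4), 2.1213)
  expect_equal(heterogeneity_z(0.4, 0.1, 0.4, 0.2), 0)
  expect_equal(round(heterogeneity_z(0.6, 0.1, 0.0, 0.1), 4), 4.2426)
  expect_error(heterogeneity_z(0.1, 0, 0.1, 0.1), "positive")
})

test_that("cis classification uses an inclusive 500 kb window", {
  gene <- list(chrom = "1", gene_start = 1000000, gene_end = 1050000)
  expect_equal(classify_cis_trans("1", 500000, gene), "cis")
  expect_equal(classify_cis_trans("1", 499999, gene), "trans")
  expect_equal(classify_cis_trans("1", 1550000, gene), "cis")
  expect_equal(classify_cis_trans("1", 1550001, gene), "trans")
  expect_equal(classify_cis_trans("2", 1000000, gene), "trans")
})

test_that("MHC membership is inclusive on chr6 26-34 Mb", {
  expect_true(in_mhc("6", 30000000))
  expect_true(in_mhc("6", 26000000))
  expect_true(in_mhc("6", 34000000))
  expect_false(in_mhc("6", 25999999))
  expect_false(in_mhc("6", 34000001))
  expect_false(in_mhc("7", 30000000))
})

test_that("variants on five or more aptamers are excluded, four are kept", {
  amap <- c("1:1:A:G" = 5L, "1:2:A:G" = 4L, "1:3:A:G" = 1L,
            "1:4:A:G" = 7L)
  expect_setequal(multi_aptamer_filter(amap), c("1:1:A:G", "1:4:A:G"))
  expect_length(multi_aptamer_filter(amap, max_aptamers = 7), 0L)
})

test_that("best-source selection takes the smaller p, ties go to study A", {
  a <- list(pval = 1e-10, beta = 0.2)
  b <- list(pval = 1e-8, beta = 0.25)
  expect_equal(select_best_source(a, b)$source, "A")
  expect_equal(select_best_source(list(pval = 1e-8), list(pval = 1e-8))$source,
               "A")
  expect_equal(select_best_source(list(pval = 1e-6), b)$source, "B")
  expect_equal(select_best_source(NULL, b)$source, "B")
  expect_error(select_best_source(NULL, NULL), "absent")
})

test_that("replication filtering applies each rule and counts losses", {
  # 6 variants: [1] replicates; [2] wrong direction in B; [3] p_B = 0.2;
  # [4] heterogeneous (|Z| >= 3); [5] ambiguous palindrome; [6] absent
  # from B (untestable, dropped by default)
  dfA <- make_assoc_df(6, pval = rep(1e-12, 6))
  dfA$beta <- c(0.3, 0.3, 0.3, 0.6, 0.3, 0.3)
  dfA$se <- rep(0.05, 6)
  dfA$effect_allele[5] <- "A"; dfA$other_allele[5] <- "T"
  dfA$eaf[5] <- 0.5
  dfB <- dfA
  dfB$pval <- c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001)
  dfB$beta <- c(0.28, -0.28, 0.3, 0.2, 0.3, 0.3)
  dfB$se <- rep(0.05, 6)
  a <- make_ss(dfA)
  b <- make_ss(dfB[-6, ], study = "studyB")
  rp <- replicated_pqtls(a, b)
  expect_equal(unname(rp$audit),
               c(6L, 1L, 1L, 2L, 1L))  # union, palindromic, untestable,
                                       # not_replicated, heterogeneous
  expect_equal(rp$records$key, variant_key("1", 110, "A", "G"))
  expect_equal(rp$records$source_study, "studyA")
})

test_that("untestable variants can be retained by flag", {
  dfA <- make_assoc_df(2, pval = c(1e-12, 1e-12))
  a <- make_ss(dfA)
  b <- make_ss(make_assoc_df(2, pval = c(0.001, 0.5))[1, ],
               study = "studyB")
  kept <- replicated_pqtls(a, b, keep_untestable = TRUE)
  dropped <- replicated_pqtls(a, b, keep_untestable = FALSE)
  expect_equal(nrow(kept$records), 2L)
  expect_equal(nrow(dropped$records), 1L)
  expect_equal(dropped$audit[["untestable"]], 1L)
})

test_that("best-source records carry the more significant study's stats", {
  dfA <- make_assoc_df(2, pval = c(1e-12, 1e-9))
  dfB <- make_assoc_df(2, pval = c(1e-8, 1e-14))
  dfB$beta <- dfA$beta + 0.01
  rp <- replicated_pqtls(make_ss(dfA), make_ss(dfB, study = "studyB"))
  expect_equal(rp$records$source_study, c("studyA", "studyB"))
  expect_equal(rp$records$beta[2], dfB$beta[2])
})

test_that("the full workflow recovers a single planted cis-pQTL", {
  scn <- sim_scenario(n_blocks = 1, block_size = 10, n_causal_cis = 1,
                      causal_ve = 0.05, seed = 5)
  hits <- vapply(1:40, function(s) {
    gw <- simulate_protein_gwas(scn, seed = s)
    panel <- simulate_reference_panel(scn, seed = s)
    inst <- build_instruments(gw$A, gw$B, scn$gene, panel)
    nrow(inst$cis) == 1L && nrow(inst$trans) == 0L &&
      inst$cis$key == scn$variants$key[scn$causal_idx]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("a causal variant inside the MHC is lost at the MHC stage", {
  scn <- sim_scenario(n_blocks = 1, block_size = 10, n_causal_cis = 1,
                      causal_ve = 0.05, chrom = "6",
                      gene_start = 30000000, gene_end = 30050000,
                      region_start = 29700000, seed = 8)
  gw <- simulate_protein_gwas(scn, seed = 8)
  panel <- simulate_reference_panel(scn, seed = 8)
  inst <- build_instruments(gw$A, gw$B, scn$gene, panel)
  expect_equal(nrow(inst$cis), 0L)
  expect_gt(inst$audit[["mhc"]], 0L)
})

test_that("correlated cis variants collapse to one instrument after clumping", {
  scn <- sim_scenario(n_blocks = 1, block_size = 6, rho = 0.95,
                      n_causal_cis = 1, causal_ve = 0.06, seed = 13)
  gw <- simulate_protein_gwas(scn, seed = 13)
  panel <- simulate_reference_panel(scn, seed = 13)
  inst <- build_instruments(gw$A, gw$B, scn$gene, panel)
  expect_equal(nrow(inst$cis), 1L)
  # and the instrument set invariant holds: pairwise r2 below threshold
  expect_gt(inst$audit[["clumped"]], 0L)
})

test_that("audit counters account for every variant in the union", {
  for (s in 1:5) {
    scn <- scenario_library("null", seed = s)
    gw <- simulate_protein_gwas(scn, seed = s)
    panel <- simulate_reference_panel(scn, seed = s)
    inst <- build_instruments(gw$A, gw$B, scn$gene, panel)
    au <- inst$audit
    expect_equal(
      au[["union"]],
      sum(au[c("palindromic", "untestable", "not_replicated",
               "heterogeneous", "no_ld", "clumped", "mhc",
               "multi_aptamer", "retained_cis", "retained_trans")])
    )
  }
})

test_that("retained instruments satisfy the set invariants", {
  scn <- scenario_library("null", seed = 21)
  gw <- simulate_protein_gwas(scn, seed = 21)
  panel <- simulate_reference_panel(scn, seed = 21)
  inst <- build_instruments(gw$A, gw$B, scn$gene, panel)
  expect_gt(nrow(inst$cis), 0L)
  expect_true(all(classify_cis_trans(inst$cis$chrom, inst$cis$pos,
                                     scn$gene) == "cis"))
  expect_false(any(in_mhc(inst$cis$chrom, inst$cis$pos)))
  if (nrow(inst$cis) > 1L) {
    R <- ld_corr(panel, inst$cis$key)
    expect_true(all(R[upper.tri(R)]^2 < 0.001))
  }
})

test_that("a pQTL shared by five aptamers is excluded at the aptamer stage", {
  ap <- simulate_aptamer_panel(seed = 2)
  rps <- lapply(ap$studies, function(st) replicated_pqtls(st$A, st$B))
  amap <- build_aptamer_map(lapply(rps, `[[`, "records"))
  expect_gte(unname(amap[ap$shared_key]), 5L)
  expect_true(ap$shared_key %in% multi_aptamer_filter(amap))
  for (k in seq_along(ap$studies)) {
    inst <- build_instruments(ap$studies[[k]]$A, ap$studies[[k]]$B,
                              ap$genes[k, ], ap$panel,
                              aptamer_map = amap, replicated = rps[[k]])
    expect_false(ap$shared_key %in% c(inst$cis$key, inst$trans$key))
    expect_gte(inst$audit[["multi_aptamer"]], 1L)
  }
})
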