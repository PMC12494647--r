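rec <- function(ea, oa, beta, eaf = 0.3, se = 0.05) {
  list(effect_allele = ea, other_allele = oa, beta = beta, eaf = eaf,
       se = se)
}

test_that("allele alignment covers swap, strand flip and orientation", {
  # already aligned
  h <- harmonise_pair(rec("A", "G", 0.2), rec("A", "G", -0.1))
  expect_false(h$dropped)
  expect_equal(c(h$beta_exp, h$beta_out), c(0.2, -0.1))
  # swapped outcome alleles negate the outcome beta
  h <- harmonise_pair(rec("A", "G", 0.2), rec("G", "A", 0.1))
  expect_equal(h$beta_out, -0.1)
  # negative exposure beta flips both (orientation convention)
  h <- harmonise_pair(rec("A", "G", -0.2), rec("A", "G", 0.1))
  expect_equal(c(h$beta_exp, h$beta_out), c(0.2, -0.1))
  # complementary-strand coding, same orientation
  h <- harmonise_pair(rec("A", "G", 0.2), rec("T", "C", 0.1))
  expect_equal(h$beta_out, 0.1)
  # complementary-strand coding with swap
  h <- harmonise_pair(rec("A", "G", 0.2), rec("C", "T", 0.1))
  expect_equal(h$beta_out, -0.1)
  # irreconcilable allele sets
  h <- harmonise_pair(rec("A", "G", 0.2), rec("A", "C", 0.1))
  expect_true(h$dropped)
  expect_equal(h$reason, "allele_mismatch")
})

test_that("palindromic pairs are resolved by frequency or dropped", {
  # clear frequencies, same allele coded: kept as-is
  h <- harmonise_pair(rec("A", "T", 0.2, eaf = 0.2),
                      rec("A", "T", 0.1, eaf = 0.22))
  expect_false(h$dropped)
  expect_equal(h$beta_out, 0.1)
  # outcome coded on the other strand: frequencies disagree, flip
  h <- harmonise_pair(rec("A", "T", 0.2, eaf = 0.2),
                      rec("A", "T", 0.1, eaf = 0.80))
  expect_equal(h$beta_out, -0.1)
  # near-0.5 frequency: ambiguous, dropped
  h <- harmonise_pair(rec("C", "G", 0.2, eaf = 0.47),
                      rec("C", "G", 0.1, eaf = 0.47))
  expect_true(h$dropped)
  expect_equal(h$reason, "palindromic_ambiguous")
  # missing frequency: dropped
  h <- harmonise_pair(rec("A", "T", 0.2, eaf = NA),
                      rec("A", "T", 0.1, eaf = 0.2))
  expect_true(h$dropped)
})

test_that("harmonisation preserves magnitudes and the Wald ratio is
           orientation-invariant", {
  set.seed(4)
  for (i in 1:40) {
    beta_x <- rnorm(1)
    beta_y <- rnorm(1, 0, 0.2)
    x <- rec("A", "G", beta_x, eaf = runif(1, 0.05, 0.95))
    y <- rec("A", "G", beta_y, eaf = x$eaf, se = runif(1, 0.01, 0.1))
    h0 <- harmonise_pair(x, y)
    # flip the stored orientation of the outcome record
    yf <- rec("G", "A", -beta_y, eaf = 1 - x$eaf, se = y$se)
    h1 <- harmonise_pair(x, yf)
    # and of the exposure record
    xf <- rec("G", "A", -beta_x, eaf = 1 - x$eaf)
    h2 <- harmonise_pair(xf, y)
    for (h in list(h0, h1, h2)) {
      expect_false(h$dropped)
      expect_equal(abs(h$beta_exp), abs(beta_x))
      expect_equal(abs(h$beta_out), abs(beta_y))
      expect_gt(h$beta_exp, 0)
      expect_equal(h$beta_out / h$beta_exp, beta_y / beta_x)
      expect_equal(h$se_exp, x$se)
    }
  }
})

# a small three-instrument world with one proxy-capable extra variant
make_proxy_world <- function(outcome_has = c(TRUE, TRUE, TRUE),
                             proxy_corr = 0.98) {
  keys <- c("1:1000:A:G", "1:2000:C:T", "1:3000:A:C", "1:1100:G:T")
  Sigma <- diag(4)
  Sigma[1, 4] <- Sigma[4, 1] <- proxy_corr  # variant 4 tags variant 1
  panel <- make_corr_panel(keys, Sigma, n = 4000, seed = 77,
                           effect_allele = c("A", "C", "A", "G"))
  inst_df <- data.frame(
    key = keys[1:3], snp = paste0("rs", 1:3), chrom = "1",
    pos = c(1000, 2000, 3000),
    effect_allele = c("A", "C", "A"), other_allele = c("G", "T", "C"),
    eaf = 0.3, beta = c(0.3, 0.25, 0.2), se = 0.02,
    pval = 1e-20, n = 10000, source_study = "studyA",
    cis_trans = "cis", stringsAsFactors = FALSE
  )
  pool <- rbind(inst_df, data.frame(
    key = keys[4], snp = "rs4", chrom = "1", pos = 1100,
    effect_allele = "G", other_allele = "T", eaf = 0.3, beta = 0.29,
    se = 0.02, pval = 1e-18, n = 10000, source_study = "studyA",
    cis_trans = "cis", stringsAsFactors = FALSE
  ))
  instr <- structure(list(protein_id = "P1",
                          gene = list(chrom = "1", gene_start = 1,
                                      gene_end = 5000),
                          cis = inst_df, trans = inst_df[0, ],
                          audit = c(union = 4L)),
                     class = "instrument_set")
  out_keys <- c(keys[1:3][outcome_has], keys[4])
  out_df <- pool[pool$key %in% out_keys, ]
  out_df$beta <- out_df$beta * 0.5 + 0.01
  outcome <- make_ss(out_df[, c("snp", "chrom", "pos", "effect_allele",
                                "other_allele", "eaf", "beta", "se",
                                "pval", "n")],
                     study = "out_study", trait = "outcome")
  list(panel = panel, instr = instr, pool = pool, outcome = outcome)
}

test_that("instruments present in the outcome are all harmonised", {
  w <- make_proxy_world()
  hs <- attach_outcome(w$instr, w$outcome, w$panel, proxy_pool = w$pool)
  expect_equal(nrow(hs$records), 3L)
  expect_true(all(is.na(hs$records$proxy_used)))
  expect_equal(hs$n_missing_no_proxy, 0L)
})

test_that("a missing instrument is replaced by a strong proxy", {
  w <- make_proxy_world(outcome_has = c(FALSE, TRUE, TRUE))
  hs <- attach_outcome(w$instr, w$outcome, w$panel, proxy_pool = w$pool)
  expect_equal(nrow(hs$records), 3L)
  pr <- hs$records[!is.na(hs$records$proxy_used), ]
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$proxy_used, "1:1100:G:T")
  expect_gt(pr$proxy_r2, 0.8)
  # both sides are measured at the proxy variant itself
  expect_equal(pr$beta_exp, 0.29)
})

test_that("a weak proxy does not qualify and the loss is counted", {
  w <- make_proxy_world(outcome_has = c(FALSE, TRUE, TRUE),
                        proxy_corr = sqrt(0.5))
  hs <- attach_outcome(w$instr, w$outcome, w$panel, proxy_pool = w$pool)
  expect_equal(nrow(hs$records), 2L)
  expect_equal(hs$n_missing_no_proxy, 1L)
})
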