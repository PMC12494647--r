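# Small in-code fixtures shared across test files.

# A well-formed association data frame (n rows, deterministic)
make_assoc_df <- function(n = 3, chrom = "1", pos0 = 100, pval = NULL) {
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  idx <- ((seq_len(n) - 1L) %% 4L) + 1L
  data.frame(
    snp = paste0("rs", seq_len(n)),
    chrom = chrom,
    pos = pos0 + seq_len(n) * 10L,
    effect_allele = vapply(pairs[idx], `[`, "", 1L),
    other_allele = vapply(pairs[idx], `[`, "", 2L),
    eaf = seq(0.1, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.05, n),
    pval = if (is.null(pval)) rep(1e-10, n) else pval,
    n = rep(10000L, n),
    stringsAsFactors = FALSE
  )
}

make_ss <- function(df, study = "studyA", trait = "P1",
                    type = "quantitative") {
  as_sumstats(df, study_label = study, trait_label = trait,
              trait_type = type)
}

# Reference panel with prescribed pairwise latent correlation structure:
# columns built from shared standard normal factors (continuous "dosages"
# are fine for correlation tests).
make_corr_panel <- function(keys, Sigma, n = 2000, seed = 42,
                            effect_allele = NULL) {
  set.seed(seed)
  Z <- matrix(rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
  # shift/scale into a dosage-like range (irrelevant to correlations)
  D <- 1 + 0.4 * Z
  reference_panel(D, keys, effect_allele = effect_allele)
}

# Harmonised set from raw vectors
make_hs <- function(beta_exp, se_exp, beta_out, se_out,
                    protein = "P1", outcome = "out") {
  k <- length(beta_exp)
  structure(
    list(protein_id = protein, outcome_label = outcome,
         trait_type = "quantitative",
         records = data.frame(
           key = sprintf("1:%d:A:G", 100 + seq_len(k)),
           beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
           beta_out = rep_len(beta_out, k),
           se_out = rep_len(se_out, k),
           proxy_used = rep(NA_character_, k),
           proxy_r2 = rep(NA_real_, k),
           stringsAsFactors = FALSE)),
    class = "harmonised_set"
  )
}

# Independent re-derivation of greedy clumping used as a brute-force
# oracle on small instances: repeatedly take the most significant
# remaining variant (ties by key), then verify/discard each remaining
# variant one at a time against the full retained set.
clump_oracle <- function(assocs, ld, r2_max, window_kb) {
  df <- assocs[order(assocs$pval, assocs$key), , drop = FALSE]
  parts <- strsplit(df$key, ":", fixed = TRUE)
  df$chrom <- vapply(parts, `[`, "", 1L)
  df$pos <- as.integer(vapply(parts, `[`, "", 2L))
  kept <- df[0L, ]
  while (nrow(df) > 0L) {
    top <- df[1L, ]
    kept <- rbind(kept, top)
    df <- df[-1L, , drop = FALSE]
    if (nrow(df) == 0L) break
    conflict <- df$chrom == top$chrom &
      abs(df$pos - top$pos) <= window_kb * 1000 &
      ld[top$key, df$key]^2 >= r2_max
    df <- df[!conflict, , drop = FALSE]
  }
  kept$key
}

# Declarative check of the greedy-clump definition: a variant is retained
# iff no strictly-more-significant retained variant conflicts with it.
is_greedy_solution <- function(kept, assocs, ld, r2_max, window_kb) {
  parts <- strsplit(assocs$key, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  rank_of <- order(order(assocs$pval, assocs$key))
  for (i in seq_len(nrow(assocs))) {
    conflicts <- which(
      chrom == chrom[i] & abs(pos - pos[i]) <= window_kb * 1000 &
        ld[assocs$key[i], assocs$key]^2 >= r2_max &
        rank_of < rank_of[i] & assocs$key %in% kept
    )
    in_set <- assocs$key[i] %in% kept
    if (in_set && length(conflicts) > 0L) return(FALSE)
    if (!in_set && length(conflicts) == 0L) return(FALSE)
  }
  TRUE
}

# z-score draw for summary-level fine-mapping tests: z ~ N(R lambda, R)
draw_z <- function(R, lambda, seed) {
  set.seed(seed)
  as.vector(R %*% lambda + chol(R + diag(1e-8, nrow(R))) %*%
              rnorm(nrow(R)))
}

ar1_mat <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), `-`))
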