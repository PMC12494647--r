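## Non-palindromic allele pairs cycled over variants; palindromic records
## for testing the ambiguity filter are constructed explicitly in tests.
ALLELE_PAIRS <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))

#' Define a simulation scenario
#'
#' A scenario fixes everything about a synthetic study: the variant map
#' (LD blocks with AR(1) correlation, allele frequencies, positions in a
#' cis window around a protein-coding gene), the causal architecture of
#' the protein in two independent pQTL cohorts, and an outcome with a
#' configurable causal effect of the protein, optional horizontal
#' pleiotropy acting directly through the instruments, and optionally a
#' distinct outcome-only causal variant. Variant metadata (positions,
#' alleles, frequencies, causal effect sizes) are drawn once,
#' deterministically, from `seed`; cohort draws use the seed passed to the
#' `simulate_*` functions.
#'
#' @param n_blocks,block_size LD structure: `n_blocks` blocks of
#'   `block_size` variants with AR(1) correlation `rho` inside each block
#'   and independence across blocks.
#' @param rho AR(1) correlation of the latent Gaussian (the realised
#'   dosage correlation is attenuated by dichotomisation).
#' @param maf_range Allele frequencies drawn uniformly from this range.
#' @param n_causal_cis Number of causal cis variants (one per block, at
#'   the block centre, starting from the first block).
#' @param causal_ve Protein variance explained per causal variant.
#' @param ve_spread Per-variant variance explained is
#'   `causal_ve * U(ve_spread[1], ve_spread[2])`, so instrument strengths
#'   vary (a spread of exposure effects is required for MR-Egger's
#'   regression to be identified).
#' @param theta Causal effect of the (standardised) protein on the
#'   standardised outcome.
#' @param pleiotropy `"none"`, `"balanced"` (direct variant effects on
#'   the outcome with mean zero) or `"directional"` (mean `pleio_mean`).
#' @param pleio_mean,pleio_sd Normal distribution of the direct
#'   per-allele variant effects on the outcome (drawn independently of
#'   the protein effects, so the InSIDE condition holds).
#' @param outcome_variant Index of a variant given a direct effect on the
#'   outcome regardless of the protein (distinct-causal-variant coloc
#'   scenarios), or `NA`.
#' @param outcome_variant_ve Outcome variance explained by that variant.
#' @param nA,nB,n_out,panel_n Sample sizes of pQTL cohort A, pQTL cohort
#'   B, the outcome cohort, and the LD reference panel.
#' @param outcome_type `"quantitative"` or `"binary"` (liability
#'   threshold at `case_fraction`, logistic-regression summaries).
#' @param case_fraction Case fraction for binary outcomes.
#' @param chrom,gene_start,gene_end,region_start,spacing Genomic layout;
#'   variants are placed from `region_start` every `spacing` bp, inside
#'   the cis window of the gene.
#' @param protein_id,label Identifiers.
#' @param seed Scenario seed (variant map and effect sizes).
#' @return A `sim_scenario` list, including the realised `variants` table
#'   and per-dosage causal effects.
#' @export
sim_scenario <- function(n_blocks = 3, block_size = 10, rho = 0.5,
                         maf_range = c(0.15, 0.45), n_causal_cis = 3,
                         causal_ve = 0.03, ve_spread = c(0.5, 1.5),
                         theta = 0,
                         pleiotropy = c("none", "balanced", "directional"),
                         pleio_mean = 0.03, pleio_sd = 0.05,
                         outcome_variant = NA_integer_,
                         outcome_variant_ve = 0.005,
                         nA = 10000, nB = 6000, n_out = 10000,
                         panel_n = 2000,
                         outcome_type = c("quantitative", "binary"),
                         case_fraction = 0.1, chrom = "1",
                         gene_start = 1000000, gene_end = 1050000,
                         region_start = 700000, spacing = 5000,
                         protein_id = "P1", label = "scenario",
                         seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_causal_cis <= n_blocks, rho >= 0, rho < 1)
  m <- n_blocks * block_size

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  maf <- runif(m, maf_range[1], maf_range[2])
  pos <- region_start + (seq_len(m) - 1L) * spacing
  pair <- ALLELE_PAIRS[((seq_len(m) - 1L) %% 4L) + 1L]
  ea <- vapply(pair, `[`, "", 1L)
  oa <- vapply(pair, `[`, "", 2L)
  variants <- data.frame(
    snp = paste0("rs", protein_id, "_", seq_len(m)),
    chrom = chrom, pos = pos, ea = ea, oa = oa, maf = maf,
    block = rep(seq_len(n_blocks), each = block_size),
    stringsAsFactors = FALSE
  )
  variants$key <- variant_key(variants$chrom, variants$pos, ea, oa)

  causal_idx <- integer(0)
  if (n_causal_cis > 0)
    causal_idx <- (seq_len(n_causal_cis) - 1L) * block_size +
      ceiling(block_size / 2)
  # spread the per-variant variance explained so instrument strengths vary
  ve <- causal_ve * runif(length(causal_idx), ve_spread[1], ve_spread[2])
  beta_cis <- sqrt(ve / (2 * maf[causal_idx] * (1 - maf[causal_idx])))

  structure(
    list(label = label, seed = seed, protein_id = protein_id,
         variants = variants, n_blocks = n_blocks,
         block_size = block_size, rho = rho,
         causal_idx = causal_idx, beta_cis = beta_cis,
         causal_ve = causal_ve, ve = ve, theta = theta,
         pleiotropy = pleiotropy, pleio_mean = pleio_mean,
         pleio_sd = pleio_sd,
         outcome_variant = outcome_variant,
         outcome_variant_ve = outcome_variant_ve,
         nA = nA, nB = nB, n_out = n_out, panel_n = panel_n,
         outcome_type = outcome_type, case_fraction = case_fraction,
         gene = data.frame(protein_id = protein_id,
                           gene_symbol = paste0("GENE_", protein_id),
                           chrom = chrom, gene_start = gene_start,
                           gene_end = gene_end,
                           stringsAsFactors = FALSE)),
    class = "sim_scenario"
  )
}

## Dosage matrix (n x m) under the scenario's LD model: latent MVN with
## block AR(1) correlation, dichotomised at Hardy-Weinberg quantiles so
## the marginal dosage is Binomial(2, maf).
simulate_genotypes <- function(scn, n) {
  m <- nrow(scn$variants)
  G <- matrix(0, n, m)
  for (b in seq_len(scn$n_blocks)) {
    idx <- which(scn$variants$block == b)
    k <- length(idx)
    S <- scn$rho^abs(outer(seq_len(k), seq_len(k), `-`))
    Z <- matrix(rnorm(n * k), n, k) %*% chol(S)
    U <- pnorm(Z)
    f <- scn$variants$maf[idx]
    q0 <- rep((1 - f)^2, each = n)
    q1 <- rep((1 - f)^2 + 2 * f * (1 - f), each = n)
    G[, idx] <- (U > q0) + (U > q1)
  }
  G
}

#' Simulate an LD reference panel for a scenario
#'
#' @param scn A `sim_scenario`.
#' @param seed Draw seed (defaults to the scenario seed).
#' @return A `ref_panel` whose dosages count the scenario's effect
#'   alleles.
#' @export
simulate_reference_panel <- function(scn, seed = scn$seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 101L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  G <- simulate_genotypes(scn, scn$panel_n)
  reference_panel(G, scn$variants$key, effect_allele = scn$variants$ea)
}

## Rank-based inverse normal transform
inverse_normal <- function(y) {
  qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

## Marginal per-variant OLS of y on each dosage column; closed form,
## vectorised (one regression per variant, as in a GWAS).
marginal_gwas <- function(G, y) {
  n <- length(y)
  yc <- y - mean(y)
  gc <- sweep(G, 2L, colMeans(G))
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[p == 0] <- .Machine$double.xmin
  list(beta = beta, se = se, pval = p)
}

## Per-variant logistic regression summaries
logistic_gwas <- function(G, y) {
  m <- ncol(G)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    X <- cbind(1, G[, j])
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    beta[j] <- fit$coefficients[2L]
    XtWX <- crossprod(X * sqrt(fit$weights))
    se[j] <- sqrt(chol2inv(chol(XtWX))[2L, 2L])
  }
  p <- 2 * pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin
  list(beta = beta, se = se, pval = p)
}

protein_value <- function(scn, G) {
  genetic <- if (length(scn$causal_idx) > 0)
    as.vector(G[, scn$causal_idx, drop = FALSE] %*% scn$beta_cis)
  else rep(0, nrow(G))
  noise_var <- max(1 - sum(scn$ve), 0.05)
  genetic + rnorm(nrow(G), 0, sqrt(noise_var))
}

gwas_to_sumstats <- function(scn, G, stats, study_label, trait_label,
                             trait_type, n) {
  v <- scn$variants
  as_sumstats(data.frame(
    snp = v$snp, chrom = v$chrom, pos = v$pos,
    effect_allele = v$ea, other_allele = v$oa,
    eaf = colMeans(G) / 2, beta = stats$beta, se = stats$se,
    pval = stats$pval, n = n, stringsAsFactors = FALSE
  ), study_label = study_label, trait_label = trait_label,
  trait_type = trait_type)
}

#' Simulate the two pQTL cohorts for a scenario
#'
#' Two independent cohorts measure the same protein. The protein is the
#' sum of causal dosage effects plus Gaussian noise (total variance one),
#' rank-based inverse-normal transformed before per-variant marginal
#' regression, mirroring how proteomic GWAS analyse SomaScan-style
#' measures.
#'
#' @inheritParams simulate_reference_panel
#' @return List with `A` and `B`, each a `sumstats` object.
#' @export
simulate_protein_gwas <- function(scn, seed = scn$seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 202L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sim_one <- function(n, lab) {
    G <- simulate_genotypes(scn, n)
    y <- inverse_normal(protein_value(scn, G))
    gwas_to_sumstats(scn, G, marginal_gwas(G, y), lab, scn$protein_id,
                     "quantitative", n)
  }
  list(A = sim_one(scn$nA, "studyA"), B = sim_one(scn$nB, "studyB"))
}

#' Simulate the outcome GWAS for a scenario
#'
#' An independent cohort in which the outcome is `theta` times the
#' (standardised) protein plus any direct variant effects (horizontal
#' pleiotropy through the instruments, or a distinct outcome-only causal
#' variant), plus noise scaled so the quantitative outcome has unit
#' variance. Binary outcomes are generated by thresholding the liability
#' at the scenario's case fraction and summarised by per-variant logistic
#' regression on the log-odds scale.
#'
#' @inheritParams simulate_reference_panel
#' @return A `sumstats` object for the outcome trait.
#' @export
simulate_outcome_gwas <- function(scn, seed = scn$seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 303L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n <- scn$n_out
  G <- simulate_genotypes(scn, n)
  protein <- protein_value(scn, G)

  direct <- rep(0, n)
  var_direct <- 0
  if (length(scn$causal_idx) > 0 && scn$pleiotropy != "none") {
    # direct per-allele effects on the outcome, redrawn per cohort and
    # independent of the instrument's protein effect (InSIDE holds); the
    # Egger intercept estimates their mean
    mu <- if (scn$pleiotropy == "directional") scn$pleio_mean else 0
    delta <- rnorm(length(scn$causal_idx), mu, scn$pleio_sd)
    direct <- direct + as.vector(G[, scn$causal_idx, drop = FALSE] %*% delta)
    var_direct <- var_direct +
      sum(delta^2 * 2 * scn$variants$maf[scn$causal_idx] *
            (1 - scn$variants$maf[scn$causal_idx]))
  }
  if (!is.na(scn$outcome_variant)) {
    j <- scn$outcome_variant
    gamma <- sqrt(scn$outcome_variant_ve /
                    (2 * scn$variants$maf[j] * (1 - scn$variants$maf[j])))
    direct <- direct + gamma * G[, j]
    var_direct <- var_direct + scn$outcome_variant_ve
  }

  liability <- scn$theta * protein + direct
  noise_var <- max(1 - scn$theta^2 - var_direct, 0.05)
  liability <- liability + rnorm(n, 0, sqrt(noise_var))

  if (scn$outcome_type == "binary") {
    y <- as.integer(liability > quantile(liability, 1 - scn$case_fraction))
    st <- logistic_gwas(G, y)
  } else {
    st <- marginal_gwas(G, liability)
  }
  gwas_to_sumstats(scn, G, st, "outcome_study", paste0(scn$label, "_outcome"),
                   scn$outcome_type, n)
}

#' Simulate a complete single-protein study
#'
#' Convenience wrapper drawing the reference panel, both pQTL cohorts and
#' the outcome GWAS for one scenario and seed.
#'
#' @inheritParams simulate_reference_panel
#' @return List with `scn`, `panel`, `gene`, `study_a`, `study_b`,
#'   `outcome`.
#' @export
simulate_study <- function(scn, seed = scn$seed) {
  gw <- simulate_protein_gwas(scn, seed)
  list(scn = scn, panel = simulate_reference_panel(scn, seed),
       gene = scn$gene, study_a = gw$A, study_b = gw$B,
       outcome = simulate_outcome_gwas(scn, seed))
}

#' Named library of study scenarios
#'
#' Fully parameterised scenarios exercising each rule of the analysis:
#' \describe{
#'   \item{null}{Three independent strong cis-pQTLs, no causal effect of
#'     the protein on the outcome (type-I error checks).}
#'   \item{causal_shared}{One strong cis causal variant in a dense LD
#'     region driving both the protein and the outcome (theta = 0.3);
#'     colocalisation should support H4.}
#'   \item{causal_distinct}{Protein and outcome each driven by a
#'     different, unlinked variant in the region; H3 should dominate.}
#'   \item{underpowered_outcome}{As causal_shared but with a very small
#'     outcome cohort; H1 should dominate.}
#'   \item{pleiotropy_balanced}{Twelve instruments with direct outcome
#'     effects of mean zero (weighted median robustness).}
#'   \item{pleiotropy_directional}{Fifty instruments with direct outcome
#'     effects of mean 0.03 (MR-Egger intercept recovery).}
#'   \item{multi_aptamer}{Five proteins sharing one planted trans-pQTL
#'     (exercises the five-or-more-aptamer exclusion); see
#'     [simulate_aptamer_panel()].}
#' }
#'
#' @param name Scenario name.
#' @param seed Scenario seed.
#' @return A `sim_scenario` (for `multi_aptamer`, a list of five).
#' @export
scenario_library <- function(name, seed = 1L) {
  switch(
    name,
    null = sim_scenario(n_blocks = 3, block_size = 10, rho = 0.5,
                        n_causal_cis = 3, causal_ve = 0.03, theta = 0,
                        label = "null", seed = seed),
    causal = sim_scenario(n_blocks = 3, block_size = 10, rho = 0.5,
                          n_causal_cis = 3, causal_ve = 0.03,
                          theta = 0.3, label = "causal", seed = seed),
    causal_shared = sim_scenario(
      n_blocks = 8, block_size = 15, rho = 0.9, n_causal_cis = 1,
      causal_ve = 0.05, theta = 0.3, panel_n = 4000, spacing = 2000,
      label = "causal_shared", seed = seed),
    causal_distinct = sim_scenario(
      n_blocks = 8, block_size = 15, rho = 0.9, n_causal_cis = 1,
      causal_ve = 0.05, theta = 0, outcome_variant = 83L,
      outcome_variant_ve = 0.005, panel_n = 4000, spacing = 2000,
      label = "causal_distinct", seed = seed),
    underpowered_outcome = sim_scenario(
      n_blocks = 8, block_size = 15, rho = 0.9, n_causal_cis = 1,
      causal_ve = 0.05, theta = 0.3, n_out = 50, panel_n = 4000,
      spacing = 2000, label = "underpowered_outcome", seed = seed),
    pleiotropy_balanced = sim_scenario(
      n_blocks = 12, block_size = 5, rho = 0.5, n_causal_cis = 12,
      causal_ve = 0.015, theta = 0.3, pleiotropy = "balanced",
      pleio_sd = 0.05, panel_n = 4000, spacing = 3000,
      label = "pleiotropy_balanced", seed = seed),
    pleiotropy_directional = sim_scenario(
      n_blocks = 50, block_size = 3, rho = 0.5, n_causal_cis = 50,
      causal_ve = 0.01, ve_spread = c(0.2, 1.8), theta = 0.3,
      pleiotropy = "directional", pleio_mean = 0.03, pleio_sd = 0.01,
      panel_n = 4000, spacing = 3000,
      label = "pleiotropy_directional", seed = seed),
    multi_aptamer = simulate_aptamer_scenarios(seed),
    stop("unknown scenario '", name, "'; options: null, causal, ",
         "causal_shared, causal_distinct, underpowered_outcome, ",
         "pleiotropy_balanced, pleiotropy_directional, multi_aptamer")
  )
}

#' Simulate inputs for a proteome-wide scan
#'
#' A panel of proteins, each with its own gene region and LD blocks on
#' its own chromosome, two pQTL cohorts per protein, and a single outcome
#' cohort GWAS'd over every protein's variants. At most one protein is
#' causal for the outcome (`theta`), with an optional shared causal
#' variant so that colocalisation follow-up can confirm it.
#'
#' @param n_proteins Number of proteins.
#' @param causal_protein Index of the causal protein (0 for none).
#' @param theta Causal effect of that protein on the outcome.
#' @param seed Seed for the whole input set.
#' @param scenario_fun Function `(k, theta, seed)` returning the
#'   `sim_scenario` for protein `k`; the default gives each protein three
#'   cis instruments.
#' @return List with `studies`, `genes`, `outcomes`, `panel`, `scns` —
#'   ready for [scan_config()].
#' @export
simulate_scan_inputs <- function(n_proteins = 20, causal_protein = 1,
                                 theta = 0.3, seed = 1L,
                                 scenario_fun = NULL) {
  if (is.null(scenario_fun))
    scenario_fun <- function(k, th, sd)
      sim_scenario(n_blocks = 3, block_size = 10, rho = 0.5,
                   n_causal_cis = 3, causal_ve = 0.03, theta = th,
                   chrom = as.character(k),
                   protein_id = sprintf("P%02d", k),
                   label = "scan", seed = sd)
  scns <- lapply(seq_len(n_proteins), function(k)
    scenario_fun(k, if (k == causal_protein) theta else 0, seed + 7L * k))

  studies <- lapply(scns, simulate_protein_gwas)
  names(studies) <- vapply(scns, function(s) s$protein_id, "")
  genes <- do.call(rbind, lapply(scns, function(s) s$gene))

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 505L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # one outcome cohort covering every protein's variants
  n_out <- scns[[1L]]$n_out
  Gs <- lapply(scns, simulate_genotypes, n = n_out)
  liability <- rnorm(n_out, 0, 1)
  if (causal_protein >= 1L) {
    cs <- scns[[causal_protein]]
    protein <- protein_value(cs, Gs[[causal_protein]])
    noise_var <- max(1 - cs$theta^2, 0.05)
    liability <- cs$theta * protein + rnorm(n_out, 0, sqrt(noise_var))
  }
  outcome_parts <- lapply(seq_along(scns), function(k) {
    st <- marginal_gwas(Gs[[k]], liability)
    v <- scns[[k]]$variants
    data.frame(snp = v$snp, chrom = v$chrom, pos = v$pos,
               effect_allele = v$ea, other_allele = v$oa,
               eaf = colMeans(Gs[[k]]) / 2, beta = st$beta, se = st$se,
               pval = st$pval, n = n_out, stringsAsFactors = FALSE)
  })
  outcome <- as_sumstats(do.call(rbind, outcome_parts),
                         study_label = "outcome_study",
                         trait_label = "outcome",
                         trait_type = "quantitative")

  panel_n <- scns[[1L]]$panel_n
  panel_G <- do.call(cbind, lapply(scns, simulate_genotypes, n = panel_n))
  keys <- unlist(lapply(scns, function(s) s$variants$key))
  eas <- unlist(lapply(scns, function(s) s$variants$ea))

  list(studies = studies, genes = genes,
       outcomes = list(outcome = outcome),
       panel = reference_panel(panel_G, keys, effect_allele = eas),
       scns = scns)
}

## Five single-protein scenarios on separate chromosomes; the shared
## trans variant is appended by simulate_aptamer_panel.
simulate_aptamer_scenarios <- function(seed = 1L) {
  lapply(seq_len(5L), function(k)
    sim_scenario(n_blocks = 1, block_size = 5, rho = 0.5,
                 n_causal_cis = 1, causal_ve = 0.04,
                 chrom = as.character(k), protein_id = paste0("APT", k),
                 label = "multi_aptamer", seed = seed + k))
}

#' Simulate a panel of aptamers sharing one pleiotropic trans-pQTL
#'
#' Generates five synthetic aptamers, each with its own cis-pQTL on its
#' own chromosome, plus one variant (on a separate chromosome) that is a
#' strong pQTL for all five — the situation the five-or-more-aptamer
#' exclusion targets.
#'
#' @param seed Seed.
#' @param shared_ve Protein variance explained by the shared variant in
#'   each aptamer.
#' @return List with `studies` (per aptamer: `A`, `B` sumstats), `genes`,
#'   `panel`, `shared_key` (the planted variant's key).
#' @export
simulate_aptamer_panel <- function(seed = 1L, shared_ve = 0.04) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 404L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  scns <- simulate_aptamer_scenarios(seed)
  maf_s <- 0.3
  shared <- data.frame(snp = "rs_shared", chrom = "9", pos = 5000000,
                       ea = "A", oa = "G", maf = maf_s, block = 99L,
                       stringsAsFactors = FALSE)
  shared$key <- variant_key(shared$chrom, shared$pos, shared$ea, shared$oa)
  b_shared <- sqrt(shared_ve / (2 * maf_s * (1 - maf_s)))

  nA <- scns[[1]]$nA
  nB <- scns[[1]]$nB

  sim_cohort <- function(n) {
    Gs <- lapply(scns, simulate_genotypes, n = n)
    g_shared <- rbinom(n, 2L, maf_s)
    list(Gs = Gs, g_shared = g_shared)
  }
  gwas_for <- function(coh, n, lab) {
    lapply(seq_along(scns), function(k) {
      scn <- scns[[k]]
      G <- coh$Gs[[k]]
      y <- protein_value(scn, G) + b_shared * coh$g_shared
      y <- inverse_normal(y)
      Gall <- cbind(G, coh$g_shared)
      st <- marginal_gwas(Gall, y)
      v <- rbind(scn$variants, shared)
      as_sumstats(data.frame(
        snp = v$snp, chrom = v$chrom, pos = v$pos, effect_allele = v$ea,
        other_allele = v$oa, eaf = colMeans(Gall) / 2, beta = st$beta,
        se = st$se, pval = st$pval, n = n, stringsAsFactors = FALSE),
        study_label = lab, trait_label = scn$protein_id)
    })
  }
  cohA <- sim_cohort(nA)
  cohB <- sim_cohort(nB)
  gwA <- gwas_for(cohA, nA, "studyA")
  gwB <- gwas_for(cohB, nB, "studyB")

  panel_n <- scns[[1]]$panel_n
  panel_G <- do.call(cbind, lapply(scns, simulate_genotypes, n = panel_n))
  panel_G <- cbind(panel_G, rbinom(panel_n, 2L, maf_s))
  keys <- c(unlist(lapply(scns, function(s) s$variants$key)), shared$key)
  eas <- c(unlist(lapply(scns, function(s) s$variants$ea)), shared$ea)

  list(
    studies = setNames(lapply(seq_along(scns), function(k)
      list(A = gwA[[k]], B = gwB[[k]])),
      vapply(scns, function(s) s$protein_id, "")),
    genes = do.call(rbind, lapply(scns, function(s) s$gene)),
    panel = reference_panel(panel_G, keys, effect_allele = eas),
    shared_key = shared$key
  )
}
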