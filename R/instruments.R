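#' Union of genome-wide significant variants across two studies
#'
#' Keys with p strictly below `p_gw` in at least one of the two pQTL
#' studies of the same protein.
#'
#' @param study_a,study_b `sumstats` objects for the same protein.
#' @param p_gw Genome-wide significance threshold (default 5e-8).
#' @return Character vector of variant keys, sorted.
#' @export
significant_union <- function(study_a, study_b, p_gw = 5e-8) {
  ka <- study_a$data$key[study_a$data$pval < p_gw]
  kb <- study_b$data$key[study_b$data$pval < p_gw]
  sort(union(ka, kb))
}

## Align record b to record a's effect allele. Both rows share one
## positional key, so the allele sets agree; a swap flips beta and eaf.
align_to <- function(a, b) {
  if (b$effect_allele == a$effect_allele && b$other_allele == a$other_allele)
    return(b)
  if (b$effect_allele == a$other_allele && b$other_allele == a$effect_allele) {
    b$beta <- -b$beta
    if (!is.na(b$eaf)) b$eaf <- 1 - b$eaf
    tmp <- b$effect_allele
    b$effect_allele <- b$other_allele
    b$other_allele <- tmp
    return(b)
  }
  stop("allele sets differ between records at ", a$key)
}

#' Cross-study replication check
#'
#' A discovery pQTL replicates when the other study reports p strictly
#' below 0.05 with the same direction of effect. Records must be aligned
#' to a common effect allele; a zero beta in either study fails the check.
#'
#' @param discovery,other Single-row association records (lists or one-row
#'   data frames) with `beta`, `pval`, `effect_allele`, `other_allele`.
#' @param p_rep Replication p-value threshold.
#' @return Logical.
#' @export
cross_replicate <- function(discovery, other, p_rep = 0.05) {
  other <- align_to(discovery, other)
  if (discovery$beta == 0 || other$beta == 0) return(FALSE)
  other$pval < p_rep && sign(discovery$beta) == sign(other$beta)
}

#' Pairwise heterogeneity z-statistic between two studies
#'
#' `Z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)` for allele-aligned
#' records; instruments are kept when `|Z| < 3`.
#'
#' @param beta_a,se_a,beta_b,se_b Aligned effect estimates and standard
#'   errors (vectorised).
#' @return Numeric z-statistics.
#' @export
heterogeneity_z <- function(beta_a, se_a, beta_b, se_b) {
  if (any(se_a <= 0) || any(se_b <= 0))
    stop("standard errors must be positive")
  (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
}

#' Classify a variant as cis or trans relative to a gene
#'
#' A pQTL is cis when it lies within `window_bp` (default 500 kb) of the
#' protein-encoding gene region, bounds inclusive; everything else is
#' trans.
#'
#' @param chrom,pos Variant coordinates (vectorised).
#' @param gene One-row list/data frame with `chrom`, `gene_start`,
#'   `gene_end`.
#' @param window_bp Flanking window in base pairs.
#' @return Character vector `"cis"`/`"trans"`.
#' @export
classify_cis_trans <- function(chrom, pos, gene, window_bp = 500000) {
  ifelse(chrom == gene$chrom &
           pos >= gene$gene_start - window_bp &
           pos <= gene$gene_end + window_bp,
         "cis", "trans")
}

#' MHC region membership
#'
#' The major histocompatibility complex (chr6, 26-34 Mb, bounds inclusive)
#' is excluded from instrument lists for its extreme LD and pleiotropy.
#'
#' @param chrom,pos Variant coordinates (vectorised).
#' @param mhc_chrom,mhc_lo,mhc_hi Region definition.
#' @return Logical vector.
#' @export
in_mhc <- function(chrom, pos, mhc_chrom = "6", mhc_lo = 26000000,
                   mhc_hi = 34000000) {
  chrom == mhc_chrom & pos >= mhc_lo & pos <= mhc_hi
}

#' Multi-aptamer pleiotropy exclusion
#'
#' Variants associated with five or more aptamers (with the default
#' `max_aptamers = 4`) are flagged as likely pleiotropic and excluded.
#' The map is built over post-replication pQTLs across all proteins; see
#' [build_aptamer_map()].
#'
#' @param aptamer_map Named integer vector: variant key -> number of
#'   distinct aptamers/proteins for which the variant is a pQTL.
#' @param max_aptamers Largest permitted aptamer count.
#' @return Character vector of excluded keys.
#' @export
multi_aptamer_filter <- function(aptamer_map, max_aptamers = 4) {
  names(aptamer_map)[aptamer_map >= max_aptamers + 1L]
}

#' Count aptamers per pQTL across proteins
#'
#' @param replicated_lists List (one element per protein/aptamer) of
#'   post-replication pQTL data frames as returned by
#'   [replicated_pqtls()], or of key vectors.
#' @return Named integer vector of per-key aptamer counts.
#' @export
build_aptamer_map <- function(replicated_lists) {
  keys <- unlist(lapply(replicated_lists, function(x)
    unique(if (is.data.frame(x)) x$key else x)), use.names = FALSE)
  if (length(keys) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

#' Pick the record from the study with the most significant p-value
#'
#' Ties favour study A (the first-listed study); a record present in only
#' one study is returned as-is.
#'
#' @param a,b Single-row records or `NULL`.
#' @return List with `record` and `source` (`"A"`/`"B"`).
#' @export
select_best_source <- function(a, b) {
  if (is.null(a) && is.null(b)) stop("both records absent")
  if (is.null(b)) return(list(record = a, source = "A"))
  if (is.null(a)) return(list(record = b, source = "B"))
  if (b$pval < a$pval) list(record = b, source = "B")
  else list(record = a, source = "A")
}

## Merge the two studies at the union keys into one aligned data.frame;
## study-B columns suffixed _b and aligned to study A's effect allele.
merge_studies <- function(study_a, study_b, keys) {
  da <- study_a$data[study_a$data$key %in% keys, , drop = FALSE]
  db <- study_b$data[study_b$data$key %in% keys, , drop = FALSE]
  m <- merge(da, db, by = "key", all = TRUE, suffixes = c("", "_b"))
  both <- !is.na(m$beta) & !is.na(m$beta_b)
  swap <- both & m$effect_allele_b == m$other_allele &
    m$other_allele_b == m$effect_allele
  m$beta_b[swap] <- -m$beta_b[swap]
  m$eaf_b[swap] <- 1 - m$eaf_b[swap]
  mismatch <- both & !swap & (m$effect_allele_b != m$effect_allele |
                                m$other_allele_b != m$other_allele)
  if (any(mismatch))
    stop("allele sets differ between studies at ",
         paste(m$key[mismatch], collapse = ", "))
  m
}

#' Replication-filtered pQTL list for one protein
#'
#' Runs the first stages of the instrument-selection workflow: genome-wide
#' significance union, ambiguous-palindrome removal, and (for variants
#' present in both studies) cross-replication with the pairwise
#' heterogeneity screen. The result feeds [build_aptamer_map()] and
#' [build_instruments()].
#'
#' @inheritParams significant_union
#' @param maf_window Ambiguity window for palindromic SNPs (see
#'   [is_ambiguous_palindromic()]).
#' @param z_max Heterogeneity cut; variants with `|Z| >= z_max` are
#'   dropped.
#' @param keep_untestable Keep variants genome-wide significant in one
#'   study but absent from the other (replication cannot be tested).
#'   Default drops them.
#' @return List with `records` (data frame of surviving variants, one row
#'   each, from the more significant source study, with `source_study`)
#'   and `audit` (named loss counts).
#' @export
replicated_pqtls <- function(study_a, study_b, p_gw = 5e-8,
                             maf_window = 0.08, z_max = 3,
                             keep_untestable = FALSE) {
  keys <- significant_union(study_a, study_b, p_gw)
  audit <- c(union = length(keys), palindromic = 0L, untestable = 0L,
             not_replicated = 0L, heterogeneous = 0L)
  empty <- data.frame()
  if (length(keys) == 0L) return(list(records = empty, audit = audit))

  m <- merge_studies(study_a, study_b, keys)
  # palindrome ambiguity judged on the record carrying the variant
  # (study A when present in both; alleles agree by construction)
  ea <- ifelse(is.na(m$beta), m$effect_allele_b, m$effect_allele)
  oa <- ifelse(is.na(m$beta), m$other_allele_b, m$other_allele)
  eaf <- ifelse(is.na(m$beta), m$eaf_b, m$eaf)
  amb <- is_ambiguous_palindromic(ea, oa, eaf, maf_window)
  audit["palindromic"] <- sum(amb)
  m <- m[!amb, , drop = FALSE]

  in_both <- !is.na(m$beta) & !is.na(m$beta_b)
  if (!keep_untestable) {
    audit["untestable"] <- sum(!in_both)
    m <- m[in_both, , drop = FALSE]
    in_both <- rep(TRUE, nrow(m))
  }
  if (nrow(m) == 0L) return(list(records = empty, audit = audit))

  # replication: the less significant study must give p < 0.05 with the
  # same direction of effect; then |Z| < z_max heterogeneity screen
  rep_ok <- het_ok <- rep(TRUE, nrow(m))
  ib <- which(in_both)
  if (length(ib) > 0L) {
    other_p <- pmax(m$pval[ib], m$pval_b[ib])
    rep_ok[ib] <- other_p < 0.05 & m$beta[ib] != 0 & m$beta_b[ib] != 0 &
      sign(m$beta[ib]) == sign(m$beta_b[ib])
    z <- heterogeneity_z(m$beta[ib], m$se[ib], m$beta_b[ib], m$se_b[ib])
    het_ok[ib] <- abs(z) < z_max
  }
  audit["not_replicated"] <- sum(!rep_ok)
  audit["heterogeneous"] <- sum(rep_ok & !het_ok)
  m <- m[rep_ok & het_ok, , drop = FALSE]
  if (nrow(m) == 0L) return(list(records = empty, audit = audit))

  # best-source selection (tie -> study A)
  use_b <- !is.na(m$beta_b) & (is.na(m$beta) | m$pval_b < m$pval)
  rec <- data.frame(
    key = m$key,
    snp = ifelse(use_b, m$snp_b, m$snp),
    chrom = ifelse(use_b, m$chrom_b, m$chrom),
    pos = ifelse(use_b, m$pos_b, m$pos),
    effect_allele = ifelse(use_b, m$effect_allele_b, m$effect_allele),
    other_allele = ifelse(use_b, m$other_allele_b, m$other_allele),
    eaf = ifelse(use_b, m$eaf_b, m$eaf),
    beta = ifelse(use_b, m$beta_b, m$beta),
    se = ifelse(use_b, m$se_b, m$se),
    pval = ifelse(use_b, m$pval_b, m$pval),
    n = ifelse(use_b, m$n_b, m$n),
    source_study = ifelse(use_b, study_b$study_label, study_a$study_label),
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  list(records = rec, audit = audit)
}

#' Build the instrument set for one protein
#'
#' Full instrument-selection workflow: significance union, palindrome
#' removal, cross-replication and heterogeneity screening, cis/trans
#' classification against the gene annotation, best-source selection,
#' per-protein greedy LD clumping (cis and trans lists clumped
#' separately), MHC exclusion, and multi-aptamer pleiotropy exclusion.
#' Audit counters record the number of variants lost at each stage, so
#' `union = sum(losses) + retained`.
#'
#' @inheritParams replicated_pqtls
#' @param gene One-row gene annotation (`protein_id`, `gene_symbol`,
#'   `chrom`, `gene_start`, `gene_end`).
#' @param panel Reference panel for LD; variants absent from the panel are
#'   dropped (counted as `no_ld`).
#' @param aptamer_map Global per-key aptamer counts from
#'   [build_aptamer_map()]; `NULL` skips the exclusion (single-protein
#'   use).
#' @param cis_window_bp Cis window around the gene region.
#' @param r2_clump,clump_window_kb Clumping parameters (see
#'   [greedy_clump()]).
#' @param mhc_chrom,mhc_lo,mhc_hi MHC bounds (see [in_mhc()]).
#' @param max_aptamers Aptamer-count cap (see [multi_aptamer_filter()]).
#' @param replicated Optional precomputed result of [replicated_pqtls()]
#'   for this protein (avoids recomputation in proteome-wide scans).
#' @return An `instrument_set`: list with `protein_id`, `gene`, `cis`,
#'   `trans` (data frames of retained instruments) and `audit`.
#' @export
build_instruments <- function(study_a, study_b, gene, panel,
                              aptamer_map = NULL, p_gw = 5e-8,
                              maf_window = 0.08, z_max = 3,
                              keep_untestable = FALSE,
                              cis_window_bp = 500000, r2_clump = 0.001,
                              clump_window_kb = 10000, mhc_chrom = "6",
                              mhc_lo = 26000000, mhc_hi = 34000000,
                              max_aptamers = 4, replicated = NULL) {
  rp <- if (!is.null(replicated)) replicated
  else replicated_pqtls(study_a, study_b, p_gw = p_gw,
                        maf_window = maf_window, z_max = z_max,
                        keep_untestable = keep_untestable)
  rec <- rp$records
  audit <- c(rp$audit, no_ld = 0L, clumped = 0L, mhc = 0L,
             multi_aptamer = 0L, retained_cis = 0L, retained_trans = 0L)
  out <- function(cis, trans) {
    audit["retained_cis"] <- nrow(cis)
    audit["retained_trans"] <- nrow(trans)
    structure(list(protein_id = gene$protein_id, gene = gene,
                   cis = cis, trans = trans, audit = audit),
              class = "instrument_set")
  }
  empty <- if (nrow(rec) > 0L) rec[0L, , drop = FALSE] else data.frame()
  if (nrow(rec) == 0L) return(out(empty, empty))

  rec$cis_trans <- classify_cis_trans(rec$chrom, rec$pos, gene,
                                      cis_window_bp)

  has_ld <- rec$key %in% panel$keys
  audit["no_ld"] <- sum(!has_ld)
  rec <- rec[has_ld, , drop = FALSE]
  if (nrow(rec) == 0L) return(out(empty, empty))

  keep <- character(0)
  for (grp in c("cis", "trans")) {
    sub <- rec[rec$cis_trans == grp, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ld <- ld_corr(panel, sub$key)
    keep <- c(keep, greedy_clump(sub, ld, r2_max = r2_clump,
                                 window_kb = clump_window_kb))
  }
  audit["clumped"] <- nrow(rec) - length(keep)
  rec <- rec[rec$key %in% keep, , drop = FALSE]

  mhc <- in_mhc(rec$chrom, rec$pos, mhc_chrom, mhc_lo, mhc_hi)
  audit["mhc"] <- sum(mhc)
  rec <- rec[!mhc, , drop = FALSE]

  if (!is.null(aptamer_map)) {
    excl <- rec$key %in% multi_aptamer_filter(aptamer_map, max_aptamers)
    audit["multi_aptamer"] <- sum(excl)
    rec <- rec[!excl, , drop = FALSE]
  }
  rownames(rec) <- NULL
  out(rec[rec$cis_trans == "cis", , drop = FALSE],
      rec[rec$cis_trans == "trans", , drop = FALSE])
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d cis, %d trans instruments\n",
              x$protein_id, nrow(x$cis), nrow(x$trans)))
  invisible(x)
}
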