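#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`, with the number of tests equal to the number of
#' proteins entering MR (those with at least one valid cis instrument),
#' per outcome.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (at least 1).
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 1724)  # 2.9002e-05
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  alpha / n_tests
}

#' Configuration for a proteome-wide scan
#'
#' Collects inputs and thresholds for [run_scan()]. Inputs may be
#' in-memory objects (named lists of `sumstats`, a `ref_panel`, a gene
#' data frame) or file paths: stacked pQTL/outcome tables with a
#' `protein_id`/trait column are read with [read_stacked_sumstats()] and
#' the panel with [read_panel()].
#'
#' @param studies Named list, one entry per protein, each `list(A=, B=)`
#'   of `sumstats`; or paths `c(A=, B=)` to stacked tables.
#' @param genes Gene annotation data frame (`protein_id`, `gene_symbol`,
#'   `chrom`, `gene_start`, `gene_end`) or a path to one.
#' @param outcomes Named list of outcome `sumstats`, or paths.
#' @param panel A `ref_panel` or a path to a dosage matrix.
#' @param alpha Family-wise error rate for Bonferroni gating.
#' @param p_gw,maf_window,z_max,keep_untestable,cis_window_bp,r2_clump,clump_window_kb,mhc_chrom,mhc_lo,mhc_hi,max_aptamers
#'   Instrument-selection thresholds (see [build_instruments()]).
#' @param r2_proxy Proxy threshold for [attach_outcome()].
#' @param p1,p2,p12 Colocalisation priors.
#' @param coloc_min_variants Minimum region size to attempt SuSiE.
#' @param susie_L Maximum signals for SuSiE fine-mapping.
#' @param secondary Also run the cis+trans secondary analysis.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Seed governing every stochastic step of the scan.
#' @param out_dir Output directory (`NULL` for no files).
#' @return A `scan_config` list.
#' @export
scan_config <- function(studies, genes, outcomes, panel, alpha = 0.05,
                        p_gw = 5e-8, maf_window = 0.08, z_max = 3,
                        keep_untestable = FALSE, cis_window_bp = 500000,
                        r2_clump = 0.001, clump_window_kb = 10000,
                        mhc_chrom = "6", mhc_lo = 26000000,
                        mhc_hi = 34000000, max_aptamers = 4,
                        r2_proxy = 0.8, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        coloc_min_variants = 10, susie_L = 10,
                        secondary = FALSE, n_boot = 1000, seed = 1L,
                        out_dir = NULL) {
  if (is.character(genes)) genes <- read_delim_auto(genes)
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.character(studies))
    studies <- read_stacked_pair(studies[["A"]], studies[["B"]])
  structure(
    list(studies = studies, genes = genes, outcomes = outcomes,
         panel = panel, alpha = alpha, p_gw = p_gw,
         maf_window = maf_window, z_max = z_max,
         keep_untestable = keep_untestable,
         cis_window_bp = cis_window_bp, r2_clump = r2_clump,
         clump_window_kb = clump_window_kb, mhc_chrom = mhc_chrom,
         mhc_lo = mhc_lo, mhc_hi = mhc_hi, max_aptamers = max_aptamers,
         r2_proxy = r2_proxy, p1 = p1, p2 = p2, p12 = p12,
         coloc_min_variants = coloc_min_variants, susie_L = susie_L,
         secondary = secondary, n_boot = n_boot, seed = seed,
         out_dir = out_dir),
    class = "scan_config"
  )
}

#' Read a stacked multi-protein summary-statistics table
#'
#' A stacked table carries one `protein_id` column plus the usual GWAS
#' columns; it is split into one `sumstats` object per protein.
#'
#' @param path File path.
#' @param column_map As in [read_sumstats()].
#' @param protein_col Name of the protein identifier column.
#' @param study_label Study label applied to every protein.
#' @return Named list of `sumstats`.
#' @export
read_stacked_sumstats <- function(path, column_map = NULL,
                                  protein_col = "protein_id",
                                  study_label = "study") {
  dt <- read_delim_auto(path)
  if (!protein_col %in% names(dt))
    stop("missing protein column '", protein_col, "' in ", path)
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  for (field in names(cmap)) {
    col <- cmap[[field]]
    if (col %in% names(dt)) names(dt)[names(dt) == col] <- field
    else if (!field %in% c("eaf", "n")) {
      stop("missing mandatory column '", col, "' in ", path)
    } else dt[[field]] <- NA
  }
  split_df <- split(dt, dt[[protein_col]])
  lapply(split_df, function(d)
    as_sumstats(d, study_label = study_label,
                trait_label = d[[protein_col]][1L]))
}

read_stacked_pair <- function(path_a, path_b, ...) {
  a <- read_stacked_sumstats(path_a, study_label = "studyA", ...)
  b <- read_stacked_sumstats(path_b, study_label = "studyB", ...)
  ids <- intersect(names(a), names(b))
  setNames(lapply(ids, function(id) list(A = a[[id]], B = b[[id]])), ids)
}

#' Read a reference panel from a delimited dosage matrix
#'
#' Rows are variants with the key (`chrom:pos:a1:a2`) in the first
#' column, remaining columns are per-sample dosages in \[0, 2\] counting
#' the key's first allele.
#'
#' @param path File path (gzip-transparent).
#' @return A `ref_panel`.
#' @export
read_panel <- function(path) {
  dt <- read_delim_auto(path)
  keys <- as.character(dt[[1L]])
  mat <- t(as.matrix(dt[, -1L, drop = FALSE]))
  reference_panel(mat, keys)
}

## Extract aligned region statistics for one trait over a key list
region_from_sumstats <- function(ss, keys) {
  idx <- match(keys, ss$data$key)
  keep <- !is.na(idx)
  d <- ss$data[idx[keep], , drop = FALSE]
  list(keys = keys[keep], d = d)
}

#' Run the proteome-wide MR scan with colocalisation follow-up
#'
#' For every protein with gene annotation: selects instruments from the
#' two pQTL studies, harmonises the cis instruments against each outcome
#' (primary analysis; optionally cis+trans as a labelled secondary
#' analysis), runs the nsnp-dispatched MR estimator suite, gates the
#' primary Wald/IVW p-value at the Bonferroni threshold (alpha divided by
#' the number of proteins with at least one valid cis instrument), and
#' follows up every flagged pair with single-causal-variant
#' colocalisation over the cis region — plus SuSiE fine-mapping and
#' credible-set-pairwise colocalisation when the region is large enough.
#' Evidence calls follow the PP(H4) > 0.8 / PP(H1) > 0.8 convention.
#'
#' With `out_dir` set, writes `mr_results.tsv`, `coloc_results.tsv`,
#' `evidence_calls.tsv`, `audit.tsv` and `run.log`; outputs are
#' deterministic given the config (including its seed), so two runs with
#' the same config produce byte-identical files.
#'
#' @param cfg A `scan_config`.
#' @return A `scan_report`: `mr`, `coloc`, `evidence`, `audit` data
#'   frames plus `n_tests`, `threshold` and `seed`.
#' @export
run_scan <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  genes <- cfg$genes
  ids <- intersect(names(cfg$studies), genes$protein_id)
  if (length(ids) == 0L) stop("no protein has both studies and annotation")

  rp <- lapply(ids, function(id)
    replicated_pqtls(cfg$studies[[id]]$A, cfg$studies[[id]]$B,
                     p_gw = cfg$p_gw, maf_window = cfg$maf_window,
                     z_max = cfg$z_max,
                     keep_untestable = cfg$keep_untestable))
  names(rp) <- ids
  aptamer_map <- build_aptamer_map(lapply(rp, `[[`, "records"))

  inst <- lapply(ids, function(id)
    build_instruments(cfg$studies[[id]]$A, cfg$studies[[id]]$B,
                      genes[genes$protein_id == id, ][1L, ], cfg$panel,
                      aptamer_map = aptamer_map,
                      cis_window_bp = cfg$cis_window_bp,
                      r2_clump = cfg$r2_clump,
                      clump_window_kb = cfg$clump_window_kb,
                      mhc_chrom = cfg$mhc_chrom, mhc_lo = cfg$mhc_lo,
                      mhc_hi = cfg$mhc_hi,
                      max_aptamers = cfg$max_aptamers,
                      replicated = rp[[id]]))
  names(inst) <- ids

  with_cis <- ids[vapply(inst, function(x) nrow(x$cis) > 0L, TRUE)]
  if (length(with_cis) == 0L) {
    audit <- do.call(rbind, lapply(ids, function(id)
      data.frame(protein_id = id, t(inst[[id]]$audit))))
    stop("no protein yields valid cis instruments; audit:\n",
         paste(utils::capture.output(print(audit)), collapse = "\n"))
  }
  n_tests <- length(with_cis)
  threshold <- bonferroni_threshold(cfg$alpha, n_tests)

  mr_rows <- list()
  coloc_rows <- list()
  evid_rows <- list()
  for (id in with_cis) {
    for (oname in names(cfg$outcomes)) {
      outcome <- cfg$outcomes[[oname]]
      hs <- attach_outcome(inst[[id]], outcome, cfg$panel,
                           r2_min = cfg$r2_proxy, cis_only = TRUE,
                           proxy_pool = rp[[id]]$records,
                           maf_window = cfg$maf_window)
      if (nrow(hs$records) == 0L) next
      res <- run_mr(hs, n_boot = cfg$n_boot, seed = cfg$seed)
      res$analysis <- "primary_cis"
      primary_p <- res$pval[res$method %in% c("wald", "ivw")][1L]
      res$significant <- res$pval < threshold &
        res$method %in% c("wald", "ivw")
      mr_rows[[length(mr_rows) + 1L]] <- res

      if (cfg$secondary && nrow(inst[[id]]$trans) > 0L) {
        hs2 <- attach_outcome(inst[[id]], outcome, cfg$panel,
                              r2_min = cfg$r2_proxy, cis_only = FALSE,
                              proxy_pool = rp[[id]]$records,
                              maf_window = cfg$maf_window)
        if (nrow(hs2$records) > 0L) {
          res2 <- run_mr(hs2, n_boot = cfg$n_boot, seed = cfg$seed)
          res2$analysis <- "secondary_cis_trans"
          res2$significant <- FALSE
          mr_rows[[length(mr_rows) + 1L]] <- res2
        }
      }

      if (is.na(primary_p) || primary_p >= threshold) next
      cl <- scan_coloc(cfg, id, inst[[id]], outcome, oname)
      if (is.null(cl)) next
      coloc_rows[[length(coloc_rows) + 1L]] <- cl$rows
      evid_rows[[length(evid_rows) + 1L]] <- data.frame(
        protein_id = id, outcome_label = oname,
        mr_pval = primary_p, pp_h4 = cl$abf$pp[["PP.H4"]],
        pp_h1 = cl$abf$pp[["PP.H1"]], call = coloc_call(cl$abf),
        stringsAsFactors = FALSE
      )
    }
  }

  audit <- do.call(rbind, lapply(ids, function(id)
    data.frame(protein_id = id, t(inst[[id]]$audit),
               stringsAsFactors = FALSE)))
  report <- structure(
    list(mr = rbind_or_empty(mr_rows), coloc = rbind_or_empty(coloc_rows),
         evidence = rbind_or_empty(evid_rows), audit = audit,
         n_tests = n_tests, threshold = threshold, seed = cfg$seed),
    class = "scan_report"
  )
  if (!is.null(cfg$out_dir)) write_scan_report(report, cfg$out_dir)
  report
}

rbind_or_empty <- function(rows) {
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

## coloc follow-up for one flagged protein x outcome pair
scan_coloc <- function(cfg, id, instr, outcome, oname) {
  g <- instr$gene
  lo <- g$gene_start - cfg$cis_window_bp
  hi <- g$gene_end + cfg$cis_window_bp
  pk <- parse_key(cfg$panel$keys)
  region_keys <- cfg$panel$keys[pk$chrom == g$chrom & pk$pos >= lo &
                                  pk$pos <= hi]
  # pick the pQTL study that sourced the lead cis instrument
  lead <- instr$cis[which.min(instr$cis$pval), ]
  study <- cfg$studies[[id]][[
    if (identical(lead$source_study, cfg$studies[[id]]$B$study_label))
      "B" else "A"]]
  r1 <- region_from_sumstats(study, region_keys)
  keys <- intersect(r1$keys, outcome$data$key)
  if (length(keys) < 2L) return(NULL)
  d1 <- study$data[match(keys, study$data$key), ]
  d2 <- outcome$data[match(keys, outcome$data$key), ]
  t1 <- region_stats(keys, d1$beta, d1$se, study$trait_type,
                     n = stats::median(d1$n))
  t2 <- region_stats(keys, d2$beta, d2$se, outcome$trait_type,
                     n = stats::median(d2$n))
  abf <- coloc_abf(t1, t2, p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12)
  rows <- data.frame(
    protein_id = id, outcome_label = oname, method = "abf",
    effect1 = NA_integer_, effect2 = NA_integer_,
    pp_h0 = abf$pp[[1L]], pp_h1 = abf$pp[[2L]], pp_h2 = abf$pp[[3L]],
    pp_h3 = abf$pp[[4L]], pp_h4 = abf$pp[[5L]],
    n_variants = abf$n_variants, stringsAsFactors = FALSE
  )
  if (length(keys) >= cfg$coloc_min_variants) {
    # per-trait signed LD aligned to each study's effect alleles
    align_ea <- function(d) d$effect_allele
    R1 <- ld_corr(cfg$panel, keys, effect_allele = align_ea(d1))
    R2 <- ld_corr(cfg$panel, keys, effect_allele = align_ea(d2))
    f1 <- suppressWarnings(susie_rss(d1$beta / d1$se, R1,
                                     n = stats::median(d1$n),
                                     L = cfg$susie_L))
    f2 <- suppressWarnings(susie_rss(d2$beta / d2$se, R2,
                                     n = stats::median(d2$n),
                                     L = cfg$susie_L))
    cs <- coloc_susie(f1, f2, p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12)
    for (r in cs) {
      rows <- rbind(rows, data.frame(
        protein_id = id, outcome_label = oname, method = "susie",
        effect1 = r$labels[1L], effect2 = r$labels[2L],
        pp_h0 = r$pp[[1L]], pp_h1 = r$pp[[2L]], pp_h2 = r$pp[[3L]],
        pp_h3 = r$pp[[4L]], pp_h4 = r$pp[[5L]],
        n_variants = r$n_variants, stringsAsFactors = FALSE
      ))
    }
  }
  list(abf = abf, rows = rows)
}

write_scan_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_table(report$mr, file.path(out_dir, "mr_results.tsv"))
  write_results_table(report$coloc,
                      file.path(out_dir, "coloc_results.tsv"))
  write_results_table(report$evidence,
                      file.path(out_dir, "evidence_calls.tsv"))
  write_results_table(report$audit, file.path(out_dir, "audit.tsv"))
  log_lines <- c(
    sprintf("proteins_tested\t%d", report$n_tests),
    sprintf("bonferroni_threshold\t%.6g", report$threshold),
    sprintf("seed\t%d", report$seed),
    sprintf("mr_rows\t%d", nrow(report$mr)),
    sprintf("flagged_pairs\t%d", nrow(report$evidence))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(paste0("<scan_report> %d proteins tested, threshold %.3g, ",
                     "%d flagged pair(s)\n"),
              x$n_tests, x$threshold, nrow(x$evidence)))
  invisible(x)
}

#' One simulated MR replicate: scenario to MR results
#'
#' Simulates a study from a scenario, runs instrument selection,
#' harmonisation and the MR estimator suite, and returns the results with
#' the simulation truth attached. The workhorse behind the type-I error,
#' parameter-recovery and pleiotropy simulation studies.
#'
#' @param scn A `sim_scenario`.
#' @param seed Replicate seed.
#' @param cis_only Primary (cis-only) analysis.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @return List with `results` (MR rows), `instruments`, `harmonised`,
#'   and `theta` (the true causal effect); `NULL` when no instrument
#'   survives selection or harmonisation.
#' @export
mr_replicate <- function(scn, seed = scn$seed, cis_only = TRUE,
                         n_boot = 200) {
  sim <- simulate_study(scn, seed)
  rp <- replicated_pqtls(sim$study_a, sim$study_b)
  instr <- build_instruments(sim$study_a, sim$study_b, sim$gene,
                             sim$panel, replicated = rp)
  pool <- if (nrow(rp$records) > 0L) rp$records else NULL
  if (nrow(instr$cis) + (!cis_only) * nrow(instr$trans) == 0L)
    return(NULL)
  hs <- attach_outcome(instr, sim$outcome, sim$panel, cis_only = cis_only,
                       proxy_pool = pool)
  if (nrow(hs$records) == 0L) return(NULL)
  list(results = run_mr(hs, n_boot = n_boot, seed = seed),
       instruments = instr, harmonised = hs, theta = scn$theta)
}

#' One simulated colocalisation replicate
#'
#' Simulates a study and colocalises the protein (study A) against the
#' outcome over the scenario's full variant region, with single-variant
#' Wakefield colocalisation and optionally SuSiE-based credible-set
#' colocalisation.
#'
#' @param scn A `sim_scenario`.
#' @param seed Replicate seed.
#' @param susie Also fine-map both traits and run [coloc_susie()].
#' @return List with `abf` (a `coloc_result`), and when requested
#'   `susie` (list of pairwise `coloc_result`s), `fit1`, `fit2`.
#' @export
coloc_replicate <- function(scn, seed = scn$seed, susie = FALSE) {
  sim <- simulate_study(scn, seed)
  keys <- scn$variants$key
  d1 <- sim$study_a$data[match(keys, sim$study_a$data$key), ]
  d2 <- sim$outcome$data[match(keys, sim$outcome$data$key), ]
  t1 <- region_stats(keys, d1$beta, d1$se, "quantitative", n = scn$nA)
  t2 <- region_stats(keys, d2$beta, d2$se, sim$outcome$trait_type,
                     n = scn$n_out)
  out <- list(abf = coloc_abf(t1, t2))
  if (susie) {
    R1 <- ld_corr(sim$panel, keys, effect_allele = d1$effect_allele)
    f1 <- suppressWarnings(susie_rss(d1$beta / d1$se, R1, n = scn$nA))
    f2 <- suppressWarnings(susie_rss(d2$beta / d2$se, R1, n = scn$n_out))
    out$fit1 <- f1
    out$fit2 <- f2
    out$susie <- coloc_susie(f1, f2)
  }
  out
}
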