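ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonise one exposure/outcome variant pair onto a common effect allele
#'
#' Aligns the outcome record to the exposure's effect allele: a swapped
#' allele order negates the outcome beta; complementary-strand coding
#' (e.g. A/G vs T/C) is resolved via allele complements; palindromic pairs
#' (A/T, C/G), where complementing cannot distinguish a swap from a strand
#' flip, are resolved by comparing effect-allele frequencies and dropped as
#' ambiguous when either frequency is missing or within `maf_window` of
#' 0.5. Finally both betas are negated if needed so that the exposure beta
#' is positive (orientation convention; the Wald ratio is invariant to it).
#'
#' @param exp,out Single-row association records (lists/one-row data
#'   frames) at the same site with `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`.
#' @param maf_window Ambiguity window for palindromic pairs.
#' @return A list: either `dropped = FALSE` plus the harmonised fields
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, or `dropped = TRUE` with a
#'   `reason` (`"palindromic_ambiguous"`, `"allele_mismatch"`,
#'   `"zero_exposure"`).
#' @export
harmonise_pair <- function(exp, out, maf_window = 0.08) {
  drop <- function(reason) list(dropped = TRUE, reason = reason)
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele
  beta_out <- out$beta
  palindromic <- oa_x == unname(ALLELE_COMPLEMENT[ea_x])

  if (palindromic) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)))
      return(drop("allele_mismatch"))
    if (is.na(exp$eaf) || is.na(out$eaf) ||
        abs(exp$eaf - 0.5) < maf_window || abs(out$eaf - 0.5) < maf_window)
      return(drop("palindromic_ambiguous"))
    # frequencies decide whether the outcome codes the same allele
    eaf_y <- if (ea_y == ea_x) out$eaf else 1 - out$eaf
    same <- abs(exp$eaf - eaf_y) <= abs(exp$eaf - (1 - eaf_y))
    if (ea_y == oa_x) beta_out <- -beta_out  # literal swap first
    if (!same) beta_out <- -beta_out         # then strand-flip correction
  } else if (ea_y == ea_x && oa_y == oa_x) {
    # aligned as stated
  } else if (ea_y == oa_x && oa_y == ea_x) {
    beta_out <- -beta_out
  } else {
    cea <- unname(ALLELE_COMPLEMENT[ea_y])
    coa <- unname(ALLELE_COMPLEMENT[oa_y])
    if (identical(cea, ea_x) && identical(coa, oa_x)) {
      # other strand, same orientation
    } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
      beta_out <- -beta_out
    } else {
      return(drop("allele_mismatch"))
    }
  }

  beta_exp <- exp$beta
  if (beta_exp == 0) return(drop("zero_exposure"))
  if (beta_exp < 0) {
    beta_exp <- -beta_exp
    beta_out <- -beta_out
  }
  list(dropped = FALSE, beta_exp = beta_exp, se_exp = exp$se,
       beta_out = beta_out, se_out = out$se)
}

#' Attach outcome associations to an instrument set
#'
#' For every instrument present in the outcome summary statistics (matched
#' by chromosome and position), harmonises the pair; for instruments absent
#' from the outcome, searches the protein's own valid pQTL list for an LD
#' proxy with r-squared strictly above `r2_min` and, when found, takes both
#' the exposure and the outcome association at the proxy variant itself.
#' Instruments with no qualifying proxy are counted and skipped.
#'
#' @param instr An `instrument_set` from [build_instruments()].
#' @param outcome A `sumstats` object for the outcome trait.
#' @param panel Reference panel used for proxy LD.
#' @param r2_min Strict proxy r-squared threshold.
#' @param cis_only Use only cis instruments (primary analysis); `FALSE`
#'   adds trans instruments (secondary analysis).
#' @param proxy_pool Optional data frame of the protein's valid
#'   (replication-surviving) pQTL records from which proxies may be drawn;
#'   defaults to the instrument lists themselves.
#' @param maf_window Palindrome ambiguity window for harmonisation.
#' @return A `harmonised_set`: `protein_id`, `outcome_label`,
#'   `trait_type`, `records` data frame (key, beta_exp, se_exp, beta_out,
#'   se_out, proxy_used, proxy_r2), and counters `n_dropped_palindromic`,
#'   `n_allele_mismatch`, `n_missing_no_proxy`.
#' @export
attach_outcome <- function(instr, outcome, panel, r2_min = 0.8,
                           cis_only = TRUE, proxy_pool = NULL,
                           maf_window = 0.08) {
  inst <- if (cis_only) instr$cis else rbind(instr$cis, instr$trans)
  od <- outcome$data
  out_site <- paste(od$chrom, od$pos, sep = ":")
  if (is.null(proxy_pool)) proxy_pool <- rbind(instr$cis, instr$trans)

  recs <- list()
  n_pal <- n_mis <- n_noproxy <- 0L
  if (!is.null(inst) && nrow(inst) > 0L) for (i in seq_len(nrow(inst))) {
    x <- inst[i, ]
    j <- match(paste(x$chrom, x$pos, sep = ":"), out_site)
    proxy_used <- NA_character_
    proxy_r2 <- NA_real_
    if (is.na(j)) {
      cand <- proxy_pool[!proxy_pool$key %in% c(inst$key, names(recs)), ,
                         drop = FALSE]
      cand <- cand[paste(cand$chrom, cand$pos, sep = ":") %in% out_site, ,
                   drop = FALSE]
      cand <- cand[cand$key %in% panel$keys, , drop = FALSE]
      if (!x$key %in% panel$keys || nrow(cand) == 0L) {
        n_noproxy <- n_noproxy + 1L
        next
      }
      ld <- ld_corr(panel, c(x$key, cand$key))
      px <- find_proxy(x$key, cand$key, ld, r2_min = r2_min)
      if (is.null(px)) {
        n_noproxy <- n_noproxy + 1L
        next
      }
      proxy_used <- px$key
      proxy_r2 <- px$r2
      x <- cand[cand$key == px$key, ]
      j <- match(paste(x$chrom, x$pos, sep = ":"), out_site)
    }
    h <- harmonise_pair(x, od[j, ], maf_window = maf_window)
    if (isTRUE(h$dropped)) {
      if (h$reason == "palindromic_ambiguous") n_pal <- n_pal + 1L
      else n_mis <- n_mis + 1L
      next
    }
    recs[[x$key]] <- data.frame(
      key = x$key, beta_exp = h$beta_exp, se_exp = h$se_exp,
      beta_out = h$beta_out, se_out = h$se_out,
      proxy_used = proxy_used, proxy_r2 = proxy_r2,
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs)
  else data.frame(key = character(0), beta_exp = numeric(0),
                  se_exp = numeric(0), beta_out = numeric(0),
                  se_out = numeric(0), proxy_used = character(0),
                  proxy_r2 = numeric(0), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(
    list(protein_id = instr$protein_id,
         outcome_label = outcome$trait_label,
         trait_type = outcome$trait_type, records = records,
         n_dropped_palindromic = n_pal, n_allele_mismatch = n_mis,
         n_missing_no_proxy = n_noproxy),
    class = "harmonised_set"
  )
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s vs %s: %d records (%d proxied)\n",
              x$protein_id, x$outcome_label, nrow(x$records),
              sum(!is.na(x$records$proxy_used))))
  invisible(x)
}
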