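#' Construct an LD reference panel
#'
#' A reference panel holds a dosage matrix (samples x variants, values in
#' \[0, 2\]) used to compute linkage disequilibrium for clumping and proxy
#' search. Dosages count the panel's recorded effect allele for each
#' variant. Variants with zero dosage variance are removed (LD is undefined
#' for them).
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#' @param keys Positional variant keys (`chrom:pos:a1:a2`), one per column.
#' @param effect_allele Allele counted by each dosage column; defaults to
#'   the lexicographically first allele of the key.
#' @return A `ref_panel` object.
#' @export
reference_panel <- function(dosage, keys, effect_allele = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != length(keys))
    stop("number of dosage columns must match number of keys")
  if (anyDuplicated(keys)) stop("variant keys must be unique")
  if (is.null(effect_allele)) effect_allele <- parse_key(keys)$a1
  v <- apply(dosage, 2L, stats::var)
  keep <- is.finite(v) & v > 0
  structure(
    list(dosage = dosage[, keep, drop = FALSE], keys = keys[keep],
         effect_allele = effect_allele[keep], n_samples = nrow(dosage)),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d variants x %d samples\n", length(x$keys),
              x$n_samples))
  invisible(x)
}

#' LD correlation matrix from a reference panel
#'
#' Pearson correlation of dosages for the requested variants, in the
#' requested order. The sign convention follows the counted effect allele:
#' passing `effect_allele` flips the sign of r for any variant whose effect
#' allele differs from the panel's counted allele (r-squared is unaffected).
#'
#' @param panel A `ref_panel`.
#' @param keys Variant keys to include (all must be present in the panel).
#' @param effect_allele Optional allele vector aligned with `keys` giving
#'   the effect allele of the caller's association records.
#' @return Correlation matrix with `keys` as dimnames.
#' @export
ld_corr <- function(panel, keys, effect_allele = NULL) {
  idx <- match(keys, panel$keys)
  if (anyNA(idx))
    stop("variant(s) absent from reference panel: ",
         paste(keys[is.na(idx)], collapse = ", "))
  R <- stats::cor(panel$dosage[, idx, drop = FALSE])
  dimnames(R) <- list(keys, keys)
  if (!is.null(effect_allele)) {
    flip <- ifelse(effect_allele == panel$effect_allele[idx], 1, -1)
    R <- R * outer(flip, flip)
  }
  R
}

#' Greedy LD clumping
#'
#' Iteratively retains the most significant remaining variant and discards
#' every remaining variant on the same chromosome within `window_kb` of it
#' whose squared correlation with it is at least `r2_max`. P-value ties are
#' broken by lexicographic key order, making the result deterministic.
#' The default r-squared threshold of 0.001 yields approximately
#' independent instruments.
#'
#' @param assocs Data frame with columns `key` and `pval` (positions and
#'   chromosomes are parsed from the key).
#' @param ld LD matrix covering all keys in `assocs` (signs irrelevant).
#' @param r2_max Squared-correlation threshold; pairs at or above it are
#'   pruned.
#' @param window_kb Clumping window in kilobases.
#' @return Character vector of retained keys, in retention order.
#' @export
greedy_clump <- function(assocs, ld, r2_max = 0.001, window_kb = 10000) {
  if (nrow(assocs) == 0L) return(character(0))
  pk <- parse_key(assocs$key)
  ord <- order(assocs$pval, assocs$key)
  keys <- assocs$key[ord]
  chrom <- pk$chrom[ord]
  pos <- pk$pos[ord]
  alive <- rep(TRUE, length(keys))
  kept <- character(0)
  win <- window_kb * 1000
  for (i in seq_along(keys)) {
    if (!alive[i]) next
    kept <- c(kept, keys[i])
    alive[i] <- FALSE
    later <- which(alive)
    if (length(later) == 0L) break
    near <- later[chrom[later] == chrom[i] &
                    abs(pos[later] - pos[i]) <= win]
    if (length(near) > 0L) {
      r2 <- ld[keys[i], keys[near]]^2
      alive[near[r2 >= r2_max]] <- FALSE
    }
  }
  kept
}

#' Find an LD proxy for a missing variant
#'
#' Returns the candidate with the highest squared correlation to the target
#' among those with r-squared strictly greater than `r2_min` (the
#' conventional proxy threshold of 0.8). Ties are broken by smaller
#' physical distance to the target, then lexicographic key order.
#'
#' @param target Target variant key (must be present in `ld`).
#' @param candidates Candidate keys (excluding the target).
#' @param ld LD matrix covering target and candidates.
#' @param r2_min Strict lower bound on r-squared.
#' @return A list with `key` and `r2`, or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.8) {
  if (!target %in% rownames(ld))
    stop("target variant absent from LD matrix: ", target)
  candidates <- setdiff(candidates, target)
  candidates <- candidates[candidates %in% rownames(ld)]
  if (length(candidates) == 0L) return(NULL)
  r2 <- ld[target, candidates]^2
  ok <- r2 > r2_min
  if (!any(ok)) return(NULL)
  cand <- candidates[ok]
  r2 <- r2[ok]
  dist <- abs(parse_key(cand)$pos - parse_key(target)$pos)
  ord <- order(-r2, dist, cand)
  list(key = cand[ord[1L]], r2 = unname(r2[ord[1L]]))
}
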