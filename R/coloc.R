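logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield approximate log Bayes factor for association at one variant
#'
#' With sampling variance `V = se^2`, prior effect variance
#' `W = prior_sd^2`, z-score `z = beta / se` and shrinkage
#' `r = W / (V + W)`, the log approximate Bayes factor of association
#' against the null is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and its standard error (vectorised).
#' @param prior_sd Prior standard deviation of the true effect; 0.15 is
#'   conventional for quantitative traits in SD units, 0.2 for binary
#'   traits on the log-odds scale.
#' @return Log approximate Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Region summary statistics for colocalisation
#'
#' @param keys Ordered variant keys.
#' @param beta,se Aligned effect estimates and standard errors.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n Sample size.
#' @param case_fraction Case fraction (binary traits only).
#' @return A `region_stats` object.
#' @export
region_stats <- function(keys, beta, se, trait_type = "quantitative",
                         n = NA_integer_, case_fraction = NA_real_) {
  stopifnot(length(keys) == length(beta), length(beta) == length(se))
  if (any(se <= 0)) stop("standard errors must be positive")
  structure(list(keys = keys, beta = beta, se = se,
                 trait_type = match.arg(trait_type,
                                        c("quantitative", "binary")),
                 n = n, case_fraction = case_fraction,
                 z = beta / se),
            class = "region_stats")
}

## Hypothesis sums over two vectors of per-variant log Bayes factors,
## entirely in log space (ABFs overflow doubles beyond |z| ~ 40).
coloc_from_lbf <- function(l1, l2, p1, p2, p12, n_variants,
                           labels = c(NA, NA)) {
  lS1 <- logsumexp(l1)
  lS2 <- logsumexp(l2)
  lS4 <- logsumexp(l1 + l2)
  lS3 <- logdiff(lS1 + lS2, lS4)  # sum over i != j
  lh <- c(0,
          log(p1) + lS1,
          log(p2) + lS2,
          log(p1) + log(p2) + lS3,
          log(p12) + lS4)
  pp <- exp(lh - logsumexp(lh))
  structure(
    list(pp = setNames(pp, paste0("PP.H", 0:4)),
         n_variants = n_variants,
         priors = c(p1 = p1, p2 = p2, p12 = p12),
         labels = labels),
    class = "coloc_result"
  )
}

#' Bayesian colocalisation under a single causal variant per trait
#'
#' Computes per-variant Wakefield log approximate Bayes factors for each
#' trait and the posterior probabilities of the five colocalisation
#' hypotheses: H0 no association in either trait; H1 only trait 1
#' associated; H2 only trait 2; H3 both, distinct causal variants; H4
#' both, one shared causal variant. Default priors are `p1 = p2 = 1e-4`
#' per variant per trait and `p12 = 1e-5` for a shared causal variant;
#' posterior probability of H4 above 0.8 is conventionally read as strong
#' evidence of a shared signal.
#'
#' @param t1,t2 `region_stats` over an identical ordered variant list
#'   (trait 1 the protein exposure, trait 2 the outcome).
#' @param p1,p2,p12 Prior probabilities.
#' @param prior_sd_quant,prior_sd_binary Wakefield prior effect SDs by
#'   trait type.
#' @return A `coloc_result` with `pp` (PP.H0..PP.H4) summing to one.
#' @export
coloc_abf <- function(t1, t2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_quant = 0.15, prior_sd_binary = 0.2) {
  if (!identical(t1$keys, t2$keys))
    stop("traits must share one variant list in the same order")
  psd <- function(t) if (t$trait_type == "binary") prior_sd_binary
  else prior_sd_quant
  l1 <- log_abf(t1$beta, t1$se, psd(t1))
  l2 <- log_abf(t2$beta, t2$se, psd(t2))
  res <- coloc_from_lbf(l1, l2, p1, p2, p12, length(t1$keys))
  stopifnot(abs(sum(res$pp) - 1) < 1e-9)
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Three-way evidence call from colocalisation posteriors
#'
#' `"H4_shared"` when PP(H4) > `cut` (strong evidence of a shared causal
#' variant), `"H1_underpowered"` when PP(H1) > `cut` (the protein is
#' associated but the outcome shows nothing — typically an underpowered
#' outcome GWAS), otherwise `"inconclusive"`.
#'
#' @param coloc A `coloc_result`.
#' @param cut Posterior probability cut-off.
#' @return Character scalar.
#' @export
coloc_call <- function(coloc, cut = 0.8) {
  if (coloc$pp[["PP.H4"]] > cut) "H4_shared"
  else if (coloc$pp[["PP.H1"]] > cut) "H1_underpowered"
  else "inconclusive"
}
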