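mr_result_row <- function(hs, method, estimate, se, pval, nsnp,
                          Q = NA_real_, Q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_p = NA_real_) {
  data.frame(
    protein_id = hs$protein_id %||% NA_character_,
    outcome_label = hs$outcome_label %||% NA_character_,
    method = method, estimate = estimate, se = se, pval = pval,
    nsnp = nsnp, Q = Q, Q_pval = Q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ratio_weights <- function(hs) {
  r <- hs$records
  list(ratio = r$beta_out / r$beta_exp,
       w = r$beta_exp^2 / r$se_out^2)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `estimate = beta_out / beta_exp` with first-order delta-method standard
#' error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param hs A `harmonised_set` with exactly one record (or a list with a
#'   one-row `records` data frame).
#' @return One-row MR result data frame.
#' @export
wald_ratio <- function(hs) {
  r <- hs$records
  if (nrow(r) != 1L) stop("wald_ratio requires exactly one instrument")
  if (r$beta_exp == 0) stop("exposure beta is zero")
  est <- r$beta_out / r$beta_exp
  se <- r$se_out / abs(r$beta_exp)
  mr_result_row(hs, "wald", est, se, 2 * pnorm(-abs(est / se)), 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' Combines per-instrument ratio estimates `r_j = beta_out_j / beta_exp_j`
#' with weights `w_j = beta_exp_j^2 / se_out_j^2` (equivalent to weighted
#' least squares of the outcome betas on the exposure betas through the
#' origin). Cochran's Q is reported with a chi-square p-value on `nsnp - 1`
#' degrees of freedom, and the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q / (nsnp - 1)))` — a multiplicative random-effects floor
#' guarding against overdispersion.
#'
#' @param hs A `harmonised_set` with at least two records.
#' @return One-row MR result data frame with `Q` and `Q_pval`.
#' @export
ivw <- function(hs) {
  k <- nrow(hs$records)
  if (k < 2L) stop("ivw requires at least two instruments")
  rw <- ratio_weights(hs)
  est <- sum(rw$w * rw$ratio) / sum(rw$w)
  Q <- sum(rw$w * (rw$ratio - est)^2)
  se <- sqrt(1 / sum(rw$w)) * max(1, sqrt(Q / (k - 1)))
  mr_result_row(hs, "ivw", est, se, 2 * pnorm(-abs(est / se)), k,
                Q = Q, Q_pval = pchisq(Q, k - 1, lower.tail = FALSE))
}

## closed-form weighted regression y ~ 1 + x with weights w
wls_fit <- function(x, y, w) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  icpt <- yb - slope * xb
  resid <- y - icpt - slope * x
  df <- length(x) - 2L
  sigma2 <- sum(w * resid^2) / df
  se_slope <- sqrt(1 / sxx)
  se_icpt <- sqrt(1 / sw + xb^2 / sxx)
  list(slope = slope, intercept = icpt, se_slope = se_slope,
       se_intercept = se_icpt, sigma2 = sigma2, df = df)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept, weights `1 / se_out^2`. The slope is the pleiotropy-adjusted
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect and its p-value is a test for directional
#' pleiotropy. Standard errors carry the same multiplicative
#' overdispersion floor as [ivw()]; p-values use a t-distribution on
#' `nsnp - 2` degrees of freedom.
#'
#' @param hs A `harmonised_set` with at least three records.
#' @return One-row MR result data frame with intercept fields.
#' @export
egger <- function(hs) {
  k <- nrow(hs$records)
  if (k < 3L) stop("egger requires at least three instruments")
  r <- hs$records
  f <- wls_fit(r$beta_exp, r$beta_out, 1 / r$se_out^2)
  infl <- max(1, sqrt(f$sigma2))
  se_s <- f$se_slope * infl
  se_i <- f$se_intercept * infl
  mr_result_row(
    hs, "egger", f$slope, se_s,
    2 * pt(-abs(f$slope / se_s), df = f$df), k,
    egger_intercept = f$intercept, egger_intercept_se = se_i,
    egger_intercept_p = 2 * pt(-abs(f$intercept / se_i), df = f$df)
  )
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1L] - r[below]) *
    (0.5 - s[below]) / (s[below + 1L] - s[below])
}

boot_se <- function(hs, point_fun, n_boot, seed) {
  r <- hs$records
  k <- nrow(r)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, r$beta_exp, r$se_exp)
    by <- rnorm(k, r$beta_out, r$se_out)
    point_fun(by / bx, bx^2 / r$se_out^2)
  }, 0.0)
  sd(est)
}

#' Weighted median MR estimate
#'
#' The weighted median of the per-instrument ratio estimates, consistent
#' when instruments carrying at least half the weight are valid. Ordered
#' ratios are interpolated at normalised cumulative weight 0.5; the
#' standard error comes from a parametric bootstrap (exposure and outcome
#' betas resampled from normal distributions, fixed seed).
#'
#' @param hs A `harmonised_set` with at least three records.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return One-row MR result data frame.
#' @export
weighted_median <- function(hs, n_boot = 1000, seed = 1L) {
  k <- nrow(hs$records)
  if (k < 3L) stop("weighted_median requires at least three instruments")
  rw <- ratio_weights(hs)
  est <- weighted_median_point(rw$ratio, rw$w)
  se <- boot_se(hs, weighted_median_point, n_boot, seed)
  mr_result_row(hs, "weighted_median", est, se,
                2 * pnorm(-abs(est / se)), k)
}

mode_point <- function(ratio, w, phi = 1) {
  if (length(unique(ratio)) == 1L) return(ratio[1L])
  # modified Silverman bandwidth on the ratio scale
  s <- 0.9 * min(sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
  if (s <= 0) s <- 0.9 * sd(ratio) * length(ratio)^(-1 / 5)
  h <- phi * s
  d <- stats::density(ratio, weights = w / sum(w), bw = h, n = 512)
  d$x[which.max(d$y)]
}

#' Mode-based MR estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed density of per-instrument ratio
#' estimates, consistent when the largest group of instruments sharing one
#' ratio value is valid (ZEMPA assumption). The bandwidth is `phi` times
#' the modified Silverman rule on the ratios; the estimate is the argmax
#' of the density evaluated on a 512-point grid. Simple mode uses equal
#' weights, weighted mode the IVW weights. Standard errors by parametric
#' bootstrap as in [weighted_median()].
#'
#' @param hs A `harmonised_set` with at least three records.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param phi Bandwidth multiplier.
#' @inheritParams weighted_median
#' @return One-row MR result data frame.
#' @export
mode_estimate <- function(hs, weighted = FALSE, phi = 1, n_boot = 1000,
                          seed = 1L) {
  k <- nrow(hs$records)
  if (k < 3L) stop("mode_estimate requires at least three instruments")
  rw <- ratio_weights(hs)
  wfun <- if (weighted) function(r, w) mode_point(r, w, phi)
  else function(r, w) mode_point(r, rep(1, length(r)), phi)
  est <- wfun(rw$ratio, rw$w)
  se <- boot_se(hs, wfun, n_boot, seed)
  mr_result_row(hs, if (weighted) "weighted_mode" else "simple_mode",
                est, se, 2 * pnorm(-abs(est / se)), k)
}

#' Run the MR estimator suite with instrument-count dispatch
#'
#' One instrument gives the Wald ratio; two to five give the IVW estimate
#' with Cochran's Q; six or more trigger the sensitivity suite (IVW,
#' MR-Egger, weighted median, simple mode, weighted mode) used to probe
#' horizontal pleiotropy.
#'
#' @param hs A `harmonised_set`.
#' @param n_boot,seed Bootstrap settings for median/mode standard errors.
#' @param phi Mode bandwidth multiplier.
#' @return Data frame of MR results, one row per method.
#' @export
run_mr <- function(hs, n_boot = 1000, seed = 1L, phi = 1) {
  k <- nrow(hs$records)
  if (k < 1L) stop("no harmonised instruments")
  if (k == 1L) return(wald_ratio(hs))
  if (k <= 5L) return(ivw(hs))
  rbind(
    ivw(hs),
    egger(hs),
    weighted_median(hs, n_boot = n_boot, seed = seed),
    mode_estimate(hs, weighted = FALSE, phi = phi, n_boot = n_boot,
                  seed = seed),
    mode_estimate(hs, weighted = TRUE, phi = phi, n_boot = n_boot,
                  seed = seed)
  )
}
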