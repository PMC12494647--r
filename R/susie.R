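## Single-effect regression on residualised summary statistics.
## d = X'X diagonal, xty = X'(residual y), sigma2 = residual variance.
## Prior effect variance V is estimated by maximum likelihood (lower
## bound 0) over the single-effect marginal likelihood.
single_effect_fit <- function(xty, d, sigma2, V = NULL) {
  betahat <- xty / d
  shat2 <- sigma2 / d
  lbf_at <- function(V) {
    0.5 * log(shat2 / (shat2 + V)) +
      0.5 * (betahat^2 / shat2) * (V / (V + shat2))
  }
  loglik <- function(V) logsumexp(lbf_at(V)) - log(length(betahat))
  if (is.null(V)) {
    upper <- max(betahat^2)
    if (upper <= 0 || !is.finite(upper)) {
      V <- 0
    } else {
      opt <- optimise(loglik, interval = c(0, 2 * upper), maximum = TRUE)
      V <- if (opt$objective > loglik(0) + 1e-10) opt$maximum else 0
    }
  }
  if (V <= 0) {
    p <- length(betahat)
    return(list(V = 0, alpha = rep(1 / p, p), mu1 = rep(0, p),
                mu2 = rep(0, p), lbf = rep(0, p), lbf_model = 0))
  }
  lbf <- lbf_at(V)
  alpha <- exp(lbf - logsumexp(lbf))
  post_var <- 1 / (1 / V + d / sigma2)
  mu1 <- post_var * xty / sigma2
  mu2 <- post_var + mu1^2
  list(V = V, alpha = alpha, mu1 = mu1, mu2 = mu2, lbf = lbf,
       lbf_model = logsumexp(lbf) - log(length(betahat)))
}

## KL(q || prior) for one single-effect component
single_effect_kl <- function(fit) {
  if (fit$V <= 0) return(0)
  p <- length(fit$alpha)
  a <- fit$alpha
  pv <- fit$mu2 - fit$mu1^2
  kl_sel <- sum(ifelse(a > 0, a * log(a * p), 0))
  kl_b <- sum(a * 0.5 * (log(fit$V / pv) + (pv + fit$mu1^2) / fit$V - 1))
  kl_sel + kl_b
}

#' SuSiE fine-mapping from z-scores and an LD matrix
#'
#' Fits the sum of single effects regression on summary statistics by
#' iterative Bayesian stepwise selection: `L` single-effect vectors, each
#' a posterior mixture over variants obtained from single-effect Bayes
#' factors on the current residual, cycled until the evidence lower bound
#' changes by less than `tol` or `max_iter` is reached. Per-effect prior
#' variances are estimated by maximum likelihood with a lower bound of
#' zero; the residual variance is fixed at one on the z-score scale.
#' Each non-null effect yields a credible set: the smallest set of
#' variants whose posterior inclusion probabilities reach `coverage`,
#' discarded when its purity (minimum absolute pairwise LD) falls below
#' `min_purity`.
#'
#' @param z Vector of z-scores (`beta / se`), aligned with `R`.
#' @param R LD correlation matrix (signed, same allele convention as `z`).
#' @param n GWAS sample size.
#' @param L Maximum number of causal signals.
#' @param coverage Credible-set coverage target (0.95 gives 95%
#'   probability that a set contains a causal variant).
#' @param min_purity Minimum within-set absolute correlation.
#' @param max_iter,tol IBSS convergence controls (ELBO-based).
#' @param ridge Diagonal regularisation added when `R` is not positive
#'   semi-definite.
#' @return A `susie_fit`: `alpha` (L x p posterior inclusion matrix),
#'   `lbf_variable` (L x p per-variant log Bayes factors), `V`,
#'   `cs` (list of credible sets with `variants`, `coverage`, `purity`),
#'   `pip`, `converged`, `elbo`.
#' @export
susie_rss <- function(z, R, n, L = 10, coverage = 0.95, min_purity = 0.5,
                      max_iter = 100, tol = 1e-3, ridge = 1e-6) {
  p <- length(z)
  if (!is.matrix(R) || nrow(R) != p || ncol(R) != p)
    stop("dimensions of R must match length of z")
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) R <- R + diag(ridge - ev_min, p)

  # sufficient statistics for standardised X and y
  d <- rep(n - 1, p)
  xty_full <- sqrt(n - 1) * z
  XtX <- (n - 1) * R
  yty <- n - 1
  sigma2 <- 1

  alpha <- matrix(1 / p, L, p)
  mu1 <- mu2 <- lbf_var <- matrix(0, L, p)
  Vl <- numeric(L)
  Eb <- alpha * mu1                      # L x p posterior mean effects
  xtxb <- function(b) as.vector(XtX %*% b)
  elbo_old <- -Inf
  converged <- FALSE
  elbo_trace <- numeric(0)

  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      b_rest <- colSums(Eb[-l, , drop = FALSE])
      xty_r <- xty_full - xtxb(b_rest)
      f <- single_effect_fit(xty_r, d, sigma2)
      alpha[l, ] <- f$alpha
      mu1[l, ] <- f$mu1
      mu2[l, ] <- f$mu2
      lbf_var[l, ] <- f$lbf
      Vl[l] <- f$V
      Eb[l, ] <- f$alpha * f$mu1
    }
    # ELBO with fixed sigma2: expected residual sum of squares plus the
    # per-effect KL terms
    b_bar <- colSums(Eb)
    erss <- yty - 2 * sum(b_bar * xty_full) + sum(b_bar * xtxb(b_bar)) -
      sum(vapply(seq_len(L), function(l)
        sum(Eb[l, ] * xtxb(Eb[l, ])), 0.0)) +
      sum(vapply(seq_len(L), function(l)
        sum(alpha[l, ] * d * mu2[l, ]), 0.0))
    kl <- sum(vapply(seq_len(L), function(l)
      single_effect_kl(list(V = Vl[l], alpha = alpha[l, ], mu1 = mu1[l, ],
                            mu2 = mu2[l, ])), 0.0))
    elbo <- -0.5 * n * log(2 * pi * sigma2) - erss / (2 * sigma2) - kl
    elbo_trace <- c(elbo_trace, elbo)
    if (abs(elbo - elbo_old) < tol) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  if (!converged)
    warning("susie_rss did not converge in ", max_iter, " iterations")

  cs <- list()
  for (l in seq_len(L)) {
    if (Vl[l] <= 0) next
    ord <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, ord])
    size <- which(csum >= coverage)[1L]
    if (is.na(size)) size <- p
    idx <- sort(ord[seq_len(size)])
    purity <- if (length(idx) == 1L) 1
    else min(abs(R[idx, idx][upper.tri(diag(length(idx)))]))
    if (purity < min_purity) next
    key <- paste(idx, collapse = ",")
    if (key %in% vapply(cs, function(s) paste(s$idx, collapse = ","), ""))
      next
    cs[[length(cs) + 1L]] <- list(effect = l, idx = idx,
                                  coverage = csum[size], purity = purity)
  }

  pip <- 1 - apply(1 - alpha * (Vl > 0), 2L, prod)
  structure(
    list(alpha = alpha, lbf_variable = lbf_var, V = Vl, cs = cs,
         pip = pip, converged = converged, elbo = elbo_trace,
         n_variants = p),
    class = "susie_fit"
  )
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("<susie_fit> %d variants, %d credible set(s), %s\n",
              x$n_variants, length(x$cs),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Colocalisation between fine-mapped signals of two traits
#'
#' For every pair of credible-set-bearing effects (one from each trait's
#' SuSiE fit on an identical variant list), runs the five-hypothesis
#' posterior computation on the per-effect single-effect log Bayes
#' factors. This relaxes the single-causal-variant assumption of
#' [coloc_abf()] to one causal variant per signal.
#'
#' @param fit1,fit2 `susie_fit` objects on the same ordered variant list.
#' @param p1,p2,p12 Priors as in [coloc_abf()].
#' @return List of `coloc_result` objects, one per effect pair, each
#'   labelled with the contributing effect indices; empty (with a
#'   `reason` attribute) when either trait has no surviving credible set.
#' @export
coloc_susie <- function(fit1, fit2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (fit1$n_variants != fit2$n_variants)
    stop("traits must be fine-mapped on the identical variant list")
  if (length(fit1$cs) == 0L || length(fit2$cs) == 0L) {
    out <- list()
    attr(out, "reason") <- "no credible sets in at least one trait"
    return(out)
  }
  out <- list()
  for (s1 in fit1$cs) for (s2 in fit2$cs) {
    res <- coloc_from_lbf(fit1$lbf_variable[s1$effect, ],
                          fit2$lbf_variable[s2$effect, ],
                          p1, p2, p12, fit1$n_variants,
                          labels = c(s1$effect, s2$effect))
    stopifnot(abs(sum(res$pp) - 1) < 1e-9)
    out[[length(out) + 1L]] <- res
  }
  out
}
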