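---
title: "Methods: proteome-wide MR with colocalisation in protmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR with colocalisation in protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`protmr` estimates causal effects of circulating proteins on outcomes
from GWAS summary statistics alone, in the two-sample Mendelian
randomisation (MR) design: instrument–exposure associations come from
protein-QTL (pQTL) GWAS, instrument–outcome associations from an
independent outcome GWAS. This vignette is the package's account of the
models it fits, the defaults it fixes, and what its simulation studies
do and do not establish.

## Instrument selection

MR with protein exposures stands or falls on instrument validity, so
instruments are built defensively from **two** pQTL studies of the same
proteome rather than one:

* **Discovery union.** Variants with p < 5×10⁻⁸ (strict) in at least
  one study enter the candidate list. Using the union rather than one
  study's list avoids conditioning the instrument set on a single
  cohort's power.
* **Ambiguous palindromes.** A/T and C/G variants cannot be
  strand-resolved from alleles; they are removed when the effect-allele
  frequency is missing or within 0.08 of 0.5 (minor-allele frequency in
  (0.42, 0.5]). The window is a documented knob (`maf_window`); 0.08 is
  a conservative value in line with common harmonisation defaults.
* **Replication and heterogeneity.** For variants present in both
  studies, the less significant study must give p < 0.05 with the same
  direction of effect, and the pairwise z-statistic
  Z = (β₁ − β₂)/√(se₁² + se₂²) must satisfy |Z| < 3. Variants present
  in only one study cannot be replication-tested and are dropped by
  default (`keep_untestable = TRUE` preserves the permissive reading).
* **cis/trans.** A pQTL is cis when it lies within ±500 kb of the
  protein-coding gene body (bounds inclusive), per the supplied gene
  annotation; everything else is trans. The gene body (not the TSS) is
  the anchor because the annotation table carries start and end
  coordinates; the window is configurable.
* **Best source.** Each surviving variant keeps the statistics of the
  study with the smaller p-value (ties go to the first-listed study, a
  deterministic rule).
* **Clumping.** Greedy LD clumping at r² < 0.001 within a 10,000 kb
  window, per protein, separately within the cis and trans lists.
  P-value ties break lexicographically by variant key so results are
  reproducible. The window is wide because the r² threshold is doing
  the work; both are knobs.
* **Exclusions.** The MHC (chr6, 26–34 Mb inclusive — a closed-interval
  reading of the conventional bounds) is removed for its extreme LD and
  pleiotropy, and any variant that is a pQTL for five or more aptamers
  is removed as likely pleiotropic. The aptamer map is counted over
  post-replication pQTLs across all proteins, *before* clumping, so the
  count does not depend on per-protein clump order.

Every stage decrements an audit counter; `union` always equals the sum
of the per-stage losses plus the retained cis and trans counts, and the
tests assert this on every build.

Variant identity throughout is positional — `chrom:pos:allele:allele`
with alleles sorted — because rsIDs drift between sources; rsIDs are
carried as labels only. All inputs are assumed on one genome build;
liftover is out of scope. Indels and non-ACGT codes are rejected at
read time.

## Harmonisation

Exposure and outcome records at the same site are aligned to a common
effect allele: a swapped allele order negates the outcome beta;
complementary-strand coding is resolved via allele complements; for
palindromic pairs, where complementing is uninformative, allele
frequencies decide (choosing the orientation that makes the frequencies
agree), with ambiguous cases dropped. Both betas are then oriented so
the exposure beta is positive; the Wald ratio is invariant to this and
the tests check it by property.

Instruments missing from the outcome may be replaced by a proxy with
r² strictly above 0.8, drawn **only from the protein's own
replication-surviving pQTL list** — not a genome-wide proxy search — so
the instrument-validity guarantees extend to the proxy. Both the
exposure and outcome statistics are taken at the proxy variant itself
(the proxy's own exposure association is inherited rather than
re-estimated, a documented choice; the alternative would require
individual-level data).

## MR estimators

With harmonised pairs (β_X, se_X, β_Y, se_Y) per instrument:

* **Wald ratio** (1 instrument): β_Y/β_X with first-order delta SE
  se_Y/|β_X|. First-order (not second-order) matches the convention of
  the summary-data MR ecosystem.
* **IVW** (≥ 2): weighted mean of ratios r_j with weights
  w_j = β_X,j²/se_Y,j², equivalent to weighted least squares of β_Y on
  β_X through the origin. Cochran's Q = Σ w_j (r_j − θ̂)² is reported
  with a χ²(k−1) p-value, and the fixed-effect SE is multiplied by
  max(1, √(Q/(k−1))) — a multiplicative random-effects floor that
  inflates uncertainty under overdispersion but never deflates it.
* **MR-Egger** (≥ 3, run at ≥ 6): weighted regression of β_Y on β_X
  *with* intercept, weights 1/se_Y². The intercept estimates average
  directional pleiotropy; the slope is the adjusted causal estimate.
  The same SE floor applies; p-values use t(k−2).
* **Weighted median** (≥ 3, run at ≥ 6): ordered ratios interpolated at
  normalised cumulative weight 0.5; consistent when valid instruments
  carry ≥ 50% of the weight. SEs by parametric bootstrap (β resampled
  from normals; 1,000 replicates by default, seed exposed).
* **Simple/weighted mode** (≥ 3, run at ≥ 6): kernel density of the
  ratios with bandwidth φ times the modified Silverman rule
  (0.9·min(sd, mad)·k^(−1/5), φ = 1 by default), estimate at the argmax
  of a 512-point grid; bootstrap SEs as for the median.

Dispatch follows instrument count: 1 → Wald; 2–5 → IVW;
≥ 6 → IVW + the four sensitivity estimators. The cut at 6 reflects
that Egger/median/mode have no useful power below that.

## Multiple testing and evidence calls

The primary analysis is cis-only (trans-pQTLs are more likely to act
through pleiotropic pathways); a labelled secondary analysis may add
trans instruments. Bonferroni correction divides α by the number of
proteins with at least one valid cis instrument, per outcome (not
across outcomes — the denominator is a protein count). At full proteome
scale this is 0.05/1,724 = 2.90×10⁻⁵; `bonferroni_threshold()` computes
it from the audit trail and the scan asserts the self-consistency.

## Colocalisation

A significant MR p-value can reflect LD between the pQTL and a distinct
outcome variant rather than a shared signal. For every flagged pair the
cis region (gene ± 500 kb, restricted to variants present in both
traits and the panel) is tested:

* **Single-causal-variant coloc.** Per-variant Wakefield log
  approximate Bayes factors, log ABF = ½(log(1−r) + r·z²) with
  r = W/(V+W), V = se², W the prior effect variance — 0.15² for
  quantitative traits (SD units), 0.2² for binary traits (log-odds).
  Hypothesis sums over H0 (no association), H1/H2 (one trait only), H3
  (both, distinct variants), H4 (both, shared variant) use priors
  p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ and are computed entirely in log space via
  log-sum-exp: plain ABFs overflow doubles near |z| ≈ 40, and cis-pQTL
  z-scores routinely exceed that.
* **SuSiE-based coloc.** To relax the one-causal-variant assumption,
  both traits are fine-mapped by the sum-of-single-effects regression
  on summary statistics (z-scores plus a signed LD matrix): L = 10
  single effects fitted by iterative Bayesian stepwise selection,
  per-effect prior variances estimated by maximum likelihood with a
  lower bound at zero, residual variance fixed at one on the z scale,
  convergence when the evidence lower bound moves by < 10⁻³. Credible
  sets are the smallest variant sets reaching 0.95 coverage, discarded
  below 0.5 purity (minimum within-set |r|). Every surviving pair of
  effects across the two traits is colocalised on its single-effect
  Bayes factors. The implementation is the basic IBSS variant without
  lambda regularisation or refinement passes — adequate for cis
  regions with a handful of signals, and stated as a simplification.

Calls follow the posterior: PP(H4) > 0.8 is strong evidence of a shared
causal signal; PP(H1) > 0.8 means the protein is associated but the
outcome carries no information — read as an underpowered outcome GWAS
rather than evidence against causality (the 0.8 cut on H1 mirrors the
H4 convention); anything else is inconclusive.

## Synthetic data: what it emulates

`sim_scenario()` fixes a variant map (blocks with AR(1) latent
correlation ρ, allele frequencies uniform on 0.15–0.45, positions in a
cis window around a gene), causal cis effects (variance explained per
causal variant, spread ×U(0.5, 1.5) across variants so instrument
strengths differ — a requirement for Egger's regression to be
identified), and an outcome θ·protein + direct variant effects + noise
scaled to unit variance. Genotypes are drawn by thresholding a Gaussian
copula at Hardy–Weinberg quantiles, which preserves marginal binomial
dosages but attenuates the latent ρ (ρ = 0.9 realises dosage r ≈
0.66–0.73 at these allele frequencies; the tests compare the realised
correlations against an analytic oracle for the thresholded bivariate
normal). Proteins are rank-inverse-normal transformed
before per-variant marginal regression, as proteomic GWAS do; binary
outcomes threshold the liability at the case fraction and use
per-variant logistic regression.

Pleiotropic direct effects are **redrawn per replicate** (not fixed per
scenario): a single fixed draw would make the deltas' sample mean a
deterministic offset, and "balanced" pleiotropy would not be balanced
across seeds. They are drawn independently of the protein effects, so
the InSIDE condition holds and the Egger intercept estimates their
mean.

Default study sizes are chosen to mirror a two-cohort proteomic design
at desk scale: pQTL cohorts nA = 10,000 and nB = 6,000 (preserving the
larger/smaller ratio of typical discovery pairs), outcome n = 10,000,
LD panel n = 2,000 (4,000 for the dense-LD colocalisation and
many-instrument pleiotropy scenarios, where panel sampling noise in r²
matters at the 0.001 clump threshold). Per-causal-variant variance
explained is 3% for the MR scenarios (power ≈ 1 at genome-wide
significance in both cohorts) and 5% for the single-signal coloc
scenarios. The `underpowered_outcome` scenario keeps θ = 0.3 but uses
n_out = 50: its defining property is that the outcome's expected
Wakefield evidence at the causal variant is negligible
(E z ≈ θ√(ve·n) ≈ 0.6), which is what makes H1 — not H4 — the correct
posterior call; larger outcome cohorts sit in a half-powered regime
where neither call is stable.

What passing these simulations does **not** show about real data: the
copula LD has no long-range structure or allele-frequency–dependent LD;
aptamer cross-reactivity and epitope artefacts are not modelled; sample
overlap between exposure and outcome cohorts is absent by construction;
and binary outcomes ignore covariates and case–control ascertainment
beyond the case fraction.

## Numerical choices and degenerate inputs

* Hypothesis sums and S3 = S1·S2 − S4 use log-sum-exp and a guarded
  log-difference (returning −∞ when the difference underflows, e.g. a
  one-variant region).
* `susie_rss` regularises non-PSD LD matrices by shifting the diagonal;
  a zero z-vector estimates all prior variances at zero and returns no
  credible sets; non-convergence returns with a warning rather than an
  error.
* Mode estimation returns the common value directly when all ratios are
  equal (the bandwidth rule degenerates); the bootstrap recomputes the
  bandwidth per replicate.
* Clumping, proxy search and best-source selection all have
  deterministic tie-breaks (key order, distance-then-key, first study)
  so a scan rerun with the same seed is byte-identical — asserted by
  diffing output files in the tests.
* Monomorphic panel variants are removed at panel construction (LD is
  undefined); instruments absent from the panel are dropped with an
  audit count rather than crashing a proteome scan.
* P-values from the simulated GWAS are floored at the smallest positive
  double rather than 0, keeping them in (0, 1].

## Simulation sizes used by the test suite

Type-I error: 2,000 null proteins (rejection rate of the IVW test at
α = 0.05 must lie in [0.03, 0.07]; the random-effects floor makes the
test mildly conservative, which the band accommodates). Parameter
recovery: 500 seeds at θ = 0.3 (mean IVW within 0.02), 500 seeds of
balanced pleiotropy (mean weighted median and IVW within 0.05), 40
seeds of directional pleiotropy with ~50 planted instruments (Egger
intercept within 3 SE of δ = 0.03 in ≥ 90% of seeds). Colocalisation:
50 seeds per architecture (H4 > 0.8 for shared, H3 > H4 for distinct,
H1 > 0.8 for underpowered, each in ≥ 90%). Clumping equals an
independent re-derivation on 500 random ≤ 8-variant instances. The
20-protein scan runs twice and must be byte-identical.
`scripts/acceptance.R` recomputes the same quantities from scratch with
seeds derived from its `--seed` argument.

## Known limitations

Single-population LD (no trans-ancestry support); no Steiger filtering,
MR-PRESSO or multivariable MR; no sample-overlap correction; proxies
inherit rather than re-estimate exposure effects; SuSiE is the basic
IBSS-ss variant; binary-outcome effects are on the logistic scale while
the liability simulation is Gaussian, so θ is not recovered on the
log-odds scale (the pathway is exercised, not calibrated).
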