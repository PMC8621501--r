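---
title: "Two-sample Mendelian randomization with mrpipe: models, design choices and simulation evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here: a serum
lipid fraction, standardized to unit variance) on a disease outcome
(here: aneurysm risk on the log-odds scale) from two independent sets of
GWAS summary statistics. For variant $j$ let $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) be its association with the exposure and $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$) its association with the outcome, both expressed for
the same effect allele. If variant $j$ is a valid instrument — associated
with the exposure, independent of confounders, and affecting the outcome
only through the exposure — then
$\beta_{Yj} = \theta\,\beta_{Xj}$, and each variant estimates the causal
log-odds ratio $\theta$ per 1 SD of exposure by the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$.

`mrpipe` implements the full analysis around this model:

1. **Harmonization** (`harmonize`): aligns both studies to a common
   effect allele, resolving swapped alleles, strand flips, and
   palindromic variants.
2. **Instrument selection** (`select_instruments`): genome-wide
   significance ($p < 5\times10^{-8}$), greedy LD clumping, exclusion of
   outcome-associated variants ($p_{out} < 5\times10^{-8}$), and the
   per-variant weak-instrument bound $F = (\hat\beta_X/\sigma_X)^2 > 10$.
3. **Estimation** (`mr_ivw`, `mr_egger`, `mr_weighted_median`,
   `mr_weighted_mode`, `mr_mvivw`, `wald_ratio`): five complementary
   estimators plus the multivariable extension.
4. **Outlier diagnostics** (`mr_presso`): simulation-based global,
   per-variant outlier, and distortion tests.
5. **Cis drug-target MR** (`extract_cis`, `target_mr`): instruments
   restricted to ±100 kb windows around lipid drug-target genes, clumped
   at $r^2 < 0.2$ / 250 kb, reported per 1 SD of trait *lowering*.
6. **Meta-analysis** (`meta_mr`): heterogeneity-gated fixed/random
   pooling across cohorts, with a Bonferroni screen
   (`bonferroni_threshold`, `classify_association`).
7. **Synthetic data** (`simulate_pair` and friends): a seeded generator
   with recorded ground truth, so every stage above is testable by
   parameter recovery and calibration.

## The estimators

**IVW.** The inverse-variance-weighted estimate is the weighted
regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin with
weights $w_j = 1/\sigma_{Yj}^2$:
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$, equivalently the inverse-variance-weighted mean of
Wald ratios. Heterogeneity is measured by Cochran's
$Q = \sum w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ with
$I^2 = \max(0, (Q - df)/Q)$. The *random-effects* variant is the
multiplicative-overdispersion model: the fixed-effects SE is inflated by
$\max\{1, \sqrt{Q/(n-1)}\}$, so heterogeneity widens the interval but
can never shrink it below the fixed-effects one. This matches the
behaviour of the standard two-sample MR software and is the default.

**MR-Egger.** The same weighted regression *with* an intercept, after
orienting every variant so $\hat\beta_X > 0$. Under the InSIDE
assumption (pleiotropic effects independent of instrument strength) the
slope remains a consistent estimate of $\theta$ and the intercept
estimates the average directional pleiotropic effect; its test against
zero is the pleiotropy alarm. SEs carry the same overdispersion
inflation (with $n-2$ df); p-values use the $t$ distribution.

**Weighted median.** The weighted median of the Wald ratios, obtained by
linear interpolation at standardized cumulative weight 0.5 with weights
$1/\mathrm{se}(\hat\theta_j)^2$. Consistent while valid instruments
carry more than half the total weight. The SE comes from a parametric
bootstrap (both association vectors resampled from normals at their
reported SEs; seeded, bit-for-bit reproducible; default 1000
replicates).

**Weighted mode.** The maximizer of a weighted Gaussian kernel density
of the ratios, bandwidth $\varphi \cdot 0.9\min(s, \mathrm{MAD})
n^{-1/5}$ with $\varphi = 1$ by default, evaluated on a 10,000-point
grid spanning the ratio mean ± 5 SD (the bootstrap uses a 512-point
grid; the discretization error this introduces is far below bootstrap
noise). Consistent when the largest cluster of similar ratios comes
from valid instruments. Degenerate inputs (all ratios equal) return the
common ratio directly.

**Multivariable IVW.** For $k$ correlated exposures, the weighted
no-intercept regression of $\hat\beta_Y$ on the $k$ columns of exposure
associations over the union of instruments significant for at least one
exposure, all aligned to the outcome's reported allele. The weighted
design's condition number is reported and a collinearity warning is
raised above 30 (the usual rule-of-thumb); an exactly rank-deficient
design is an error naming the offending exposures. SEs are reported
with overdispersion scaling $\max\{1,\sqrt{RSS_w/(n-k)}\}$ and the
unscaled version is attached, since published analyses are not always
explicit about which they use.

**Wald SE choice.** The single-variant SE is first-order
($\sigma_Y/|\hat\beta_X|$), matching the convention of dividing the
outcome association by the exposure association; the second-order
formula that propagates $\sigma_X$ is available via
`wald_ratio(..., second_order = TRUE)`.

## MR-PRESSO

`mr_presso` detects pleiotropic outliers by comparing each variant's
weighted residual about its *leave-one-out* IVW fit against residuals
from data simulated under the no-pleiotropy model
($\hat\beta_X^* \sim N(\hat\beta_X, \sigma_X)$,
$\hat\beta_Y^* \sim N(b_{(-j)}\hat\beta_X, \sigma_Y)$). Empirical
p-values use the $(1+\text{count})/(1+n_{sim})$ convention, so they are
never exactly zero; per-variant p-values are Bonferroni-multiplied by
the number of variants. Two practical consequences are worth knowing:

* with $n_{sim} = 1000$ (the default) the smallest attainable adjusted
  p-value is $n/1001$, so the outlier test cannot reach $\alpha = 0.05$
  with more than ~50 instruments unless $n_{sim}$ is raised;
* the leave-one-out slope for a variant that dominates the weighted
  design is poorly determined, so the test has little power to flag a
  single dominant variant among otherwise weak instruments — instruments
  should pass the usual strength filters before `mr_presso`.

When outliers are found the function reports both the raw and the
outlier-corrected random-effects IVW (the corrected one is exactly
`mr_ivw` on the reduced set) plus the distortion test, which compares
the observed shift against shifts from random same-size subsets. The
pipeline reports both estimates rather than silently dropping variants;
`analysis_config(primary=)` chooses which one downstream summaries
treat as primary.

## Harmonization rules

Matching is by variant identifier only. Outcome records whose alleles
are swapped relative to the exposure have their effect sign and allele
frequency complemented; alleles that match only after reverse
complementation are strand-corrected first; anything else is dropped
and logged. Palindromic variants (A/T, C/G) cannot be strand-resolved
from labels, so the default policy `infer_by_eaf` keeps them only when
both allele frequencies are outside [0.42, 0.58] and uses frequency
agreement to fix the strand; variants with ambiguous or missing
frequency are excluded. This window is the conventional two-sample MR
default; published lipid–aneurysm analyses are typically silent on the
point, which is why the policy is an explicit argument (`"drop"` and
`"keep"` are also available). Harmonization is idempotent, and
double-flipping the outcome's alleles in the input reproduces identical
aligned pairs — both properties are tested.

## Instrument selection and clumping

Selection applies, in order: exposure significance, LD clumping,
harmonization, outcome-association exclusion, and the F filter, logging
every exclusion with a reason so instrument counts per filter are
auditable. Greedy clumping repeatedly keeps the smallest-p remaining
variant and discards neighbours with $r^2$ at or above the threshold
within the distance window; ties break by position, then identifier, so
the output is deterministic. Two presets matter in practice: the strict
trait-instrument preset ($r^2 < 0.001$, 10 Mb) and the cis drug-target
preset ($r^2 < 0.2$, 250 kb). Published descriptions of lipid
instrument selection quote both $r^2 < 0.001$ and $r^2 > 0.01$/10 Mb in
different places; both are plain arguments here and the strict
combination is the default. The greedy implementation is verified
against an independent brute-force re-execution of the definition on
hundreds of random instances.

Because clumping at $r^2 < 0.2$ leaves non-negligible correlation,
`target_mr(..., correlated = TRUE)` offers a generalized
least-squares IVW using the LD correlation matrix; note $r^2$ carries
no sign, so correlations are taken positive — a documented limitation.
The default estimator ignores residual LD, mirroring common practice,
and the two agree exactly when LD is zero (tested).

## Meta-analysis and the Bonferroni screen

Cohort-level log-OR estimates are pooled fixed-effects
(weights $1/se^2$); DerSimonian–Laird
$\tau^2 = \max\{0,(Q-(k-1))/(\sum w - \sum w^2/\sum w)\}$ and
$I^2$ are computed from the fixed fit, and the random-effects pool
(weights $1/(se^2+\tau^2)$) is used only when $p_Q < 0.1$ **and**
$I^2 > 50\%$ — the gated rule used in the aneurysm analyses this
pipeline reproduces. With only two cohorts $\tau^2$ is a noisy moment
estimate; that is inherent to the design and documented rather than
patched. The Bonferroni screen is $\alpha/(k_{exp}\,k_{out})$ — 0.05
over 4 exposures and 7 outcomes gives 0.0018 at two significant
figures — and `classify_association` labels p-values significant
($p<$ threshold), suggestive (threshold $\le p < 0.05$; the only
coherent reading of the printed suggestive interval), or null.

## The synthetic generator: what it emulates

`simulate_pair` draws, in a documented order from one seeded generator:
MAFs uniform on `maf_range`; instrument membership; true exposure
effects $\gamma_j \sim N(0, \sigma_\gamma^2)$ (optionally correlated
within LD blocks); pleiotropic direct effects
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ for the invalid subset;
and observed effects equal to the truth plus noise at the
frequency-determined SEs
$\sigma_X = (2 n_X p(1-p))^{-1/2}$ and
$\sigma_Y = (2 n_Y p(1-p)\varphi(1-\varphi))^{-1/2}$, the logistic
approximation with case fraction $\varphi$. Two modelling choices
deserve emphasis:

* **Directional pleiotropy is defined on the exposure-raising allele.**
  The reported allele of a variant is arbitrary, and every MR estimator
  is invariant to joint sign flips; if $\alpha$ were attached to the
  reported allele of mean-zero $\gamma$'s, a nonzero $\mu_\alpha$ would
  cancel under orientation and bias nothing. The generator therefore
  multiplies the drawn $\alpha$ by $\mathrm{sign}(\gamma_j)$, which is
  exactly the regime in which IVW bias has the sign of
  $\mu_\alpha/\overline{|\gamma|}$ and the Egger intercept estimates
  $\mu_\alpha$ times the invalid fraction.
* **Effects are sampled before noise and selection is applied
  afterwards**, so winner's curse is a measurable property of the
  pipeline rather than something hidden in the generator.

Defaults (`sim_config()`) encode the study regime the package targets:
a lipid-scale exposure GWAS of $n_X = 190{,}000$; a rare binary outcome
($\varphi = 0.01$) at $n_Y = 400{,}000$; 150 variants of which 60% are
instruments with $\sigma_\gamma = 0.048$, chosen so the true variance
explained $\sum 2p(1-p)\gamma^2 \approx 7.5\%$, inside the 5.6–9.6%
band reported for lipid instruments, with selected instrument counts
(~55–90) matching published lipid instrument sets. MAFs span
0.05–0.5. The generator does not emulate: sample overlap between the
two GWAS (the two-sample assumption is enforced), individual-level
genotypes, winner's-curse-corrected discovery, population stratification,
or allele-frequency measurement error — so passing simulations show
estimator correctness under the stated model, not robustness to those
additional real-data pathologies.

`simulate_multi_exposure` draws per-variant effects for $k$ exposures
from a multivariate normal with a user correlation matrix;
`simulate_gene_region` places variants in a flanked gene window with an
order-based AR(1) LD correlation and reports *marginal* effects
$R\gamma$, the regime cis instrument extraction has to untangle.

## Simulation scenarios behind the acceptance checks

The test suite fixes one scenario per operating characteristic. Problem
sizes (reps) are the package's choice, set so each block completes in
seconds while leaving Monte-Carlo error well inside the asserted bands.

* **Null calibration** — 100 valid instruments, $\theta = 0$; 2000 reps
  for the IVW type-I error (asserted within [0.03, 0.07]; the
  overdispersion cap at 1 makes the test mildly conservative, ~0.04
  observed) and 300 reps for the MR-PRESSO global test (≤ 8%).
* **Recovery** — the default regime with $\theta = 0.3$ run through the
  *full* selection pipeline, 500 reps: mean estimate within 5% of
  $\theta$, 95% CI coverage within [0.92, 0.97]. Winner's curse from
  in-sample significance selection is below 1% here because selected
  instruments sit far above the threshold; regimes with many
  near-threshold instruments attenuate by several percent — measurable
  with the generator by comparing truth-set and selected-set fits.
* **Robustness** — 40% invalid instruments with directional
  $\mu_\alpha = 0.02$. The criterion fixes the contamination but not
  the outcome precision, and the two estimators' contrast is only
  identifiable when the per-variant outcome SE is small: IVW's
  pleiotropy bias $0.4\,\mu_\alpha E[w|\gamma|]/E[w\gamma^2] \approx
  0.13$ is independent of $\sigma_Y$, while the weighted median's
  one-sided-contamination bias scales with the ratio noise
  $\sigma_Y/|\gamma|$. The scenario therefore uses a balanced
  case-control outcome ($\varphi = 0.5$, $n_Y = 300{,}000$,
  $\sigma_Y \approx 0.006$), for which the algebra predicts a median
  bias of ~0.04 and an Egger intercept $z \approx 4$ — borne out at
  ~97% median wins and ~92% intercept power. Under the rare-outcome
  regime ($\sigma_Y \approx 0.035$) the same contamination is
  essentially undetectable (intercept power near $\alpha$) and the
  median's advantage shrinks to ~78% of reps — an honest statement
  about sensitivity analyses on rare outcomes, reproducible by rerunning
  the same scenario with `case_fraction = 0.01`.
* **Outlier recovery** — 30 strong instruments
  ($\sigma_\gamma = 0.1$) passed through selection, then a direct
  effect of 8× the outcome SE planted on the highest-weight instrument
  (the case in which pleiotropy distorts IVW most, and the reason the
  outlier test exists); 200 reps: ≥ 90% detection and ≥ 90%
  corrected-closer-than-raw among flagged reps.

## Known limitations

No proxy-variant lookup for instruments missing from the outcome GWAS,
no Steiger directionality filter, no MR-RAPS or simple-mode estimators,
no multivariable MR-PRESSO, no colocalization for drug targets, and no
cross-ancestry meta-analysis — all deliberately outside scope. The
drug-target gene coordinates ship as an editable GRCh37 TSV rather than
an annotation-service query. Forest figures are intentionally simple
(one panel per outcome, log OR axis, hollow points for CIs crossing 1).

## A minimal worked example

```{r example, eval = FALSE}
cfg <- sim_config(theta = 0.3, seed = 42)
sim <- simulate_pair(cfg)
inst <- select_instruments(sim$exposure, sim$outcome, sim$ld)
mr_ivw(inst$variants)
mr_presso(inst$variants, seed = 1)
```
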