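---
title: "Methods: bidirectional two-sample MR in bidirmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR in bidirmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirmr)
```

## Setting and model

Two-sample Mendelian randomization uses SNPs as instrumental variables to
estimate the causal effect of an exposure (here: a circulating inflammatory
regulator, measured on an inverse-normalized SD scale in a GWAS of several
thousand individuals) on an outcome (a binary disease phenotype, measured as
log-odds in independent case-control GWAS sources). For instrument $j$ with
per-allele exposure effect $\hat\gamma_j$ (SE $\sigma_{xj}$) and outcome
effect $\hat\Gamma_j$ (SE $\sigma_{yj}$), the structural model is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\theta$ is the causal effect (log-odds per SD) and $\alpha_j$ is a
horizontal-pleiotropy term that is zero for a valid instrument. A
*bidirectional* design runs the same machinery in both directions — panel of
exposures against the outcome, then the outcome's own instruments against
each exposure — and uses Steiger filtering to guard against instruments
whose association runs through the outcome.

The three instrumental-variable assumptions are: relevance (enforced by
significance-tier selection and the mean-F bar), exchangeability
(approximated by the confounder screen), and exclusion restriction (probed,
not enforced, by the sensitivity estimators).

## Estimators

All estimators operate on a harmonized instrument set: per-SNP pairs
$(\hat\gamma_j, \hat\Gamma_j)$ expressed for the same effect allele.

**Wald ratio.** $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order
SE $\sigma_{yj}/|\hat\gamma_j|$. The second-order term
$\hat\Gamma_j^2\sigma_{xj}^2/\hat\gamma_j^4$ is available behind a flag; the
first-order form is the two-sample convention and is what the simulations
validate.

**IVW.** $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ with
$w_j = \hat\gamma_j^2/\sigma_{yj}^2$, identical to the zero-intercept
weighted regression of $\hat\Gamma$ on $\hat\gamma$ with weights
$1/\sigma_{yj}^2$. Fixed-effect SE $1/\sqrt{\sum w_j}$; the multiplicative
random-effects variant scales it by $\max(1, \sqrt{Q/(k-1)})$, taking no
under-dispersion credit. The `auto` model (pipeline default) uses random
effects iff the Cochran $Q$ p-value is below 0.05. A single instrument
degenerates to its Wald ratio.

**MR-Egger.** Weighted regression *with* intercept after orienting every
record so $\hat\gamma_j \ge 0$ (the fit is not invariant to allele coding
without orientation). The slope estimates $\theta$ under InSiDE (instrument
strength independent of direct effects); the intercept estimates average
directional pleiotropy and its test is the pleiotropy diagnostic. SEs carry
the same multiplicative floor, $\max(1, \sqrt{RSS_w/(k-2)})$. P-values are
normal by default (the summary-data convention); $t_{k-2}$ is a flag.

**Weighted median.** Wald ratios sorted ascending, weights normalized,
cumulative midpoints $p_j = \mathrm{cum}_j - w_j/2$, estimate interpolated
at $p = 0.5$ (clamped to the extreme ratios outside $[p_1, p_k]$).
Consistent while valid instruments hold a majority of the weight. The SE is
a parametric bootstrap — resample $\hat\gamma_j, \hat\Gamma_j$ from normals
at their SEs, recompute, take the SD — with a mandatory seed and a default
of 1000 replicates, so stochastic SEs are exactly reproducible.

**MR-PRESSO.** Observed statistic
$RSS = \sum_j \sigma_{yj}^{-2}(\hat\Gamma_j - \hat\theta_{(-j)}\hat\gamma_j)^2$
with leave-one-out IVW slopes $\hat\theta_{(-j)}$. The null distribution is
simulated ($\hat\Gamma_j^* \sim N(\hat\theta_{(-j)}\hat\gamma_j, \sigma_{yj})$,
$\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{xj})$, statistic recomputed);
the global p-value is the add-one estimator $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$,
never exactly zero. Per-SNP outlier p-values compare each observed squared
residual with its own simulated distribution and are Bonferroni-corrected by
$k$; outliers are reported only when the global test is significant. The
corrected estimate is IVW on the remaining SNPs. The distortion test refers
the observed relative change $(\hat\theta_{corr}-\hat\theta_{raw})/\hat\theta_{raw}$
to the distribution obtained by removing equally many SNPs at random — the
exact resampling null is not fully pinned down by the method's published
shorthand, and random-removal is the expected-distortion construction we
adopt. Note the add-one floor: the smallest attainable corrected outlier
p-value is $k/(n_{sim}+1)$, so outlier detection at level 0.05 needs
$n_{sim} \gtrsim 20k$; the default $n_{sim} = 1000$ covers instrument sets
up to $k \approx 50$.

**Heterogeneity.** $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$, df $k-1$,
$I^2 = \max(0, (Q - df)/Q)$.

## Instrument selection and QC

* **Two-tier selection.** Genome-wide $5\times10^{-8}$ primarily; when
  fewer than 3 independent (post-clumping) SNPs survive, the trait falls
  back to $5\times10^{-6}$ — the standard compromise for molecular traits
  with few genome-wide hits. `tier_mode` can force either tier so both
  designs of a two-tier study can be reproduced.
* **Clumping.** Greedy by p-value: the best remaining SNP becomes an index;
  neighbours on the same chromosome within 10 Mb with $r^2 > 0.001$ are
  removed. Ties on p-value resolve to the lexicographically smaller SNP id,
  making the result input-order invariant. SNPs absent from the LD panel
  are treated as unlinked with a warning — summary panels are incomplete
  and a hard failure would block a 41-trait batch.
* **Proxies.** An instrument missing from the outcome is replaced by the
  highest-$r^2$ outcome SNP with $r^2 > 0.80$ (strict), its effect carried
  across via the panel's allele-phase sign. Substitution happens before
  harmonization, so a palindromic proxy is still subject to the
  palindromic filter.
* **Harmonization.** Allele pairs matched directly, by swap (sign flip),
  by strand complement, or both; palindromic SNPs are deleted by default
  because strand cannot be resolved from alleles. A frequency-based rescue
  (`keep_if_eaf_informative`, both EAFs at least 0.08 from 0.5) exists but
  is not the default: with no statement of how frequencies should
  arbitrate, we do not guess.
* **Confounder screen.** A SNP associated with any measured confounder at
  $p < \alpha/k$ — $k$ the *pre-filter* instrument count — is removed.
  Applied in both directions by default (`screen_reverse`).
* **Mean F.** Default is the per-SNP squared z-score mean,
  $\bar F = k^{-1}\sum (\hat\beta_j/se_j)^2$, which needs no allele
  frequencies; the variance-explained form
  $F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$ is a flag. The source study names
  an F-statistic without a formula; the per-SNP mean is the common
  two-sample choice.
* **Steiger filter.** Per SNP, variance explained is approximated by
  $r^2 = F/(F + n - 2)$; a SNP with $r^2_{out} > r^2_{exp}$ (strict) is
  removed. The z-test compares Fisher-transformed correlations with
  variance $1/(n_{exp}-3) + 1/(n_{out}-3)$. For the binary outcome this is
  applied on the log-odds scale with the *effective* sample size
  $n_{eff} = 4/(1/n_{case} + 1/n_{ctrl})$ — a documented approximation that
  keeps $r^2$ comparable across a quantitative exposure and an unbalanced
  case-control outcome; the generator stores $n_{eff}$ in the outcome `n`
  column so the approximation is self-consistent.

## Meta-analysis and evidence classification

Per-source primary estimates (IVW, or the Wald ratio when only one
instrument survives) are pooled with inverse-variance fixed effects, or
DerSimonian–Laird random effects
($\tau^2 = \max(0, (Q-df)/(\sum w - \sum w^2/\sum w))$) when Cochran $Q$ is
significant at 0.05 — mirroring the practice of defaulting to fixed effects
unless heterogeneity is detected. With two sources $I^2$ is reported but
flagged unstable. Forward effects convert to odds ratios per 1-SD exposure,
$e^{\beta}$, and percent risk change $(OR-1)\times100$; display rounding
(one decimal for percents) never touches stored values. Evidence labels use
strict cuts: meta p below $0.05/n_{exposures}$ (0.0012 for a 41-trait
panel) is *strong*; between that and 0.05 *suggestive*; else *none*.

## The synthetic generator

`simulate_pair()`/`simulate_study()` emulate the *structure* of a
cytokine-vs-retinopathy study: a quantitative exposure GWAS of $n = 8{,}293$
and two case-control outcome sources (2,025/284,826 and 398/2,848) with
zero sample overlap. Per instrument: $\gamma_j \sim N(\mu_\gamma,
\sigma_\gamma)$; with probability $\rho$ a direct effect $\alpha_j \sim
N(\mu_\alpha, \sigma_\alpha)$ (optionally correlated with $\gamma_j$ to
violate InSiDE); $\Gamma_j = \theta\gamma_j + \alpha_j$. Observed effects
are drawn at the analytic SEs $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$
(effective $n$ for case-control), so generated records satisfy the
$p = 2\Phi(-|\beta/se|)$ invariant by construction. Null filler SNPs make
thresholding non-trivial; LD blocks attach satellite SNPs at declared $r^2$
with signed phase (summary-level LD — sufficient for clumping and proxy
logic, no haplotypes); a configurable fraction of SNPs is palindromic and
the outcome representation is randomly allele-swapped and strand-flipped so
harmonization does real work. Reverse-causation traits draw the SNP effect
on the *outcome* ($\delta_j$) and give the exposure only the mediated part
$\gamma_j = \theta_{rev}\delta_j$. All randomness flows from one seed;
identical truth objects produce byte-identical files.

What the generator does **not** emulate: realistic allele-frequency
spectra, genome-wide LD structure, population stratification, or sample
overlap. Passing tests therefore demonstrate the correctness and
calibration of the *analysis machinery* under the stated generating model,
not robustness to those data pathologies.

### Scenario presets and why they look the way they do

| scenario | k | key settings | purpose |
|---|---|---|---|
| `null` | 30 | $\theta=0$ | type-I error of IVW and the PRESSO global test |
| `causal` | 50 | $\theta=0.1$, $\gamma \sim N(0.15, 0.05)$ | bias and CI coverage |
| `balanced_pleiotropy` | 200 | $\rho=0.3$, $\mu_\alpha=0$ | heterogeneity without direction |
| `directional_pleiotropy` | 300 | $\rho=0.3$, $\mu_\alpha=0.25$, $\sigma_\alpha=0.05$, $\gamma \sim N(0.15,0.07)$ | Egger-intercept detection, median robustness |
| `outliers` | 30 | two SNPs planted at $\alpha = 10\sigma_\alpha$ | PRESSO outlier detection |
| `reverse_causation` | 20 | $\theta=0$, $\theta_{rev}=0.3$, $\delta \sim N(0.35,0.05)$ | Steiger filtering signal |
| `weak_instruments` | 30 | $\gamma \sim N(0.055, 0.015)$ | mean F in the 5–15 window |

Two presets deserve their design rationale spelled out.

*Directional pleiotropy uses a polygenic exposure (k = 300).* The Egger
intercept estimates $\rho\mu_\alpha$ against a residual that contains the
irreducible Bernoulli mixing variance of valid/invalid instruments,
$\rho(1-\rho)\mu_\alpha^2$; its z-statistic is bounded above by
$\sqrt{\rho/(1-\rho)} \cdot \sqrt{k/(1 + \bar x^2/\mathrm{var}(x))}$ no
matter how strong the pleiotropy. In addition the mandatory orientation
$\hat\gamma_j \ge 0$ randomizes the sign of $\alpha_j$ for instruments with
$\gamma_j$ near zero — exactly the points with maximal intercept leverage —
so instrument effects must be bounded away from zero while retaining
spread. At study-scale $k$ (tens of SNPs) the intercept test simply does
not have usable power under a 30% invalid fraction; the preset therefore
uses the polygenic-exposure design standard in MR robustness simulations
(hundreds of instruments, $\gamma \sim N(0.15, 0.07)$, under 2% negative
mass), where the predicted and realized detection rate is ~90–95%.

*Weak instruments are evaluated without significance selection.* Selection
at $p < 5\times10^{-6}$ implies $F \gtrsim 21$ for every surviving SNP, so
a mean F of 5–15 cannot coexist with selection; the preset's mean F is
meant to be computed on the instrument set directly, which is how the
weak-instrument warning in the pipeline is exercised.

Defaults elsewhere: maf $\sim U(0.1, 0.4)$; 15% palindromic SNPs (close to
the genome-wide share of A/T+C/G variants); 300 null fillers; outcome
representation scrambled with probability 0.3 each for swaps and strand
flips. These were fixed once, before the validation suite was frozen.

## Numerical and reproducibility choices

* Ties in clumping and proxy search break to the smaller SNP id.
* Add-one (permutation-style) estimators for all resampling p-values.
* SE floors at 1 for both multiplicative dispersion scalings.
* Degenerate pipeline inputs (no instruments, everything palindromic,
  everything Steiger-removed) yield a flagged `not estimable` result, never
  an exception — a 41×2×2 batch must not die on one degenerate trait.
* Per-analysis seeds derive deterministically from the run seed and the
  trait-pair identity (`seed_for()`), so results are independent of batch
  composition and byte-identical across reruns.
* Stored tables are never display-rounded.

## Validation design

The test suite and `scripts/acceptance.R` use: 1000 random instances for
the IVW/Egger weighted-least-squares oracle equivalence (tolerance
$10^{-10}$); 500 replicates for IVW type-I error (accepted band
$[0.03, 0.07]$) and for recovery under `causal` (|mean bias| < 0.005,
coverage ≥ 90%); 200 replicates for the PRESSO global null (band
$[0.02, 0.08]$, $n_{sim} = 1000$) and the directional-pleiotropy hierarchy
(intercept detection ≥ 80%, weighted-median beating IVW's absolute bias in
≥ 70%); 50 seeds for planted-outlier detection (≥ 90%) and Steiger
reverse-SNP removal (≥ 80%). These sizes make each Monte-Carlo band at
least ~2 binomial SDs wide around its target while keeping the whole suite
in a few minutes on one CPU.

## Limitations

Wald SEs ignore exposure-side noise by default (first-order); the Steiger
$r^2$ for binary traits is an effective-sample-size approximation; LD is
summary-level; the DerSimonian–Laird estimator with two sources is
reported with its known instability flagged; and the generator's clean
normal world cannot surface harmonization failures caused by mislabeled
strands *and* frequencies simultaneously — real-data audits should still
inspect the dropped-SNP sidecars.
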