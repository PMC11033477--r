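---
title: "Models and design choices in refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

`refstab` evaluates candidate reference genes for RT-qPCR normalization.
This vignette records the statistical models the package implements, the
conventions it fixes where the literature leaves room, and what its
synthetic-data tests do and do not establish.

## The data model

The universal input is a `ct_table`: a genes × samples matrix of
cycle-threshold values with one group label per sample. Ct is the PCR
cycle at which fluorescence crosses a fixed threshold and is inversely
log-proportional to starting template, so *one cycle ≈ one doubling* for
a perfectly efficient assay. The package enforces Ct ∈ (0, 45]: values
outside that range are instrument artifacts, not measurements.

Three structural assumptions run through everything downstream:

* **Additivity on the Ct scale.** A sample-wide loading shift (more or
  less cDNA in the well) adds the same constant to every gene's Ct of
  that sample. ΔCt, geNorm, and NormFinder are all invariant to such
  shifts by construction; BestKeeper deliberately is not, because it
  describes raw Ct.
* **Replicate exchangeability.** Biological replicates of one unit are
  interchangeable; `aggregate_replicates()` collapses them by mean
  (default) or median before analysis. Whether technical triplicates
  should be pre-averaged is assay-specific, so replicate handling is a
  flag (`aggregate = "none"` treats every column as a sample).
* **Pairwise-complete missingness.** Each statistic drops exactly the
  samples that are missing for the quantities it compares (a gene pair
  for ΔCt/geNorm, a gene for BestKeeper descriptives) and records a
  warning. No imputation is done anywhere.

## Relative quantities

geNorm operates on linear-scale relative quantities, not Ct.
`to_relative_quantities()` uses

$$q_{ij} = E_i^{\,\min_j Ct_{ij} - Ct_{ij}}, \qquad E_i = 1 + \text{efficiency}_i/100,$$

anchoring each gene at its minimum Ct so that $q \in (0, 1]$ and
$\max_j q_{ij} = 1$ — the common geNorm convention, and one whose
invariant is directly testable. An anchor at the mean Ct would change no
ratio and hence no stability value; the minimum keeps the scale
interpretable ("fraction of the best-expressed sample"). The default
base is 2 (100 % efficiency), because published stability rankings are
computed from raw Ct ranks without efficiency correction; per-gene
efficiencies are an opt-in argument, accepted in the [50, 150] % range
(anything outside is an implausible assay and an error, not a warning).

## Amplification efficiency

`fit_standard_curve()` fits ordinary least squares
$Ct = b_0 + b_1 \log_{10}(\text{dilution})$ over a dilution series
(≥ 3 points, ≥ 2 distinct dilutions) and converts the slope with
$E = (10^{-1/b_1} - 1)\times 100\,\%$. $R^2$ is the squared correlation
of fitted vs observed values, computed directly from the residual and
total sums of squares so an exactly collinear series returns 1 without
numerical warnings. A non-negative slope is rejected: it cannot come
from an amplifying assay. Efficiency is *reported* to 2 decimals but
never rounded internally.

## The four stability statistics

**Comparative ΔCt.** For each ordered pair (i, k) the per-sample
differences $Ct_i - Ct_k$ are formed and their sample SD (n−1
denominator) taken; gene i's stability is the mean SD over all partners.

**geNorm.** Pairwise variation $V_{ik} = SD_j[\log_2(q_i/q_k)]$,
$M_i = \text{mean}_k V_{ik}$. At base 2,
$\log_2(q_i/q_k)$ equals $Ct_k - Ct_i$ up to a constant, so *initial M
equals the ΔCt stability exactly* — the package's cross-method oracle,
asserted to 1e−9 in the tests. The gene with the largest M is removed
and M recomputed until two genes remain. Conventions fixed here:

* the reported per-gene value is its M *at the step of its elimination*;
  the final two genes — which the algorithm can never separate — both
  receive their mutual variation from the 2-gene panel and share rank 1.
  This matches how published tables show one M per gene with a tie only
  at the top. The full-panel ("initial") M is kept in the details.
* ties for the largest M are broken by removing the lexicographically
  *last* gene id — deterministic and documented, nothing more.
* $V_{n/n+1} = SD_j[\log_2(NF_n/NF_{n+1})]$ over the stability-ordered
  list, $NF_n$ the per-sample geometric mean of the n most stable genes'
  quantities. The reported recommendation is the smallest n (minimum 2)
  with V < 0.15, the conventional threshold; the threshold is a
  parameter, not a constant.

**NormFinder.** Log2 expression $y = -Ct \cdot \log_2 E$ (so base 2
gives $y = -Ct$; the sign convention only flips reported deviations,
stability is sign-symmetric). Per-sample means over genes are
subtracted, removing loading. Ungrouped mode scores each gene by the
sample SD of its centered values. Grouped mode computes per (gene,
group) the mean deviation $d_g$ from the size-weighted grand mean and
the unbiased intragroup variance $s^2_g$, estimates the between-group
variance by method of moments,
$\tau^2 = \max(0, \sum_g d_g^2/(G-1) - \text{mean}_g(s^2_g/n_g))$,
shrinks $\tilde d_g = d_g \cdot \tau^2/(\tau^2 + s^2_g/n_g)$ (zero when
$\tau^2 = 0$), and reports
$S = \text{mean}_g(|\tilde d_g| + \sqrt{s^2_g/n_g})$. The original
method's interior is under-specified in secondary sources; these
formulas are this package's documented variant, chosen so that (a) the
size-weighted raw deviations sum to zero exactly, (b) with no true
group effects $\tau^2 \to 0$ and S reduces to the mean standard error,
and (c) with one group S is exactly the SD of the centered values —
each of which is asserted in the test suite. A group with a single
sample has undefined variance and is an error naming the group; a
single-group table falls back to ungrouped mode with a warning.

**BestKeeper.** Descriptives of raw Ct per gene; the ranking value is
the dispersion, by default the sample SD. The historical tool used the
mean absolute deviation, offered here as
`dispersion = "mean_abs_dev"`; the SD default matches how published
"BestKeeper stability" columns behave. The per-sample index (geometric
mean Ct over genes) and each gene's Pearson r against it — with a
two-sided t-test p on n−2 df — are reported for inspection only and
never enter the rank: published rankings order by SD. A constant gene
has undefined correlation, reported as `NA`, not an error.

## Consensus

Per-method ranks are *dense* (ties share a rank, no gaps) and aggregated
by their geometric mean; genes are ordered ascending, ties broken by
mean rank then gene id, and the first two genes form the recommended
pair — a pair, because at least two reference genes are standard
practice and the V-rule's minimum is 2. All four methods are equally
weighted; the method subset is configurable. Note that a consensus
recomputed by the RefFinder web service can differ in rank ties, since
its internal method variants and tie conventions are not published;
matching it gene-for-gene is explicitly not a goal.

## Target-gene validation

`relative_expression()` implements 2^−ΔΔCt with a multi-gene reference:
the per-sample reference aggregate is the arithmetic mean of reference
Ct values, which is exactly the geometric mean of their relative
quantities at base 2 — the standard multi-reference extension. The
calibrator is a *group*; its mean ΔCt anchors ΔΔCt at zero, so the
calibrator group's mean log-fold is 0 by construction. Because the
original study does not name its calibrator tissue, the calibrator is a
required explicit argument rather than a default. Efficiency-corrected
(Pfaffl-type) ratios are out of scope. Group standard errors are
computed on the fold-change scale across biological replicates.
`group_anova()` runs one-way ANOVA with Tukey HSD at α = 0.05 and
builds a compact letter display from the maximal cliques of the
not-significantly-different graph (groups sharing a letter are
indistinguishable); identical values short-circuit to p = 1 and a
single letter.

## The synthetic-data generator

`simulate_ct()` draws

$$Ct_{igjr} = \mu_i + L_j + \delta_i u_{ig} + \varepsilon_{igjr},$$

with loading $L_j \sim N(0, \text{loading\_sd}^2)$ per biological
sample, group effects $u_{ig} \sim N(0, 1)$ per (gene, group) scaled by
$\delta_i$, and noise $\varepsilon \sim N(0, \sigma_i^2)$ per
measurement. All draws are standard normals scaled afterwards, so the
draw stream — and hence the realization — is aligned across noise
settings with the same seed; the caller's RNG state is saved and
restored. The recorded truth is the per-gene disturbance
$\sqrt{\sigma_i^2 + \delta_i^2 v_i}$, with $v_i$ the population variance
(denominator G) of the realized group effects — the quantity the
stability statistics estimate — and the ordering it induces.

`paper_like_design()` mirrors a typical insect reference-gene study:
a 10-gene candidate panel (ACT, ARF1, AK, EF1a, GAPDH, aTUB, RPL6,
RPL13, RPS3, RPS18), four condition designs (3 adult ages, 6 tissues,
5 temperatures, 2 sexes), 3 biological replicates per group. Defaults
and why:

* **σ, δ profile**: ribosomal protein genes RPL6/RPL13 most stable
  (σ ≈ 0.12, δ ≈ 0.05 cycles), GAPDH/ACT least (σ ≈ 0.4–0.45,
  δ ≈ 0.8–0.9), giving ΔCt stabilities in the 0.5–1.3 cycle range
  typical of published panels and a > 3× disturbance separation between
  the two most and two least stable genes. Group effects are drawn per
  (gene, group) rather than as fixed patterns so the truth stays
  computable for any condition.
* **loading_sd = 0.25 cycles**: calibrated from published stability
  tables rather than guessed — for the most stable genes of a
  six-tissue panel, raw-Ct SD (≈ 0.47) only slightly exceeds the
  ΔCt-implied per-gene noise (≈ 0.6/√2 ≈ 0.43), implying loading shifts
  of roughly $\sqrt{0.47^2 - 0.43^2} \approx 0.2$–0.3 cycles. Rank
  recovery is flat across that whole band.
* **n_technical = 1**: the emulated studies feed one Ct per biological
  replicate to the stability programs; technical triplicates, where
  wanted, share σ with biological noise (a documented simplification)
  and are collapsed by `aggregate_replicates()`.

**What a green test establishes — and what it does not.** The generator
produces Gaussian, additively-shifted Ct with exchangeable group
effects. Real data add what it omits: amplification inhibitors,
plate/batch effects correlated within runs, heteroscedastic noise at
high Ct, primer-dimer artifacts, and truly fixed (not random) tissue
expression patterns. Passing the rank-recovery test therefore shows the
*pipeline* is correct and well-powered under its own model at realistic
noise, not that any particular laboratory panel will behave this way.
Published per-gene stability values cannot be reproduced at all — the
underlying raw Ct tables are not public — so the package reproduces the
published *efficiency* surface exactly, and the stability machinery is
verified against hand-worked fixtures, closed-form limits
(iid noise: M → √2·σ; NormFinder S → σ√((K−1)/K)), cross-method
identities, and ground-truth recovery instead.

## Numerical conventions

* Sample SDs use the n−1 denominator everywhere.
* Dense ranks: `match(x, sort(unique(x)))`.
* Degenerate inputs fail loudly and early (duplicate records name the
  offending triple; out-of-range Ct cites the contract; an all-equal
  dilution series is a "degenerate design"); the one deliberate
  exception is the undefined BestKeeper correlation of a constant gene,
  which is `NA` by design.
* Monte-Carlo assertions in the test suite use 5 % relative tolerance
  at n = 800–2000 with fixed seeds; simulation sizes were chosen to
  keep the whole suite under half a minute.

## Known limitations

* No instrument-native input (RDML, CFX exports) — CSV only.
* No raw-fluorescence or per-well efficiency estimation (LinRegPCR
  territory).
* geNorm is implemented to M and V; the full normalization-factor
  workflow of the original VBA tool (qbase+) is out of scope.
* The NormFinder interior is a documented variant, not a bit-exact port
  of the original Excel add-in.
* Consensus ranks mirror the comprehensive-ranking convention but will
  not necessarily tie-break identically to the RefFinder web service.
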