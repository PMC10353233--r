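---
title: "Spatial price indexes for medical services: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial price indexes for medical services: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialppp)
```

## The problem

Administered fee schedules price the same physician services differently
across neighbouring regions. To compare *price levels* rather than single
fees, one needs a spatial analogue of a consumer price index: a purchasing
power parity (PPP) for medical services. `spatialppp` implements the full
estimation chain for a set of regions that share a common service
nomenclature (the situation created by a national specification of service
codes): match services, estimate parities within groups of similar services,
aggregate with expenditure weights, and make the comparisons transitive.

The worked case is a four-region comparison (Shanghai, Jiangsu, Zhejiang,
Anhui) whose bilateral Fisher matrix is shipped as a fixture; everything
upstream of that matrix is exercised on synthetic systems with known ground
truth, because the underlying fee schedules and claims-derived weights are
not redistributable.

## The estimation chain

**1. Matching.** Services are matched across regions by exact service code
(a normalized-name fallback exists but is off by default; codes are the
national key, names are noisier). Only services present in *every* region
enter the comparison. A matched service priced at or below zero in any
region is excluded and counted: published schedules do contain 0.00 entries,
and a geometric mean is undefined on them. Exclusion, rather than
imputation, keeps the estimand clean; the count is reported so the loss is
visible. When a schedule carries several price tiers per code, an optional
pre-pass keeps the maximum (the provincial ceiling, which is the quantity
set by the price administration and hence the comparable one).

**2. Basic-heading parities.** Within each of the four service categories
(basic headings) the parity of region $j$ on base $k$ is the Jevons index,
the unweighted geometric mean of price ratios over the heading's $N_h$
services:
$$\mathrm{PPP}^{(h)}_{jk} = \prod_{i=1}^{N_h}\left(\frac{P_{ij}}{P_{ik}}\right)^{1/N_h}.$$
It is computed as a difference of mean log prices: with thousands of
services a raw product of ratios under- or overflows double precision. The
country-product-dummy (CPD) regression — $\log P_{ij} = \alpha_j + \beta_i +
\varepsilon_{ij}$, base region's $\alpha$ fixed at 0, solved by sparse
normal equations — is provided as the second route. On a complete tableau
the two are algebraically identical, which the test suite asserts to 1e-10;
CPD additionally handles missing cells (`cpd_fit()`), where the two differ.
The dummy coding is equivalent to sum-to-zero coding up to a constant that
cancels in every parity ratio.

**3. Aggregation.** Expenditure weights exist per heading and region only
(claims data aggregate to the four categories), so weights enter at the
heading level and nowhere else. For base $j$ and comparison $k$:
$$L_{kj} = \sum_h \mathrm{PPP}^{(h)}_{kj} W_{hj}, \qquad
  P_{kj} = \Big(\sum_h \frac{W_{hk}}{\mathrm{PPP}^{(h)}_{kj}}\Big)^{-1}, \qquad
  F_{kj} = \sqrt{L_{kj} P_{kj}},$$
the base-weighted arithmetic mean, the comparison-weighted harmonic mean,
and their geometric mean (Fisher, which alone satisfies region reversal:
$F_{jk}F_{kj} = 1$). The Paasche–Laspeyres spread
$\mathrm{PLS}_{jk} = |\log(L_{jk}/P_{jk})|$ measures how much the two
regions' expenditure structures disagree.

**4. Multilateral levels.** Bilateral Fisher indexes are not transitive.
Two standard repairs are implemented:

* **GEKS**: $\mathrm{GEKS}_{jk} = \prod_{i=1}^{M} (F_{ji} F_{ik})^{1/M}$,
  the geometric mean over all bridge regions. It treats regions
  symmetrically and is the transitive matrix closest to $F$ in the
  log-least-squares sense (asserted numerically for $M=3$ against direct
  minimization).
* **MST** (Hill): build the minimum spanning tree of the complete region
  graph with PLS edge weights, then chain Fisher links along tree paths.
  Pairs with the most similar expenditure structures — where Laspeyres and
  Paasche nearly agree and the Fisher link is most reliable — are linked
  directly; transitivity follows from path uniqueness.

Results are presented as base-100 matrices ("the column region = 100") with
half-even rounding to 2 decimals; rounding is presentation-only and never
fed back into computation.

**5. Back-casting.** A reference-year comparison is moved to earlier years
by pure deflation with each region's CPI for medical services
(previous-year = 100 convention by default; fixed-base accepted):
$\mathrm{level}(r,t) = \mathrm{level}(r,\mathrm{ref})\big/\prod_{s=t+1}^{\mathrm{ref}}
\mathrm{CPI}_r(s)/100$, then the panel is renormalized to the reference
region and year. Cross-region comparability in earlier years is inherited
from the reference year — this is a preliminary estimate, not a
year-specific re-matching, and the package makes no stronger claim.

## Numerical choices

* All geometric means, CPD fits and GEKS averages run in log space.
* `geks()` and `mst_levels()` antisymmetrize the log Fisher input — each
  pair is replaced by $\sqrt{F_{jk}/F_{kj}}$ — before averaging or chaining.
  On an exactly computed Fisher matrix this is a no-op (Fisher is reciprocal
  by construction); on a matrix re-entered from a published table rounded to
  2 decimals it removes the ~1e-4 reciprocity violation that rounding
  introduces, so transitivity and reciprocity of the output hold to machine
  precision for any input.
* Kruskal's greedy edge addition with union-find builds the MST; ties are
  broken by lexicographic region-pair order. Ties have measure zero on real
  spreads but the tie-break makes reruns byte-identical. Optimality is
  tested against exhaustive enumeration of all spanning trees for
  $M \le 7$.
* Quartiles in descriptive summaries use linear interpolation between order
  statistics (`quantile` type 7), recorded in the output.
* Weights are renormalized to sum to one on load, with a warning when the
  input was off by more than 1e-6; negative shares are errors.
* The spread of a region with itself is defined as exactly 0.

## The synthetic generator

`generate_system()` draws a complete $M \times N$ price system with known
truth: price of service $i$ in region $r$ is
$\mathrm{base}_i \cdot \lambda_r \cdot \tau_{r,h(i)} \cdot e^{\eta_{ir}}$,
with

* $\lambda_r$ — true level multipliers, default 1.28 / 0.93 / 1.00 / 1.03
  (reference region third), matching the magnitude of the published
  four-region comparison;
* $\mathrm{base}_i \sim \mathrm{Lognormal}(\log 150,\ 1.5^2)$ CNY — median
  ~150 CNY and maxima in the tens of thousands over 3000 draws, the scale
  and skew of real schedules. A single lognormal cannot reproduce the
  published quartiles *and* maxima simultaneously; the median and the tail
  were prioritized, so the simulated interquartile range is narrower than a
  real schedule's;
* $\tau_{r,h}$ — per-region, per-heading tilt,
  lognormal with $\sigma = 0.1$ by default and geometric mean 1 across
  headings, so heading parities disagree and the Laspeyres–Paasche spread,
  and hence the MST, are non-trivial while the region's overall multiplier
  stays $\lambda_r$;
* $\eta_{ir} \sim N(0, 0.3^2)$ — item-level noise, multiplicative so prices
  stay positive and log-scale proportionality is preserved in expectation;
* weights per region from a Dirichlet with concentration 8 per heading —
  moderately uneven shares, drawn once per region;
* 750 services in each of 4 headings (3000 matched items, the scale of the
  real matched basket).

What the generator does **not** emulate: tiered institutional pricing,
prefecture-level decentralization, correlated noise within service
families, and quality differences between regions. Passing recovery tests
therefore show the estimators are correct for independently noisy,
multiplicatively separable price systems — not that real schedules satisfy
those assumptions.

With noise and tilt at zero the system is exactly proportional and the full
pipeline returns the configured $\lambda$ ratios to 1e-10 through both GEKS
and MST — the headline correctness test. With `noise_sigma = 0.3` and 3000
items, the log estimates are unbiased for $\log \lambda$: over 200 replicate
seeds the mean log estimate lies within 3 Monte-Carlo standard errors of
truth, and each replicate's spread is of order
$0.3/\sqrt{3000} \approx 0.5\%$, as geometric-mean sampling theory predicts.
These problem sizes (200 replicates, 3000 items, 4 regions) keep the whole
suite under half a minute while leaving the Monte-Carlo bands tight enough
to detect a bias of a few tenths of a percent.

## The packaged four-region fixture

The 2020 bilateral Fisher matrix for Shanghai/Jiangsu/Zhejiang/Anhui is
shipped as `yrd_fisher_matrix()` (base-100 as published, returned on the
ratio scale). Applying GEKS to it reproduces the published multilateral
table to within 0.02 on the base-100 scale — the residual is the 2-decimal
rounding of the inputs. The spanning tree behind the published MST table is
shipped as `yrd_mst_tree()` and is flagged `inferred`: the spreads that
would derive it were not published, so the edge set
{Shanghai–Jiangsu, Shanghai–Zhejiang, Zhejiang–Anhui} was reconstructed
from the consistency of the published MST table with the Fisher matrix.
Chaining along it reproduces that table to 2 decimals.

The published per-region descriptive statistics and the 2015 back-cast
values depend on the full schedules and CPI series, which are not
redistributable; those operations are therefore validated by property tests
and the synthetic system, not against the published numbers.

## Open choices made here

* Near-matches (same service, slightly different code or name) are not
  adjudicated; strict code equality is the default and the name fallback is
  opt-in. With a national code specification this loses few items and never
  mismatches.
* Whether zero-priced services were dropped before or after matching in the
  original study is unknowable from the published account; this package
  drops them after matching, which is the conservative order (a zero
  anywhere removes the service everywhere, keeping the basket identical
  across regions).
* The CPI convention (previous year = 100) is the statistical-yearbook
  standard; a fixed-base switch is provided since sources differ.

## Limitations

No quality adjustment of services; no within-region price variation (the
schedules' ceilings are compared); no standard errors on the indexes
themselves (the Monte-Carlo machinery quantifies estimator error only under
the generator's assumptions); extension points, not implementations, for
Törnqvist/Walsh bilateral forms and other multilateral methods.
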