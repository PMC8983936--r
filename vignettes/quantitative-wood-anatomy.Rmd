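---
title: "Methods: intra-ring vessel traits, dual standardization, and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-ring vessel traits, dual standardization, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qwanat)
```

## The problem

In diffuse-porous hardwoods such as European beech, the water-conducting
vessels change size and packing gradually across each annual ring: wide,
often grouped vessels early in the season, smaller and denser vessels
toward the ring end. Quantitative wood anatomy measures every vessel in
dated rings (lumen area and radial position, typically exported by image
analysis software as cell tables) and asks how the resulting traits vary
within rings, between trees and sites, and with climate. `qwanat`
implements that analysis chain as composable functions: sectorization and
trait computation, two complementary standardizations, chronology
robustness statistics, permutation-based group comparisons, monthly
climate correlations, and extreme-year contrasts — plus a synthetic
generator so that every stage can be exercised and validated without
field data.

## Sector traits

Vessels are assigned to `k` equal-width sectors of the relative radial
position axis (`sector = floor(p * k) + 1`, position 1 closing the last
sector). Five sectors give robust per-sector samples; ten give a
semi-continuous intra-ring profile. Positions below 0.5 are
conventionally read as early formed wood, the rest as late formed wood.

Per sector (and for the pooled ring, reported as sector 0) the package
computes:

* **VA** — mean vessel lumen area (µm²);
* **VA95** — the 95th percentile of lumen area (µm²), a robust proxy for
  maximum vessel size;
* **DH** — the hydraulically weighted mean diameter `Σd⁵ / Σd⁴` (µm)
  over equivalent circular diameters `d = 2√(A/π)`. This convention
  weights conduits by their conductance contribution; the alternative
  `(Σd⁴/n)^¼` exists in the literature, and `Σd⁵/Σd⁴` was chosen because
  it is the convention of the vessel-centred hydraulics literature this
  trait set comes from. DH always lies between the smallest and largest
  diameter and above the unweighted mean.
* **KH** — theoretical hydraulic conductivity by the Hagen–Poiseuille
  law, `(πρ / 128η) Σ dᵢ⁴`, with diameters in m and constants for pure
  water at 20 °C (ρ = 998.2 kg m⁻³, η = 1.002×10⁻⁹ MPa s), in
  kg m MPa⁻¹ s⁻¹. The constants are fixed and documented so results are
  reproducible to the bit; KH scales as the fourth power of diameter.
* **VD** — vessel density (mm⁻²). The analyzed area of a sector is taken
  as `xylem_area / k`: sectors are equal-width bands of the analyzed
  image, and per-sector measured areas are not part of the input format.
* **RVA** — relative vessel area, total lumen over analyzed area.
* **VG** — vessel grouping index, vessels per vessel group (a solitary
  vessel is a group of one). Groups come from an explicit `group_id`
  column when available; otherwise, if vessel centre coordinates are
  present, groups are detected by single-link clustering with contact
  defined as centre distance below `r_i + r_j + 3 µm` (a wall allowance,
  exposed as `group_gap_um`); with neither, VG is NA rather than guessed.

Two filters precede trait computation. A sector with fewer than five
vessels is discarded — a 95th percentile or mean over four values is not
an estimate worth propagating. A ring is discarded entirely when a
sector band (`trw / k`, µm) is not wider than the largest vessel radius
in that sector, because vessels then straddle band borders and the
positional assignment is unreliable. Both flags are carried with reasons
and counted in the filter report, so a run documents exactly what it
dropped.

## The two standardizations

Vessel dimensions carry a strong ontogenetic trend (vessels widen as the
tree gains height), so raw values confound age with environment. Two
standardizations separate the questions:

**Indexed series (X_ind)** target inter-annual variation. For each tree,
trait and sector, the annual series is divided by a fitted cubic
smoothing spline, leaving a dimensionless index fluctuating around 1.
The spline is defined by its frequency-response contract: the amplitude
of a sinusoid with a 30-year period is damped to exactly 50%, so decadal
and slower variation (height growth, stand dynamics, disturbance) goes
into the fitted curve and year-to-year variation survives in the index.
The roughness penalty that realizes this contract is calibrated
numerically — bisection on the measured amplitude response of a probe
sinusoid spanning ten cutoff periods, evaluated over its central two
thirds — rather than trusting any package's internal parameterization,
because penalty conventions differ while the response contract is
directly testable. The calibrated penalty is expressed on the physical
year scale (`λ_phys = λ_unit · range³`, accounting for the unit-interval
rescaling in `stats::smooth.spline`) and cached per cutoff; calibration
is deterministic and seed-free. Missing years are excluded from the fit
and stay missing (no interpolation), constant series are returned
unchanged, and years with a non-positive fitted value yield NA indices
with a warning — relevant mainly for monthly temperature in climates
with near-zero winter means, which the ratio convention handles poorly.
Monthly climate series are indexed the same way, each calendar month
across years independently, so climate trends cannot masquerade as
growth associations.

**Standardized profiles (X_std)** target the within-ring shape. Each
sector value is divided by the whole-ring value of the same trait in the
same tree and year — the pooled-vessel ring value, not the mean of
sector values. The two denominators differ for count-weighted traits;
the pooled reading was chosen because "the annual value of the ring" is
naturally the trait of the ring as one unit, and it yields the exact
identity that count-weighted sector VA values average back to 1. Only
same-year data enter, so level shifts between years cancel and profiles
from different decades are comparable.

## Chronologies, Rbar and EPS

Per site, trait and sector, indexed tree series are averaged into a site
chronology over a common period. Robustness is summarized by Rbar, the
mean of all pairwise Pearson correlations between tree series
(pairwise-complete over the common period — sample sizes are small and
spans unequal in real collections), and by the expressed population
signal `EPS = n·rbar / (1 + (n−1)·rbar)`, the classic estimate of how
well an n-tree mean tracks the hypothetical population chronology. An
EPS reporting flag at 0.85 marks chronologies conventionally considered
robust; traits with weak common signal should not be pushed into climate
correlation, where they mostly produce spurious cells.

## Permutation inference

Anatomical values are skewed and heteroscedastic, so group comparisons
use distribution-free Monte-Carlo permutation tests. The global test of
independence uses the maximum absolute standardized group-sum deviation
(`max_g |S_g − n_g·m| / sd(S_g)` with the exact relabelling variance of
`S_g`); the maximum form was chosen over the quadratic form because its
per-group contributions are directly interpretable as post-hoc leads.
Post-hoc pairwise tests permute the Welch t statistic within each pair.
P-values use the add-one estimator `(b + 1)/(N + 1)`, which is valid
(never anti-conservative in expectation) and bounded below by
`1/(N + 1)`; permutations are Monte-Carlo rather than exhaustive because
group sizes vary, with the seed carried in the test configuration for
reproducibility. Benjamini–Hochberg correction is applied within each
analysis family — the 24 months of one site × trait × sector × variable
in climate correlations, the sectors of one site × trait in period
comparisons, the pairs of one post-hoc family — a scope choice exposed
in the interfaces rather than hidden.

Climate correlations are Spearman (average ranks), computed against
indexed monthly temperature and precipitation over a 24-month window
from previous-year January to current-year December: a superset of any
plausible "previous and current growing season", so lagged associations
are not cut off by a narrower window choice.

Extreme years are classified from the June–August trimester (the
seasonal drought window): the five highest and five lowest years by JJA
mean temperature and by JJA precipitation sum, ties broken by the
earlier calendar year for determinism. Each tail is verified against the
85th/15th percentile of the study period (and of a longer series when
supplied); with k = 5 of 37 years and distinct values this holds by
order statistics (rank 33 of 37 sits at quantile 0.889).

## The synthetic generator

`synth_config()` defines the study conditions the package is validated
under: 3 sites × 5 trees × 37 years (1968–2004), ~200 vessels per
average-width ring (scaled by ring width), 1300 µm mean ring width, and
an analyzed area set so relative vessel area fluctuates around one
quarter. Expected vessel area follows a plateau over the first half of
the ring and a linear decline to 30% of the plateau at the ring end;
vessel positions are drawn from a uniform/beta mixture (weight 0.45 on a
beta with mode at 0.9, concentration 8), so vessel density rises toward
the ninth decile of the ring. An ontogenetic trend of +1% expected
vessel area per cambial-age year, lognormal vessel noise with CV 0.4,
tree-level inter-annual noise (SD 0.1 on the log scale), multiplicative
site offsets for VA and VG, and a climate coupling that multiplies
early-wood vessel sizes by `exp(0.2 · signal · z)` with `z` the
standardized log JJA precipitation sum complete the model. These effect
sizes are calibration choices — the field literature reports the shapes
(size decline, late density peak, ontogenetic widening, summer-rain
sensitivity of early-wood maximum vessel size) but not portable effect
sizes — fixed once at values a wood anatomist would call realistic for
beech. Climate is a Mediterranean-mountain monthly model: sinusoidal
temperature (annual mean 13.3 °C, January minimum ~4 °C) with AR(1)
annual anomalies, and seasonal precipitation with a summer trough and
lognormal anomalies.

A single master seed drives everything; per-tree substreams are derived
deterministically from it, and the caller's RNG state is restored, so
identical configurations produce byte-identical tables regardless of
call order.

What the generator does **not** emulate: spatial vessel coordinates
(grouping is injected through labels, not geometry), missing rings,
measurement error in ring borders, semi-ring-porous transitions, cell
walls, fibers and parenchyma, and any climate influence beyond the
single JJA-precipitation channel. Passing recovery tests therefore show
that the pipeline detects the structure it is told to inject — not that
real beech data contain that structure.

## Numerical choices and degenerate inputs

* VA95 uses the linear-interpolation quantile (type 7), documented so
  results are bit-stable across platforms.
* Identical vessels give DH = d and VA95 = VA; all-constant test vectors
  give permutation p = 1 with a note rather than 0/0.
* Relative position 1.0 is accepted (closed upper bound) and mapped to
  the last sector; position 0.5 opens the late-wood half.
* Numeric CSV output is serialized with 17 significant digits so
  write→read round trips are exact.
* Tables are validated strictly on read: named error conditions with row
  numbers for non-numeric fields, out-of-range values, duplicate keys,
  and gaps in the monthly climate grid (reported as `YYYY-MM`).

## Problem sizes in the validation suite

The test suite validates the trait formulas against a brute-force oracle
on 100 random rings, the EPS formula against an algebraically
independent variance-ratio form on 1000 random `(n, rbar)` pairs, the
spline response on 300-year probes, permutation-test size on 2000
simulated null datasets × 999 permutations, intraclass-correlation
recovery over 200 simulated chronologies, and generator-structure
recovery over 50 seeds of a one-site stand; these sizes keep Monte-Carlo
error well below the asserted tolerances while the full suite runs in a
few minutes.

## Known limitations

* Per-sector analyzed areas are approximated by `xylem_area / k`; if the
  imaging pipeline exports true per-sector areas, VD and RVA
  denominators should use them (not representable in the current input
  format).
* Ratio indexing is undefined around zero; temperature indices in cold
  climates need an additive detrending variant that is not implemented.
* EPS uses the standard formula; published tables computed with
  effective-rbar or overlap-weighted variants can differ by a few
  hundredths.
* The permutation test compares distributions through location shifts of
  standardized group sums; it is not sensitive to pure dispersion
  differences.
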