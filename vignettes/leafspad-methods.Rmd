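---
title: "Methods: locating the optimal SPAD measurement position on a rice blade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating the optimal SPAD measurement position on a rice blade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspad)
```

## The problem

A SPAD chlorophyll meter clips onto a small patch of leaf and reports a
unitless index proportional to chlorophyll content, widely used to diagnose
crop nitrogen status in the field. The reading depends strongly on *where*
on the blade it is taken: chlorophyll rises from the leaf base to a maximum
near mid-blade and declines toward the tip, and on thin-leaved cereals such
as rice the narrow, midrib-dominated basal region gives noisy readings. A
defensible measurement protocol therefore needs a position that is both
**representative** — the local chlorophyll equals the whole-blade value —
and **stable** — repeated readings there vary little across leaves.

`leafspad` implements the full chain that identifies such a position from
flatbed-scanner images: DN→SPAD calibration, profile fitting, area-weighted
averaging over the irregular blade silhouette, profile inversion, and
variance-based selection.

## Model and procedure

**Calibration (linear).** Scanner digital numbers of the red band relate
linearly to SPAD: $\mathrm{SPAD} = \beta_1 R + \beta_0$. The package ships
the reference red-band model ($\beta_1 = -0.2509$, $\beta_0 = 52.735$,
$r^2 = 0.851$, $n = 39$) for use when no local pairs exist, and
`fit_dn_spad()` refits by ordinary least squares otherwise. The red band is
the default carrier; the green band correlates comparably well but no
reference coefficients are available for it, so a green calibration must be
user-fitted. The exact p-value of the reference fit was reported only as
p < 0.01 and is stored as `NA`. Calibration is plain OLS with an intercept;
no weighting and no intercept-free option, matching how the reference
coefficients were obtained.

**Chlorophyll profile (concave quadratic).** Along-blade SPAD is modelled
as $\mathrm{SPAD}(L) = a_2 L^2 + a_1 L + a_0$ with $L$ the distance in cm
from the leaf base and $a_2 < 0$ for healthy mature blades. `fit_profile()`
solves the least-squares problem through the QR decomposition of the
Vandermonde design — no iterative optimization — so three distinct points
are interpolated exactly and noiseless quadratics are recovered to
numerical precision. The regressor may be absolute (cm) or proportional
(fraction of blade length); both coefficient sets are stored, related by
rescaling. Higher-order or spline profiles are out of scope.

**Representative value (the calculus method).** With the blade divided
into $k$ parts of equal axial length, the representative value is the
area-weighted mean
$$C = \frac{\sum_{i=1}^{k} A_i\,\mathrm{SPAD}_i}{\sum_{i=1}^{k} A_i},$$
where $A_i = \int w(x)\,dx$ over part $i$ and $w$ is the digitized blade
width. `segment_areas()` evaluates the integrals by a composite trapezoid
rule, 100 panels per part by default, interpolating the width samples
linearly. Because the integrand is piecewise linear, the rule is exact on
constant and linear widths, and part areas sum to the whole-blade integral
to floating-point accuracy — both asserted in the tests. $C$ is a convex
combination of the $\mathrm{SPAD}_i$, reduces to the arithmetic mean under
equal areas, and is invariant to rescaling all widths; these invariants are
property-tested on random inputs. The conventional method is the plain
arithmetic mean.

**Candidate positions.** `invert_profile()` solves
$a_2 L^2 + a_1 L + (a_0 - C) = 0$ with the numerically stable quadratic
formula. A discriminant below $-10^{-12}$ yields an explicit
no-real-roots result rather than a clamped position — a target above the
profile maximum has no representative position and fabricating one would
be misleading. Within $\pm 10^{-12}$ of zero the double root is returned.
Roots outside $[0, L_t]$ are returned but flagged. Both roots are always
reported; choosing between them is deliberately left to the variance rule
rather than hard-coded.

**Selection rule.** A fractional candidate $p$ lies in part
$\lceil p\,k\rceil$. `select_position()` picks the candidate whose part has
the lowest SD across a leaf population, breaking ties toward the candidate
nearest 2/3 of the blade — the empirically quiet region. All SDs use the
sample ($n-1$) definition. For multi-position meter protocols,
`dipositional_sd()` scores each combination (a, b, c, ab, ac, bc, abc of
the 1/3, 1/2, 2/3 positions) by averaging member positions within each
replicate leaf and taking the SD across replicates; whether to average
before or after the SD is genuinely ambiguous in the field literature, and
averaging first matches the reading "combination of the corresponding
positions".

**Chlorophyll extraction.** For wet-lab validation data,
`chla_b()` converts ethanol-extract absorbances to total chlorophyll:
$\mathrm{Chl}_{a+b} = (5.1\,A_{665} + 20.04\,A_{649})\,V/m$ in mg per g
fresh mass, with $V$ in litres and $m$ in grams. `regress_linear()` /
`regress_quadratic()` provide the OLS machinery (with pointwise 95%
confidence bands for the mean response) used to relate SPAD indicators to
chlorophyll or leaf nitrogen concentration; the field data behind the
published versions of those regressions are not distributed, so only the
machinery is in scope, verified by exact recovery of generating
coefficients.

## Scan processing

Real and synthetic scans pass through the same five stages.

* **Normalization.** Per channel, a linear map sends the black-standard
  mean to 0 and the white-standard mean to 255 (then rounding and 8-bit
  clipping). This removes scanner gain/offset drift between scans and is
  idempotent up to 1 DN. Equal or inverted standard means raise a
  degenerate-standards error.
* **Segmentation.** Green tissue is isolated by the excess-green index
  $2G - R - B > 30$ (threshold configurable) on the normalized raster;
  white background and the grey-scale standard patches score near zero.
  The standard rectangles are excluded outright and the largest
  8-connected component (EBImage) is taken as the leaf.
* **Axis and width digitization.** The blade axis is the leading principal
  direction of the mask pixels, canonically oriented; the base end is the
  end whose adjacent 10% of axial stations is wider on average (rice
  blades are wider near the base than the tip), overridable where the
  heuristic would misfire. Width at each of 51 stations is the transect
  extent in pixels times $2.54/\mathrm{DPI}$ cm.
* **Slicing.** Parts are equal in *axial length*, not equal in area —
  the digital analogue of cutting the scanned blade at equal intervals —
  with part 1 at the base. Partition exactness (disjoint parts whose
  union is the mask) is property-tested.
* **Per-part DN.** Mean DN per channel excludes what a careful operator
  avoids: the central 20% of each transect (midrib) and a 2-pixel margin
  erosion. Whether the original manual workflow excluded the midrib is
  not documented; both exclusions are configurable, and part areas always
  come from the full part pixel count. A part left empty by exclusion is
  an error, not a silent NA.

## The synthetic generator

The generator exists so that every downstream stage has ground truth.

* **Shape.** $w(x) \propto (x + x_0)^{\alpha}(L_t - x)^{\beta}$ with
  $x_0 = 0.05\,L_t$ and $\alpha$ solved from $\beta$ (default 1.2) so the
  peak sits exactly at `peak_frac`·$L_t$. The offset $x_0$ gives the small
  positive collar width real blades have (the un-shifted family would
  force zero width at the base), while keeping a closed-form integral
  (incomplete beta) that the area code is tested against. Defaults
  — length 25 cm, maximum width 1.2 cm, peak at mid-blade — are typical
  of a mature rice blade; 25 cm is also the length implied by the
  reference profile's reported root positions in cm and percent. The true
  silhouette family of any particular real blade is unknown; this one is
  a smooth single-peaked stand-in, not a botanical claim.
* **Profile and presets.** `make_profile()` builds the quadratic from
  base/peak values in vertex form. `n_rate_profile()` provides three
  nitrogen-rate presets: the reference profile for light deficiency
  (150 kg N/ha), and level-shifted synthetic stand-ins for severe
  deficiency (N0: base 29.5, peak 36.5) and normal supply (N225: base
  35.5, peak 42.5), consistent with how N supply shifts leaf chlorophyll
  while preserving the concave along-blade form.
* **Scan render.** Inside the silhouette the red DN is the exact inverse
  of the calibration line; green $= 0.55\,R + 110$ and blue $= 20$
  reproduce the observed channel ordering green > red > blue while
  keeping red the information carrier; the background is white and two
  standard patches sit along the top edge. Configurable black/white patch
  levels emulate scanner gain/offset, which normalization must undo.
  Sensor noise is additive Gaussian on DN before 8-bit rounding/clipping —
  the simplest model consistent with scanner sensors. 300 DPI is the
  default (the reference scanning resolution); tests render at 60–100 DPI,
  which keeps rasters small while leaving rasterization error well inside
  the 0.5-SPAD round-trip tolerance. Optics (glare, shadows, vignetting)
  and multi-leaf scenes are not simulated.
* **Populations.** `simulate_spad_population()` draws per-leaf part
  values: profile part means (width-weighted when a shape is given) plus
  a common per-leaf offset (SD 0.5 SPAD, biological level variation) plus
  independent per-part noise whose SD follows a U-shape along the blade
  (`sd_profile_u()`: 2.0 SPAD at the base falling to 0.4 at 70% of the
  blade), reflecting that narrow basal tissue under the meter window and
  tip senescence both inflate variance while the 60–80% region is quiet.
  The default population is 20 leaves, the size of the reference
  variance populations.

Passing tests on these synthetics show the pipeline is internally
consistent — each stage inverts the generator's forward model — not that
any particular real scanner or cultivar obeys the generator. Real scans
add optical artefacts, midrib reflectance structure, and silhouette
irregularities the generator deliberately omits; the calibration should be
refitted per scanner.

## Numerical choices and edge cases

* Quadratic roots use $q = -(b + \operatorname{sign}(b)\sqrt{\Delta})/2$
  to avoid cancellation; every returned root satisfies
  $|\mathrm{SPAD}(L) - \mathrm{target}| < 10^{-6}$ (asserted).
* The discriminant tolerance $10^{-12}$ separates double roots from
  no-roots; a vertex-level target printed at 3 decimals can fall above
  the true maximum by more than this, so exact vertex values should be
  computed from the coefficients, not re-entered from rounded output.
* Trapezoid panels per part default to 100; doubling changes areas by
  less than $10^{-6}$ relative on smooth shapes (asserted), and the rule
  is exact on the piecewise-linear width representation, which makes the
  area total an exact invariant rather than an approximation.
* All randomness is seeded per call via `withr::with_seed()`; no function
  touches the global RNG state, and fixed seeds give bit-identical
  renders and reports (asserted).
* Degenerate inputs fail loudly with classed conditions
  (`leafspad_singular_design`, `leafspad_degenerate_standards`,
  `leafspad_empty_part`, ...) rather than returning NAs.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 1000 random inputs for the
equal-area and convexity properties; 200 random profiles for the root
round-trip; a 25 cm blade rendered at 100 DPI for the end-to-end scan
round trip (tolerance 0.5 SPAD, dominated by 8-bit DN quantization, which
contributes up to ~0.13 SPAD, and rasterization); and 200 Monte-Carlo
populations of 20 leaves for the selection rule. The SD-localization check
uses 200-leaf populations: with 20 leaves the sample SD resolves the
U-curve's minimum only coarsely, which is itself informative about how
many leaves a field protocol needs before per-part SD rankings stabilize.

## Known limitations

* The area-weighted $C$ of the original analysis (39.11) and its
  associated positions (8.96/16.00 cm) depend on an unpublished digitized
  silhouette and are mutually inconsistent with the printed profile
  equation (that value of $C$ on that profile yields roots near 6.4 and
  18.6 cm); they are documented but not reproduction targets. The
  conventional pair (38.42 → 5.21/19.76 cm) is internally consistent and
  is the package's worked-example check.
* Only the red-band reference calibration ships as a constant; green-band
  use requires local fitting.
* The base-end heuristic assumes the blade is wider nearer the base;
  for unusual silhouettes use the `base_end` override.
* Leaf-rank effects (LFT1–4) are carried as a grouping variable in
  `dipositional_sd()` but the package does not model rank-specific
  chlorophyll dynamics.
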