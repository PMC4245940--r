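---
title: "Methods: deamination kinetics and mutagenic potential in nucleosomes"
author: "nucdeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deamination kinetics and mutagenic potential in nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdeam)
```

## Scope

`nucdeam` quantifies how the rotational position of a methylated CpG site in
a nucleosome core particle modulates the two chemical steps behind
UV-induced C→T mutations: cyclobutane pyrimidine dimer (CPD) formation and
the subsequent deamination of the 5-methyl-C inside the dimer. The package
covers the downstream quantitative analysis only: band intensities from the
tandem-gel assay, cleavage intensities from hydroxyl-radical footprints and
coordinates from a PDB file are taken as given. Gel densitometry, lane
alignment, the photoreversion/digestion biochemistry, and repair or
replication kinetics are out of scope.

## The kinetic model

The assay labels the 5-methyl-dC of one site with ³²P. After irradiation
and incubation, each aliquot yields two band intensities, and the deaminated
fraction is

$$f(t) = \frac{T}{T + {}^m\!C}.$$

A terminal aliquot driven to complete deamination gives
$f_\infty = T_\infty / (T_\infty + {}^m\!C_\infty)$, which plays two roles:
it normalizes the time course, and it *is* the CPD photoproduct yield —
after photoreversion of intact CPDs back to undamaged DNA, only label that
was trapped in a deaminated CPD migrates as dT.

Deamination of the CPD subpopulation is first order, so the remaining-CPD
fraction decays exponentially and

$$\ln\left(1 - f(t)/f_\infty\right) = a - k\,t .$$

`fit_deamination()` estimates $k$ by unweighted ordinary least squares on
this log-linear form. Three choices matter:

- **Natural log throughout.** The slope is $-k$ only if one base is used
  consistently; we fix $\ln$ and report $t_{1/2} = \ln 2 / k$, with the
  half-life standard error propagated as
  $\sigma(t_{1/2}) = \ln 2 \cdot \sigma(k) / k^2$. Reported `±` values are
  1 SE from the fit.
- **Free intercept.** The initial amount of dT is nonzero and varies between
  samples (deamination during organic extraction), so the line is not forced
  through $\ln 1 = 0$. For an exponential course the intercept offsets the
  line without biasing the slope; the noiseless round-trip tests verify
  recovery of $k$ to a relative $10^{-9}$ at any intercept.
- **Exclusion rule.** Noise can push $f(t) \ge f_\infty$, making the
  measured remaining fraction nonpositive with no finite log. Such points
  are excluded with a warning and counted (`n_excluded`); a fit requires at
  least three surviving points. A fitted slope $\ge 0$ is reported as an
  invalid fit (no detectable deamination) rather than silently returned.

`deamination_rates()` maps this fit over a many-site table and, given a
reference site, appends yield, rate and half-life fold changes. Fold changes
derived downstream are always recomputed from rate constants, never from
already-rounded fold columns, to avoid compounding rounding error.

## Energetics

`ddg_from_rates()` converts a rate ratio into a transition-state
free-energy difference, $\Delta\Delta G^\ddagger = R T \ln(k_1/k_2)$ with
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹. Defaults follow the assay
conditions: 310.15 K (37 °C) for deamination and 277.15 K (4 °C) for
photoproduct formation, both overridable. Photoproduct *yields* are used as
proxies for relative formation rates when computing the formation-side
profile; this is an approximation (yields saturate at high dose) and is the
reason the formation-side span is reported as indicative rather than pinned
to a reference value. On the packaged site table the deamination span
(≈1.5 kcal/mol between the innermost and outermost position at 310.15 K) is
2–4 times the yield-derived formation span, consistent with the qualitative
"about three times larger" reading; the exact ratio depends on the
temperature attached to the yield comparison, which is genuinely ambiguous,
so no test pins it beyond that interval.

## Mutagenic potential

Ignoring repair and replication, the probability that a site acquires a C→T
mutation scales with the rate of CPD formation times the rate of
deamination. `relative_potential()` therefore scores a rotational position
as

$$\text{potential} = \frac{y_{\mathrm{ncp}}}{y_{\mathrm{free}}} \cdot
  \frac{k_{\mathrm{ncp}}}{k_{\mathrm{free}}},$$

and `average_potential()` takes the unweighted arithmetic mean across
positions — the score a weakly rotationally positioned nucleosome would
express, and the averaging rule under which the packaged table reproduces
its published mean of 2.3. Potentials below 1 are also reported as
reciprocals ("x-fold lower"). On the packaged table the potential peaks at
position 6 (≈6.8) and bottoms at position 1 (≈0.18).

## Footprint periodicity and orientation calls

`fit_periodicity()` fits the single-harmonic model

$$I(x) = b + A\cos\!\big(2\pi (x - \varphi)/p\big)$$

by grid search over the period $p$ (default window 9–12 bp, step 0.01 bp)
with the closed-form linear least-squares solution for $b$, $A$, $\varphi$
at each candidate period; the best period minimizes the residual sum of
squares and ties resolve to the smaller period. The reported phase is the
fitted maximum closest to the centre of the profile. Missing intensities are
skipped, never imputed. A numerically zero amplitude (e.g. a constant
profile) sets a `degenerate` flag and blocks orientation calls.

`classify_orientation()` dichotomizes positions at the fitted baseline.
Real footprints are not symmetric cosines: protection where the backbone
contacts the histone core appears as *narrow* periodic troughs on a broad
plateau. A symmetric threshold on the fitted cosine necessarily calls half
of each period inside, which cannot reproduce the observed pattern of about
three protected positions per helical turn at the dyad; thresholding the
*observed* intensity at the fitted baseline does, because only positions
within a trough fall below the baseline. The observed-intensity rule is
therefore the default, and the symmetric fitted-cosine rule remains
available as `method = "fitted"`. Calls are invariant to affine transforms
of the intensity scale under both rules.

`generate_protection_profile()` produces exactly this trough-on-plateau
shape (Gaussian troughs of width ~0.9 bp every helical repeat); with the
default construction — troughs at 70.8, 81.2, … bp — the fitted period is
10.4 bp and positions 71, 72 and 80 are called inside with 73–79 outside,
the configuration expected for ten consecutive sites spanning one helical
turn at the dyad.

## Structural geometry

`parse_structure()` reads PDB records (via bio3d) into a tidy atom table,
excluding waters and resolving alternate locations by highest occupancy
(ties to the first record). Malformed coordinate fields are reported by line
number. Only PDB input is supported; mmCIF is a known limitation.

- **Superhelix axis.** The nucleosomal DNA phosphorus cloud forms a flat
  disc; `superhelix_axis()` takes the eigenvector of the smallest
  eigenvalue of the P-coordinate covariance as the disc normal, anchored at
  the P centroid, signed toward lab +z (ties toward +x). An exactly
  isotropic cloud has no unique normal and is refused. Note that PCA on a
  *pitched* helical arc has a minor axis tilted from the winding axis; the
  idealized generator below therefore re-expresses its output in the disc
  frame (a rigid motion) so the estimated axis is exact by construction.
- **Base orientation.** The "outward perpendicular to the histone surface"
  is realized as the cylindrical radial vector from the axis line to the
  base-ring centroid (mean of the six ring atoms) — the orientation ordering
  only depends on inward/outward, not on a local surface mesh. The base
  vector bisects the ring from the midpoint of C6/N1 to the midpoint of
  N3/C4, crossing toward the C4/major-groove edge. The reported angle is
  their arccosine, in [0°, 180°]: 0° faces directly away from the core.
- **Temperature factors.** `mean_b_factors()` averages the B-factor over
  *all* atoms of each nucleotide (base, sugar, phosphate), unweighted.
- **Photodimer geometry.** For sequential pyrimidines on one strand,
  `photodimer_geometry()` reports the distance between the C5–C6 bond
  midpoints and the improper torsion C5(i)–C6(i)–C6(j)–C5(j) by the
  standard four-point formula (IUPAC sign; verified against an independent
  torsion implementation). An eclipsed stack gives 0°, an anti-eclipsed one
  ±180°. The torsion of four points is invariant under reversing their
  order, so the pair's geometry does not depend on which residue is listed
  first; the sign flips only under mirror reflection.

All geometric outputs are invariant under rigid rotation and translation of
the structure (tested with random rigid motions at fixed seeds). Mapping
file residue numbers to rotational positions 1–10 is the user's
responsibility — numbering conventions differ between structures, and
derived per-residue values depend on the construction choices above, so no
external-structure values are pinned by tests.

## Synthetic data: what it emulates, and what it does not

`generate_time_course()` simulates the assay generatively:

$$f(t) = y\,\big(1 - (1 - f_0)e^{-kt}\big),$$

with $y$ the true yield and $f_0$ the fraction already deaminated at $t=0$
(default 0.05, matching deamination during workup). Band intensities get
independent multiplicative log-normal noise per band (default
$\sigma = 0.05$), the natural model for positive phosphorimager counts with
a roughly constant coefficient of variation; a common per-aliquot loading
factor cancels exactly in the fractions (scale invariance, tested). The
terminal aliquot is simulated at $f = y$ with the same band noise.

**Sampling schedule.** By default, aliquot times are proportional to the
true half-life: $t = t_{1/2}\,\{0, 0.2, 0.5, 1, 1.5, 2, 2.5\}$, mirroring
how the assay itself assigns schedules per substrate (a site with
$t_{1/2} = 3.5$ h is not sampled on the same clock as one with 117 h). This
choice is substantive, not cosmetic: the measured remaining fraction carries
an *additive* noise floor of about $\sigma\sqrt{2}$ inherited from the band
noise, so aliquots taken beyond ~2.5 half-lives measure noise, and a
log-linear fit that includes them is biased toward slower rates — severely
so for fast sites sampled on a slow schedule (tens of percent). With the
matched schedule, the median bias of $\hat k$ stays within 2% across the
whole observed rate range (0.017–0.2 h⁻¹) at $\sigma = 0.05$, verified on
500 replicates per rate at a fixed seed.

**What the fit's standard errors do and do not mean.** The single terminal
aliquot's error is shared by every point of a course, so residuals are
correlated; OLS standard errors describe the scatter *within* one course and
understate the replicate-to-replicate spread of $\hat k$ (in simulation, the
±1 SE interval covers the true rate in roughly a quarter of replicates
rather than the nominal two-thirds). The `±` values should be read as fit
diagnostics, not as calibrated confidence intervals; calibrated intervals
would need replicate terminal aliquots or an error model for $f_\infty$,
both outside the data the assay produces.

Not emulated: photoproduct-spectrum competition (6-4 photoproducts, Dewar
isomers), gel migration artifacts, enzyme kinetics of photolyase or P1
digestion, and replicate measurements per time point (one per time, as in
the assay). Passing tests therefore demonstrate correctness of the analysis
under the stated statistical structure, not robustness to systematic
artifacts upstream of band quantification.

`generate_helix()` builds a placeholder duplex — one phosphorus plus six
ring atoms per base pair — on a superhelix (defaults: radius 41.9 Å, pitch
25.9 Å, 10.4 bp per helical turn, 147 bp, rise 3.4 Å/bp along the path),
with base outwardness rotating once per helical turn and the B-factor
placeholder set to each atom's distance from the superhelix winding axis.
It exists to give the structural operations a fixture with known ground
truth: the estimated axis is exact, the orientation-angle minimum and the
B-factor maximum coincide with the built outward base pair, and the
inward-facing maximum sits half a turn (5 bp) away. It is not a model of
DNA: ring geometry, groove widths and backbone chemistry are placeholders.

## Reference table and printed precision

`deamination_site_data()` packages the per-site yields (%), half-lives (h)
and 1-SE errors for the free-DNA control, the ten rotational positions, and
the TmCA flanking variants at positions 1 and 6 (15 rows). Fold-change
columns are stored as printed strings so their precision is explicit.
Agreement "at printed precision" throughout the package means within one
unit in the last printed digit: several printed folds were evidently rounded
from unrounded source data (e.g. a printed 3.1 where the tabulated columns
give 41/13 = 3.15), so strict re-rounding equality is not attainable from
the table itself and a ±1-ulp criterion is the sharpest check the data
support. One published summary — the "5.3-fold lower" potential at position
1, where the table's columns give 5.5 — is outside even that tolerance; it
is reported in `reference_analysis()$flagged` rather than silently checked
or hidden.

## Problem sizes

The test suite and acceptance script use: 500 replicates per rate for
stochastic recovery (three rates in the acceptance run), 147-position
profiles for footprint fits, a 147-bp idealized helix for structural
checks, and the 15-row reference table for all derived summaries. The whole
suite runs in well under a minute on one core.

## Known limitations

- PDB only; no mmCIF.
- The base-orientation construction (bisecting vector, radial realization
  of the surface normal) is one documented choice among several the
  geometry would admit; orderings are robust to it, absolute angles are not.
- SE calibration for $\hat k$ as discussed above.
- The potential score deliberately ignores repair and replication; it ranks
  formation-plus-deamination propensity only.
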