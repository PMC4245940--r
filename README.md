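# nucdeam

Quantitative analysis of how nucleosome rotational positioning modulates
UV-photoproduct formation and deamination at methylated CpG sites — the two
steps that together set the C→T mutation risk of a site in chromatin.

## The problem

Sunlight-induced C→T mutation hotspots in skin cancer arise mostly at
methylated CpG sites. UV light forms cyclobutane pyrimidine dimers (CPDs)
there; the 5-methyl-C inside a CPD then hydrolytically deaminates to T over
hours to days, and translesion synthesis fixes the change as a mutation. In a
nucleosome, both steps depend on the *rotational position* of the site: which
face of the double helix the base presents to the histone core, a geometry
that repeats every ~10.4 bp. `nucdeam` is for researchers who quantify this
modulation: it turns gel band-intensity time courses, hydroxyl-radical
footprint profiles and nucleosome coordinate files into rate constants,
free-energy differences and a per-position mutagenic-potential score.

## The model

For one site, an aliquot at time *t* gives band intensities for ³²P-5-methyl-dC
and ³²P-dT. The deaminated fraction is `f(t) = T / (T + mC)`, and one fully
deaminated terminal aliquot gives `f∞ = T∞ / (T∞ + mC∞)`, which is also the
CPD photoproduct yield. Deamination is first order in the CPD population:

    ln(1 − f(t)/f∞) = a − k·t,        t½ = ln 2 / k

fitted by ordinary least squares with a free intercept *a* (the initial
amount of deamination is nonzero and varies between samples). Comparisons
between conditions use:

- fold changes of yields, rates and half-lives (`fold_change()`);
- transition-state free-energy differences `ΔΔG‡ = R·T·ln(k₁/k₂)`
  (`ddg_from_rates()`, R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹);
- the mutagenic potential of a rotational position, the product of its
  relative CPD formation and relative deamination rate
  (`relative_potential()`, `mutagenic_potential()`).

Two further modules support the structural interpretation: `fit_periodicity()`
fits the ~10–11 bp periodicity of hydroxyl-radical cleavage profiles and
`classify_orientation()` calls each backbone position inside (against the
histone core) or outside; `read_structure()` / `base_orientation()` /
`mean_b_factors()` / `photodimer_geometry()` compute per-nucleotide geometry
(base orientation angle to the histone surface, temperature factors, C5–C6
interbond distance and improper torsion) from a PDB coordinate file. A
synthetic-data module (`generate_time_course()`, `generate_profile()`,
`generate_protection_profile()`, `generate_helix()`) generates every input
the pipeline consumes, and `deamination_site_data()` packages the reference
per-site yield/half-life table.

## Worked example

Fit three synthetic sites (free DNA, the innermost and the outermost
rotational position) and score them:

```r
library(nucdeam)
courses <- dplyr::bind_rows(
  generate_time_course(k = log(2) / 13,  cpd_yield = 0.12,  site_id = "Free ds1-10", seed = 1),
  generate_time_course(k = log(2) / 41,  cpd_yield = 0.069, site_id = "NCP ds1",     seed = 2),
  generate_time_course(k = log(2) / 3.5, cpd_yield = 0.22,  site_id = "NCP ds6",     seed = 3)
)
rates <- deamination_rates(courses, reference_site = "Free ds1-10")
dplyr::select(rates, site_id, k, half_life_h, half_life_se_h, yield_percent, rate_fold)
#> # A tibble: 3 × 6
#>   site_id          k half_life_h half_life_se_h yield_percent rate_fold
#>   <chr>        <dbl>       <dbl>          <dbl>         <dbl>     <dbl>
#> 1 Free ds1-10 0.0601       11.5           1.27          12.6      1
#> 2 NCP ds1     0.0125       55.4           2.36           8.34     0.208
#> 3 NCP ds6     0.195         3.56          0.152         22.4      3.24

mutagenic_potential(rates, reference_site = "Free ds1-10")
#> # A tibble: 2 × 5
#>   site_id yield_fold rate_fold potential reciprocal
#>   <chr>        <dbl>     <dbl>     <dbl>      <dbl>
#> 1 NCP ds1      0.660     0.208     0.137      7.28
#> 2 NCP ds6      1.77      3.24      5.74       0.174
```

Each fitted row reports the rate constant (h⁻¹), half-life ± 1 SE (h), yield
(%) and the fold change against the reference site; the potential column says
the outermost site is ~6-fold more mutagenic than free DNA and the innermost
~7-fold less, before any repair or replication effects.

The packaged reference table reproduces the derived summaries end to end:

```r
reference_analysis()
#> Rotational-position analysis of the packaged site table
#>   free k = 0.0533 h^-1, mean NCP k = 0.0833 h^-1 (ratio 1.56)
#>   deamination range 11.7-fold; average mutagenic potential 2.28
#>   ddG(inner vs outer) = 1.52 kcal/mol at 310.15 K
#>   printed-value checks: 36/36 agree at printed precision
```

`autoplot()` methods draw the log-linear fit diagnostics and the footprint
periodicity fit; `plot_rotational_profile()` gives the per-position bar
profiles.

## The methods vignette

`vignettes/nucleosome-cpd-deamination.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic-data generators do and do not emulate, and the numerical design
choices (fit exclusion rules, tie-breaks, degenerate-input handling).
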