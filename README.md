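# nanoaroma

Analysis toolkit for controlled-release studies of nanoencapsulated
essential oils. It covers the computational side of a typical
formulation-and-release workflow:

- **Compound registry** — physicochemical and olfactory properties of
  headspace volatiles: molar mass *M* (g/mol), vapor pressure *P*vap (Pa),
  odor threshold *ODT* (mg/m³), density, and 1–3 ranked olfactory families
  from the canonical eight-family vocabulary (citrus, fruity, floral,
  green, herbal, musk, oriental, woody).
- **Quantification** — GC-MS composition bookkeeping, external-standard
  calibration, encapsulation efficiency
  `EE% = 100·(m_if − m_uf)/m_i0`, DPPH radical scavenging
  `%SR = 100·(ABS_control − ABS_sample)/ABS_control`, and the coefficient
  of variation `CV% = 100·σ/μ`.
- **Headspace model** — equilibrium gas-phase concentrations from the
  liquid composition under the ideal (Raoult-law) approximation:
  `c_i = x_i·P_vap,i·M_i/(R·T)` in mg/m³.
- **Perfumery radar** — odor values `OV_i = c_i/ODT_i`, distributed over
  ranked families with weights 100% / 70–30% / 60–30–10%, normalized to
  `OV′_j = OV_j/ΣOV_j` and laid out on a fixed eight-axis polygon.
- **Release kinetics** — the power-law (Korsmeyer–Peppas) model
  `M_t/M_∞ = k·tⁿ`, fitted by Nelder–Mead least squares in linear space
  (log–log OLS initializer), with R², adjusted R², SSE, RMSE, and
  transport-mechanism classification from the exponent (spheres: *n* =
  0.43 Fickian, 0.43 < *n* < 0.85 anomalous, *n* = 0.85 Case II).
- **Synthetic data** — seed-reproducible generators for noisy power-law
  release curves, Dirichlet-perturbed GC composition tables, and
  saturating DPPH assay series, so the whole pipeline is testable without
  instrument data.

Packaged fixtures provide a worked data set: the GC-MS composition of a
steam-distilled *Achyrocline satureioides* (marcela) essential oil and the
property table of its ten headspace-relevant terpenes.

## Worked example

```r
library(nanoaroma)

reg <- load_registry(system.file("extdata", "table6_properties.csv",
                                 package = "nanoaroma"))
tab <- read_composition(system.file("extdata", "table2_composition.csv",
                                    package = "nanoaroma"))

identified_total(tab)
#> $identified_percent   93.18
#> $unidentified_percent  6.82

res <- radar_from_composition(tab, reg)
round(res$profile$values, 4)
#>   citrus   fruity   floral    green   herbal     musk oriental    woody
#>   0.0094   0.0000   0.2070   0.0000   0.0887   0.0000   0.0055   0.6893
dominant_family(res$profile)
#> [1] "woody"
```

The radar says: of the total odor intensity predicted in the equilibrium
headspace, 69% falls on the woody axis — the α-pinene-dominated mixture
smells predominantly woody. Compounds without a tabulated odor threshold,
or contributing less than 0.1% of the summed odor value, are listed in
`res$exclusions` with their reasons.

Release kinetics on a simulated nanocapsule curve (generating parameters
`k = 0.0786`, `n = 0.30`, 2% multiplicative noise):

```r
curve <- simulate_release(seed = 7, k = 0.0786, n = 0.30,
                          noise_sigma = 0.02)
fit <- fit_peppas(curve)
fit
#> <peppas_fit> k = 0.08029 min^-n, n = 0.2981
#>   R2 = 0.9989, R2adj = 0.9987, SSE = 0.0009771, RMSE = 0.00699
#>   20 points used; converged: TRUE
classify_mechanism(fit$n)
#> <mechanism_call> n = 0.2981 (sphere, band +/-0.01): quasi-Fickian/combined
```

The fitted exponent recovers the generating value within noise; below the
spherical Fickian reference (0.43) the release is classified as
quasi-Fickian/combined transport. Assay formulas work the same way:

```r
encapsulation_efficiency(mi0 = 100, mif = 72, muf = NA)  # filtrate clean
#> [1] 72   (attr lower_bound = TRUE: the true EE can only be larger)
coefficient_of_variation(178.30, 1.18)
#> [1] 0.66
```

File-level pipelines (`run_radar()`, `run_release()`) read the CSV
dialects documented on each reader, write CSV + JSON reports, and record a
provenance file (package version, seed, config hash) so a run can be
reproduced bit-exactly.

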