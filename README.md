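# weanmix

Reconstruction of breastfeeding and weaning practices from bone-collagen
stable isotopes in archaeological skeletal series.

Breastfeeding infants consume their mother's tissue, so their bone-collagen
δ15N sits roughly one trophic step (≈ 2–4 ‰) above the adult-female mean and
declines as breast milk is replaced by weaning foods. `weanmix` turns a table
of per-individual collagen measurements (δ13C, δ15N, %C, %N, C/N, collagen
yield) for juveniles and adult females into:

* **Collagen QC and age grouping** — the standard preservation screen
  (%N ≥ 4.8, %C ≥ 13, C/N in 2.9–3.6) and assignment of juveniles to the
  age groups 0–0.5, 0.5–1, 1–2 and 2–6 years by age-interval midpoint.
* **A breast-milk isotope source** inferred from adult-female collagen via
  keratin-based offset chains: Δ(milk→maternal collagen) =
  Δ(keratin→collagen) − Δ(keratin→milk), and the exclusive-milk-diet
  fractionation Δ(milk diet→infant collagen) = Δ(milk→newborn hair) +
  Δ(keratin→collagen), both applied endpoint-wise to literature intervals.
* **A concentration-dependent Bayesian mixing model** for the dietary source
  proportions *p* of each age group. For element *j* with source
  concentrations *q*, consumer values are modelled as

      x_ij ~ N( Σ_k p_k q_jk (μ_jk + Δ_jk) / Σ_k p_k q_jk ,
                Σ_k w_k² (s_jk² + s_Δjk²) + σ_j² ),   w_k = p_k q_jk / Σ p q

  with a Dirichlet(1) prior on *p*, half-normal priors on the residual SDs
  σ_j, and random-walk Metropolis sampling on the log-ratio-transformed
  simplex. Posterior summaries are boundary-reflected KDE modes with central
  95 % credibility intervals.
* **An ABC model of weaning ages.** The dietary δ15N signal is
  `female + enrichment` before weaning starts (t1), declines linearly to the
  weaning-food value by its end (t2), and collagen relaxes toward it at an
  age-dependent turnover rate r(t) = r∞ + (r0 − r∞)·exp(−t/τ):

      dδcol/dt = r(t) · (δdiet(t) − δcol(t)),   δcol(0) = female mean

  integrated by fixed-step RK4. Rejection ABC draws (t1, t2−t1, enrichment,
  weaning-food) from uniform priors, keeps the simulations closest (RMS) to
  the observed juvenile values, and reports maximum-density estimates (MDE)
  from kernel density estimates of the accepted draws.
* **Group statistics** — Shapiro–Wilk checks, one-way ANOVA and Tukey–Kramer
  pairwise comparisons across the four juvenile groups and the females.
* **Synthetic-cohort generators** for every stage, so the whole pipeline can
  be exercised against known ground truth.

The package bundles, as plain-text fixtures, the published collagen table of
a pre-contact Caribbean fisher–gatherer/horticulturalist skeletal series
(49 individuals: 31 juveniles, 18 adult females) and its four-source
weaning-food table (breast milk, root cultigens, legumes, tropical fruits).

## Worked example

```r
library(weanmix)

tab1 <- read_collagen(weanmix_example("canimar_collagen.tsv"))
tab1 <- qc_screen(tab1, override = "E-29")   # flagged C/N 2.80, kept as published
tab1 <- tab1[tab1$qc_keep, ]

group_summary(tab1)[, c("group", "n", "mean_d15N", "sd_d15N")]
#>     group  n mean_d15N  sd_d15N
#> 1      G1 11 10.810909 2.365487
#> 2      G2  6 11.785000 1.534128
#> 3      G3  8 11.995000 1.566589
#> 4      G4  6  8.911667 3.529303
#> 5 females 18 10.911111 1.190407

juv <- tab1[tab1$cohort == "juvenile", ]
fem <- tab1[tab1$cohort == "adult_female", ]
fit <- fit_warn_abc(age_midpoint(juv$age_low_years, juv$age_high_years),
                    juv$d15N, mean(fem$d15N), turnover_model(), abc_config())
fit
#> Weaning-age posterior (5000 accepted of 1000000 simulated draws)
#>         mde lower95 upper95
#> t1     2.12    1.34    2.55
#> t2     2.61    2.09    3.48
#> enrich 1.01    0.45    1.47
#> wnfood 4.76    2.15    6.57
```

Read: weaning most plausibly began around age 2 and was complete by
roughly 2.6 years (95 % CI 2.1–3.5); exclusively breastfed collagen sat
about 1.0 ‰ above the female mean; a fully weaned diet corresponds to a
collagen value near 4.8 ‰. The weaning-food estimate (and, less strongly,
the ages) depends on the assumed turnover schedule — see the methods
vignette.

The full pipeline — QC, summaries, milk-source construction, per-group
mixing fits, the ABC fit and the comparison statistics, written out as a
report bundle with a checksummed manifest — is one call:

```r
report <- run_pipeline(pipeline_config(output_dir = "report"))
```

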