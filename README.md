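# fruitsignals

Do fruits trade colour against odour? In communities with both
visually-oriented and olfactory-oriented seed dispersers, plants might
invest in chromatic signals at the expense of volatile emissions (or vice
versa). `fruitsignals` implements a complete, tested analysis chain for
this question on community fruit-trait data:

* **Trait indices** — ellipsoid fruit surface area (Knud-Thomsen,
  `S = 4π[((ab)^p + (bc)^p + (ac)^p)/3]^{1/p}`, `p = 1.6075`), the
  surface-area-scaled VOC index `log10(VOC/S)`, brightness-normalized
  reflectance spectra, and band percentages for UV (300–400 nm),
  blue (400–500), green (500–600) and red (600–700).
* **Correlation screen** — Pearson correlations of the VOC index against
  the four bands and `log10` surface-area:weight, with exact t tests.
* **Spectral spline regression** — OLS of the VOC index on five
  natural-cubic-spline predictors of the whole spectrum (knots at
  350–590 nm, 650 nm referent) plus the size covariate, a 5-df F test for
  the overall spectral effect, and delta-method cumulative band effects
  (`c'β̂` with variance `c'Σ̂c`).
* **Phylogenetic signal** — a framework tree from taxonomy, continuous
  -character (linear/Farris) parsimony with consistency and retention
  indices, Blomberg's K with a randomization test, and Pagel's λ with a
  likelihood-ratio test.
* **Synthetic communities** — a generator with injectable colour→odour and
  size→odour effects, used to calibrate and validate every estimator.

The published trait table for 56 endemic wild fruit species of a Malagasy
tropical dry forest (19 families, 10 orders) ships with the package as
`madagascar_fruit_traits()`.

## Worked example

```r
library(fruitsignals)

d <- madagascar_fruit_traits()
cm <- correlation_matrix(d)
print(cm)
```

```
Pearson correlations (N = 56; bands on total denominator; SA:W log10)
         voc      uv    blue   green  red
voc
uv     -0.01
blue  -0.32*  0.43**
green   0.14 -0.55** -0.74**
red     0.04  -0.33*    0.00 -0.49**
saw   0.50**    0.17   -0.01   -0.18 0.14
*  p < 0.05, ** p < 0.01
```

Blue reflectance is the one colour channel negatively associated with
odour (r = −0.32, p = 0.02): bluer fruits are less odiferous. Smaller
fruits — higher surface-area:weight — emit more VOC per unit surface
(r = 0.50). The band indices are re-expressed on a common 300–700 nm
denominator before correlating (see the vignette for why this matters).

Phylogenetic signal on the framework tree built from the table's taxonomy:

```r
tab <- phylo_signal_table(d, n_perm = 1000, seed = 42)
print(tab, digits = 3)
```

```
  trait steps    ci     ri     k   k_p lambda lambda_p
1   voc  19.6 0.122 0.1590 0.765 0.020  0.563 0.085287
2    uv 310.5 0.187 0.1111 0.924 0.002  1.000 0.000931
3  blue 261.9 0.125 0.1324 0.861 0.003  1.000 0.004705
4 green 438.9 0.153 0.0782 0.693 0.121  0.116 0.840091
5   red 286.1 0.172 0.1584 0.663 0.214  0.262 0.462999
```

Consistency indices of 0.12–0.19 mean every trait is heavily homoplastic
(CI = 1 would be homoplasy-free). Signal statistics depend strongly on the
tree used — see the vignette before interpreting K/λ on a taxonomy
scaffold.

On synthetic data with a known injected blue effect:

```r
cmty <- generate_community(community_config(n_species = 500, seed = 8))
fit  <- fit_spectral_model(cmty)
band_effect(fit, "blue")
```

```
   band cumulative_coefficient   std_error    t_stat  df p_two_tailed
1  blue             -0.0337700 0.001488984 -22.67990 493 1.585846e-78
```

The injected effect is −0.04 per unit blue percent; the fitted band effect
recovers its sign and ~84% of its magnitude — the remainder is the
smoothing attenuation inherent to representing a band-limited (step)
effect with a 5-df spline (vignette, "What the estimator can and cannot
recover").

The numbered scripts under `analysis/` run these stages end to end and
write their tables under `results/`.

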