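# gutflux

Kinetic analysis of intraintestinal ¹³C-SCFA tracer experiments: how much of
the acetate, propionate and butyrate produced (or delivered) in the human gut
lumen ends up in plasma glucose, and how fast?

The package is written for researchers running stable-isotope tracer studies
of gut-microbial short-chain fatty acid (SCFA) metabolism. Its inputs are
plasma mass-isotopologue distributions (MIDs) and ¹³C-glucose enrichment time
courses; its outputs are excess labelling fractions, per-SCFA source
attributions, apparent first-order rate constants, and fractional dose
incorporations.

## The model

A bolus of ¹³C-SCFA (`A0` mmol [1-¹³C₁]-acetate, `P0` mmol
[1,2,3-¹³C₃]-propionate, `B0` mmol [1,2,3,4-¹³C₄]-butyrate) is delivered into
the gut lumen at t = 0. Three compartments — gut, liver, plasma — are linked
by eight apparent first-order rate constants (min⁻¹):

    dA_gut/dt   = −(k_1a + k_0a) A_gut
    dA_liver/dt = k_1a A_gut − k_La A_liver
    dG_a/dt     = (k_La A_liver − k_2 V G_a) / V

    dP_gut/dt   = −(k_1p + k_0p) P_gut
    dG_p/dt     = (k_1p P_gut − k_2 V G_p) / V

    dB_gut/dt   = −(k_1b + k_0b) B_gut
    dG_b/dt     = (k_1b B_gut − k_2 V G_b) / V

Gut and liver pools are in mmol, the plasma ¹³C-glucose pools `G_a`, `G_p`,
`G_b` (one per source SCFA) in mM; `V = 0.15 L/kg × body weight` converts
between them. Only acetate needs the liver intermediate — its appearance in
glucose is too slow for a single lumped step. The fraction of each delivered
tracer incorporated into glucose is

    f_x = k_1x / (k_1x + k_0x)  ≡  AUC × CL / dose,   CL = k_2 V,

an identity the package verifies numerically (the AUC is taken over the whole
fitted curve, numerically to where the gut tracer is negligible plus an exact
analytic tail).

Not all eight constants can be estimated from three plasma curves: the
collinearity index γ = 1/√λ_min of the column-normalised sensitivity Gram
matrix, computed exhaustively over all 247 parameter subsets, shows that at
most six are jointly identifiable (γ < 20). The data-poor pair (`k_La` and a
companion chosen by `select_second_fixed()`) is fixed by grid search on the
unweighted residual objective; the remaining six are estimated by
Levenberg–Marquardt on sd-weighted residuals.

Upstream of the kinetics, measured MIDs are corrected for natural ¹³C
abundance (binomial convolution matrix, inverted by least squares with
non-negative labelled fractions) and attributed to the three SCFA by
regression on their expected labelling patterns — e.g. fumarate scrambling
splits propionate-derived label equally between M+2 and M+3 glucose, and one
butyrate labels two glucose units via two [1,2-¹³C₂]-acetyl-CoA.

## Worked example

No clinical data ship with the package; the synthetic generator reproduces
the study conditions (8 subjects, 9.6/4/0.9 mmol dose, sampling every 15 min
from −15 to 210 min, 5% noise, 20% inter-subject CV on the constants):

```r
library(gutflux)

cfg <- generator_config(seed = 20)
avg <- average_curves(generate_enrichment_curves(cfg)$curves)
fit <- fit_rate_constants(avg, tracer_dose(), subject_profile())
fit
#> <fit_result> converged (weighted SSE 4.262, n = 48)
#>     estimate std_error   p_value
#> k1a 0.005088 0.0005821 5.323e-11
#> k1p 0.003258 0.0001771 1.025e-21
#> k1b 0.007046 0.0002764 3.526e-27
#> k2  0.014980 0.0009301 1.397e-19
#> k0a 0.046010 0.0068340 3.507e-08
#> k0b 0.002743 0.0008003 1.374e-03
#> fixed: kLa = 0.0071, k0p = 0.0109
#> fractional incorporation: acetate = 0.1, propionate = 0.23, butyrate = 0.72
```

The six free constants are recovered with small standard errors and
p-values; the fractional incorporations scatter around the generator truth
(0.12 / 0.23 / 0.79) with single-cohort sampling error, butyrate being by far
the most efficient glucose precursor per delivered mmol. The two routes to
the fraction agree to numerical precision:

```r
fraction_auc(fit$estimated, tracer_dose(), subject_profile())
#>         scfa  auc clearance fraction_auc fraction_ratio agreement_gap
#> 1    acetate 5.67     0.169       0.0996         0.0996      3.19e-16
#> 2 propionate 5.46     0.169       0.2301         0.2301      1.39e-16
#> 3   butyrate 3.84     0.169       0.7198         0.7198      1.33e-15
```

And the identifiability analysis reproduces the six-of-eight structure:

```r
S <- sensitivity_matrix(cfg$true_k, cfg$dose, subject_profile(), observed = avg)
identifiable_subsets(S)
#> <collinearity_report> 247 subsets, threshold 20, max identifiable size 6
#>   ...
#>   size 6:  12/ 28 identifiable; best k1p+k1b+kLa+k0a+k0p+k0b (index 2.80)
#>   size 7:   0/  8 identifiable; best k1a+k1p+k1b+kLa+k0a+k0p+k0b (index 24.38)
```

`run_pipeline(list(out_dir = "out", seed = 1))` chains all five stages
(correct → attribute → fit → identify → fractions) and writes one CSV/JSON
artifact per stage.

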