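# strokeperf

Quantitative perfusion and diffusion MRI analysis for acute ischemic
stroke, with a ground-truth digital phantom that makes the whole chain
testable without patient data.

## The problem and who this is for

In acute stroke imaging, the perfusion–diffusion mismatch separates
irreversibly injured tissue (the DWI lesion, with restricted diffusion)
from hypoperfused but potentially salvageable tissue-at-risk (TAR).
Quantifying it requires a chain of non-trivial steps — tracer-kinetic
conversion of dynamic susceptibility contrast (DSC) signal to
concentration, deconvolution against an arterial input function (AIF),
ADC mapping, seeded segmentation, and effect-size statistics — each of
which is easy to get subtly wrong and hard to validate on clinical data
with no ground truth. `strokeperf` is for imaging methodologists and
stroke researchers who need that chain as tested, scriptable R, and a
synthetic phantom that proves each stage by parameter recovery.

## Method core

Signal is converted to relaxation-rate change
ΔR2\*(t) = −(k/TE)·ln(S(t)/S0) (k = 1), then to concentration via
ΔR2\* = r_tissue·C with r_tissue = 0.044 ms⁻¹mM⁻¹ (1.5 T); the AIF
voxel instead uses the large-vessel quadratic law
ΔR2\* = r·C + q·C² (r = 7.6×10⁻³ ms⁻¹mM⁻¹, q = 574×10⁻⁶ ms⁻¹mM⁻²),
inverted by its non-negative root. The convolution model
C(t) = CBF·R(t) ⊗ C_a(t) is solved per voxel by **block-circulant
truncated SVD** (zero-padding to 2N, singular values below 0.2·σ_max
zeroed), which is insensitive to bolus arrival delay. From the scaled
residue k(t) = CBF·R(t): CBF = max k, Tmax = argmax k (earliest on
ties), CBV = Σk·Δt, MTT = CBV/CBF (central volume theorem). ADC comes
from the Stejskal–Tanner decay S_b = S0·exp(−b·ADC) with the three
diffusion directions combined by geometric mean. The DWI lesion is
grown from seeds under ADC < 550×10⁻⁶ mm²/s, hypoperfusion is grown
from the lesion under Tmax > 6 s, and TAR is their set difference.
Per-VOI median parameters feed Box–Cox-normalised two-way
(compartment × group) ANOVAs with partial η² classified at
0.04 / 0.25 / 0.64 (small / moderate / large).

See `vignettes/perfusion-methods.Rmd` for the models, numerical
choices, and limitations.

## Worked example

Run one synthetic subject end to end (noiseless phantom, default
32×32×4 grid, 45 frames):

```r
library(strokeperf)
res <- run_subject(list(subject_id = "demo", group = "M1",
                        phantom = list(noise_sigma = 0)))
res$voi_rows
#>   subject_id group        voi volume_ml adc_median tmax_median cbf_median cbv_median mtt_median
#> 1       demo    M1 dwi_lesion    0.6715    0.00040           8          8     0.9999      7.499
#> 2       demo    M1        tar    2.6861    0.00075           8         15     1.9996      7.998
```

The DWI-lesion row recovers the phantom's infarct-core truth (ADC
400×10⁻⁶ mm²/s, CBF 8 ml/100g/min, CBV 1 ml/100g, MTT 7.5 s, bolus
delay 8 s → Tmax 8 s) and the TAR row the penumbra truth (CBV 2, MTT 8)
to three decimals — the deconvolution, segmentation and VOI stages are
exact on noiseless input. A matched-pair two-group cohort with a CBV
offset of 1.3× in the second group:

```r
sim <- simulate_cohort(n_per_group = 16, seed = 1)
format_effect_table(sim$report)
#>     parameter             lesion_compartment                               group
#> 1  adc_median eta2 = 1.00 (p = 0.000, large) eta2 = 0.00 (p = 0.868, negligible)
#> 2 tmax_median eta2 = 0.05 (p = 0.086, small) eta2 = 0.02 (p = 0.295, negligible)
#> 3  cbf_median eta2 = 0.86 (p = 0.000, large) eta2 = 0.00 (p = 0.814, negligible)
#> 4  cbv_median eta2 = 0.88 (p = 0.000, large)   eta2 = 0.48 (p = 0.000, moderate)
#> 5  mtt_median eta2 = 0.21 (p = 0.000, small)   eta2 = 0.36 (p = 0.000, moderate)
```

Reading the group column: only CBV (and MTT, which inherits the offset
through MTT = 60·CBV/CBF) shows a group effect; the compartment column
shows the core/penumbra contrasts (ADC trivially large, since ADC
defines the lesion). A thin CLI over the same functions is installed at
`inst/scripts/strokeperf.R` (`phantom`, `subject`, `cohort`
subcommands, YAML configs, 0-based voxel coordinates).

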