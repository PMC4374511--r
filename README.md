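# punctaquant

Quantification of synaptic fluorescence puncta along neuronal cords.

Fluorescent synaptic-vesicle reporters (GFP::RAB-3, SNB-1::GFP, …) appear
as discrete bright puncta along the nerve cords of *C. elegans*; mutations
in vesicle-trafficking genes make the signal diffuse, retain it in cell
bodies, or enlarge the puncta. `punctaquant` implements the standard
line-scan quantification of such images for researchers scoring these
phenotypes:

* **profile extraction** — a calibrated 1D intensity profile sampled along
  a traced cord polyline (bilinear interpolation, perpendicular-maximum
  aggregation), with interval masks for cell bodies;
* **punctum calling** — a candidate peak is a punctum when
  peak PF / average IPF ≥ 2 (inclusive), where PF is punctal and IPF
  inter-punctal fluorescence; because PF and IPF regions define each other,
  the rule is resolved by a shrinking fixed point;
* **per-animal statistics** — PN (puncta number) and SE (synaptic
  enrichment, total PF / total IPF) over a 100 µm window centred on the
  cord;
* **group comparison** — per-genotype mean ± SD and two-sided pooled
  Student's t-tests with `NS` / `*` / `**` labels;
* **synthetic scenes** — a ground-truthed generator for punctate, diffuse,
  enlarged-puncta and soma-retention phenotypes (Poisson–Gaussian camera
  noise, 1D profiles and 2D TIFFs), used to validate the whole pipeline
  end to end.

See `vignettes/puncta-quantification.Rmd` for the model, parameter
rationale and limitations.

## Worked example

```r
library(punctaquant)

# a synthetic wild-type cord, 120 um at 0.1 um/pixel, with ground truth
sc <- make_profile(preset_library()$wild_type,
                   length_um = 120, pixel_size_um = 0.1, seed = 42)
sc$truth
#> <scene_truth> preset=wild_type seed=42 puncta=36 soma_blobs=0

q <- quantify_animal(sc$profile)
q
#> <profile_quant> PN = 31, SE = 1.247 (window 10.0-110.0 um)

head(q$puncta[, c("peak_position_um", "peak_intensity", "ratio")], 3)
#>   peak_position_um peak_intensity    ratio
#> 1             2.35       195.3066 3.469522
#> 2             4.65       184.0456 3.269477
#> 3             7.95       220.4085 3.915446
```

31 puncta fall inside the 100 µm analysis window (the ground truth holds 36
over the full 120 µm cord), and SE = 1.247 means the summed punctal signal
exceeds the summed inter-punctal signal by ~25%. Each punctum's `ratio` is
its peak intensity over the converged average IPF; all are well above the
calling threshold of 2.

Group-level reporting over 20 simulated animals per genotype:

```r
se_wt <- vapply(1:20, function(s) quantify_animal(
  make_profile(preset_library()$wild_type, 120, 0.1, seed = s)$profile)$se,
  numeric(1))
se_mut <- vapply(1:20, function(s) quantify_animal(
  make_profile(preset_library()$diffuse_mutant, 120, 0.1, seed = s)$profile)$se,
  numeric(1))

summarize_group(se_wt, "wild_type", "se")
#>    genotype metric  n     mean         sd
#> 1 wild_type     se 20 1.095483 0.05848684

compare_groups(se_wt, se_mut, group_a = "wild_type", group_b = "diffuse_mutant")
#>     group_a        group_b   t_stat df      p_value label
#> 1 wild_type diffuse_mutant 83.76496 38 1.012173e-44    **
```

The diffuse mutant calls no puncta (SE = 0 for every animal), and the
genotypes separate decisively — the simulated analogue of a punctate
vs. diffuse phenotype contrast.

`run_pipeline(run_config(), "outdir/")` runs the whole
simulate → quantify → summarise → compare chain for all four presets and
writes every artifact plus a `manifest.json` that reproduces the run
bit-identically. A thin command-line front end with `simulate`, `extract`,
`quantify`, `compare` and `run` subcommands is installed at
`system.file("cli/punctaquant", package = "punctaquant")`.

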