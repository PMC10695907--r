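# bioptiq

Structural quality assessment of endomyocardial biopsy specimens from 3D
micro-CT volumes.

When a biopsy forceps (bioptome) cuts tissue out of the heart wall, the
cut itself can damage the specimen: internal ruptures, a torn outer
surface, crush marks at the jaw contact points. Synchrotron micro-CT of
the paraffin-embedded specimen (2 µm isotropic voxels) shows this damage
non-destructively, and `bioptiq` turns such volumes into per-specimen
quality numbers and group-level statistics. It is aimed at imaging
scientists and device developers comparing bioptome designs.

## The measurements

For a segmented specimen mask with `n_seg` foreground voxels:

* **Volume**: `n_seg × edge_um³ × 10⁻⁹` mm³ (at 2 µm voxels,
  `n_seg × 8 × 10⁻⁹`).
* **Inner integrity** = `n_seg / n_filled_inner`, where `n_filled_inner`
  counts the mask after a 3D morphological closing (3×3×3 cube, one
  iteration) followed by enclosed-hole filling. Internal cracks and
  cavities enlarge the denominator, so 1 means no internal rupture.
* **Outer integrity** = `n_smoothed / n_filled_outer`, where the raw
  mask is first hole-filled and then opened (3×3×3 cube, one
  iteration). Thin surface protrusions are removed by the opening, so 1
  means a smooth, cleanly cut surface.
* **Compression score**: median of ordinal 0/1/2 observer ratings of
  pinch sites (lower median for even observer counts).

Specimens are segmented by deterministic fixed-band region growing
(band = seed-neighbourhood mean ± 3.5 SD, 26-connectivity). Groups are
compared per feature with a Mann–Whitney U test — exact by full
enumeration up to a configurable cap (the 18-vs-6 design is always
exact), otherwise a tie-corrected, continuity-corrected normal
approximation.

Because the original imaging data are not public, the package includes a
phantom generator (`generate_phantom()`, `generate_group_cohort()`)
producing biopsy-like volumes with *exact* ground truth: ellipsoidal
bodies with enclosed voids, thin cracks, 1-voxel surface spikes,
high-density pinch foci and Gaussian noise. Group presets (`CN-like`,
`B1-like`, `B2-like`) are designed so a cohort reproduces the
qualitative pattern of a sharp-jawed device (larger specimens,
control-like integrity) versus a duller one (lower inner and outer
integrity, higher compression).

## Worked example

```r
library(bioptiq)

spec <- calibrated_phantom_spec(seed = 7, void_fraction = 0.05)
ph   <- generate_phantom(spec)            # volume + ground truth
mask <- region_grow(ph$volume, phantom_seed(spec))
dice(mask, ph$truth_mask)
#> [1] 0.9997943
summarize_specimen(mask)[, c("n_seg", "volume_mm3", "inner_integrity",
                             "outer_integrity")]
#>   n_seg  volume_mm3 inner_integrity outer_integrity
#> 1 24307 0.000194456       0.9496035       0.9997656
```

The designed void fraction was 0.05, and the measured inner integrity is
0.950 ≈ 1 − 0.05; the outer surface is defect-free, so outer integrity
is ~1. The full bundled study (18 + 18 + 6 phantoms, fixed seeds) runs
end to end with:

```r
report <- run_pipeline(demo_config(), output_dir = "results/demo")
print(report)
#> <run_report> bioptiq 0.1.0: 42 specimens
#> group medians:
#>  group  volume_mm3 inner_integrity outer_integrity
#>     B1 0.000346012       0.9923799       0.9978196
#>     B2 0.000212720       0.9245927       0.9840772
#>     CN 0.000183900       0.9905770       0.9973283
#> comparisons (vs control):
#>            feature group_a u_statistic  p_two_sided significant
#>         volume_mm3      B1       108.0 1.485928e-05        TRUE
#>  compression_score      B1        46.0 6.856667e-01       FALSE
#>    inner_integrity      B1        53.0 9.741003e-01       FALSE
#>    outer_integrity      B1        67.0 4.148860e-01       FALSE
#>         volume_mm3      B2        68.0 3.781242e-01       FALSE
#>  compression_score      B2        83.5 5.593034e-02       FALSE
#>    inner_integrity      B2         0.0 1.485928e-05        TRUE
#>    outer_integrity      B2         0.0 1.485928e-05        TRUE
```

B1 differs from control only in volume; B2 shows significantly lower
inner and outer integrity — the designed contrast. The same study is
available as a narrative under `analysis/` (`01_generate_cohort.R` →
`04_invivo_success.R`), each step writing its tables under `results/`.

`04_invivo_success.R` additionally computes the two in vivo summary
rates — procedural success (≥ 6 biopsies from an animal, no major
complication) and cutting success (biopsies per cutting manoeuvre,
mean ± SD across animals) — on a bundled, clearly synthetic stand-in
record set.

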