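# blebquant

Per-cell image cytometry for duplex immunofluorescence assays of DNA
damage and apoptosis in fixed tissue sections.

## The problem

γH2AX (histone H2AX phosphorylated at Ser-139) is the standard
immunofluorescence biomarker for DNA double-strand breaks, but it cannot
tell *drug-induced* DNA damage apart from the genome-wide DNA
fragmentation that accompanies apoptosis. Cleaved caspase-3 (CC3) marks
apoptosis, but diffuse cytoplasmic CC3 also occurs in many non-apoptotic
cells. What is specific to apoptosis is CC3 aggregated into discrete
perinuclear **puncta**, the correlate of apoptotic membrane blebbing.

`blebquant` implements the quantitative pipeline for this duplex readout
on multichannel fluorescence fields (DAPI / CC3 / γH2AX):

1. **Nuclear segmentation** from the DAPI channel (smoothing → Otsu
   threshold → hole filling → distance-transform watershed), with nuclei
   retained only in the 50–200 µm² area window.
2. **Simulated cytoplasm**: an exclusive perinuclear ring mask per cell,
   built by a 1–5 µm dilation from the nuclear border (width chosen
   automatically per specimen); contested pixels go to the nearer
   nucleus.
3. **Marker calls per cell**:
   - cytoplasmic CC3⁺ if the mean ring intensity exceeds a threshold;
   - **CC3(bleb)⁺** if the ring contains ≥ 2 CC3 puncta, where a punctum
     is a thresholded 8-connected spot with area in [0.2, 5] µm²;
   - γH2AX⁺ if the mean nuclear intensity exceeds an automatically
     derived threshold;
   - **colocalization⁺** (the apoptosis readout) if γH2AX⁺ *and*
     CC3(bleb)⁺.
4. **Statistics**: per-field percent-positive values compared between
   treatment groups with two-sided Mann-Whitney U tests (exact
   permutation null for small tie-free groups, tie- and
   continuity-corrected normal approximation otherwise), annotated with
   the conventional strict star thresholds (\*p < 0.05 … \*\*\*\*p < 0.0001).

Because suitable annotated tissue images are rarely shareable, the
package ships a **synthetic-field generator** with exact per-cell ground
truth (elliptical nuclei, diffuse cytoplasmic CC3, perinuclear puncta,
pan-nuclear γH2AX, decoy spots outside the punctum size window, additive
noise), so every pipeline stage is testable end to end.

## Worked example

A packaged two-group demonstration study (3 synthetic fields per group,
150 cells per field; vehicle 2 % vs treated 20 % colocalization truth):

```r
library(blebquant)
cfg <- system.file("extdata", "study_small.yaml", package = "blebquant")
res <- run_assay(cfg, output_dir = "demo_out")
res$summaries[, c("field_id", "group_label", "n_cells",
                  "pct_bleb", "pct_gh2ax", "pct_coloc")]
#>     field_id group_label n_cells pct_bleb pct_gh2ax pct_coloc
#>  vehicle_f01     vehicle     150     5.33      25.3       2.0
#>  vehicle_f02     vehicle     150     5.33      25.3       2.0
#>  vehicle_f03     vehicle     150     5.33      25.3       2.0
#>  treated_f01     treated     150    25.33      30.0      20.0
#>  treated_f02     treated     148    25.00      30.4      20.3
#>  treated_f03     treated     148    25.68      30.4      20.3
```

Each row is one image field: `n_cells` evaluable cells, and the percent
of them positive for CC3 blebbing, nuclear γH2AX, and γH2AX/CC3(bleb)
colocalization — the recovered values sit within a fraction of a point
of the generator truth. The configured group contrast:

```r
res$comparisons
#>  group_a group_b    metric u_statistic p_value               method stars
#>  vehicle treated pct_coloc           0  0.0593 normal-approximation    ns
```

With only three fields per group even complete separation cannot reach
p < 0.05 — which is exactly why the assay design analyses at least six
fields per specimen; the full-scale packaged study
(`study_demo.yaml`, 2 × 6 fields, > 15,000 cells) yields p < 0.01 on the
same contrast.

Real TIFF fields are analysed the same way via a `manifest:` block in the
config (per-file channel mapping and micron calibration), and a thin CLI
is installed at `exec/blebquant` inside the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "blebquant", package = "blebquant"))')" config.yaml --out out/
```

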