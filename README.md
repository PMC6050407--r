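# qflowkit

Quantitative flow (qFlow) cytometry analysis in R: convert single-cell
fluorescence to **absolute plasma-membrane receptor concentrations**
(receptors/cell) with bead calibration, resolve cell populations by
hierarchical gating, quantify receptor heterogeneity, and score candidate
drug targets.

Tumors — glioblastoma in particular — resist receptor-targeted therapy
partly because receptor expression varies cell to cell: a minority
subpopulation carrying a receptor at very high density can sustain an
alternative signaling route that bulk averages never reveal. `qflowkit`
implements the analysis chain that makes this variation measurable and
comparable across instruments and studies. It is aimed at cytometry and
tumor-biology groups quantifying receptor tyrosine kinases (VEGFR1/2,
PDGFRα/β, EGFR, IGFR, Tie2, NRP1, …) on dissociated tumor or xenograft
samples.

## The method

1. **Bead calibration.** Beads with known fluorophore counts $F$ give a
   log-log standard curve $\log_{10} I = b + a\log_{10}F$ (median intensity
   per peak, least squares). Cell fluorescence converts as
   $R = \rho\,10^{(\log_{10}I - b)/a}$ receptors/cell, with $\rho$ the
   receptors-per-fluorophore stoichiometry (default 1 for PE conjugates).
2. **Hierarchical gating.** 1-D threshold gates in a tree — live
   (viability-dye⁻) → CD45⁻ → CD34⁺ EC-like / CD133⁺ stem-like / other —
   with composition reported as percent of live cells.
3. **Ensemble statistics.** Geometric-mean receptors/cell per population ×
   marker (plus arithmetic mean and a seeded bootstrap interval).
4. **Cell-by-cell heterogeneity.** Each distribution is decomposed into
   $k = 1$–$9$ log-normal components by EM; $k$ is selected by lowest
   BIC $= (3k-1)\ln n - 2\ell$ ( ≤ 2 components ⇒ low heterogeneity).
   Independently, Rao **quadratic entropy**
   $\mathrm{QE} = \sum_{i,j} p_i p_j\,|c_i - c_j|$ over 500 equally
   spaced log10 bins summarizes distributional diversity
   (QE < 0.7 ⇒ low heterogeneity).
5. **Target scoring.** A marker on a population is a *primary target* if
   ≥ 70% of cells carry > 6,000 receptors/cell, QE < 0.7, and (when a
   healthy reference is available) the ensemble is ≥ 2-fold elevated; it
   is a *combination candidate* if a minority component (weight ≤ 0.15)
   sits ≥ 10× above the ensemble geometric mean.

A synthetic-data module generates bead sets and multi-population event
tables with known ground truth — including a ready-made glioblastoma
PDX-like scenario (`paperlike_scenario()`) with encoded minority
subpopulations — so every stage is testable without specimens.

## Worked example

Simulate the PDX-like scenario at 20,000 events, then run the full
pipeline from the generated configuration:

```r
library(qflowkit)

dir   <- file.path(tempdir(), "qf-demo")
paths <- simulate_command("paperlike", n = 20000, seed = 7, out_dir = dir)
res   <- run_pipeline(load_config(paths$config), out_dir = file.path(dir, "out"))

res$composition
#> <composition_report> 20000 live events (0 ungated)
#>  population count percent
#>       other 12490  62.45%
#>    mouse_EC  6265  31.32%
#>    human_EC  1059   5.29%
#>         GSC   186   0.93%
```

The composition recovers the generator's encoded population structure
(bulk ~62.5%, mouse EC-like at 6× the human EC-like fraction, stem cells
~0.9%). Heterogeneity analysis of human EC-like VEGFR1 finds the encoded
minority subpopulation — ~10% of cells near 41,000 receptors/cell over a
~3,600 ensemble mean:

```r
res$fits[["human_EC/VEGFR1"]]
#> <mixture_fit> k = 2 components, n = 1059 cells, BIC = 958.6
#>   weight mu_log10 sigma_log10 receptors
#> 1 0.8939    3.427      0.2766      2674
#> 2 0.1061    4.634      0.2213     43075
```

Target scoring separates broadly available, low-entropy markers from
minority-subpopulation (combination-therapy) candidates:

```r
res$scores[["mouse_EC/PDGFRA"]]
#> <target_score> mouse_EC / PDGFRA: availability 80.9%, QE 0.429, k=2 -> PRIMARY TARGET
res$scores[["human_EC/VEGFR1"]]
#> <target_score> human_EC / VEGFR1: availability 19.5%, QE 0.482, k=2 -> not primary + combination candidate
```

`res$targets` ranks all population × marker scores (primary targets
first); `run_pipeline(..., out_dir =)` writes `composition.csv`,
`stats.csv`, `targets.csv`, `fits.json` and a run log. A thin CLI wrapper
with the same two verbs lives at `inst/cli/qflow`:

```sh
Rscript inst/cli/qflow simulate --n 20000 --seed 7 --out-dir sim/
Rscript inst/cli/qflow run --config sim/config.json --out-dir results/
```

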