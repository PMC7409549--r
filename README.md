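# spliffr

Quantification and temporal inference for **SPLIFF** split-ubiquitin cleavage
reporter experiments and **FRAP** recovery measurements, written for yeast
cell biologists who time-resolve protein–protein interactions over the cell
cycle.

## The measurements

**SPLIFF.** A bait protein carries an mCherry–Cub–GFP (CCG) fusion. When a
prey tagged with the N-terminal ubiquitin half (Nub) interacts with the bait,
the reconstituted ubiquitin is cleaved and the GFP moiety is released and
rapidly degraded, while the mCherry-bearing product persists. The local
red/green ratio therefore records *when and where* the interaction occurred.
From three regions of interest per frame (site of interest, cytosol,
extracellular background), the package computes

- localized intensity `FI_c = I_roi − I_cytosol` per channel,
- relative fluorescence intensity `RFI_c(t) = FI_c(t) / FI_c(t_ref)`, with
  `t_ref` the last frame before cell fusion,
- the conversion statistic

  ```
  FD(t) = 100 · (RFI_red − RFI_green) / RFI_red   [percent]
  ```

Single-cell FD traces are pooled with loess (degree 2, tricube weights) into
a population curve with a 95% band; a sliding window of three consecutive
grid points (two sampling intervals) gets a linear trend fitted to the pooled
replicate values, and a window is called an interaction when

- mean conversion < 70%: slope ≥ 1 %/min and P < 0.05, or
- mean conversion ≥ 70%: slope > 0 and P < 0.05,

and the same criterion is *not* met by a non-interacting negative control in
that window (stars: `***` P < 0.001, `**` P < 0.01, `*` P < 0.05). Windows at
or above 80% conversion carry an interpretability caveat flag. Measurements
are phase-resolved: PCDI (site of cell fusion), PCDII (bud-site assembly and
bud growth), PCDIII (bud neck until abscission).

**FRAP.** Recovery traces are double-normalized (ROI/reference ratio, then
rescaled so the pre-bleach mean is 1 and the first post-bleach frame is 0)
and fitted with the one-phase association model
`F(t) = Y0 + (P − Y0)(1 − e^(−kt))`; the recovery half-time is
`t½ = ln 2 / k` and the plateau estimates the mobile fraction. Group
comparisons are routed through the D'Agostino–Pearson normality test to a
t test / Mann–Whitney U (two groups) or ANOVA / Kruskal–Wallis (more groups).

Because the raw microscopy data are not public, the package ships a
forward simulator (linear cleavage/degradation kinetics, per-exposure
photobleaching, additive measurement noise, FRAP recovery with immobile
fraction) whose ground truth is retained, so every stage of the pipeline is
validated end to end on synthetic data.

## Worked example

```r
library(spliffr)

# simulate the standard benchmark (20 cells, 2-min frames, 115 min, one true
# interaction window per phase), analyse it with a null control, score calls
res <- run_recovery_benchmark(seed = 1)
res$fit
#> SPLIFF interaction fit: 20 cells, 55 windows, 18 called
#>   interaction 6-20 min
#>   interaction 44-58 min
#>   interaction 98-112 min
```

The three reported intervals recover the interaction windows the population
was simulated with — (6, 18), (44, 56) and (100, 110) minutes — to within one
sliding window:

```r
summary(res$fit)
#> SPLIFF interaction fit (span 0.25, alpha 0.05, slope floor 1 %/min)
#>   cells: 20; pooled points: 1149
#>   conversion at end of recording: 82.7% (95% CI 81.8-83.6)
#>   windows called: 18 of 55 (0 with the >=80% caveat)
#>   called windows by phase: PCDI=6, PCDII=7, PCDIII=5
res$score$f1
#> [1] 1
```

`coef(res$fit)` returns the per-window slope table (slope in %/min, P-value,
mean conversion, call, stars, reason) and `plot(res$fit)` draws the
conversion-versus-time panel with the 95% band and called windows. A FRAP
round trip:

```r
fit_frap <- frap_roundtrip(frap_sim_config(rate_k = log(2) / 8.82))
fit_frap
#> FRAP one-phase association fit for cell1 (group1)
#>   k = 0.07859 /s, t_1/2 = 8.82 s, mobile fraction = 1 (RMS 4.15e-11)
```

A command-line wrapper with `simulate`, `analyze`, `frap` and `benchmark`
subcommands is installed at `inst/cli/spliff`.

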