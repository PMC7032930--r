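# dgsep — feedback inhibition and pattern separation in a dentate gyrus lamella

`dgsep` is a spiking-network model of a 2 mm dentate gyrus (DG)
lamella — 400 perforant-path (PP) afferents, 2000 granule cells (GCs),
24 basket cells (BCs), 24 hilar perforant-path-associated cells (HCs)
and 60 mossy cells (MCs) — together with the complete in-silico
pipeline for studying how the quantitative properties of *net* feedback
inhibition shape pattern separation of temporally structured input.

The model is constrained in a tuning phase to three slice-physiology
measurements of the DG feedback circuit:

* steep recruitment — half-maximal compound feedback IPSC at ~2%
  active GCs for local and ~3.2% for remote (800 µm) activation;
* spatially graded inhibition (local BC pools, global HC connectivity);
* strong short-term facilitation of the compound feedback IPSC
  (index ≈ 1.4 at 10 Hz, ≈ 2.1 at 50 Hz for 10-pulse trains), carried
  by Tsodyks–Markram facilitation at mossy-fiber outputs.

With parameters then frozen, the experimental phase drives the network
with families of 25 overlapping PP patterns (24 of 400 afferents
active; theta 10 Hz or slow-gamma 30 Hz sinusoid-modulated
inhomogeneous-Poisson trains, 600 ms, peak 100 Hz) and quantifies
pattern separation on population rate vectors: `R_in` (PP) versus
`R_out` (GC) for all 325 pattern pairs, per similarity measure
(Pearson R, cosine/NDP, overlap), binwise curves, the mean
`R_in − R_out` area to the unity line, and pairwise-isolated condition
effects ΔR_out (e.g. full − no-feedback, on identical input). The
package reproduces the frequency dependence of feedback-inhibitory
pattern separation: for highly similar inputs (0.9 ≤ R_in ≤ 1) the
isolated feedback effect roughly doubles from theta- to
gamma-modulated input.

## Worked example

```r
library(dgsep)

## build the full-scale tuned lamella (one wiring replicate)
net <- build_network(network_config(), seed = 1)
net
#> dentate lamella network [FULL]
#>   PP 400 | GC 2000 | BC 24 | HC 24 | MC 60 on 2000 um
#>   120960 edges in 9 classes (seed 1)

## tuning-phase physiology: recruitment of feedback inhibition
ra <- recruitment_analysis(net, probe_positions = seq(400, 1600, length.out = 8))
c(local = ra$halfmax_local, remote = ra$halfmax_remote)
#>    local   remote
#> 1.583579 2.534274

## facilitation of the compound feedback IPSC, 10-pulse trains
facilitation_curve(net, freqs = c(10, 50),
                   probe_positions = seq(600, 1400, length.out = 6))
#>  freq    index        sd n
#>    10 1.528473 0.1597466 6
#>    50 2.056975 0.5890804 6

## pattern-separation experiment (desk scale: quarter-size circuit,
## full 400-afferent input space, 2 wiring replicates)
plan <- experiment_plan(
  conditions = c("FULL", "NO_FB"), frequencies = c(10, 30),
  n_seeds = 2, base_seed = 1,
  network_config = network_config(scale = 0.25, keep_input = TRUE))
ex <- run_experiment(plan)
subset(ex$isolated, measure == "pearson")
#>  seed frequency condition measure mean_delta_isolated band_delta_isolated
#>     1        10     NO_FB pearson          0.04582854          0.02737880
#>     1        30     NO_FB pearson          0.12051713          0.06619367
#>  7920        10     NO_FB pearson          0.08125921          0.02021822
#>  7920        30     NO_FB pearson          0.07168017          0.05724603
```

The first block prints one replicate's half-maximal recruitment
fractions (percent of GCs; compare 1.99 ± 0.22% local and 3.17 ± 0.57%
remote in slices — like the slice estimates, single-network values
scatter, so the headline numbers average several wiring replicates:
1.87% and 2.87% over five) and facilitation indices (compare
1.41 ± 0.11 at 10 Hz and 2.09 ± 0.19 at 50 Hz; five-replicate means
1.37 and 2.19). The second block isolates the feedback-inhibition
effect on pattern separation pair by pair: `band_delta_isolated` is
the mean ΔR_out for highly similar inputs (0.9 ≤ R_in ≤ 1), which
more than doubles from 10 Hz to 30 Hz input modulation
(two-replicate means 0.024 at theta vs 0.062 at slow gamma).

A thin command-line front end over the same functions is included:

```sh
Rscript inst/scripts/dgsep.R tune-recruitment --seed 1
Rscript inst/scripts/dgsep.R run --plan plan.json --out results/
Rscript inst/scripts/dgsep.R scan --axis tau --levels 0.5,1,2,5
```

See the methods vignette (`vignettes/dgsep-methods.Rmd`) for the model
description, conventions and limitations.

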