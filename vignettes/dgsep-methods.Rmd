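---
title: "Modelling feedback inhibition and pattern separation in a dentate gyrus lamella"
author: "dgsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feedback inhibition and pattern separation in a dentate gyrus lamella}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dgsep)
```

## The scientific problem

The dentate gyrus (DG) is widely believed to perform *pattern
separation*: it maps similar cortical input patterns onto less similar
granule-cell (GC) output patterns before they reach CA3. Feedback
inhibition — GCs recruiting interneurons that in turn inhibit the GC
population — is the circuit motif most often credited with this
computation, because it implements direct competition between active
cell assemblies. Slice physiology constrains this motif quantitatively:
net feedback inhibition in the DG is recruited steeply (half-maximal
compound IPSCs at about 2% active GCs for local activation and about
3.2% for remote activation, saturating below ~5%), it is spatially
graded along the DG blade, and it *facilitates* strongly during
repetitive activity (compound-IPSC facilitation indices of about 1.4 at
10 Hz and 2.1 at 50 Hz), driven by facilitating mossy-fiber synapses
onto hilar cells and basket cells.

`dgsep` implements a spiking network model of a 2 mm DG lamella that is
tuned, in a dedicated *tuning phase*, to exactly these three
quantitative properties, and an *experimental phase* that measures the
model's pattern-separation behaviour on temporally structured
(theta- or gamma-modulated) perforant-path input without further
parameter changes. The headline in-silico observation this pipeline
reproduces is that the isolated contribution of feedback inhibition to
pattern separation is frequency dependent: for highly similar input
patterns it more than doubles when the input modulation moves from the
theta band (10 Hz) to the slow-gamma band (30 Hz).

## Circuit architecture

At full scale the lamella holds 400 perforant-path (PP) afferents,
2000 GCs, 24 basket cells (BCs), 24 hilar perforant-path-associated
cells (HCs) and 60 mossy cells (MCs), all evenly spread over a
2000 µm axis. Wiring follows per-edge-class rules: each presynaptic
cell contacts a fixed number of distinct targets drawn from a spatial
target pool (clipped at the lamella boundaries — a lamella is not
periodic, so there is no wraparound).

* `pp_gc` — each PP contacts 100 GCs sampled without replacement under
  a Gaussian spatial weighting (SD 1 mm) around a random peak position,
  giving broad, nearly uniform input connectivity.
* `pp_bc` — feedforward drive of BCs from a local (~600 µm) pool.
* `gc_bc`, `gc_hc`, `gc_mc` — mossy-fiber (MF) outputs into the
  feedback circuit; these are the facilitating synapses.
* `bc_gc` — *local* inhibition: BC inputs and outputs are restricted to
  a ~600 µm pool.
* `hc_gc` — *global* inhibition: HC connectivity is independent of
  space.
* `mc_bc`, `mc_hc` — MC projections within the feedback circuit. The
  direct MC→GC projection is absent: mossy cells project to GCs mostly
  outside the lamellar plane, so a single-lamella model omits it.

The local/global split between BC and HC output pools is what produces
the experimentally observed difference between local and remote
recruitment curves.

## Cell and synapse models

Cells are adaptive conductance-based leaky integrate-and-fire point
neurons (per-type capacitance, leak, threshold, reset, refractory
period, and a spike-triggered adaptation conductance with reversal at
−90 mV). Channel-level biophysics is deliberately out of scope: every
quantity on the package's acceptance surface is circuit-level
(normalised IPSC amplitudes, recruitment fractions, facilitation
indices, population rate-vector statistics), and those are set by
thresholds, integration time constants and synaptic dynamics rather
than by individual current kinetics. Spike thresholds carry a
deterministic per-cell spread (uniform, ±1 mV for GCs, ±12 mV for
interneurons, drawn from the wiring seed), representing the
heterogeneity of intrinsic excitability that makes interneuron
recruitment graded rather than all-or-none.

Synapses are single-exponential conductances with per-class decay time
constant, delay and reversal potential. Mossy-fiber outputs use a
Tsodyks–Markram facilitation rule: the utilisation `u` jumps by
`U (1 − u)` at each presynaptic spike and relaxes with `tau_facil`;
the conductance increment is `weight · u / U`, so an isolated spike
delivers exactly `weight` and the maximal facilitation ratio is `1/U`.
`tau_facil = 0` switches facilitation off, which is how the
`NO_FACILITATION` condition is implemented.

Interneurons and mossy cells additionally receive white membrane
current noise (85–120 pA·√ms, i.e. a ~2–3 mV voltage SD), which makes
their recruitment probabilistic near threshold. This is what renders
the compound IPSC a smooth function of drive in a circuit with only 48
inhibitory interneurons; together with the threshold spread it stands
in for the synaptic and channel noise of the real circuit. Granule
cells carry no noise, so the zero-drive network is silent and the
interneuron resting state (tens of mV below threshold) makes
spontaneous noise-driven spikes practically impossible.

Integration is forward Euler at `dt = 0.05` ms with exact exponential
decay for all conductance states; spike delays are rounded to whole
steps. The simulator is reproducible: wiring, thresholds and input
spikes come from R-side seeded generators on three named streams
(network wiring, PP wiring, input spikes), and the membrane noise from
a seeded generator inside the integrator, so a network seed can be
held fixed while patterns vary and vice versa, and identical calls
give bit-identical results.

## The tuning phase

Three protocols hold the model to the slice measurements. All IPSCs
are measured at a probe GC voltage-clamped at 0 mV with its excitatory
synapses disabled, as the experimental voltage-clamp isolation does;
amplitudes are normalised to the probe cell's maximum over stimulation
site and strength, so half-maximal always means 50% of that global
maximum.

**Recruitment** (`recruitment_analysis`): populations of increasing
size adjacent to the probe (local) or 800 µm away (remote) are forced
to spike by suprathreshold current pulses (12 ms: the optogenetic
pulses lasted 20 ms, but only spikes preceding the evoked IPSC recruit
it, so the effective recruiting burst is shorter), delivered in
triplicate over independent noise realisations, and the half-maximal
active GC fraction is interpolated linearly between the measured
points. Averaged over five independently wired replicates the tuned
model yields ≈1.9% (local) and ≈2.9% (remote), within one experimental
SD of the slice values (1.99 ± 0.22% and 3.17 ± 0.57%).

**Spatial profile** (`spatial_profile`): the same activation swept
along the lamella at 100 µm steps maps spatially graded inhibition;
the saturated profile decreases monotonically with distance from the
probe, and flattens under the `GLOBAL_FB` condition.

**Facilitation** (`facilitation_protocol`, `facilitation_curve`):
trains of ten brief, strong current pulses emulate antidromic
mossy-fiber stimulation. Two design choices matter here. First, the
pulses are strong and brief (5 nA, 2 ms) because antidromic stimulation
fires axons directly — evoked inhibition must not be able to veto the
stimulated spikes, unlike in the optogenetic recruitment protocol where
somatic veto is physiological. Second, the stimulated pool is *small*
(a few percent of GCs, staggered over 4 ms to mimic conduction-delay
spread), mirroring the experimental use of minimal stimulation power:
a near-saturating first IPSC would clamp the measurable facilitation
toward 1 regardless of the synaptic dynamics. The facilitation index is
the mean of the last three IPSC peaks over the first. At short
inter-pulse intervals compound IPSCs ride on the decay of their
predecessors, which compresses naive flat-baseline amplitudes; the
amplitudes entering the index (pulses 1 and 8–10) are therefore
measured by omission differencing — the train is resimulated with the
pulse of interest omitted, and since the trajectory is deterministic
per noise seed the difference trace isolates that pulse's response
exactly. The stimulated pool is calibrated per probe cell to the
smallest size whose weakest-trial volley response reaches a fixed
fraction of the probe's single-volley saturation, emulating the
per-slice adjustment to minimal reliable stimulation power. Because
the experimental indices are means over recorded cells and repeated
trials, the package's headline numbers average the protocol over six
probe cells spread along the central lamella, each train delivered in
triplicate over independent noise realisations, and indices outside
triple SD (typically a probe with a very small initial IPSC) are
excluded. Averaged over five wiring replicates the tuned model yields
index ≈1.4 at 10 Hz and ≈2.2 at 50 Hz (slice values 1.41 ± 0.11 and
2.09 ± 0.19).

The free parameters actually adjusted during tuning are the MF weights
onto BCs and HCs, the interneuron output weights, the interneuron
threshold spread, and `(U, tau_facil)` of the MF synapses; everything
else (counts, pools, kinetics of the base circuit) is fixed structure.
After the tuning targets are met the model is frozen; the pattern
separation experiment changes nothing but the input.

## Input patterns

Inputs are families of 25 patterns over the 400 PP afferents. Pattern
`p` activates the 24 adjacent afferents starting at afferent `p`, so
consecutive patterns overlap in 23 of 24 afferents and overlap decays
linearly to zero at a shift of 24. Every active afferent fires an
inhomogeneous Poisson train with a sinusoidal rate profile (peak
100 Hz, minimum 0 Hz, 600 ms — about five theta cycles), modulated at
10 Hz (theta) or 30 Hz (slow gamma); the mean drive (30 expected
spikes per afferent) is independent of the modulation frequency. The
sinusoid starts at its trough to avoid an onset burst. Trains are
generated once per afferent from the per-afferent seed
`xor(seed_input, afferent)` and shared across patterns, so two
patterns are bit-identical on their common afferents — input
similarity is controlled purely by afferent-set overlap. Spike trains
are drawn by thinning a homogeneous Poisson process at the peak rate,
which makes window counts exactly Poisson with the integrated-rate
mean.

## Separation statistics

For every pattern pair the input similarity `R_in` (over PP rate
vectors) and output similarity `R_out` (over GC rate vectors) are
computed in a common window — the full 600 ms, or 100 ms / 33 ms
windows for the time-resolved variants. Three measures are supported:
Pearson correlation, normalised dot product (cosine), and pattern
overlap (coactive over active cells). Pearson on a zero-variance
vector is undefined; such pairs are returned as `NA` and excluded
downstream rather than given an arbitrary value. 25 patterns give 325
comparisons including self-pairs, 300 without.

Summary statistics follow the binwise convention: `R_in` bins of width
0.1 covering [0, 1] (left-closed, right-open, `R_in = 1` in the top
bin), binwise mean `R_out`, and the *area to the unity line* — the
mean over occupied bins of binwise `R_in − R_out` — as the scalar
separation measure. Only occupied bins enter the mean; empty bins are
flagged, not interpolated. Binwise `R_in` uses the bin means of the
member pairs, not the bin centres (with 300+ pairs per family the two
differ by <0.01; bin means keep the statistic exact for sparse bins).
Isolated effects of a manipulation are computed pairwise — `ΔR_out`
between the two conditions for each individual pattern pair, run on
identical input — and then binned; subtracting and averaging commute,
which the test suite asserts numerically. The coefficient of variation
of `ΔR_out` uses per-bin sample SD over bin mean, averaged over bins
within 0.2 < `R_in` < 0.8 only, because near-zero bin means at the
edges make the ratio unstable. The headline band for "highly similar
inputs" is `0.9 ≤ R_in ≤ 1`.

## Conditions and the experiment runner

`apply_condition` derives every experimental condition from the full
tuned network by changing only the declared parameters: `NO_FB` zeroes
all MF outputs into the feedback circuit, `NO_INHIBITION` zeroes all
interneuron outputs, `GLOBAL_FB` redraws BC outputs from a global pool
at unchanged out-degree, `NO_FACILITATION` zeroes the MF facilitation
time constant, `FF_X2` doubles the feedforward PP→BC weight, and
`TAU_SCALE` / `PP_SCALE` scale the inhibitory decay constants and the
PP→GC weight. An edge-table audit (`audit_conditions`) verifies that
nothing else moved; the test suite runs it for every condition.

`run_experiment` crosses conditions with modulation frequencies over
independently wired network replicates, feeding the same input family
to every condition within a replicate (the paired design that isolated
effects require), and persists spikes, pair tables and a JSON manifest
so that every summary number is re-derivable from the stored spikes.

## The surrogate generator

The statistics layer is testable without the simulator through
surrogate rate vectors with controlled structure: sparse activity with
log-normal rates among active cells, and a shared-component mixture
for correlation control — a fraction `target_r` of cells carries
identical values in both vectors, the rest are independent draws from
the same marginal. Because shared entries contribute the full marginal
variance to the covariance, the expected Pearson correlation equals
`target_r` exactly, with no distributional approximation. Surrogate
rasters are homogeneous Poisson and use the same spike-table format as
the simulator, so they are drop-in inputs for the analysis functions.
What surrogate tests do *not* exercise is temporal structure within
the window — oscillatory phase locking, bursting, inhibition-imposed
timing — which only the simulator produces; surrogate-based results
therefore validate the statistics, never the biology.

## Scaling for desk runs

`network_config(scale = s)` shrinks all populations proportionally.
Divergences shrink with the target population and synaptic weights are
compensated by the inverse convergence ratio, preserving the expected
summed conductance per cell — the same device the model itself uses in
reverse when up-scaling from its base circuit. `keep_input = TRUE`
retains the full 400-afferent input space while scaling the cellular
populations, preserving the input-overlap geometry of the pattern
families (at a quarter scale with a scaled input space, adjacent
patterns would no longer reach the high-similarity band at all). The
package's desk preset for the separation experiment is scale 0.25 with
`keep_input = TRUE`, 2 network seeds and 25 patterns; the tuning-phase
protocols are cheap enough to run at full scale everywhere, and the
test suite does so. Down-scaled networks preserve the qualitative
ordering (active GC fraction FULL < NO_FB < NO_INHIBITION) and the
sign and frequency-ordering of the isolated feedback effect, but not
the exact effect magnitudes, which is why the full-scale, 7-seed
experiment remains the reference configuration
(`experiment_plan(n_seeds = 7)`, hours of compute).

## Numerical and convention details

* Units: ms, mV, nS, pF, pA, µm. Cell indices are 1-based in R and
  0-based in the on-disk TSV format.
* `dt = 0.05` ms default; `run_simulation` refuses `dt > 0.2` ms.
* IPSC peaks are baseline-subtracted (baseline at pulse onset) and
  searched within 100 ms of the pulse; train amplitudes entering the
  facilitation index use the omission-differencing baseline described
  above.
* Remote activation sites beyond the lamella boundary are reflected to
  the opposite side of the probe.
* Facilitation state is per presynaptic cell and edge class (all
  synapses of one MF share one spike train, hence one utilisation
  state).

## Known limitations

* Point neurons cannot reproduce dendritic filtering of PP input or
  the depolarising envelope of mossy cells; all tuning targets are
  circuit-level by design.
* No CA3 backprojection, no long-range or extralamellar inhibition, no
  neurogenesis; the model is a single isolated lamella.
* Absolute IPSC amplitudes (pA) are not calibrated — only normalised
  amplitudes are meaningful.
* The inhibitory decay constants of the compound IPSC (15 ms local,
  20 ms remote, reflecting the slower decay of remotely evoked
  responses) are set to plausible values rather than fitted to traces;
  the separation result is robust to scaling them (the `TAU_SCALE`
  scan), which is why this coarseness is acceptable.
* Without synaptic facilitation (`NO_FACILITATION`) the compound IPSC
  index is ~1 at theta intervals, but a residual (~1.2-1.3) remains at
  gamma intervals from membrane temporal integration across short
  inter-pulse intervals; the facilitation the model is tuned to is the
  component on top of that residual.
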