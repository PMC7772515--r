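---
title: "Methods: spine morphometry, the two-layer neuron and information transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine morphometry, the two-layer neuron and information transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

## Scope

`spinesim` bundles three strands of analysis around excitatory synapses on
dendritic spines:

1. **Morphometry** — measurement formulas for serial-section (FIB/SEM-style)
   reconstructions: spine head volume, postsynaptic density (PSD) area,
   dendritic diameter, per-dendrite densities, the PSD-area/neck-length
   ratio, axon-coupled spine and endoplasmic-reticulum (ER) statistics.
2. **A two-layer model neuron** — dendritic branches as independent leaky
   integrate-and-fire (LIF) units with lognormal synaptic weights, feeding
   a somatic LIF unit, analysed with mutual information (MI) between
   binarized input and spike sequences.
3. **Uncaging-response quantification** — amplitude extraction from
   repeated uEPSP/uEPSC traces and the spine-geometry grouping rules used
   with them.

A seeded synthetic-data generator emulates the summary statistics of the
regional EM datasets so that every stage can be exercised and tested
without imaging data.

## Morphometric definitions

All measurements operate on pre-annotated quantities; no image processing
is performed. For a contour stack with per-section cross-sectional areas
$a_i$ (µm²) and section thickness $t$ (µm, typically 0.04):

* head volume $V = t \sum_i a_i$;
* PSD area $A = t \sum_i \ell_i$ for a cross-sectioned synapse with
  per-section trace lengths $\ell_i$, or the single-section area verbatim
  for a synapse cut en face (a stack carrying both representations is
  rejected as ambiguous);
* dendritic diameter = mean of per-section widths across the widest
  transect of the narrowest dimension.

Dendrite-level quantities divide by the reconstructed dendrite length
$L$: spine density $n/L$ (filopodia excluded — they bear no synapse), PSD
area density $\sum A_s / L$, neck-length density $\sum \ell^{neck}_s / L$.
Spines whose PSD could not be measured (neck leaving the field of view)
are dropped from PSD aggregates but kept for density, and the excluded
count is reported as a QC attribute. The dendrite-level PSD/neck ratio is
the ratio of totals $\sum A_s / \sum \ell^{neck}_s$, deliberately *not*
the mean of per-spine ratios. Stubby spines (no measurable neck) are
excluded from ratio statistics with a warning; this handling is a package
choice, since annotation practice varies. ER hotspot adjacency is ordinal
(the previous/next spine in positional order), not a distance threshold.

## The two-layer model neuron

Each of $N_{branch} = 20$ branches receives $N_{syn} = 250$ synapses.
Synapse $i$ of branch $j$ fires at Poisson times with frequency $f \in
[0.5, 10]$ Hz and carries weight $W_{ij}$ drawn from a lognormal
distribution with location $\mu_e$ and shape $\sigma_e$. The branch
membrane obeys

$$\frac{dV_j}{dt} = -\frac{V_j - V_{rest}}{\tau_{dend}} + \sum_i \sum_k
W_{ij}\,\delta(t - t_{ijk}),$$

with a spike emitted when $V_j > \theta$ (strict inequality), after which
$V_j \to V_{reset,dend}$. The soma integrates dendritic spikes the same
way with weight $W = 20$ mV per spike. Constants: $V_{rest} = -75$ mV,
$V_{reset,dend} = -75$ mV, $V_{reset,soma} = -80$ mV, $\theta = -40$ mV,
$\tau_{dend} = 10$ ms, $\tau_{soma} = 20$ ms, 20-ms refractory period in
both layers.

**Weight units.** With $\mu_e = -6$ the median weight is $e^{-6} \approx
2.5\times10^{-3}$; on a millivolt scale no branch could ever span the
35-mV gap from rest to threshold, so the lognormal weights are
interpreted on a **volt** scale and converted to mV inside the integrator
(`w_scale = 1000`). Under this reading the strongest of 250 synapses at
$\sigma_e = 1$ sits near threshold, which is exactly the regime the MI
analysis requires, and the default $\sigma_e = 1$ needs no further
calibration (`tuning_curve()` exposes the sweep if other shapes are of
interest).

**Two weight scenarios.** Case 1 draws all weights from a single
lognormal; case 2 first draws a per-branch location $\mu_e^{(j)} \sim
N(-6, 0.4)$, making synaptic strength heterogeneous across branches while
each branch stays lognormal.

### Numerical integration

Between events the membrane relaxes exponentially, so the simulator is
event-driven and *exact*: $V(t^-) = V_{rest} + (V(t_0) - V_{rest})
e^{-(t - t_0)/\tau}$, followed by the instantaneous jump $V \mathrel{+}=
W$ (a Dirac-delta input integrated across the event). The threshold is
examined after each jump; simultaneous events are applied in ascending
synapse index. The refractory period is an absolute 20-ms lockout: jumps
arriving during it still depolarise the membrane but cannot trigger a
spike, and because the membrane can still sit above threshold when the
lockout expires, both integrators also examine the threshold at the
expiry instant.

As an independent cross-check the package ships a fixed-step grid
integrator (`lif_grid_reference()`, default $dt = 0.01$ ms) that advances
the membrane with the exact per-step decay factor, applies events at the
end of the step containing them and checks the threshold at every grid
point. The forward-Euler decay factor $(1 - dt/\tau)$ was rejected for
the reference because its systematic bias (≈0.02 mV near threshold) is of
the same order as typical near-threshold margins and would turn grazing
crossings into coin flips. For the same reason, equivalence tests draw
event times *on the $dt$ grid*: both integrators then examine the
threshold at identical instants and must agree spike for spike, which
turns the comparison into an exact test of the integration logic rather
than of threshold-detection discretisation noise.

## Mutual information

Input and spike sequences are binned at 5 ms (bins anchored at $t = 0$, a
trailing partial bin dropped) and binarized (1 = at least one event in
the bin). For the binarized pair the plug-in MI over the empirical 2×2
joint table is

$$MI = \sum_{x \in \{0,1\}} \sum_{y \in \{0,1\}} p(x, y) \log_2
\frac{p(x,y)}{p(x)\,p(y)},$$

with $0 \log 0 \equiv 0$. Base 2 (bits per bin) is a package choice — no
base is canonical here and every ordering/zero property is base-invariant.
No bias correction is applied; the estimator is the bare
maximum-likelihood plug-in. Information transfer is measured between the
input train of each branch's *strongest* synapse and (a) the same
branch's dendritic spike train, (b) the somatic spike train;
`tuning_curve()` sweeps the input frequency and reports the across-branch
mean MI per trial, summarised as mean ± SD across trials. Both per-branch
values and their mean are available, since either convention is
defensible.

The qualitative behaviour (computed by the acceptance script and the test
suite, not asserted here): the dendritic MI rises from the low-frequency
end, peaks at an interior frequency and collapses at high input rates as
background-driven spiking decouples output from the strongest input;
branch-heterogeneous weights (case 2) do not improve somatic MI at the
case-1 optimum; and lowering $\mu_e$ moves the optimum to higher input
frequencies.

## Statistical workflow

`choose_and_correlate()` and `choose_and_compare()` reproduce a
normality-gated test choice: Shapiro–Wilk at $\alpha = 0.05$ **per
sample** (the pooled alternative is equally defensible; per-group was
chosen and is stated here so results are interpretable); all samples must
pass for the parametric branch. Correlation: Pearson vs Spearman
(midranks for ties). Two groups: Student's *t* vs Mann–Whitney *U*.
Three or more: one-way ANOVA vs Kruskal–Wallis, followed by all pairwise
comparisons in the same family with Bonferroni-adjusted $p$ values capped
at 1. Samples beyond Shapiro–Wilk's $n = 5000$ limit are thinned to 5000
evenly spaced order statistics for the gate only. Stars follow the usual
0.05 / 0.01 / 0.001 convention.

## Uncaging quantification

`response_amplitude()` subtracts a pre-pulse baseline (default 20 ms),
finds the extremum within a post-pulse search window (default 50 ms) and
averages the 2-ms window centred on it, per trial, returning the trial
mean. Search and baseline windows are configuration, not constants,
because they are conventions rather than physical parameters. uEPSPs are
positive deflections; uEPSCs negative with magnitude reported (the `sign`
flag). No failure-trial rejection is applied before averaging. The
spine-length/head-width ratio applies a 0.2-µm minimum length for spines
without a discernible neck; `split_neck_groups()` partitions at the
sample median (sort-and-halve), with an explicit threshold override — the
delimitation rule is not standardised, so it is exposed rather than
hidden.

## The synthetic-data generator

`generate_region()` emulates the *summary structure* of regional spine
populations:

* **Head volumes** are lognormal (right skew and 10–200-fold ranges make
  a Gaussian untenable); the configured log-location/shape are
  moment-matched to the published mean ± SD.
* **Neck length and diameter** are Gaussians truncated at a 0.02-µm
  floor, with location/scale solved numerically so the *truncated*
  distribution has the configured mean and SD (naive truncation biases
  the mean upward by several SE at $n = 10^4$). Neck length and diameter
  are generated independently — neck length is a poor predictor of neck
  diameter, and no within-region covariance is published.
* **PSD areas** follow a linear-in-head-volume relation plus Gaussian
  noise, floored at a small positive value; only correlation
  coefficients, not a functional form, are available, and a
  linear-plus-noise model reproduces any target rank correlation with one
  noise knob.
* **Diameter scaling**: each dendrite draws its diameter uniformly over
  the configured range; spine density is correlated with diameter via a
  Gaussian copula (`density_diameter_cor`), and a per-spine PSD offset
  proportional to the diameter deviation (`psd_density_slope`) reproduces
  the increase of PSD-area density with dendritic diameter.
* **Spine counts** are `round(density × length)` — deterministic given
  the per-dendrite density, so that a noise-free configuration yields an
  exactly predictable dataset; across-dendrite variability enters through
  the configured density SD.
* **ER-containing spines** are selected at the configured rate and their
  head volumes multiplied by `er_size_boost`, after which *all* volumes
  are rescaled by $1/(1 - p + pb)$ so the marginal mean stays at the
  configured lognormal mean while ER+/ER− means differ by the boost
  factor. The marginal SD is therefore slightly above the configured
  lognormal SD whenever the boost is active — the price of imposing a
  mean-preserving mixture.
* **Axon coupling**: per-spine Bernoulli candidates are paired within
  their dendrite; odd candidate counts are rounded to an even number in a
  mean-preserving way, so the realised coupled fraction is an unbiased
  binomial-like draw. Coupled pairs have their PSD areas shrunk towards
  the pair mean (reduced intra-pair variance).
* **Flags** (filopodia, stubby, perforated, branched) are Bernoulli at
  the configured per-region rates; filopodia carry no PSD and no axon;
  branched spines appear as paired records sharing a branch-group ID.

One seed drives everything; identical seed and configuration reproduce
the dataset byte for byte, and the caller's RNG state is restored.

What the generator does **not** emulate: segmentation/annotation error,
spatial clustering beyond ER adjacency, 3-D geometry, the true joint
distribution of all morphometric variables (only the published marginals
and selected correlations), or region differences beyond the configured
summaries. Passing tests therefore validate the *pipeline arithmetic and
statistical machinery* on data with the published summary structure, not
the biology of any particular reconstruction.

## Problem sizes and reproducibility

Defaults were chosen so a full test run stays in the minutes range on one
CPU: parameter-recovery checks use ~10^4 spines (220 dendrites); the MI
tuning curve uses 20 frequencies × 10 trials × 100-s simulations (the
acceptance script uses 50-s simulations and 5 trials for its summary);
the LIF equivalence check uses 100 one-second instances at $dt = 0.01$
ms; statistical calibration uses 1000 null simulations; the uncaging
comparison regenerates 200 cohorts of 2 × 35 spines. `run_pipeline()`
derives per-stage sub-seeds from the global seed by stable hashing of the
stage name, so inserting a stage does not reshuffle the randomness of the
others and reruns are byte-identical.

## Known limitations

* The plug-in MI estimator is biased upward at short durations; curves
  from different durations should not be compared directly.
* The refractory implementation is an absolute lockout; a raised-threshold
  ("relative" in the adaptation sense) variant would need an extra state
  variable and is left as an extension point.
* The generator's per-region presets encode published summary tables; any
  quantity that depends on unpublished microstructure (e.g. true spatial
  spine arrangements) is outside what synthetic data can validate.
* Dendrite-level statistics assume each dendrite is an independent
  sampling unit, as in the source analyses.
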