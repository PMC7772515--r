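# spinesim

Dendritic spine morphometry, a two-layer model neuron, and mutual-information
analysis of dendrite-to-soma information transfer.

## What this package is for

Excitatory synapses sit on dendritic spines, and two anatomical quantities
proxy their strength: the postsynaptic density (PSD) area, which scales with
receptor content, and the spine neck length, which attenuates the potential
reaching the dendrite. Serial-section volume EM (FIB/SEM) yields
reconstruction tables — one row per spine with head volume, neck dimensions
and PSD area, grouped into dendritic segments. `spinesim` provides, for
users analysing such tables or modelling their consequences:

* **Morphometry** (`head_volume()`, `psd_area()`, `spine_density()`,
  `psd_area_density()`, `neck_length_density()`, `dendrite_psd_neck_ratio()`,
  `axon_coupled_fraction()`, `er_hotspot_fraction()`, `fold_range()`,
  `cv()`, `morphometry_summary()`): the standard measurement formulas, e.g.
  head volume as total contour cross-section × section thickness, PSD-area
  density as Σ PSD area / dendrite length, and the dendrite-level ratio
  Σ PSD / Σ neck (an anatomical index of total synaptic strength per unit
  dendrite).
* **A statistics workflow** (`choose_and_correlate()`,
  `choose_and_compare()`): Shapiro–Wilk-gated selection between
  Pearson/Spearman and t/Mann–Whitney/ANOVA/Kruskal–Wallis, with
  Bonferroni-corrected pairwise comparisons.
* **A two-layer model neuron** (`two_layer_neuron()`, `run_simulation()`):
  20 leaky integrate-and-fire dendritic branches, each with 250 Poisson
  synapses carrying lognormal weights W_ij,

      dV_j/dt = −(V_j − V_rest)/τ_dend + Σ_i Σ_k W_ij δ(t − t_ijk),
      spike and reset when V_j > θ,

  whose dendritic spikes drive a somatic integrator (+20 mV each,
  τ_soma = 20 ms). Integration is event-driven and exact, with a fixed-step
  reference integrator (`lif_grid_reference()`) as an independent
  cross-check.
* **Information transfer** (`binarize()`, `mutual_information()`,
  `tuning_curve()`): plug-in mutual information between 5-ms-binned,
  binarized input and spike sequences, MI = Σ p(x,y) log₂ p(x,y)/(p(x)p(y)),
  swept over input frequency, for homogeneous (case 1) vs
  branch-heterogeneous (case 2) synaptic-strength scenarios.
* **Uncaging analysis** (`response_amplitude()`, `lw_ratio()`,
  `split_neck_groups()`, `normalized_intensity()`): uEPSP/uEPSC amplitude
  from repeated traces (baseline-subtracted, 2-ms window at the post-pulse
  extremum, averaged over 5–10 trials) and the length/width grouping rules.
* **A synthetic-data generator** (`region_config()`, `region_presets()`,
  `generate_region()`, `generate_contour_stack()`,
  `generate_uncaging_traces()`): seeded datasets whose summary statistics
  match configured regional values (lognormal head volumes, PSD–volume
  coupling, diameter scaling, axon-coupled pairs, ER occupancy), so the
  whole pipeline is testable without imaging data.
* **Orchestration** (`run_pipeline()`): generate → measure → test →
  simulate → MI → uncaging with one global seed and byte-identical reruns.

## Worked example

```r
library(spinesim)

ds <- generate_region(region_presets("CA1_PSR"), n_dendrites = 30, seed = 1)
ds
#> Synthetic spine dataset: CA1_PSR (seed 1)
#>   30 dendrites, 1448 spines
#>   head volume 0.050 +/- 0.056 um^3; density 3.18 spines/um

ms <- morphometry_summary(ds)
round(ms$per_region[, c("spine_density_mean", "head_volume_mean",
                        "psd_area_density_mean", "axon_coupled_fraction")], 3)
#>   spine_density_mean head_volume_mean psd_area_density_mean axon_coupled_fraction
#> 1              3.087             0.05                  0.21                 0.042
```

The per-dendrite spine density (3.09 spines/µm), mean head volume
(0.05 µm³), PSD-area density (0.21 µm²/µm) and axon-coupled fraction
(4.2 %) recover the configured CA1 proximal-stratum-radiatum preset. Head
volume and PSD area are coupled:

```r
choose_and_correlate(ds$spines$head_volume_um3, ds$spines$psd_area_um2)
#> Spearman rank correlation: statistic = 0.6549, p = 4.348e-178 ***
#>   direction: positive
```

(The Shapiro–Wilk gate routes these heavily skewed volumes to Spearman.)
Simulating the two-layer neuron and sweeping the input frequency:

```r
p <- two_layer_neuron(duration = 5e4)   # 20 branches x 250 synapses, 50 s
curve <- tuning_curve(p, case = 1, freqs = c(0.5, 1, 2, 4, 8),
                      n_trials = 3, seed = 1)
curve
#> MI tuning curve (case 1, 5 frequencies, 3 trials)
#>  freq_hz mi_dend_mean mi_dend_sd mi_soma_mean mi_soma_sd
#>      0.5    1.535e-02  6.839e-04    1.082e-03  1.529e-04
#>      1.0    2.408e-02  1.541e-03    1.518e-03  1.802e-04
#>      2.0    2.250e-02  1.291e-03    6.624e-05  1.729e-05
#>      4.0    3.363e-03  4.396e-04    8.892e-05  1.139e-05
#>      8.0    6.289e-05  6.518e-06    8.540e-05  5.161e-05
#>   dendritic MI peaks at 1 Hz
```

Information transfer from the strongest synapse to its branch rises with
input frequency, peaks at an interior frequency (here 1 Hz: a moderate rate
of weak background inputs helps the strongest synapse trigger dendritic
spikes) and collapses at high rates, where background-driven spiking
decouples the output from the input. `plot(curve)` draws both curves with
SD whiskers.

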