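# Shared fixtures built in code.

# A dendrite record in the shape morphometry functions accept.
make_dendrite <- function(psd, neck, length_um, pos = seq_along(psd),
                          er = rep(FALSE, length(psd)),
                          filo = rep(FALSE, length(psd))) {
  list(spines = data.frame(position_um = pos, psd_area_um2 = psd,
                           neck_length_um = neck, er = er,
                           filopodium = filo),
       length_um = length_um)
}

# A minimal hand-built simulation result for the MI helpers.
make_sim <- function(strongest_input, dendritic, somatic, duration) {
  structure(list(
    dendritic = lapply(dendritic, spike_train, duration = duration),
    somatic = spike_train(somatic, duration),
    strongest_input = lapply(strongest_input, spike_train,
                             duration = duration),
    strongest_synapse = seq_along(dendritic),
    weights = NULL, params = NULL, case = 1L
  ), class = "two_layer_sim")
}

# A noiseless region config for degenerate-case tests.
noiseless_config <- function(density = 2, length_um = 10) {
  region_config(
    region_label = "degenerate",
    spine_density_mean = density, spine_density_sd = 0,
    head_volume_logmu = log(0.05), head_volume_logsigma = 0,
    neck_length_mean = 0.5, neck_length_sd = 0,
    neck_diameter_mean = 0.2, neck_diameter_sd = 0,
    psd_per_volume_slope = 1.2, psd_noise_sd = 0,
    diameter_range = c(0.6, 0.6),
    dendrite_length_range = c(length_um, length_um)
  )
}

ca1_psr_config <- function() region_presets("CA1_PSR")
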