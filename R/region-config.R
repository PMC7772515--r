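#' Lognormal parameters from a target mean and SD
#'
#' Moment-matches a lognormal distribution to a target arithmetic mean and
#' standard deviation, returning the log-scale location and shape.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic standard deviation (> 0).
#' @return Named list with `meanlog` and `sdlog`.
#' @examples
#' p <- lognormal_params(0.05, 0.045)
#' exp(p$meanlog + p$sdlog^2 / 2)  # 0.05
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), mean > 0, sd > 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Region configuration for the synthetic spine generator
#'
#' Bundles the distributional parameters that describe the spine population
#' of one brain region: spine density along the dendrite, lognormal head
#' volume, truncated-Gaussian neck length and diameter, the linear
#' PSD-area/head-volume coupling, the diameter scaling of PSD content, the
#' axon-coupling rate and the endoplasmic-reticulum (ER) occupancy.
#'
#' @param region_label Region name (free text).
#' @param spine_density_mean,spine_density_sd Spine density across dendrites,
#'   spines/um. The SD must be smaller than the mean.
#' @param head_volume_logmu,head_volume_logsigma Log-scale location and shape
#'   of the lognormal head-volume distribution (log-um^3).
#' @param neck_length_mean,neck_length_sd Neck length, um (truncated Gaussian).
#' @param neck_diameter_mean,neck_diameter_sd Neck diameter, um (truncated
#'   Gaussian).
#' @param psd_per_volume_slope Slope of the linear PSD-area vs head-volume
#'   relation, um^2/um^3.
#' @param psd_noise_sd SD of the Gaussian noise added to PSD areas, um^2.
#'   Together with the slope this sets the PSD/head-volume correlation.
#' @param diameter_range Length-2 range of dendritic diameters, um; diameters
#'   are drawn uniformly over it.
#' @param psd_density_slope Increase of PSD-area density per um of dendritic
#'   diameter (um^2/um per um), realised as a per-spine PSD offset.
#' @param axon_coupling_rate Fraction of spines sharing an axon with another
#'   spine on the same dendrite, in [0, 1].
#' @param er_fraction Fraction of spines containing ER, in [0, 1].
#' @param er_size_boost Multiplicative head-volume factor for ER+ spines.
#'   The generator renormalises so the marginal head-volume mean is
#'   unchanged; the boost controls the ER+/ER- mean ratio.
#' @param dendrite_length_range Length-2 range of dendrite lengths, um.
#' @param density_diameter_cor Correlation between a dendrite's diameter and
#'   its spine density, in [-1, 1].
#' @param filopodia_rate,stubby_rate,perforated_rate,branched_rate Per-spine
#'   probabilities of the corresponding morphological flags, in [0, 1].
#' @param neck_floor,psd_floor Positive truncation floors for neck
#'   dimensions (um) and PSD areas (um^2).
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `region_config` (a validated named list).
#' @seealso [region_presets()], [generate_region()]
#' @export
region_config <- function(region_label,
                          spine_density_mean, spine_density_sd,
                          head_volume_logmu, head_volume_logsigma,
                          neck_length_mean, neck_length_sd,
                          neck_diameter_mean, neck_diameter_sd,
                          psd_per_volume_slope, psd_noise_sd,
                          diameter_range, psd_density_slope = 0,
                          axon_coupling_rate = 0, er_fraction = 0,
                          er_size_boost = 1,
                          dendrite_length_range = c(5, 25),
                          density_diameter_cor = 0,
                          filopodia_rate = 0, stubby_rate = 0,
                          perforated_rate = 0, branched_rate = 0,
                          neck_floor = 0.02, psd_floor = 0.005,
                          seed = 1L) {
  cfg <- list(
    region_label = as.character(region_label),
    spine_density_mean = spine_density_mean,
    spine_density_sd = spine_density_sd,
    head_volume_logmu = head_volume_logmu,
    head_volume_logsigma = head_volume_logsigma,
    neck_length_mean = neck_length_mean,
    neck_length_sd = neck_length_sd,
    neck_diameter_mean = neck_diameter_mean,
    neck_diameter_sd = neck_diameter_sd,
    psd_per_volume_slope = psd_per_volume_slope,
    psd_noise_sd = psd_noise_sd,
    diameter_range = diameter_range,
    psd_density_slope = psd_density_slope,
    axon_coupling_rate = axon_coupling_rate,
    er_fraction = er_fraction,
    er_size_boost = er_size_boost,
    dendrite_length_range = dendrite_length_range,
    density_diameter_cor = density_diameter_cor,
    filopodia_rate = filopodia_rate,
    stubby_rate = stubby_rate,
    perforated_rate = perforated_rate,
    branched_rate = branched_rate,
    neck_floor = neck_floor,
    psd_floor = psd_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "region_config"
  validate_region_config(cfg)
}

validate_region_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid region_config field '%s': %s", field, msg),
         call. = FALSE)
  num1 <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      fail(field, "must be a single finite number")
    x
  }
  for (f in c("axon_coupling_rate", "er_fraction", "filopodia_rate",
              "stubby_rate", "perforated_rate", "branched_rate",
              "density_diameter_cor")) {
    x <- num1(f)
    lo <- if (f == "density_diameter_cor") -1 else 0
    if (x < lo || x > 1) fail(f, sprintf("must lie in [%d, 1]", lo))
  }
  for (f in c("spine_density_mean", "neck_length_mean", "neck_diameter_mean",
              "psd_per_volume_slope", "head_volume_logsigma",
              "er_size_boost", "neck_floor", "psd_floor")) {
    if (num1(f) <= 0 && f != "head_volume_logsigma")
      fail(f, "must be > 0")
    if (f == "head_volume_logsigma" && cfg[[f]] < 0)
      fail(f, "must be >= 0")
  }
  for (f in c("spine_density_sd", "neck_length_sd", "neck_diameter_sd",
              "psd_noise_sd", "psd_density_slope")) {
    if (num1(f) < 0) fail(f, "must be >= 0")
  }
  num1("head_volume_logmu")
  if (cfg$spine_density_sd >= cfg$spine_density_mean)
    fail("spine_density_sd", "must be smaller than spine_density_mean")
  for (f in c("diameter_range", "dendrite_length_range")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        any(x <= 0) || x[1] > x[2])
      fail(f, "must be two positive increasing values")
  }
  cfg
}

#' @export
print.region_config <- function(x, ...) {
  hv <- exp(x$head_volume_logmu + x$head_volume_logsigma^2 / 2)
  cat("Region configuration:", x$region_label, "\n")
  cat(sprintf("  spine density  %.2f +/- %.2f spines/um\n",
              x$spine_density_mean, x$spine_density_sd))
  cat(sprintf("  head volume    mean %.3f um^3 (lognormal %.3f, %.3f)\n",
              hv, x$head_volume_logmu, x$head_volume_logsigma))
  cat(sprintf("  neck           %.2f +/- %.2f um long, %.2f +/- %.2f um wide\n",
              x$neck_length_mean, x$neck_length_sd,
              x$neck_diameter_mean, x$neck_diameter_sd))
  cat(sprintf("  axon coupling  %.1f%%   ER fraction %.1f%%\n",
              100 * x$axon_coupling_rate, 100 * x$er_fraction))
  invisible(x)
}

#' Region presets mirroring the study's per-region summary tables
#'
#' Ready-made [region_config()] objects for the six sampled regions:
#' hippocampal CA1 proximal stratum radiatum (`CA1_PSR`), CA1 stratum
#' lacunosum-moleculare (`CA1_SLM`), layer 1 somatosensory cortex
#' (`cortex`), dorsolateral striatum (`striatum`) and the cerebellar
#' molecular layer (`CB`). Densities, head-volume, neck and ER statistics
#' follow the published per-region means and SDs; the PSD/head-volume slope
#' is set so the mean PSD area per spine reproduces the reported PSD-area
#' density at the reported spine density.
#'
#' @param region Optional region name; if omitted, the full named list is
#'   returned.
#' @return A `region_config`, or a named list of them.
#' @export
region_presets <- function(region = NULL) {
  mk <- function(label, dens, hv, nl, nd, psd_dens, coupling, er, boost,
                 diam, diam_cor, psd_slope_diam, flags, len = c(5, 25)) {
    hvp <- lognormal_params(hv[1], hv[2])
    region_config(
      region_label = label,
      spine_density_mean = dens[1], spine_density_sd = dens[2],
      head_volume_logmu = hvp$meanlog, head_volume_logsigma = hvp$sdlog,
      neck_length_mean = nl[1], neck_length_sd = nl[2],
      neck_diameter_mean = nd[1], neck_diameter_sd = nd[2],
      psd_per_volume_slope = (psd_dens / dens[1]) / hv[1],
      psd_noise_sd = 0.6 * hv[2] * (psd_dens / dens[1]) / hv[1],
      diameter_range = diam,
      psd_density_slope = psd_slope_diam,
      axon_coupling_rate = coupling, er_fraction = er, er_size_boost = boost,
      dendrite_length_range = len,
      density_diameter_cor = diam_cor,
      filopodia_rate = flags[1], perforated_rate = flags[2],
      stubby_rate = flags[3], branched_rate = flags[4]
    )
  }
  presets <- list(
    CA1_PSR = mk("CA1_PSR", c(3.04, 0.825), c(0.05, 0.045), c(0.46, 0.246),
                 c(0.20, 0.087), 0.18, 0.047, 0.136, 2.75,
                 c(0.38, 0.80), 0.71, 0.41,
                 c(0.0178, 0.0272, 0.0290, 0.0797)),
    CA1_SLM = mk("CA1_SLM", c(0.75, 0.360), c(0.12, 0.086), c(0.49, 0.289),
                 c(0.25, 0.127), 0.08, 0.257, 0.157, 1.64,
                 c(0.39, 0.77), 0, 0,
                 c(0, 0.50, 0.0143, 0)),
    cortex = mk("cortex", c(1.14, 0.723), c(0.08, 0.101), c(1.09, 0.561),
                c(0.23, 0.121), 0.11, 0.054, 0.403, 3.5,
                c(0.41, 0.89), 0.43, 0.19,
                c(0.0307, 0.0860, 0.0226, 0.0950)),
    striatum = mk("striatum", c(1.94, 0.621), c(0.07, 0.109), c(1.12, 0.556),
                  c(0.26, 0.104), 0.15, 0.089, 0.551, 4.5,
                  c(0.60, 0.94), 0, 0,
                  c(0.0584, 0.0447, 0, 0.1340)),
    CB = mk("CB", c(7.10, 1.693), c(0.13, 0.035), c(0.74, 0.300),
            c(0.27, 0.054), 0.77, 0.261, 1.0, 1.0,
            c(0.63, 1.41), 0.47, 0.74,
            c(0.0419, 0, 0, 0.1262), len = c(5, 20))
  )
  if (is.null(region)) return(presets)
  if (!region %in% names(presets))
    stop("unknown region preset: ", region, call. = FALSE)
  presets[[region]]
}
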