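# Synthetic-data generation: morphometry tables, contour stacks and
# uncaging trace sets with the statistical structure of the study's
# per-region summaries, so the whole pipeline is testable without EM data.

# Run `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Moments of a normal(mu, s) truncated below at `floor`.
truncnorm_moments <- function(mu, s, floor) {
  a <- (floor - mu) / s
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + s * lam
  v <- s^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Location/scale of the floored normal whose *truncated* moments equal the
# configured mean/sd, so floor truncation does not bias parameter recovery.
# Negligible truncation mass short-circuits to the plain parameters.
truncnorm_match <- function(mean, sd, floor) {
  if (stats::pnorm(floor, mean, sd) < 1e-6)
    return(c(mu = mean, s = sd))
  fit <- stats::optim(c(mean, sd), function(p) {
    if (p[2] <= 0) return(1e6)
    mm <- truncnorm_moments(p[1], p[2], floor)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], s = fit$par[2])
}

# Gaussian truncated below at `floor`, moment-matched to (mean, sd);
# sd = 0 collapses to the mean.
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  p <- truncnorm_match(mean, sd, floor)
  plo <- stats::pnorm(floor, p[["mu"]], p[["s"]])
  stats::qnorm(stats::runif(n, plo, 1), p[["mu"]], p[["s"]])
}

# Round a candidate count to an even value without changing its expectation
# (1 -> {0, 2} with prob 1/2; odd k >= 3 -> k -/+ 1 with prob 1/2).
even_count <- function(k) {
  if (k %% 2L == 0L) return(k)
  if (k == 1L) return(if (stats::runif(1) < 0.5) 0L else 2L)
  k + sample(c(-1L, 1L), 1L)
}

#' Generate a synthetic spine dataset for one region
#'
#' Draws dendrites and spines whose summary statistics match a
#' [region_config()]: per-dendrite spine counts follow the configured
#' density (optionally correlated with dendritic diameter), head volumes are
#' lognormal, PSD areas follow a linear-in-head-volume relation with
#' Gaussian noise plus a diameter-dependent offset, ER-containing spines are
#' upweighted in head volume at a fixed marginal mean, and a configured
#' fraction of spines share presynaptic axons within a dendrite
#' (axon-coupled spines, with reduced intra-pair PSD variance).
#'
#' @param config A [region_config()].
#' @param n_dendrites Number of dendritic segments to generate (>= 1).
#' @param seed Integer seed; defaults to the seed stored in `config`. The
#'   caller's RNG state is preserved.
#' @return A `spine_dataset`: list with `dendrites` and `spines` data frames
#'   (column schema documented in [write_spine_dataset()]), the `config` and
#'   the `seed`.
#' @examples
#' ds <- generate_region(region_presets("CA1_PSR"), n_dendrites = 5)
#' head(ds$spines)
#' @export
generate_region <- function(config, n_dendrites, seed = config$seed) {
  if (!inherits(config, "region_config"))
    stop("config must be a region_config object", call. = FALSE)
  validate_region_config(config)
  if (!is.numeric(n_dendrites) || length(n_dendrites) != 1L || n_dendrites < 1)
    stop("n_dendrites must be a single value >= 1", call. = FALSE)
  n_dendrites <- as.integer(n_dendrites)

  with_seed(seed, {
    cfg <- config
    len <- stats::runif(n_dendrites, cfg$dendrite_length_range[1],
                        cfg$dendrite_length_range[2])
    diam <- stats::runif(n_dendrites, cfg$diameter_range[1],
                         cfg$diameter_range[2])
    # density correlated with diameter through a Gaussian copula on z-scores
    z_diam <- if (diff(cfg$diameter_range) > 0)
      (diam - mean(cfg$diameter_range)) / (diff(cfg$diameter_range) / sqrt(12))
    else rep(0, n_dendrites)
    rho <- cfg$density_diameter_cor
    z <- rho * z_diam + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_dendrites)
    density <- pmax(0.05, cfg$spine_density_mean + cfg$spine_density_sd * z)
    counts <- as.integer(round(density * len))

    dendrites <- data.frame(
      dendrite_id = sprintf("d%03d", seq_len(n_dendrites)),
      region = cfg$region_label,
      length_um = len,
      diameter_um = diam,
      stringsAsFactors = FALSE
    )

    diam_mid <- mean(cfg$diameter_range)
    per_spine_psd_offset <- cfg$psd_density_slope * (diam - diam_mid) /
      cfg$spine_density_mean

    spine_list <- vector("list", n_dendrites)
    for (d in seq_len(n_dendrites)) {
      n <- counts[d]
      if (n == 0L) next
      pos <- sort(stats::runif(n, 0, len[d]))
      filo <- stats::runif(n) < cfg$filopodia_rate
      stubby <- !filo & stats::runif(n) < cfg$stubby_rate
      perf <- !filo & stats::runif(n) < cfg$perforated_rate
      er <- !filo & stats::runif(n) < cfg$er_fraction

      v <- stats::rlnorm(n, cfg$head_volume_logmu, cfg$head_volume_logsigma)
      v[er] <- v[er] * cfg$er_size_boost
      # keep the marginal mean at exp(logmu + logsigma^2/2)
      v <- v / (1 - cfg$er_fraction + cfg$er_fraction * cfg$er_size_boost)

      nl <- rtruncnorm_floor(n, cfg$neck_length_mean, cfg$neck_length_sd,
                             cfg$neck_floor)
      nl[stubby] <- 0
      nd <- rtruncnorm_floor(n, cfg$neck_diameter_mean, cfg$neck_diameter_sd,
                             cfg$neck_floor)

      psd <- cfg$psd_per_volume_slope * v + per_spine_psd_offset[d] +
        stats::rnorm(n, 0, cfg$psd_noise_sd)
      psd <- pmax(cfg$psd_floor, psd)
      psd[filo] <- 0

      # branched spines: pairs of records (two heads) sharing a branch group
      branch_group <- rep(NA_character_, n)
      branched <- rep(FALSE, n)
      n_br <- even_count(sum(!filo & stats::runif(n) < cfg$branched_rate))
      cand_br <- which(!filo)
      if (n_br >= 2L && length(cand_br) >= 2L) {
        n_br <- min(n_br, 2L * (length(cand_br) %/% 2L))
        heads <- sample(cand_br, n_br)
        branched[heads] <- TRUE
        branch_group[heads] <- sprintf("d%03d_b%d", d,
                                       rep(seq_len(n_br / 2L), each = 2L))
      }

      # axon coupling: even number of same-dendrite spines paired per axon
      axon <- sprintf("d%03d_ax%03d", d, seq_len(n))
      cand <- which(!filo)
      k <- even_count(sum(stats::runif(length(cand)) < cfg$axon_coupling_rate))
      k <- min(k, 2L * (length(cand) %/% 2L))
      if (k >= 2L) {
        coupled <- sample(cand, k)
        pair_of <- rep(seq_len(k / 2L), each = 2L)
        axon[coupled] <- sprintf("d%03d_shared%03d", d, pair_of)
        # axon-coupled spines have similar PSD areas: shrink towards pair mean
        for (p in seq_len(k / 2L)) {
          idx <- coupled[pair_of == p]
          psd[idx] <- pmax(cfg$psd_floor,
                           mean(psd[idx]) +
                             stats::rnorm(2, 0, cfg$psd_noise_sd / 3))
        }
      }
      axon[filo] <- NA_character_

      spine_list[[d]] <- data.frame(
        dendrite_id = dendrites$dendrite_id[d],
        spine_id = sprintf("d%03d_s%03d", d, seq_len(n)),
        position_um = pos,
        head_volume_um3 = v,
        neck_length_um = nl,
        neck_diameter_um = nd,
        psd_area_um2 = psd,
        perforated = perf,
        branched = branched,
        er = er,
        filopodium = filo,
        stubby = stubby,
        branch_group = branch_group,
        axon_id = axon,
        stringsAsFactors = FALSE
      )
    }
    spines <- do.call(rbind, spine_list)
    if (is.null(spines)) spines <- empty_spine_table()
    rownames(spines) <- NULL

    structure(list(dendrites = dendrites, spines = spines,
                   config = cfg, seed = seed),
              class = "spine_dataset")
  })
}

empty_spine_table <- function() {
  data.frame(dendrite_id = character(), spine_id = character(),
             position_um = numeric(), head_volume_um3 = numeric(),
             neck_length_um = numeric(), neck_diameter_um = numeric(),
             psd_area_um2 = numeric(), perforated = logical(),
             branched = logical(), er = logical(), filopodium = logical(),
             stubby = logical(), branch_group = character(),
             axon_id = character(), stringsAsFactors = FALSE)
}

#' @export
print.spine_dataset <- function(x, ...) {
  cat(sprintf("Synthetic spine dataset: %s (seed %d)\n",
              x$config$region_label, x$seed))
  cat(sprintf("  %d dendrites, %d spines\n",
              nrow(x$dendrites), nrow(x$spines)))
  if (nrow(x$spines) > 0)
    cat(sprintf("  head volume %.3f +/- %.3f um^3; density %.2f spines/um\n",
                mean(x$spines$head_volume_um3), stats::sd(x$spines$head_volume_um3),
                nrow(x$spines) / sum(x$dendrites$length_um)))
  invisible(x)
}

#' Generate a contour stack reproducing a target head volume
#'
#' Produces per-section cross-sectional areas whose sum times the section
#' thickness equals `target_volume`, emulating the serial-section
#' representation from which head volumes are measured. Optionally also
#' produces PSD trace lengths reproducing a target PSD area.
#'
#' @param target_volume Head volume, um^3 (> 0).
#' @param thickness Section thickness, um (> 0; the study's z-step is
#'   0.04 um).
#' @param n_sections Number of sections (>= 1).
#' @param target_psd_area Optional PSD area, um^2; if given, per-section PSD
#'   trace lengths summing to `target_psd_area / thickness` are included.
#' @return A [contour_stack()].
#' @examples
#' st <- generate_contour_stack(0.04, 0.04, 2)
#' sum(st$areas)  # 1.0
#' @export
generate_contour_stack <- function(target_volume, thickness, n_sections,
                                   target_psd_area = NULL) {
  if (!is.numeric(target_volume) || target_volume <= 0)
    stop("target_volume must be > 0", call. = FALSE)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0", call. = FALSE)
  if (!is.numeric(n_sections) || n_sections < 1)
    stop("n_sections must be >= 1", call. = FALSE)
  n <- as.integer(n_sections)
  u <- stats::runif(n, 0.5, 1.5)
  areas <- u / sum(u) * target_volume / thickness
  psd <- NULL
  if (!is.null(target_psd_area)) {
    if (target_psd_area < 0) stop("target_psd_area must be >= 0", call. = FALSE)
    w <- stats::runif(n, 0.5, 1.5)
    psd <- w / sum(w) * target_psd_area / thickness
  }
  contour_stack(areas = areas, thickness = thickness, psd_trace_lengths = psd)
}

#' Generate a synthetic uncaging trace set
#'
#' Builds repeated voltage (or current) traces around an uncaging pulse:
#' baseline plus a difference-of-exponentials transient that peaks at the
#' programmed amplitude, plus Gaussian noise. Used as a fixture for
#' [response_amplitude()].
#'
#' @param amplitude Programmed peak amplitude, mV (>= 0).
#' @param n_trials Number of test-pulse repetitions (the study uses 5-10).
#' @param rise_ms,decay_ms Rise and decay time constants, ms; `decay_ms`
#'   must exceed `rise_ms`.
#' @param noise_sd Gaussian noise SD, mV.
#' @param pulse_time_ms Uncaging pulse time within the record, ms.
#' @param duration_ms Record length, ms.
#' @param dt_ms Sampling interval, ms.
#' @param sign `+1` for positive deflections (uEPSPs), `-1` for negative
#'   (uEPSCs; magnitudes are reported by the analysis).
#' @return An `uncaging_traces` object: list with `time_ms`, `traces`
#'   (trials x samples matrix), `pulse_time_ms`, `sign` and the kinetic
#'   parameters.
#' @examples
#' tr <- generate_uncaging_traces(1.0, n_trials = 5, noise_sd = 0)
#' max(tr$traces)  # 1.0
#' @export
generate_uncaging_traces <- function(amplitude, n_trials, rise_ms = 2,
                                     decay_ms = 20, noise_sd = 0.1,
                                     pulse_time_ms = 20, duration_ms = 120,
                                     dt_ms = 0.1, sign = 1) {
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0", call. = FALSE)
  if (decay_ms <= rise_ms)
    stop("decay_ms must exceed rise_ms (ill-defined kinetics)", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (pulse_time_ms <= 0 || pulse_time_ms >= duration_ms)
    stop("pulse_time_ms must lie inside the record", call. = FALSE)

  time_ms <- seq(0, duration_ms, by = dt_ms)
  s <- time_ms - pulse_time_ms
  g <- ifelse(s >= 0, exp(-s / decay_ms) - exp(-s / rise_ms), 0)
  t_peak <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  g_max <- exp(-t_peak / decay_ms) - exp(-t_peak / rise_ms)
  transient <- sign * amplitude * g / g_max
  n_trials <- as.integer(n_trials)
  traces <- matrix(rep(transient, n_trials), nrow = n_trials, byrow = TRUE)
  if (noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(length(traces), 0, noise_sd),
                              nrow = n_trials)
  structure(list(time_ms = time_ms, traces = traces,
                 pulse_time_ms = pulse_time_ms, sign = sign,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 peak_time_ms = pulse_time_ms + t_peak),
            class = "uncaging_traces")
}

#' @export
print.uncaging_traces <- function(x, ...) {
  cat(sprintf("Uncaging trace set: %d trials x %d samples, pulse at %g ms\n",
              nrow(x$traces), ncol(x$traces), x$pulse_time_ms))
  invisible(x)
}

#' Write / read a spine dataset as plain CSV tables
#'
#' `write_spine_dataset()` writes `<prefix>_spines.csv`,
#' `<prefix>_dendrites.csv` and `<prefix>_config.json`;
#' `read_spine_dataset()` reads them back. The spine table columns are
#' `dendrite_id, spine_id, position_um, head_volume_um3, neck_length_um,
#' neck_diameter_um, psd_area_um2, perforated, branched, er, filopodium,
#' stubby, branch_group, axon_id`; the dendrite table columns are
#' `dendrite_id, region, length_um, diameter_um`.
#'
#' @param dataset A `spine_dataset`.
#' @param prefix Path prefix for the output files.
#' @return `write_spine_dataset()` returns the written paths invisibly;
#'   `read_spine_dataset()` returns a `spine_dataset`.
#' @export
write_spine_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "spine_dataset"))
  paths <- c(spines = paste0(prefix, "_spines.csv"),
             dendrites = paste0(prefix, "_dendrites.csv"),
             config = paste0(prefix, "_config.json"))
  utils::write.csv(dataset$spines, paths[["spines"]], row.names = FALSE)
  utils::write.csv(dataset$dendrites, paths[["dendrites"]], row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(generator_seed = dataset$seed)),
                       paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_spine_dataset
#' @export
read_spine_dataset <- function(prefix) {
  spines <- utils::read.csv(paste0(prefix, "_spines.csv"),
                            stringsAsFactors = FALSE)
  dendrites <- utils::read.csv(paste0(prefix, "_dendrites.csv"),
                               stringsAsFactors = FALSE)
  cfg_path <- paste0(prefix, "_config.json")
  cfg <- NULL
  seed <- NA_integer_
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    seed <- raw$generator_seed
    raw$generator_seed <- NULL
    cfg <- structure(raw, class = "region_config")
  }
  structure(list(dendrites = dendrites, spines = spines,
                 config = cfg, seed = seed),
            class = "spine_dataset")
}
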