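# Quantification of uncaging-evoked responses and the spine-geometry
# grouping / fluorescence-normalization rules used with them.

#' Uncaging response amplitude
#'
#' Per trial: the mean over `baseline_ms` before the pulse is subtracted,
#' the extremum within `search_ms` after the pulse is located, and the
#' 2-ms window centred on it is averaged. The returned amplitude is the
#' mean across trials (5-10 test pulses in the study), as a positive
#' magnitude (the trace set's `sign` field marks uEPSPs as positive and
#' uEPSCs as negative deflections).
#'
#' @param traces An `uncaging_traces` object (see
#'   [generate_uncaging_traces()]), or a list with `time_ms`, `traces`
#'   matrix (trials x samples), `pulse_time_ms` and optional `sign`.
#' @param search_ms Post-pulse search window, ms (default 50).
#' @param baseline_ms Pre-pulse baseline window, ms (default 20).
#' @param window_ms Averaging window centred on the extremum, ms (default 2).
#' @return Mean amplitude across trials (mV or pA magnitude), with
#'   per-trial values in attribute `per_trial`.
#' @examples
#' tr <- generate_uncaging_traces(1, n_trials = 3, noise_sd = 0)
#' response_amplitude(tr)
#' @export
response_amplitude <- function(traces, search_ms = 50, baseline_ms = 20,
                               window_ms = 2) {
  time <- traces$time_ms
  m <- traces$traces
  pulse <- traces$pulse_time_ms
  sgn <- if (is.null(traces$sign)) 1 else traces$sign
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (nrow(m) < 1L) stop("need at least one trial", call. = FALSE)
  if (pulse + search_ms > max(time))
    stop("uncaging pulse too close to the end of the record for a ",
         search_ms, "-ms search window", call. = FALSE)
  base_idx <- which(time >= pulse - baseline_ms & time < pulse)
  if (!length(base_idx)) stop("no samples in the baseline window", call. = FALSE)
  search_idx <- which(time > pulse & time <= pulse + search_ms)

  per_trial <- apply(m, 1, function(v) {
    v <- v - mean(v[base_idx])
    ext <- if (sgn >= 0) search_idx[which.max(v[search_idx])]
    else search_idx[which.min(v[search_idx])]
    win <- which(abs(time - time[ext]) <= window_ms / 2)
    sgn * mean(v[win])
  })
  structure(mean(per_trial), per_trial = per_trial)
}

#' Spine length to head width ratio
#'
#' The spine length (tip of the head to the base of the neck) divided by
#' the head width at its widest transect. Spines with no discernible neck
#' are assigned a minimum length of 0.2 um before taking the ratio.
#'
#' @param spine_length Spine length(s), um.
#' @param head_width Head width(s), um (> 0).
#' @param min_length Minimum length applied before the ratio (default 0.2).
#' @return Ratio(s), dimensionless.
#' @examples
#' lw_ratio(0.1, 0.5)  # 0.4 (floor applied)
#' @export
lw_ratio <- function(spine_length, head_width, min_length = 0.2) {
  if (any(!is.finite(head_width)) || any(head_width <= 0))
    stop("head width must be positive", call. = FALSE)
  if (any(spine_length < 0)) stop("spine length must be >= 0", call. = FALSE)
  pmax(spine_length, min_length) / head_width
}

#' Split spines into long- and short-neck groups
#'
#' Partitions spines by their length/width ratio at the sample median
#' (sort-and-halve: the lower half of the sorted ratios forms the short
#' group). The threshold can be overridden.
#'
#' @param ratios Numeric length/width ratios (n >= 2), e.g. from
#'   [lw_ratio()].
#' @param threshold Optional explicit cut; ratios <= threshold are short.
#' @return List with integer index vectors `short` and `long`, the group
#'   ratio values `short_ratios` / `long_ratios`, and the `threshold` used.
#' @examples
#' split_neck_groups(c(0.9, 1.0, 1.6, 1.7))$short  # 1 2
#' @export
split_neck_groups <- function(ratios, threshold = NULL) {
  n <- length(ratios)
  if (n < 2L) stop("need at least 2 spines", call. = FALSE)
  if (any(!is.finite(ratios))) stop("ratios must be finite", call. = FALSE)
  if (length(unique(ratios)) == 1L)
    stop("degenerate split: all ratios identical", call. = FALSE)
  if (is.null(threshold)) {
    ord <- order(ratios)
    short <- sort(ord[seq_len(n %/% 2)])
    long <- sort(ord[(n %/% 2 + 1):n])
    threshold <- stats::median(ratios)
  } else {
    short <- which(ratios <= threshold)
    long <- which(ratios > threshold)
    if (!length(short) || !length(long))
      stop("threshold leaves one group empty", call. = FALSE)
  }
  list(short = short, long = long,
       short_ratios = ratios[short], long_ratios = ratios[long],
       threshold = threshold)
}

#' Normalized spine fluorescence intensity
#'
#' Spine intensity divided by the mean of four background-subtracted
#' regions of interest on the dendritic shaft.
#'
#' @param spine_intensity Integrated spine fluorescence (arbitrary units).
#' @param shaft_roi_intensities Exactly four positive shaft ROI values.
#' @return Dimensionless normalized intensity.
#' @examples
#' normalized_intensity(50, c(100, 100, 100, 100))  # 0.5
#' @export
normalized_intensity <- function(spine_intensity, shaft_roi_intensities) {
  if (length(shaft_roi_intensities) != 4L)
    stop("exactly four shaft ROI intensities are required", call. = FALSE)
  if (any(!is.finite(shaft_roi_intensities)) ||
      mean(shaft_roi_intensities) <= 0)
    stop("shaft ROI mean must be positive after background subtraction",
         call. = FALSE)
  spine_intensity / mean(shaft_roi_intensities)
}

#' Generate and measure a synthetic uncaging cohort
#'
#' Draws per-spine true amplitudes from a floored Gaussian (uEPSP
#' magnitudes are positive), synthesises a trace set for each spine with
#' [generate_uncaging_traces()] and quantifies it with
#' [response_amplitude()]. Used to emulate the study's long-neck vs
#' short-neck uEPSP cohorts.
#'
#' @param n_spines Number of spines.
#' @param amp_mean,amp_sd Gaussian amplitude mean and SD, mV.
#' @param amp_floor Positive floor on true amplitudes, mV (default 0.05).
#' @param n_trials Test pulses per spine (default 5).
#' @param noise_sd Trace noise SD, mV (default 0.1).
#' @param dt_ms Sampling interval, ms (default 0.5).
#' @param ... Further arguments to [generate_uncaging_traces()].
#' @return Data frame with `true_amplitude` and measured `amplitude` per
#'   spine.
#' @export
measure_uncaging_cohort <- function(n_spines, amp_mean, amp_sd,
                                    amp_floor = 0.05, n_trials = 5,
                                    noise_sd = 0.1, dt_ms = 0.5, ...) {
  true_amp <- pmax(amp_floor, stats::rnorm(n_spines, amp_mean, amp_sd))
  measured <- vapply(true_amp, function(a) {
    as.numeric(response_amplitude(
      generate_uncaging_traces(a, n_trials = n_trials, noise_sd = noise_sd,
                               dt_ms = dt_ms, ...)))
  }, numeric(1))
  data.frame(true_amplitude = true_amp, amplitude = measured)
}
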