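# Mutual information between binned, binarized input and spike sequences,
# and MI tuning curves over input frequency.

#' Bin and binarize a spike train
#'
#' Divides the record into `bin_ms` bins anchored at t = 0 and sets bit k
#' to 1 iff at least one event falls in `[k*bin, (k+1)*bin)`. A trailing
#' partial bin is discarded.
#'
#' @param train A [spike_train()] (or numeric event vector with a
#'   `duration` attribute / explicit `duration`).
#' @param bin_ms Bin width, ms (study value 5).
#' @param duration Record duration, ms, if not carried by `train`.
#' @return Integer vector of 0/1 bits with attribute `bin_ms`.
#' @examples
#' binarize(spike_train(c(1, 12), 20), bin_ms = 5)  # 1 0 1 0
#' @export
binarize <- function(train, bin_ms = 5, duration = attr(train, "duration")) {
  if (is.null(duration)) stop("duration is required", call. = FALSE)
  if (bin_ms <= 0) stop("bin width must be > 0", call. = FALSE)
  n_bins <- floor(duration / bin_ms)
  bits <- integer(n_bins)
  if (length(train)) {
    idx <- floor(as.numeric(train) / bin_ms) + 1L
    idx <- idx[idx >= 1L & idx <= n_bins]
    bits[unique(idx)] <- 1L
  }
  structure(bits, bin_ms = bin_ms)
}

#' Mutual information of two binary sequences
#'
#' Plug-in (maximum-likelihood) mutual information of two equal-length
#' binary sequences over their empirical 2x2 joint distribution,
#' MI = sum p(x, y) log2 p(x, y) / (p(x) p(y)), with the 0 log 0 = 0
#' convention. Reported in bits per bin.
#'
#' @param x,y Equal-length 0/1 vectors (e.g. from [binarize()]).
#' @return MI in bits (>= 0, symmetric in its arguments).
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("sequences must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("sequences must be non-empty", call. = FALSE)
  n <- length(x)
  x <- as.integer(x != 0L)
  y <- as.integer(y != 0L)
  n11 <- sum(x & y)
  n10 <- sum(x) - n11
  n01 <- sum(y) - n11
  n00 <- n - n11 - n10 - n01
  joint <- c(n00, n01, n10, n11) / n
  px <- c(n00 + n01, n10 + n11) / n   # x = 0, 1
  py <- c(n00 + n10, n01 + n11) / n   # y = 0, 1
  prod_marg <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / prod_marg[nz]))
}

#' Per-branch information transfer
#'
#' `mi_vs_dendrite()` computes, for every branch, the mutual information
#' between the binarized input sequence of the branch's strongest synapse
#' and the branch's binarized dendritic spike sequence over the same time
#' bins. `mi_vs_soma()` uses the somatic spike sequence instead.
#'
#' @param result A `two_layer_sim` from [run_simulation()].
#' @param bin_ms Bin width, ms (default 5).
#' @return Numeric vector of per-branch MI values (bits per bin).
#' @export
mi_vs_dendrite <- function(result, bin_ms = 5) {
  stopifnot(inherits(result, "two_layer_sim"))
  vapply(seq_along(result$dendritic), function(j) {
    mutual_information(binarize(result$strongest_input[[j]], bin_ms),
                       binarize(result$dendritic[[j]], bin_ms))
  }, numeric(1))
}

#' @rdname mi_vs_dendrite
#' @export
mi_vs_soma <- function(result, bin_ms = 5) {
  stopifnot(inherits(result, "two_layer_sim"))
  soma_bits <- binarize(result$somatic, bin_ms)
  vapply(seq_along(result$strongest_input), function(j) {
    mutual_information(binarize(result$strongest_input[[j]], bin_ms),
                       soma_bits)
  }, numeric(1))
}

#' MI tuning curve over input frequency
#'
#' Runs repeated simulations across a grid of synaptic input frequencies
#' and summarises the branch-averaged dendritic and somatic MI per
#' frequency (mean and SD across trials).
#'
#' @param params A [two_layer_neuron()]; its `input_freq` field is swept.
#' @param case Weight scenario (1 or 2), see [run_simulation()].
#' @param freqs Input frequencies, Hz. The study explores 0.5-10 Hz;
#'   values outside produce a warning.
#' @param n_trials Simulations per frequency.
#' @param seed Optional base seed (trial t at frequency index f uses
#'   `seed + 1000 * f + t`).
#' @param bin_ms MI bin width, ms.
#' @return An `mi_curve`: data frame with columns `freq_hz, mi_dend_mean,
#'   mi_dend_sd, mi_soma_mean, mi_soma_sd`, with per-trial matrices in
#'   attributes `trials_dend` / `trials_soma` and the parameter snapshot in
#'   attribute `params`.
#' @export
tuning_curve <- function(params, case = 1, freqs = seq(0.5, 10, by = 0.5),
                         n_trials = 10, seed = NULL, bin_ms = 5) {
  stopifnot(inherits(params, "two_layer_neuron"))
  if (any(freqs < 0.5 | freqs > 10))
    warning("frequencies outside the 0.5-10 Hz study range", call. = FALSE)
  md <- ms <- matrix(NA_real_, n_trials, length(freqs))
  for (f in seq_along(freqs)) {
    p <- params
    p$input_freq <- freqs[f]
    for (t in seq_len(n_trials)) {
      sim <- run_simulation(p, case = case,
                            seed = if (is.null(seed)) NULL
                            else seed + 1000L * f + t)
      md[t, f] <- mean(mi_vs_dendrite(sim, bin_ms))
      ms[t, f] <- mean(mi_vs_soma(sim, bin_ms))
    }
  }
  curve <- data.frame(freq_hz = freqs,
                      mi_dend_mean = colMeans(md),
                      mi_dend_sd = apply(md, 2, stats::sd),
                      mi_soma_mean = colMeans(ms),
                      mi_soma_sd = apply(ms, 2, stats::sd))
  structure(curve, trials_dend = md, trials_soma = ms, params = params,
            case = case, class = c("mi_curve", "data.frame"))
}

#' @export
print.mi_curve <- function(x, ...) {
  cat(sprintf("MI tuning curve (case %d, %d frequencies, %d trials)\n",
              attr(x, "case"), nrow(x), nrow(attr(x, "trials_dend"))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  fopt <- x$freq_hz[which.max(x$mi_dend_mean)]
  cat(sprintf("  dendritic MI peaks at %g Hz\n", fopt))
  invisible(x)
}

#' Plot an MI tuning curve
#'
#' Branch-averaged dendritic and somatic MI against input frequency, with
#' +/- 1 SD whiskers across trials.
#'
#' @param x An `mi_curve` from [tuning_curve()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mi_curve <- function(x, ...) {
  graphics::matplot(x$freq_hz, cbind(x$mi_dend_mean, x$mi_soma_mean),
                    type = "b", pch = c(16, 17), lty = 1,
                    col = c("black", "firebrick"),
                    xlab = "input frequency (Hz)", ylab = "MI (bits/bin)",
                    ...)
  graphics::arrows(x$freq_hz, x$mi_dend_mean - x$mi_dend_sd,
                   x$freq_hz, x$mi_dend_mean + x$mi_dend_sd,
                   length = 0.02, angle = 90, code = 3, col = "black")
  graphics::arrows(x$freq_hz, x$mi_soma_mean - x$mi_soma_sd,
                   x$freq_hz, x$mi_soma_mean + x$mi_soma_sd,
                   length = 0.02, angle = 90, code = 3, col = "firebrick")
  graphics::legend("topright", c("dendritic", "somatic"), pch = c(16, 17),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
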