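# Two-layer model neuron: Poisson synaptic input with lognormal weights
# drives leaky integrate-and-fire dendritic branches whose spikes drive a
# somatic leaky integrator.

#' Spike train
#'
#' A sorted vector of event times on `[0, duration)` ms.
#'
#' @param times Event times, ms.
#' @param duration Record duration, ms.
#' @return An object of class `spike_train` (numeric vector with a
#'   `duration` attribute).
#' @export
spike_train <- function(times, duration) {
  times <- sort(as.numeric(times))
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("event times must lie in [0, duration)", call. = FALSE)
  structure(times, duration = duration, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d events over %g ms (rate %.3g Hz)\n",
              length(x), attr(x, "duration"),
              1000 * length(x) / attr(x, "duration")))
  invisible(x)
}

#' Two-layer model neuron parameters
#'
#' Builds the parameter set of the two-layer neuron: `n_branch` dendritic
#' branches, each receiving `n_syn` synapses with lognormal weights, feed a
#' somatic integrator. Both layers are leaky integrate-and-fire units with
#' instantaneous (Dirac-delta) synaptic jumps, strict `V > theta` threshold,
#' reset on spiking and a 20-ms refractory lockout during which membrane
#' updates continue but no spike can be emitted.
#'
#' Synaptic weights are lognormal on a volt scale (location `mu_e`, shape
#' `sigma_e`, so the median weight is `exp(mu_e)` V) and converted to mV by
#' `w_scale` inside the integrator; with `mu_e = -6` the median weight is
#' about 2.5 mV.
#'
#' @param n_branch Number of dendritic branches (default 20).
#' @param n_syn Synapses per branch (default 250).
#' @param v_rest Resting potential, mV (default -75).
#' @param v_reset_dend,v_reset_soma Reset potentials, mV (defaults -75 and
#'   -80).
#' @param theta Spike threshold, mV, both layers (default -40).
#' @param tau_dend,tau_soma Membrane time constants, ms (defaults 10 and 20).
#' @param w_soma Somatic depolarisation per dendritic spike, mV (default 20).
#' @param refractory Refractory period, ms (default 20).
#' @param mu_e,sigma_e Location and shape of the lognormal weight
#'   distribution (log-volts; defaults -6 and 1).
#' @param branch_mu_sd SD of the per-branch location parameter in the
#'   heterogeneous scenario (case 2), where each branch's `mu_e` is drawn
#'   from N(`mu_e`, `branch_mu_sd`) (default 0.4).
#' @param input_freq Poisson input frequency per synapse, Hz (study range
#'   0.5-10; default 4).
#' @param duration Simulated time, ms (default 100000 = 100 s).
#' @param w_scale Conversion from weight units (volts) to mV (default 1000).
#' @return An object of class `two_layer_neuron`.
#' @seealso [run_simulation()], [simulate.two_layer_neuron()],
#'   [tuning_curve()]
#' @export
two_layer_neuron <- function(n_branch = 20L, n_syn = 250L,
                             v_rest = -75, v_reset_dend = -75,
                             v_reset_soma = -80, theta = -40,
                             tau_dend = 10, tau_soma = 20, w_soma = 20,
                             refractory = 20, mu_e = -6, sigma_e = 1,
                             branch_mu_sd = 0.4, input_freq = 4,
                             duration = 1e5, w_scale = 1000) {
  p <- list(n_branch = as.integer(n_branch), n_syn = as.integer(n_syn),
            v_rest = v_rest, v_reset_dend = v_reset_dend,
            v_reset_soma = v_reset_soma, theta = theta,
            tau_dend = tau_dend, tau_soma = tau_soma, w_soma = w_soma,
            refractory = refractory, mu_e = mu_e, sigma_e = sigma_e,
            branch_mu_sd = branch_mu_sd, input_freq = input_freq,
            duration = duration, w_scale = w_scale)
  if (p$theta <= p$v_rest) stop("theta must exceed v_rest", call. = FALSE)
  if (p$tau_dend <= 0 || p$tau_soma <= 0)
    stop("time constants must be > 0", call. = FALSE)
  if (p$refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  if (p$input_freq <= 0) stop("input_freq must be > 0", call. = FALSE)
  if (p$sigma_e < 0) stop("sigma_e must be >= 0", call. = FALSE)
  if (p$n_branch < 1 || p$n_syn < 1)
    stop("n_branch and n_syn must be >= 1", call. = FALSE)
  if (p$duration <= 0) stop("duration must be > 0", call. = FALSE)
  class(p) <- "two_layer_neuron"
  p
}

#' @export
print.two_layer_neuron <- function(x, ...) {
  cat("Two-layer model neuron\n")
  cat(sprintf("  %d branches x %d synapses; weights lognormal(mu_e = %g, sigma_e = %g)\n",
              x$n_branch, x$n_syn, x$mu_e, x$sigma_e))
  cat(sprintf("  dendrite: tau %g ms, reset %g mV; soma: tau %g ms, reset %g mV, W %g mV\n",
              x$tau_dend, x$v_reset_dend, x$tau_soma, x$v_reset_soma,
              x$w_soma))
  cat(sprintf("  threshold %g mV, rest %g mV, refractory %g ms\n",
              x$theta, x$v_rest, x$refractory))
  cat(sprintf("  input %g Hz per synapse, duration %g s\n",
              x$input_freq, x$duration / 1000))
  invisible(x)
}

#' Sample a lognormal synaptic weight matrix
#'
#' Draws `n_syn` x `n_branch` weights with log-weights Normal(`mu_e`,
#' `sigma_e`). In the branch-heterogeneous scenario (case 2) each branch
#' first draws its own location parameter from N(`mu_e`, `branch_mu_sd`).
#'
#' @param mu_e,sigma_e Lognormal location and shape (log-volts).
#' @param n_syn,n_branch Matrix dimensions.
#' @param branch_mu_sd SD of per-branch locations; 0 (default) reproduces
#'   the homogeneous case.
#' @return Numeric matrix (synapses in rows, branches in columns), weights
#'   in volts; the per-branch locations are attached as attribute
#'   `branch_mu`.
#' @examples
#' w <- sample_weights(-6, 0, 5, 2)
#' all(w == exp(-6))
#' @export
sample_weights <- function(mu_e, sigma_e, n_syn, n_branch,
                           branch_mu_sd = 0) {
  if (sigma_e < 0 || branch_mu_sd < 0)
    stop("shape parameters must be >= 0", call. = FALSE)
  mu_b <- if (branch_mu_sd > 0) stats::rnorm(n_branch, mu_e, branch_mu_sd)
  else rep(mu_e, n_branch)
  w <- matrix(stats::rlnorm(n_syn * n_branch,
                            meanlog = rep(mu_b, each = n_syn),
                            sdlog = sigma_e),
              nrow = n_syn, ncol = n_branch)
  attr(w, "branch_mu") <- mu_b
  w
}

#' Homogeneous Poisson input train
#'
#' @param rate_hz Event rate, Hz (>= 0).
#' @param duration_ms Duration, ms.
#' @return A [spike_train()].
#' @export
generate_poisson_inputs <- function(rate_hz, duration_ms) {
  if (rate_hz < 0) stop("rate must be >= 0", call. = FALSE)
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  spike_train(stats::runif(n, 0, duration_ms), duration_ms)
}

# Merge per-synapse trains into an event stream sorted by time (ties by
# ascending synapse index) with per-event weights in mV.
merge_events <- function(input_trains, weights_mv) {
  if (!length(input_trains))
    return(list(times = numeric(0), weights = numeric(0)))
  lens <- lengths(input_trains)
  times <- unlist(input_trains, use.names = FALSE)
  syn <- rep(seq_along(input_trains), lens)
  ord <- order(times, syn)
  list(times = times[ord], weights = weights_mv[syn[ord]])
}

#' Simulate one dendritic branch
#'
#' Event-driven exact integration of the branch membrane: between events
#' the potential relaxes exponentially towards rest; each input adds its
#' synaptic weight instantaneously; on a strict threshold crossing a
#' dendritic spike is emitted and the membrane resets, with a refractory
#' lockout during which inputs still depolarise the membrane but cannot
#' trigger spikes.
#'
#' @param params A [two_layer_neuron()].
#' @param weights_col Weights of the branch's synapses (volts), one per
#'   input train.
#' @param input_trains List of [spike_train()]s, one per synapse.
#' @return A [spike_train()] of dendritic spike times.
#' @export
simulate_branch <- function(params, weights_col, input_trains) {
  stopifnot(inherits(params, "two_layer_neuron"))
  if (length(weights_col) != length(input_trains))
    stop("one input train per synapse is required", call. = FALSE)
  ev <- merge_events(input_trains, weights_col * params$w_scale)
  spikes <- lif_event_cpp(ev$times, ev$weights, params$v_rest,
                          params$v_reset_dend, params$theta,
                          params$tau_dend, params$refractory,
                          params$duration)
  spike_train(spikes, params$duration)
}

#' Simulate the soma from dendritic spike trains
#'
#' Every dendritic spike depolarises the somatic integrator by `w_soma` mV;
#' integration, threshold, reset and refractory behave as in
#' [simulate_branch()] with the somatic constants.
#'
#' @param params A [two_layer_neuron()].
#' @param dendritic_trains List of `n_branch` [spike_train()]s.
#' @return A [spike_train()] of somatic spike times.
#' @export
simulate_soma <- function(params, dendritic_trains) {
  stopifnot(inherits(params, "two_layer_neuron"))
  if (length(dendritic_trains) != params$n_branch)
    stop("need one dendritic train per branch", call. = FALSE)
  times <- sort(unlist(dendritic_trains, use.names = FALSE))
  spikes <- lif_event_cpp(times, rep(params$w_soma, length(times)),
                          params$v_rest, params$v_reset_soma, params$theta,
                          params$tau_soma, params$refractory,
                          params$duration)
  spike_train(spikes, params$duration)
}

#' Run a full two-layer simulation
#'
#' Samples the weight matrix (case 1: a single lognormal for all branches;
#' case 2: per-branch location parameters drawn from N(`mu_e`,
#' `branch_mu_sd`)), generates Poisson input trains for every synapse,
#' simulates all dendritic branches and the soma, and records the index
#' and input train of the strongest synapse of each branch.
#'
#' @param params A [two_layer_neuron()].
#' @param case `1` (homogeneous synaptic strength across branches) or `2`
#'   (branch-heterogeneous locations).
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param store_inputs Keep all per-branch input event streams (times and
#'   synapse indices). Off by default: only the strongest-synapse trains
#'   needed for information analysis are retained.
#' @return A `two_layer_sim`: list with `dendritic` (list of spike trains),
#'   `somatic` (spike train), `weights` (volts), `strongest_synapse`
#'   (index per branch), `strongest_input` (list of spike trains), `params`,
#'   `case` and optionally `inputs`.
#' @examples
#' p <- two_layer_neuron(n_branch = 2, n_syn = 20, duration = 2000)
#' sim <- run_simulation(p, case = 1, seed = 1)
#' sim$somatic
#' @export
run_simulation <- function(params, case = 1, seed = NULL,
                           store_inputs = FALSE) {
  stopifnot(inherits(params, "two_layer_neuron"))
  if (!case %in% c(1, 2)) stop("case must be 1 or 2", call. = FALSE)
  with_seed(seed, {
    w <- sample_weights(params$mu_e, params$sigma_e, params$n_syn,
                        params$n_branch,
                        branch_mu_sd = if (case == 2) params$branch_mu_sd else 0)
    rate_ms <- params$input_freq / 1000
    dendritic <- vector("list", params$n_branch)
    strongest_input <- vector("list", params$n_branch)
    imax <- integer(params$n_branch)
    inputs <- if (store_inputs) vector("list", params$n_branch)
    for (j in seq_len(params$n_branch)) {
      counts <- stats::rpois(params$n_syn, rate_ms * params$duration)
      times <- stats::runif(sum(counts), 0, params$duration)
      syn <- rep.int(seq_len(params$n_syn), counts)
      ord <- order(times, syn)
      times <- times[ord]; syn <- syn[ord]
      spikes <- lif_event_cpp(times, w[syn, j] * params$w_scale,
                              params$v_rest, params$v_reset_dend,
                              params$theta, params$tau_dend,
                              params$refractory, params$duration)
      dendritic[[j]] <- spike_train(spikes, params$duration)
      imax[j] <- which.max(w[, j])
      strongest_input[[j]] <- spike_train(times[syn == imax[j]],
                                          params$duration)
      if (store_inputs) inputs[[j]] <- list(times = times, synapse = syn)
    }
    somatic <- simulate_soma(params, dendritic)
    structure(list(dendritic = dendritic, somatic = somatic, weights = w,
                   strongest_synapse = imax,
                   strongest_input = strongest_input,
                   inputs = inputs, params = params, case = case,
                   seed = seed),
              class = "two_layer_sim")
  })
}

#' @export
print.two_layer_sim <- function(x, ...) {
  dcounts <- lengths(x$dendritic)
  cat(sprintf("Two-layer simulation (case %d, %g s, %g Hz input)\n",
              x$case, x$params$duration / 1000, x$params$input_freq))
  cat(sprintf("  dendritic spikes/branch: median %g (range %d-%d)\n",
              stats::median(dcounts), min(dcounts), max(dcounts)))
  cat(sprintf("  somatic spikes: %d (%.3g Hz)\n", length(x$somatic),
              1000 * length(x$somatic) / x$params$duration))
  invisible(x)
}

#' Simulate method for the two-layer neuron
#'
#' Runs `nsim` independent simulations of a [two_layer_neuron()].
#'
#' @param object A [two_layer_neuron()].
#' @param nsim Number of simulations.
#' @param seed Optional base seed; replicate `i` uses `seed + i - 1`.
#' @param case Weight scenario, as in [run_simulation()].
#' @param ... Unused.
#' @return A list of `two_layer_sim` objects (a single object when
#'   `nsim = 1`).
#' @export
simulate.two_layer_neuron <- function(object, nsim = 1, seed = NULL,
                                      case = 1, ...) {
  sims <- lapply(seq_len(nsim), function(i) {
    run_simulation(object, case = case,
                   seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Fixed-step reference integrator
#'
#' Fine-step grid integration of the same leaky integrate-and-fire
#' dynamics, used as an independent cross-check of the event-driven path:
#' the membrane is advanced on a regular `dt` grid (exact per-step decay),
#' events are applied at the end of the step containing them and the
#' threshold is examined at every grid point, so spike times agree with the
#' event-driven integrator to within one step.
#'
#' @param times,weights_mv Event times (ms, sorted) and per-event jumps (mV).
#' @param v_rest,v_reset,theta,tau,refractory,duration LIF constants as in
#'   [two_layer_neuron()].
#' @param dt Step size, ms (default 0.01).
#' @return Numeric vector of spike times (grid times).
#' @export
lif_grid_reference <- function(times, weights_mv, v_rest = -75,
                               v_reset = -75, theta = -40, tau = 10,
                               refractory = 20, duration = 1000,
                               dt = 0.01) {
  lif_grid_cpp(times, weights_mv, v_rest, v_reset, theta, tau, refractory,
               duration, dt)
}

#' Event-driven LIF on a raw event stream
#'
#' Low-level access to the event-driven integrator used by
#' [simulate_branch()] and [simulate_soma()]: takes explicit event times
#' and jump sizes rather than per-synapse trains.
#'
#' @inheritParams lif_grid_reference
#' @return Numeric vector of spike times, ms.
#' @export
lif_event_driven <- function(times, weights_mv, v_rest = -75, v_reset = -75,
                             theta = -40, tau = 10, refractory = 20,
                             duration = 1000) {
  ord <- order(times)
  lif_event_cpp(times[ord], weights_mv[ord], v_rest, v_reset, theta, tau,
                refractory, duration)
}
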