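# Two-layer LIF model: weight sampling, Poisson inputs, closed-form
# integration checks, refractory contract and the grid-integrator oracle.

test_that("lognormal weights have the configured location and shape", {
  w0 <- sample_weights(-6, 0, 5, 3)
  expect_true(all(w0 == exp(-6)))
  expect_equal(dim(w0), c(5L, 3L))

  set.seed(30)
  w <- sample_weights(-6, 1, 1000, 100)     # 1e5 draws
  expect_lt(abs(median(w) - exp(-6)) / exp(-6), 0.01)
  lw <- log(sample_weights(-6, 1, 100, 100))
  ks <- ks.test((lw - mean(lw)) / sd(lw), "pnorm")
  expect_gt(ks$p.value, 0.01)

  # case 2: per-branch locations spread as configured
  wb <- sample_weights(-6, 1, 200, 400, branch_mu_sd = 0.4)
  mus <- attr(wb, "branch_mu")
  expect_equal(mean(mus), -6, tolerance = 4 * 0.4 / sqrt(400))
  expect_equal(sd(mus), 0.4, tolerance = 0.1)
})

test_that("Poisson input trains have the right rate and exponential gaps", {
  expect_length(generate_poisson_inputs(0, 1000), 0)
  set.seed(31)
  counts <- replicate(500, length(generate_poisson_inputs(10, 1e5)))
  se <- sqrt(1000 / 500)
  expect_lt(abs(mean(counts) - 1000) / se, 3)
  # inter-event intervals at n ~ 1e4
  train <- generate_poisson_inputs(10, 1e6)
  ks <- suppressWarnings(ks.test(diff(train), "pexp", 10 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("branch integration matches single- and two-event closed forms", {
  p <- two_layer_neuron()
  mk_train <- function(t) spike_train(t, 1000)
  # +40 mV at t = 5 crosses threshold from rest (-35 > -40): spike, reset
  sp <- simulate_branch(p, weights_col = 0.040,
                        input_trains = list(mk_train(5)))
  expect_equal(as.numeric(sp), 5)
  # two +10 mV inputs 5 ms apart: V(5) = -75 + 10 exp(-0.5) + 10 = -58.9 mV
  sp2 <- simulate_branch(p, weights_col = c(0.010, 0.010),
                         input_trains = list(mk_train(0), mk_train(5)))
  expect_length(sp2, 0)
  # exactness at the threshold: second jump crosses iff it exceeds the
  # closed-form margin theta - (v_rest + 20 exp(-1.3))
  margin <- -40 - (-75 + 20 * exp(-13 / 10))
  for (eps in c(1e-9, -1e-9)) {
    w2 <- (margin + eps) / 1000
    spm <- simulate_branch(p, weights_col = c(0.020, w2),
                           input_trains = list(mk_train(0), mk_train(13)))
    if (eps > 0) expect_equal(as.numeric(spm), 13) else expect_length(spm, 0)
  }
  expect_length(simulate_branch(p, numeric(0), list()), 0)
  expect_error(simulate_branch(p, 0.01, list(mk_train(1), mk_train(2))),
               "one input train per synapse")
})

test_that("somatic integration needs coincident dendritic spikes", {
  p <- two_layer_neuron(n_branch = 2)
  p$duration <- 1000
  # two simultaneous dendritic spikes: -75 + 2 * 20 = -35 > -40
  soma <- simulate_soma(p, list(spike_train(10, 1000), spike_train(10, 1000)))
  expect_equal(as.numeric(soma), 10)
  # a single +20 mV dendritic spike stays subthreshold (-55 mV)
  soma1 <- simulate_soma(p, list(spike_train(10, 1000),
                                 spike_train(numeric(0), 1000)))
  expect_length(soma1, 0)
  soma0 <- simulate_soma(p, list(spike_train(numeric(0), 1000),
                                 spike_train(numeric(0), 1000)))
  expect_length(soma0, 0)
  expect_error(simulate_soma(p, list(spike_train(1, 1000))), "per branch")
})

test_that("full simulations are deterministic and case 2 collapses to case 1", {
  p <- two_layer_neuron(n_branch = 4, n_syn = 50, duration = 5000)
  s1 <- run_simulation(p, case = 1, seed = 7)
  s2 <- run_simulation(p, case = 1, seed = 7)
  expect_identical(s1$weights, s2$weights)
  expect_identical(lapply(s1$dendritic, as.numeric),
                   lapply(s2$dendritic, as.numeric))
  expect_identical(as.numeric(s1$somatic), as.numeric(s2$somatic))
  # with branch_mu_sd = 0 the heterogeneous scenario equals case 1
  p0 <- p; p0$branch_mu_sd <- 0
  c1 <- run_simulation(p0, case = 1, seed = 11)
  c2 <- run_simulation(p0, case = 2, seed = 11)
  expect_identical(c1$weights, c2$weights)
  expect_identical(as.numeric(c1$somatic), as.numeric(c2$somatic))
  # strongest synapse is the argmax of each branch's weights
  expect_equal(s1$strongest_synapse, apply(s1$weights, 2, which.max))
})

test_that("every emitted train respects the 20-ms refractory contract", {
  p <- two_layer_neuron(n_branch = 5, n_syn = 100, input_freq = 8,
                        duration = 20000)
  sim <- run_simulation(p, case = 1, seed = 17)
  for (tr in c(sim$dendritic, list(sim$somatic))) {
    if (length(tr) >= 2)
      expect_gte(min(diff(as.numeric(tr))), 20 - 1e-9)
  }
  expect_gt(sum(lengths(sim$dendritic)), 0)  # non-vacuous
})

test_that("doubling all weights never lowers the dendritic spike count", {
  set.seed(33)
  p <- two_layer_neuron()
  p$duration <- 10000
  for (i in 1:10) {
    n_syn <- 20
    w <- rlnorm(n_syn, -6, 1)
    trains <- lapply(seq_len(n_syn), function(s)
      generate_poisson_inputs(5, p$duration))
    n1 <- length(simulate_branch(p, w, trains))
    n2 <- length(simulate_branch(p, 2 * w, trains))
    expect_gte(n2, n1)
  }
})

test_that("zero-input relaxation follows the exponential closed form to 1e-9", {
  # a subthreshold perturbation decays as v_rest + V0 exp(-t / tau);
  # a probe jump at time t crosses threshold iff it exceeds the closed-form
  # margin, bracketed at +/- 1e-9 mV
  for (t_probe in c(3, 17, 42)) {
    margin <- -40 - (-75 + 30 * exp(-t_probe / 10))
    for (eps in c(1e-9, -1e-9)) {
      sp <- lif_event_driven(c(0, t_probe), c(30, margin + eps),
                             tau = 10, duration = 100)
      expect_equal(length(sp), as.integer(eps > 0))
    }
  }
})

test_that("event-driven and fine-step grid integration agree spike for spike", {
  set.seed(34)
  dt <- 0.01
  for (i in 1:10) {
    n_ev <- 150
    # distinct event times on the integration grid, so threshold checks
    # happen at the same instants in both integrators
    times <- sort(sample.int(99999, n_ev)) * dt
    w <- rlnorm(n_ev, log(8), 0.75)
    ev <- lif_event_driven(times, w, duration = 1000)
    gr <- lif_grid_reference(times, w, duration = 1000, dt = dt)
    expect_equal(length(ev), length(gr))
    if (length(ev))
      expect_lt(max(abs(ev - gr)), dt + 1e-9)
  }
})
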