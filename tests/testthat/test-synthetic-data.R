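# Synthetic-data generator: degenerate cases, parameter recovery,
# determinism and the induced correlation structure.

test_that("noiseless configuration yields exactly density * length identical spines", {
  ds <- generate_region(noiseless_config(density = 2, length_um = 10),
                        n_dendrites = 1, seed = 1)
  expect_equal(nrow(ds$spines), 20L)
  expect_equal(length(unique(ds$spines$head_volume_um3)), 1L)
  expect_equal(length(unique(ds$spines$psd_area_um2)), 1L)
  expect_equal(unique(ds$spines$neck_length_um), 0.5)
  expect_true(all(ds$spines$position_um >= 0 &
                    ds$spines$position_um <= 10))
  expect_true(!is.unsorted(ds$spines$position_um))
})

test_that("identical seed and config reproduce the dataset exactly", {
  cfg <- ca1_psr_config()
  ds1 <- generate_region(cfg, 10, seed = 42)
  ds2 <- generate_region(cfg, 10, seed = 42)
  expect_identical(ds1$spines, ds2$spines)
  expect_identical(ds1$dendrites, ds2$dendrites)
  ds3 <- generate_region(cfg, 10, seed = 43)
  expect_false(identical(ds1$spines, ds3$spines))
})

test_that("generator recovers configured head-volume mean within 3 SE", {
  # lognormal configured to mean 0.05, SD 0.045 um^3
  ds <- generate_region(ca1_psr_config(), n_dendrites = 250, seed = 7)
  v <- ds$spines$head_volume_um3
  expect_gt(length(v), 5000)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.05), 3 * se)
})

test_that("distributional fields are recovered within 4 SE at n ~ 10^4", {
  cfg <- ca1_psr_config()
  cfg$er_size_boost <- 1  # pure lognormal marginal (ER boost checked below)
  ds <- generate_region(cfg, n_dendrites = 220, seed = 99)
  sp <- ds$spines
  n <- nrow(sp)
  expect_gt(n, 8000)

  lv <- log(sp$head_volume_um3)
  expect_lt(abs(mean(lv) - cfg$head_volume_logmu), 4 * sd(lv) / sqrt(n))
  expect_lt(abs(sd(lv) - cfg$head_volume_logsigma),
            4 * cfg$head_volume_logsigma / sqrt(2 * n))

  nl <- sp$neck_length_um[!sp$stubby]
  expect_lt(abs(mean(nl) - cfg$neck_length_mean), 4 * sd(nl) / sqrt(length(nl)))
  nd <- sp$neck_diameter_um
  expect_lt(abs(mean(nd) - cfg$neck_diameter_mean), 4 * sd(nd) / sqrt(n))

  dens <- sapply(split(sp$dendrite_id, sp$dendrite_id), length) /
    ds$dendrites$length_um[match(names(table(sp$dendrite_id)),
                                 ds$dendrites$dendrite_id)]
  expect_lt(abs(mean(dens) - cfg$spine_density_mean),
            4 * sd(dens) / sqrt(length(dens)))

  er <- mean(sp$er)
  expect_lt(abs(er - cfg$er_fraction),
            4 * sqrt(cfg$er_fraction * (1 - cfg$er_fraction) / n))
})

test_that("ER upweighting preserves the marginal head-volume mean", {
  cfg <- ca1_psr_config()  # er_size_boost 2.75
  ds <- generate_region(cfg, n_dendrites = 220, seed = 5)
  v <- ds$spines$head_volume_um3
  target <- exp(cfg$head_volume_logmu + cfg$head_volume_logsigma^2 / 2)
  expect_lt(abs(mean(v) - target), 4 * sd(v) / sqrt(length(v)))
  ratio <- mean(v[ds$spines$er]) / mean(v[!ds$spines$er])
  expect_gt(ratio, 1.5)  # ER+ spines are substantially larger
})

test_that("realized axon-coupled fraction is binomially consistent with the rate", {
  cfg <- region_presets("CB")  # coupling rate 0.261
  cfg$axon_coupling_rate <- 0.26
  ds <- generate_region(cfg, n_dendrites = 115, seed = 13)
  sp <- ds$spines[!ds$spines$filopodium, ]
  n <- nrow(sp)
  expect_gt(n, 9000)
  frac <- as.numeric(axon_coupled_fraction(sp))
  ci_half <- qnorm(0.995) * sqrt(0.26 * 0.74 / n)
  expect_lt(abs(frac - 0.26), ci_half)
})

test_that("head volume and PSD area are strongly rank-correlated", {
  ds <- generate_region(ca1_psr_config(), n_dendrites = 100, seed = 21)
  sp <- ds$spines[!ds$spines$filopodium, ]
  rho <- cor(sp$head_volume_um3, sp$psd_area_um2, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("axon-coupled pairs have less PSD spread than the population", {
  ds <- generate_region(region_presets("CB"), n_dendrites = 60, seed = 31)
  sp <- ds$spines[!ds$spines$filopodium, ]
  key <- paste(sp$dendrite_id, sp$axon_id)
  coupled <- key %in% names(which(table(key) >= 2))
  # intra-pair absolute PSD difference vs difference of random spine pairs
  pair_diff <- sapply(split(sp$psd_area_um2[coupled], key[coupled]),
                      function(x) max(x) - min(x))
  set.seed(1)
  rand_diff <- replicate(500, abs(diff(sample(sp$psd_area_um2, 2))))
  expect_lt(median(pair_diff), median(rand_diff))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(region_config("x", spine_density_mean = 1,
                             spine_density_sd = 2,
                             head_volume_logmu = -3, head_volume_logsigma = 1,
                             neck_length_mean = .5, neck_length_sd = .1,
                             neck_diameter_mean = .2, neck_diameter_sd = .05,
                             psd_per_volume_slope = 1, psd_noise_sd = .01,
                             diameter_range = c(.4, .8)),
               "spine_density_sd")
  cfg <- ca1_psr_config()
  cfg$er_fraction <- 1.5
  expect_error(generate_region(cfg, 2), "er_fraction")
  cfg2 <- ca1_psr_config()
  cfg2$diameter_range <- c(0.8, 0.4)
  expect_error(generate_region(cfg2, 2), "diameter_range")
  expect_error(generate_region(ca1_psr_config(), 0), "n_dendrites")
})

test_that("contour stacks reproduce the target volume", {
  set.seed(2)
  st <- generate_contour_stack(0.04, 0.04, 2)
  expect_equal(sum(st$areas), 1.0, tolerance = 1e-12)
  st1 <- generate_contour_stack(0.12, 0.03, 1)
  expect_equal(st1$areas, 0.12 / 0.03, tolerance = 1e-12)
  # round trip over random geometries
  for (i in 1:100) {
    v <- runif(1, 0.001, 2); t <- runif(1, 0.01, 0.1)
    k <- sample(1:40, 1)
    expect_equal(head_volume(generate_contour_stack(v, t, k)), v,
                 tolerance = 1e-9)
  }
  expect_error(generate_contour_stack(-1, 0.04, 2), "target_volume")
  expect_error(generate_contour_stack(1, 0, 2), "thickness")
})

test_that("uncaging trace fixtures honour the programmed kinetics", {
  tr <- generate_uncaging_traces(1.0, n_trials = 3, noise_sd = 0)
  # sampling grid sits within 0.05 ms of the analytic peak time
  expect_equal(max(tr$traces), 1.0, tolerance = 1e-5)
  peak_idx <- which.max(tr$traces[1, ])
  expect_equal(tr$time_ms[peak_idx], tr$peak_time_ms, tolerance = 0.1)

  flat <- generate_uncaging_traces(0, n_trials = 4, noise_sd = 0)
  expect_true(all(flat$traces == 0))

  expect_error(generate_uncaging_traces(1, 5, rise_ms = 20, decay_ms = 2),
               "kinetics")

  # trial-mean amplitude within 3 SE of the programmed 1.66 mV
  set.seed(3)
  tr2 <- generate_uncaging_traces(1.66, n_trials = 10, noise_sd = 0.1)
  amp <- response_amplitude(tr2)
  expect_lt(abs(as.numeric(amp) - 1.66), 3 * 0.1 / sqrt(10) + 0.01)
})

test_that("dataset CSV round trip preserves the tables", {
  ds <- generate_region(ca1_psr_config(), 5, seed = 8)
  prefix <- file.path(tempdir(), "roundtrip")
  write_spine_dataset(ds, prefix)
  back <- read_spine_dataset(prefix)
  expect_equal(back$spines$head_volume_um3, ds$spines$head_volume_um3)
  expect_equal(back$dendrites$length_um, ds$dendrites$length_um)
  expect_equal(back$config$spine_density_mean,
               ds$config$spine_density_mean)
})
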