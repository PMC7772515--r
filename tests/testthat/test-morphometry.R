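# Measurement operators: closed-form cases, independent re-summation
# oracles and the algebraic invariants (linearity, additivity, reordering).

test_that("head volume is total contour area times section thickness", {
  expect_equal(head_volume(contour_stack(c(0.5, 0.5), 0.04)), 0.04)
  expect_equal(head_volume(contour_stack(0.7, 0.03)), 0.7 * 0.03)
  set.seed(10)
  for (i in 1:50) {
    areas <- runif(sample(1:30, 1), 0, 2)
    t <- runif(1, 0.01, 0.1)
    oracle <- 0
    for (a in areas) oracle <- oracle + a * t  # per-section re-summation
    expect_identical(head_volume(contour_stack(areas, t)), sum(areas) * t)
    expect_equal(head_volume(contour_stack(areas, t)), oracle,
                 tolerance = 1e-12)
  }
  expect_error(contour_stack(numeric(0), 0.04), ">= 1 section")
})

test_that("PSD area handles cross-sectioned and en face synapses", {
  expect_equal(psd_area(contour_stack(1, 0.04,
                                      psd_trace_lengths = c(0.2, 0.3))),
               0.02)
  expect_equal(psd_area(contour_stack(1, 0.04, en_face_area = 0.05)), 0.05)
  expect_error(psd_area(contour_stack(1, 0.04,
                                      psd_trace_lengths = 0.2,
                                      en_face_area = 0.05)),
               "ambiguous")
  expect_error(psd_area(contour_stack(1, 0.04)), "no PSD")
  set.seed(11)
  for (i in 1:50) {
    tr <- runif(sample(1:20, 1), 0, 1)
    t <- runif(1, 0.01, 0.1)
    oracle <- 0
    for (l in tr) oracle <- oracle + l * t
    expect_equal(psd_area(contour_stack(rep(1, length(tr)), t,
                                        psd_trace_lengths = tr)),
                 oracle, tolerance = 1e-12)
  }
})

test_that("volume and PSD measures are linear in thickness and additive over partitions", {
  set.seed(12)
  areas <- runif(20, 0, 2)
  tr <- runif(20, 0, 1)
  t <- 0.04
  v1 <- head_volume(contour_stack(areas, t))
  expect_equal(head_volume(contour_stack(areas, 2 * t)), 2 * v1)
  # split the stack anywhere: results add exactly
  for (cut in c(1, 7, 19)) {
    expect_equal(v1,
                 head_volume(contour_stack(areas[1:cut], t)) +
                   head_volume(contour_stack(areas[-(1:cut)], t)),
                 tolerance = 1e-12)
    a1 <- psd_area(contour_stack(rep(1, cut), t,
                                 psd_trace_lengths = tr[1:cut]))
    a2 <- psd_area(contour_stack(rep(1, 20 - cut), t,
                                 psd_trace_lengths = tr[-(1:cut)]))
    expect_equal(a1 + a2,
                 psd_area(contour_stack(rep(1, 20), t,
                                        psd_trace_lengths = tr)),
                 tolerance = 1e-12)
  }
})

test_that("dendrite diameter is the mean of section widths", {
  expect_equal(dendrite_diameter(c(0.6, 0.6, 0.6)), 0.6)
  expect_equal(dendrite_diameter(c(0.5, 0.7)), 0.6)
  set.seed(13)
  w <- runif(17, 0.2, 1.5)
  expect_equal(dendrite_diameter(w), sum(w) / length(w))
  expect_error(dendrite_diameter(numeric(0)), "section width")
})

test_that("densities follow their defining ratios and exclusion rules", {
  d <- make_dendrite(psd = rep(0.05, 30), neck = rep(0.4, 30), length_um = 10)
  expect_equal(spine_density(d), 3.0)
  expect_equal(spine_density(make_dendrite(numeric(0), numeric(0), 5)), 0)
  # filopodia are excluded from the spine count
  d_filo <- make_dendrite(psd = c(0.05, 0.05, 0), neck = c(0.4, 0.4, 0.1),
                          length_um = 2, filo = c(FALSE, FALSE, TRUE))
  expect_equal(spine_density(d_filo), 1.0)

  expect_equal(psd_area_density(make_dendrite(c(0.05, 0.15), c(.4, .5), 2)),
               0.10, ignore_attr = TRUE)
  # spines with missing PSD are excluded and QC-counted
  dmiss <- make_dendrite(c(0.05, NA, 0.15), c(.4, .5, .6), 2)
  res <- psd_area_density(dmiss)
  expect_equal(as.numeric(res), 0.10)
  expect_equal(attr(res, "qc_excluded"), 1L)
  expect_error(psd_area_density(make_dendrite(0.05, 0.4, 0)), "length")

  expect_equal(neck_length_density(make_dendrite(c(.1, .2), c(0.5, 1.5), 4)),
               0.5)
})

test_that("densities are order-invariant and scale as 1/length", {
  set.seed(14)
  psd <- runif(25); neck <- runif(25, 0.1, 1)
  d <- make_dendrite(psd, neck, 10)
  perm <- sample(25)
  dp <- make_dendrite(psd[perm], neck[perm], 10, pos = perm)
  expect_equal(as.numeric(psd_area_density(d)),
               as.numeric(psd_area_density(dp)))
  expect_equal(neck_length_density(d), neck_length_density(dp))
  d2 <- make_dendrite(psd, neck, 20)
  expect_equal(as.numeric(psd_area_density(d2)),
               as.numeric(psd_area_density(d)) / 2)
  expect_equal(spine_density(d2), spine_density(d) / 2)
  # groupby-sum oracle
  expect_equal(as.numeric(psd_area_density(d)), sum(psd) / 10)
})

test_that("PSD/neck ratios distinguish dendrite totals from per-spine means", {
  expect_equal(psd_neck_ratio(0.08, 0.4), 0.2)
  d1 <- make_dendrite(c(0.1, 0.3), c(0.5, 1.5), 2)
  expect_equal(dendrite_psd_neck_ratio(d1), 0.2)
  # distinguishes the total ratio from the mean of per-spine ratios
  d2 <- make_dendrite(c(0.1, 0.2), c(0.5, 0.5), 2)
  expect_equal(dendrite_psd_neck_ratio(d2), 0.3)
  expect_equal(mean(psd_neck_ratio(c(0.1, 0.2), c(0.5, 0.5))), 0.3)
  # stubby spines (zero neck) are excluded with a warning
  expect_warning(r <- psd_neck_ratio(c(0.1, 0.2), c(0.5, 0)), "stubby")
  expect_true(is.na(r[2]))
  set.seed(15)
  psd <- runif(40); neck <- runif(40, 0.1, 2)
  expect_equal(dendrite_psd_neck_ratio(make_dendrite(psd, neck, 5)),
               sum(psd) / sum(neck))
})

test_that("fold range and CV follow their definitions", {
  expect_equal(fold_range(c(0.01, 1.24)), 124)
  expect_equal(fold_range(rep(0.3, 5)), 1)
  expect_equal(cv(rep(0.3, 5)), 0)
  set.seed(16)
  x <- runif(50, 0.01, 3)
  mx <- x[1]; mn <- x[1]
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  expect_equal(fold_range(x), mx / mn)
  expect_equal(cv(x), sd(x) / mean(x))
  expect_error(fold_range(c(0, 1)), "positive")
  expect_error(cv(1), "two values")
})

test_that("axon-coupled fraction counts repeated (dendrite, axon) pairs", {
  sp <- data.frame(dendrite_id = "d1",
                   axon_id = c("A", "A", "b", "c", "e"))
  res <- axon_coupled_fraction(sp)
  expect_equal(as.numeric(res), 0.40)
  expect_equal(attr(res, "multiplicity_range"), c(2L, 2L))

  expect_equal(as.numeric(axon_coupled_fraction(
    data.frame(dendrite_id = "d1", axon_id = letters[1:5]))), 0)
  res4 <- axon_coupled_fraction(data.frame(dendrite_id = "d1",
                                           axon_id = rep("A", 4)))
  expect_equal(as.numeric(res4), 1.0)
  expect_equal(attr(res4, "multiplicity_range"), c(4L, 4L))
  # same axon on different dendrites does not couple
  sp2 <- data.frame(dendrite_id = c("d1", "d2"), axon_id = c("A", "A"))
  expect_equal(as.numeric(axon_coupled_fraction(sp2)), 0)
  expect_equal(as.numeric(axon_coupled_fraction(sp2[0, ])), 0)
})

test_that("ER hotspot fraction uses ordinal adjacency", {
  sp <- data.frame(position_um = 1:5,
                   er = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(er_hotspot_fraction(sp, length_um = 10), 2 / 3)
  expect_equal(er_hotspot_fraction(
    data.frame(position_um = 1:4, er = rep(TRUE, 4)), length_um = 5), 1.0)
  expect_equal(er_hotspot_fraction(
    data.frame(position_um = 1:4, er = c(TRUE, FALSE, TRUE, FALSE)),
    length_um = 5), 0.0)
  expect_true(is.na(er_hotspot_fraction(
    data.frame(position_um = 1, er = TRUE), length_um = 5)))
  # unsorted positions are ordered before adjacency is evaluated
  sp_shuffled <- sp[c(3, 1, 5, 2, 4), ]
  expect_equal(er_hotspot_fraction(sp_shuffled, length_um = 10), 2 / 3)
})

test_that("surface-area fractions normalize to one", {
  expect_equal(unname(surface_area_fractions(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(unname(surface_area_fractions(0, 0, 0, 5)), c(0, 0, 0, 1))
  set.seed(17)
  for (i in 1:25) {
    x <- runif(4, 0, 10)
    f <- surface_area_fractions(x[1], x[2], x[3], x[4])
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_equal(unname(f), x / sum(x))
  }
  expect_error(surface_area_fractions(0, 0, 0, 0), "at least one")
})

test_that("per-dendrite summaries recover generator parameters", {
  ds <- generate_region(ca1_psr_config(), n_dendrites = 220, seed = 3)
  ms <- morphometry_summary(ds)
  n_d <- nrow(ms$per_dendrite)
  se_dens <- sd(ms$per_dendrite$spine_density) / sqrt(n_d)
  expect_lt(abs(ms$per_region$spine_density_mean - 3.04), 4 * se_dens)
  se_hv <- ms$per_region$head_volume_sd / sqrt(ms$per_region$n_spines)
  expect_lt(abs(ms$per_region$head_volume_mean - 0.05), 4 * se_hv)
  # PSD-area density scales with diameter as configured
  ct <- choose_and_correlate(ms$per_dendrite$diameter_um,
                             ms$per_dendrite$psd_area_density)
  expect_gt(ct$statistic, 0.3)
  expect_lt(ct$p_value, 0.001)
})
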