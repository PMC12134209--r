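test_that("identity fold gives a uniform signal channel with ratio exactly 1", {
  cfg <- tiny_config(channel_folds = c(SIGNAL = 1), psf_sigma = 0,
                     noise = noiseless, seed = 3L)
  res <- generate_nucleus(cfg)
  x <- get_channel(res$stack, "SIGNAL")
  expect_equal(length(unique(x[res$truth$nucleus_mask])), 1L)
  tm <- truth_masks(res$truth, cfg$voxel_size)
  enr <- compute_enrichment(res$stack, "SIGNAL", tm$nucleus, tm$domains)
  expect_equal(enr$ratio_global, 1)
  expect_true(all(enr$per_domain_ratios$ratio == 1))
})

test_that("configured fold is measured exactly by direct voxel means", {
  cfg <- tiny_config(channel_folds = c(SIGNAL = 2), psf_sigma = 0,
                     noise = noiseless, seed = 4L)
  res <- generate_nucleus(cfg)
  # oracle: direct means over the truth voxel sets, no package ratio code
  x <- get_channel(res$stack, "SIGNAL")
  inside <- mean(x[res$truth$cc_mask])
  outside <- mean(x[res$truth$nucleus_mask & !res$truth$cc_mask])
  expect_equal(inside / outside, 2)
})

test_that("identical config and seed give bit-identical stacks", {
  cfg <- tiny_config(channel_folds = c(SIGNAL = 1.7), seed = 11L)
  a <- generate_nucleus(cfg)
  b <- generate_nucleus(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cc_labels, b$truth$cc_labels)
})

test_that("ground-truth masks are nested and chromocenters disjoint", {
  for (seed in 1:5) {
    res <- generate_nucleus(tiny_config(seed = seed))
    expect_true(all(res$truth$nucleus_mask[res$truth$cc_mask]))
    # pairwise disjoint by construction: label array has one id per voxel;
    # check sphere centres are separated by at least the radius sum
    ctr <- res$truth$cc_centres
    rad <- res$truth$cc_radii
    if (nrow(ctr) > 1L) {
      dd <- as.matrix(dist(ctr))
      sums <- outer(rad, rad, `+`)
      expect_true(all(dd[upper.tri(dd)] >= sums[upper.tri(sums)]))
    }
  }
})

test_that("pre-noise in/out ratio increases strictly with configured fold", {
  folds <- c(0.7, 1.0, 1.3, 1.8, 2.4)
  measured <- vapply(folds, function(r) {
    cfg <- tiny_config(channel_folds = c(SIGNAL = r), psf_sigma = 0,
                       noise = noiseless, seed = 99L)
    res <- generate_nucleus(cfg)
    tm <- truth_masks(res$truth, cfg$voxel_size)
    compute_enrichment(res$stack, "SIGNAL", tm$nucleus, tm$domains)$ratio_global
  }, numeric(1L))
  expect_true(all(diff(measured) > 0))
})

test_that("impossible chromocenter packing raises a placement error", {
  cfg <- tiny_config(n_chromocenters = 200L,
                     chromocenter_radius = c(0.8, 0.01), seed = 1L)
  expect_error(generate_nucleus(cfg), class = "chromofied_placement_error")
})

test_that("generate_population draws labels from the preset mixture", {
  preset <- condition_preset(
    "mix", c(Enriched = 0.7, Even = 0.3, Excluded = 0),
    config_overrides = list(nucleus_radii = c(2, 3, 3),
                            voxel_size = c(0.4, 0.25, 0.25),
                            n_chromocenters = c(5L, 8L)))
  expect_length(generate_population(preset, 0L), 0L)
  n <- 40L
  pop <- generate_population(preset, n, seed = 123L)
  labels <- vapply(pop, function(el) el$truth$pattern, character(1L))
  # oracle: an independent multinomial draw consuming the same seed stream
  oracle <- withr::with_seed(123L, sample(c("Enriched", "Even", "Excluded"),
                                          n, replace = TRUE,
                                          prob = c(0.7, 0.3, 0)))
  expect_identical(labels, oracle)
  expect_true(all(labels %in% c("Enriched", "Even")))
  # per-nucleus folds respect the label's range
  for (el in pop) {
    rng <- preset$fold_ranges[[el$truth$pattern]]
    f <- el$truth$channel_folds[["SIGNAL"]]
    expect_gte(f, rng[1L]); expect_lte(f, rng[2L])
  }
})

test_that("empirical pattern frequencies match the mixture within 3 SE", {
  # scaled down from the spec's n = 1000 sweep: labels only, no rendering
  preset <- condition_preset("mix", c(Enriched = 0.55, Even = 0.35,
                                      Excluded = 0.10))
  n <- 1000L
  labels <- withr::with_seed(7L, sample(names(preset$pattern_mixture), n,
                                        replace = TRUE,
                                        prob = preset$pattern_mixture))
  for (lab in names(preset$pattern_mixture)) {
    p <- preset$pattern_mixture[[lab]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(labels == lab) - p), 3 * se + 1e-12)
  }
})

test_that("marker and FUCCI schemes render the documented channels", {
  res_m <- generate_nucleus(tiny_config(scheme = "markers", stage = "MidS",
                                        seed = 2L))
  expect_true(has_channel(res_m$stack, "EDU"))
  expect_true(has_channel(res_m$stack, "AURORAB"))
  res_f <- generate_nucleus(tiny_config(scheme = "fucci", stage = "G2",
                                        seed = 2L))
  expect_true(has_channel(res_f$stack, "GEMININ"))
  # G2: Geminin high, hCdt1 dark
  expect_gt(mean(get_channel(res_f$stack, "GEMININ")[res_f$truth$nucleus_mask]),
            10 * mean(get_channel(res_f$stack, "HCDT1")[res_f$truth$nucleus_mask]))
  expect_error(generate_nucleus(tiny_config(scheme = "markers", seed = 2L)),
               class = "chromofied_config_error")
})
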