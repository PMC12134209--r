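make_fixture_stack <- function(fill) {
  # 10 x 20 x 20 canvas with a hand-placed box nucleus and two box domains
  a <- array(0, c(10, 20, 20))
  nucleus <- array(FALSE, c(10, 20, 20))
  nucleus[3:8, 4:17, 4:17] <- TRUE
  labels <- array(0L, c(10, 20, 20))
  labels[4:5, 6:8, 6:8] <- 1L
  labels[6:7, 12:14, 12:14] <- 2L
  a[nucleus] <- fill(sum(nucleus))
  vs <- c(0.4, 0.25, 0.25)
  list(stack = image_stack(list(dapi = a, sig = a), vs,
                           c(DAPI = "dapi", SIGNAL = "sig")),
       nucleus = nucleus_mask(1L, nucleus, vs),
       domains = chromocenter_set(1L, labels, vs))
}

test_that("uniform intensity gives global and per-domain ratios of exactly 1", {
  fx <- make_fixture_stack(function(n) rep(42, n))
  enr <- compute_enrichment(fx$stack, "SIGNAL", fx$nucleus, fx$domains)
  expect_equal(enr$ratio_global, 1)
  expect_equal(enr$per_domain_ratios$ratio, c(1, 1))
})

test_that("forced arithmetic: domains at 200 over outside at 100 gives 2", {
  fx <- make_fixture_stack(function(n) rep(100, n))
  x <- fx$stack$channels$sig
  x[fx$domains$labels > 0L] <- 200
  stk <- image_stack(list(dapi = x, sig = x), fx$stack$voxel_size,
                     fx$stack$channel_roles)
  enr <- compute_enrichment(stk, "SIGNAL", fx$nucleus, fx$domains,
                            background = 0)
  expect_equal(enr$ratio_global, 2)
  expect_equal(enr$per_domain_ratios$ratio, c(2, 2))
})

test_that("arbitrary voxel values match the brute-force voxel-list oracle", {
  fx <- make_fixture_stack(function(n) withr::with_seed(9L, runif(n, 10, 500)))
  enr <- compute_enrichment(fx$stack, "SIGNAL", fx$nucleus, fx$domains)
  oracle <- fied_oracle(fx$stack$channels$sig, fx$nucleus$mask,
                        fx$domains$labels)
  expect_equal(enr$ratio_global, oracle$ratio_global, tolerance = 1e-12)
  expect_equal(enr$per_domain_ratios$ratio, unname(oracle$per_domain),
               tolerance = 1e-12)
  expect_equal(enr$per_domain_ratios$domain_id, oracle$ids)
})

test_that("global ratio equals the volume-weighted mean of per-domain ratios", {
  for (seed in c(2, 5, 8)) {
    res <- generate_nucleus(tiny_config(channel_folds = c(SIGNAL = 1.6),
                                        seed = seed))
    tm <- truth_masks(res$truth, res$stack$voxel_size)
    enr <- compute_enrichment(res$stack, "SIGNAL", tm$nucleus, tm$domains)
    w <- tm$domains$domains$n_voxels
    expect_equal(enr$ratio_global,
                 sum(w * enr$per_domain_ratios$ratio) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("ratios are invariant to intensity scaling after background removal", {
  fx <- make_fixture_stack(function(n) withr::with_seed(3L, runif(n, 50, 300)))
  e1 <- compute_enrichment(fx$stack, "SIGNAL", fx$nucleus, fx$domains)
  scaled <- image_stack(lapply(fx$stack$channels, `*`, 13), fx$stack$voxel_size,
                        fx$stack$channel_roles)
  e2 <- compute_enrichment(scaled, "SIGNAL", fx$nucleus, fx$domains)
  expect_equal(e1$ratio_global, e2$ratio_global, tolerance = 1e-12)
  expect_equal(e1$per_domain_ratios$ratio, e2$per_domain_ratios$ratio,
               tolerance = 1e-12)
})

test_that("degenerate inputs are handled per contract", {
  # zero outside mean -> undefined-ratio error
  fx <- make_fixture_stack(function(n) rep(0, n))
  x <- fx$stack$channels$sig
  x[fx$domains$labels > 0L] <- 50
  stk <- image_stack(list(dapi = x, sig = x), fx$stack$voxel_size,
                     fx$stack$channel_roles)
  expect_error(compute_enrichment(stk, "SIGNAL", fx$nucleus, fx$domains),
               class = "chromofied_undefined_ratio")
  # empty domain set -> NA global ratio, zero rows
  fx2 <- make_fixture_stack(function(n) rep(10, n))
  empty <- chromocenter_set(1L, array(0L, dim(fx2$nucleus$mask)),
                            fx2$stack$voxel_size)
  enr <- compute_enrichment(fx2$stack, "SIGNAL", fx2$nucleus, empty)
  expect_true(is.na(enr$ratio_global))
  expect_equal(enr$n_domains, 0L)
  expect_equal(nrow(enr$per_domain_ratios), 0L)
})

test_that("background subtraction shifts ratios as expected", {
  fx <- make_fixture_stack(function(n) rep(100, n))
  x <- fx$stack$channels$sig + 50          # constant offset everywhere
  x[fx$domains$labels > 0L] <- 250         # in-domain 250, outside 150
  stk <- image_stack(list(dapi = x, sig = x), fx$stack$voxel_size,
                     fx$stack$channel_roles)
  raw <- compute_enrichment(stk, "SIGNAL", fx$nucleus, fx$domains)
  corr <- compute_enrichment(stk, "SIGNAL", fx$nucleus, fx$domains,
                             background = 50)
  expect_equal(raw$ratio_global, 250 / 150)
  expect_equal(corr$ratio_global, 2)
})

test_that("modal background is estimated from outside the nuclei", {
  res <- generate_nucleus(tiny_config(seed = 12L))
  nuc <- segment_nuclei(res$stack)
  bg <- estimate_background(res$stack, "DAPI", nuc)
  expect_lt(bg, 10)  # rendered background is 0 + read noise
})
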