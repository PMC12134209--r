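test_that("empty or constant DAPI yields zero nuclei, not an error", {
  a <- array(0, c(4, 10, 10))
  stk <- image_stack(list(dapi = a), c(0.4, 0.25, 0.25), c(DAPI = "dapi"))
  expect_length(segment_nuclei(stk), 0L)
  stk2 <- image_stack(list(dapi = a + 7), c(0.4, 0.25, 0.25),
                      c(DAPI = "dapi"))
  expect_length(segment_nuclei(stk2), 0L)
})

test_that("a noiseless synthetic sphere is recovered as the analytic mask", {
  # hand-built sphere, independent of the generator
  vs <- c(0.4, 0.25, 0.25)
  d <- c(16L, 30L, 30L)
  cz <- ((seq_len(d[1]) - 0.5) - d[1] / 2) * vs[1]
  cy <- ((seq_len(d[2]) - 0.5) - d[2] / 2) * vs[2]
  cx <- ((seq_len(d[3]) - 0.5) - d[3] / 2) * vs[3]
  r2 <- outer(outer(cz^2, cy^2, `+`), cx^2, `+`)
  analytic <- r2 <= 2.6^2
  stk <- image_stack(list(dapi = 100 * analytic), vs, c(DAPI = "dapi"))
  nuc <- segment_nuclei(stk, smooth_sigma = 0)
  expect_length(nuc, 1L)
  expect_identical(nuc[[1]]$mask, analytic)
})

test_that("two nuclei in one stack are found with volumes within 10% of truth", {
  # two generator nuclei pasted side by side on one canvas, default noise
  cfg <- tiny_config(seed = 31L)
  r1 <- generate_nucleus(cfg)
  r2 <- generate_nucleus(tiny_config(seed = 32L))
  d1 <- dim(r1$stack$channels$DAPI)
  canvas <- array(0, c(d1[1], d1[2], 2L * d1[3]))
  canvas[, , seq_len(d1[3])] <- r1$stack$channels$DAPI
  canvas[, , d1[3] + seq_len(d1[3])] <- r2$stack$channels$DAPI
  stk <- image_stack(list(dapi = canvas), cfg$voxel_size, c(DAPI = "dapi"))
  nuc <- segment_nuclei(stk)
  expect_length(nuc, 2L)
  truth_vol <- prod(cfg$voxel_size) *
    c(sum(r1$truth$nucleus_mask), sum(r2$truth$nucleus_mask))
  got <- sort(vapply(nuc, function(n) n$volume, numeric(1L)))
  expect_true(all(abs(got - sort(truth_vol)) / sort(truth_vol) < 0.10))
})

test_that("border-touching and sub-volume components are removed", {
  vs <- c(0.4, 0.25, 0.25)
  a <- array(0, c(12, 30, 30))
  a[3:10, 4:26, 4:26] <- 100         # interior block, well above 50 um^3
  a[1:2, 1:3, 1:3] <- 100            # touches the border -> dropped
  a[6, 28, 28] <- 100                # speck below min volume -> dropped
  stk <- image_stack(list(dapi = a), vs, c(DAPI = "dapi"))
  nuc <- segment_nuclei(stk, smooth_sigma = 0)
  expect_length(nuc, 1L)
  expect_gt(nuc[[1]]$volume, 50)
})

test_that("uniform DAPI inside the nucleus yields zero chromocenters", {
  vs <- c(0.4, 0.25, 0.25)
  a <- array(0, c(12, 30, 30))
  a[3:10, 4:26, 4:26] <- 100
  stk <- image_stack(list(dapi = a), vs, c(DAPI = "dapi"))
  nuc <- segment_nuclei(stk, smooth_sigma = 0)
  dom <- segment_chromocenters(stk, nuc[[1]])
  expect_equal(dom$n_domains, 0L)
})

test_that("noiseless generator foci are recovered with matching centroids", {
  cfg <- tiny_config(n_chromocenters = 5L, dapi_fold = 2.5, psf_sigma = 0,
                     noise = noiseless, seed = 17L)
  res <- generate_nucleus(cfg)
  nuc <- segment_nuclei(res$stack, smooth_sigma = 0)
  dom <- segment_chromocenters(res$stack, nuc[[1]])
  expect_equal(dom$n_domains, 5L)
  # centroids within 2 voxels (xy pitch) of the truth sphere centres
  truth_ctr <- res$truth$cc_centres
  d <- dim(res$truth$nucleus_mask)
  origin <- cfg$voxel_size * d / 2   # truth centres are relative to centre
  for (i in seq_len(nrow(truth_ctr))) {
    got <- as.matrix(dom$domains[, c("cz", "cy", "cx")])
    dd <- sqrt(colSums((t(got) - (truth_ctr[i, ] + origin))^2))
    expect_lt(min(dd), 2 * max(cfg$voxel_size))
  }
})

test_that("foci below min_domain_volume are dropped", {
  vs <- c(0.4, 0.25, 0.25)
  a <- array(0, c(12, 30, 30))
  a[3:10, 4:26, 4:26] <- 100
  a[6:7, 10:13, 10:13] <- 400        # 32 voxels * 0.025 = 0.8 um^3, kept
  a[6, 20, 20] <- 400                # 0.025 um^3, dropped
  stk <- image_stack(list(dapi = a), vs, c(DAPI = "dapi"))
  nuc <- segment_nuclei(stk, smooth_sigma = 0)
  dom <- segment_chromocenters(stk, nuc[[1]])
  expect_equal(dom$n_domains, 1L)
  expect_gt(dom$domains$volume, 0.15)
})

test_that("segmentation is invariant to intensity scaling", {
  res <- generate_nucleus(tiny_config(seed = 23L))
  stk1 <- res$stack
  stk2 <- image_stack(lapply(stk1$channels, function(x) x * 37.5),
                      stk1$voxel_size, stk1$channel_roles)
  n1 <- segment_nuclei(stk1)
  n2 <- segment_nuclei(stk2)
  expect_length(n2, length(n1))
  expect_identical(n1[[1]]$mask, n2[[1]]$mask)
  d1 <- segment_chromocenters(stk1, n1[[1]])
  d2 <- segment_chromocenters(stk2, n2[[1]])
  expect_identical(d1$labels, d2$labels)
})

test_that("noiseless masks reach the Jaccard floor; counts are recovered at default SNR", {
  # noiseless: voxel-level Jaccard >= 0.95 (nucleus) and >= 0.8 (domains)
  cfg <- tiny_config(psf_sigma = 0, noise = noiseless, seed = 41L)
  res <- generate_nucleus(cfg)
  nuc <- segment_nuclei(res$stack, smooth_sigma = 0)
  dom <- segment_chromocenters(res$stack, nuc[[1]])
  expect_gte(mask_jaccard(nuc[[1]]$mask, res$truth$nucleus_mask), 0.95)
  expect_gte(mask_jaccard(dom$labels > 0, res$truth$cc_mask), 0.8)

  # chromocenter count recall/precision at default SNR (scaled down from
  # the spec's 100-nucleus sweep to 30 for runtime; see methods vignette)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (seed in 1:30) {
    cfg <- tiny_config(seed = 500L + seed)
    res <- generate_nucleus(cfg)
    nuc <- segment_nuclei(res$stack)
    dom <- segment_chromocenters(res$stack, nuc[[1]])
    n_true <- res$truth$n_chromocenters
    n_got <- dom$n_domains
    tp <- tp + min(n_true, n_got)
    fp <- fp + max(0L, n_got - n_true)
    fn <- fn + max(0L, n_true - n_got)
  }
  expect_gte(tp / (tp + fn), 0.95)  # recall
  expect_gte(tp / (tp + fp), 0.95)  # precision
})
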