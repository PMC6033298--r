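test_that("threshold formula matches hand evaluation", {
  expect_equal(phansalkar_threshold(0, 0.3), 0)
  expect_equal(phansalkar_threshold(1, 0.5), 1 + 2 * exp(-10))
  expect_equal(phansalkar_threshold(0.5, 0.25),
               0.5 * (1 + 2 * exp(-5) - 0.125))
  expect_error(phansalkar_params(r = 0), "nonzero")
  expect_error(phansalkar_threshold(-0.1, 0), "\\[0, 1\\]")
  expect_error(phansalkar_threshold(0.5, -1), "nonnegative")
})

test_that("threshold formula matches the naive oracle on random grids", {
  set.seed(7)
  mu <- runif(500); sigma <- runif(500)
  p <- phansalkar_params()
  oracle <- vapply(seq_along(mu), function(i)
    mu[i] * (1 + p$p * exp(-p$q * mu[i]) + p$k * (sigma[i] / p$r - 1)),
    numeric(1))
  expect_lt(max(abs(phansalkar_threshold(mu, sigma) - oracle)), 1e-12)
})

test_that("binarization equals the brute-force per-pixel oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(11 * 11), 11, 11)
    params <- phansalkar_params(window_radius = 3)
    st <- naive_local_stats(m, 3)
    oracle_mask <- m > phansalkar_threshold(st$mean, st$sd, params)
    expect_identical(binarize(m, params), oracle_mask)
  }
})

test_that("binarization handles degenerate and invalid maps", {
  expect_false(any(binarize(matrix(0, 40, 40))))
  expect_error(binarize(matrix(0.5, 10, 10)), "window diameter")
  expect_error(binarize(matrix(2, 40, 40)), "\\[0, 1\\]")
})

test_that("a noiseless nucleus footprint is recovered (IoU >= 0.9)", {
  nuc <- nucleus_spec(c(32, 32), c(9, 6), 0.4, 0.7)
  sp <- render_patch(list(nuc), size = 64, background_eosin = 0.25, noise_sd = 0)
  h <- hematoxylin_map(separate_stains(sp$patch))
  mask <- binarize(h)
  footprint <- h > 0.5  # noiseless: exactly the rendered ellipse
  iou <- sum(mask & footprint) / sum(mask | footprint)
  expect_gte(iou, 0.9)
})

test_that("watershed splitting behaves on canonical blob layouts", {
  # two disjoint blobs -> 2 labels
  m <- circle_pair_mask(64, 64, r = 9, d = 40)
  expect_equal(max(split_touching(m)), 2L)
  # one circular blob -> 1 label, no spurious splits
  m1 <- circle_pair_mask(64, 64, r = 12, d = 0)
  lab1 <- split_touching(m1)
  expect_equal(max(lab1), 1L)
  expect_equal(sum(lab1 > 0), sum(m1))
  # 20%-of-radius overlap (centers 1.8 r apart) -> split into 2
  m2 <- circle_pair_mask(64, 64, r = 10, d = 18)
  expect_equal(max(split_touching(m2)), 2L)
  # speck suppression
  sp <- matrix(FALSE, 32, 32); sp[5:6, 5:6] <- TRUE
  expect_equal(max(split_touching(sp, min_area = 15)), 0L)
  expect_equal(max(split_touching(sp, min_area = 0)), 1L)
  expect_error(split_touching(matrix(1, 4, 4)), "logical")
})

test_that("contour tracing returns closed outer borders with exact areas", {
  expect_equal(trace_contours(matrix(0L, 8, 8)), list())
  sq <- matrix(0L, 8, 8); sq[3:5, 3:5] <- 1L
  ct <- trace_contours(sq)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$area, 9L)
  expect_equal(nrow(ct[[1]]$boundary), 8)           # the ring of the square
  # boundary is an 8-connected closed cycle on the region
  b <- ct[[1]]$boundary
  steps <- rbind(diff(b), b[1, ] - b[nrow(b), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
  expect_true(all(sq[b] == 1L))
  # random blobs: per-label area equals the pixel-count oracle
  set.seed(13)
  m <- matrix(runif(40 * 40) < 0.35, 40, 40)
  lab <- split_touching(m, min_area = 0)
  cts <- trace_contours(lab)
  counted <- tabulate(lab[lab > 0])
  for (ctr in cts) expect_equal(ctr$area, counted[ctr$label])
  expect_equal(sum(vapply(cts, function(x) x$area, integer(1))), sum(m))
})

test_that("measure_nuclei composes the pipeline correctly", {
  white <- rgb_patch(array(1, c(64, 64, 3)))
  mw <- measure_nuclei(white)
  expect_equal(mw$count, 0L)
  expect_equal(mw$total_area, 0L)
  # 10 well-separated noiseless nuclei: count exact, area within 15%
  pop <- generate_cellwise_population(
    1, cluster1 = cellwise_cluster_params(10, c(7, 10)),
    cluster2 = cellwise_cluster_params(10, c(7, 10)),
    size = 256, noise_sd = 0, seed = 99)
  sp <- pop[[1]]
  m <- measure_nuclei(sp$patch)
  expect_equal(m$count, sp$true_count)
  expect_lt(abs(m$total_area - sp$true_total_area) / sp$true_total_area, 0.15)
})

test_that("adding a disjoint nucleus never decreases the measurements", {
  set.seed(17)
  nuclei <- list(nucleus_spec(c(30, 30), c(8, 6), 0, 0.7))
  extra <- list(nucleus_spec(c(90, 90), c(7, 5), 1, 0.6),
                nucleus_spec(c(30, 95), c(6, 6), 0, 0.8),
                nucleus_spec(c(95, 30), c(9, 5), 2, 0.5))
  prev <- measure_nuclei(render_patch(nuclei, size = 128, noise_sd = 0)$patch)
  for (nuc in extra) {
    nuclei <- c(nuclei, list(nuc))
    cur <- measure_nuclei(render_patch(nuclei, size = 128, noise_sd = 0)$patch)
    expect_gte(cur$count, prev$count)
    expect_gte(cur$total_area, prev$total_area)
    prev <- cur
  }
})

test_that("measurements are invariant under 90-degree rotation", {
  pop <- generate_cellwise_population(1, size = 128, noise_sd = 0, seed = 23)
  p <- pop[[1]]$patch
  rot <- array(0, dim = dim(p)[c(2, 1, 3)])
  for (ch in 1:3) rot[, , ch] <- t(p[, , ch])[, nrow(p):1]  # rotate 90 deg
  m0 <- measure_nuclei(p)
  m1 <- measure_nuclei(rgb_patch(rot))
  expect_equal(m1$count, m0$count)
  expect_equal(m1$total_area, m0$total_area)
})
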