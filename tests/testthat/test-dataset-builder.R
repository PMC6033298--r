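test_that("tissue patch extraction follows the grid and purity rules", {
  # uniform epithelium mask: all four 256-cells kept
  mask <- matrix(1L, 512, 512)
  rec <- extract_tissue_patches(mask)
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$label == "epithelium"))
  # boundary-straddling cells are discarded under purity 0.9
  half <- matrix(1L, 512, 512); half[, 385:512] <- 2L
  rec2 <- extract_tissue_patches(half)  # right cells are 50/50 at col 257..512
  expect_equal(sort(rec2$label), c("epithelium", "epithelium"))
  expect_true(all(rec2$col == 1))
  # shape mismatch
  expect_error(extract_tissue_patches(mask, image = array(0, c(100, 100, 3))),
               "shapes differ")
  expect_error(extract_tissue_patches(matrix(5L, 8, 8)), "values")
})

test_that("patch extraction equals exhaustive enumeration on toy masks", {
  for (seed in 1:3) {
    set.seed(seed)
    mask <- matrix(sample(0:2, 24 * 24, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                   24, 24)
    ps <- 4L; purity <- 0.9
    rec <- extract_tissue_patches(mask, patch_size = ps, purity = purity)
    kept <- 0L
    for (gi in seq_len(6)) for (gj in seq_len(6)) {
      cell <- mask[((gi - 1) * ps + 1):(gi * ps), ((gj - 1) * ps + 1):(gj * ps)]
      if (max(table(factor(cell, 0:2))) / ps^2 >= purity) kept <- kept + 1L
    }
    expect_equal(nrow(rec), kept)
  }
})

test_that("filtering applies both exclusion criteria with logged reasons", {
  feats <- data.frame(count = c(0, 3, 50), total_area = c(0, 100, 900),
                      mean_h = c(0.001, 0.05, 0.05))
  all_kept <- filter_patches(feats, filter_policy(0, 0))
  expect_equal(nrow(all_kept$kept), 3L)
  part <- filter_patches(feats, filter_policy(min_count = 3, min_mean_h = 0.02))
  expect_equal(part$kept$count, c(3, 50))
  expect_equal(part$excluded$reason, "too_few_nuclei;stain_inconformity")
  # random predicate oracle
  set.seed(4)
  rf <- data.frame(count = rpois(200, 4), total_area = rpois(200, 300),
                   mean_h = runif(200, 0, 0.06))
  pol <- filter_policy(min_count = 3, min_mean_h = 0.03)
  got <- filter_patches(rf, pol)
  oracle <- rf$count >= 3 & rf$mean_h >= 0.03
  expect_equal(nrow(got$kept), sum(oracle))
  expect_equal(got$kept$count, rf$count[oracle])
})

test_that("K-means recovers planted populations and orders clusters by count", {
  set.seed(8)
  planted <- rbind(
    data.frame(total_area = rnorm(200, 4000, 400), count = rnorm(200, 8, 1.5)),
    data.frame(total_area = rnorm(200, 2500, 400), count = rnorm(200, 40, 4)))
  truth <- rep(1:2, each = 200)
  lab <- cluster_cellwise(planted, seed = 123)
  expect_gte(mean(lab == truth), 0.95)
  # cluster 1 must be the fewer-larger population
  expect_lt(mean(planted$count[lab == 1]), mean(planted$count[lab == 2]))
  # determinism and stability under reordering
  expect_identical(lab, cluster_cellwise(planted, seed = 123))
  perm <- sample(nrow(planted))
  lab_perm <- cluster_cellwise(planted[perm, ], seed = 123)
  expect_gte(mean(lab_perm == truth[perm]), 0.95)
})

test_that("K-means degenerate inputs are rejected or trivially handled", {
  same <- data.frame(total_area = rep(100, 5), count = rep(3, 5))
  expect_error(cluster_cellwise(same), "distinct")
  two <- data.frame(total_area = c(1, 2, 3), count = c(1, 2, 3))
  expect_equal(sort(unique(cluster_cellwise(two, k = 2, seed = 1))), 1:2)
  expect_equal(unique(cluster_cellwise(two, k = 1, seed = 1)), 1L)
})

test_that("90/10 split arithmetic rounds half up", {
  expect_equal(split_train_val(10), c(train = 9L, validation = 1L))
  expect_equal(split_train_val(0), c(train = 0L, validation = 0L))
  expect_error(split_train_val(10, 1.2), "\\[0, 1\\]")
  # split counts always sum to the input count
  set.seed(15)
  for (n in c(0:5, sample.int(1e5, 50))) {
    s <- split_train_val(n)
    expect_identical(s[["train"]] + s[["validation"]], as.integer(n))
  }
})

test_that("stratified split assignment matches the per-stratum arithmetic", {
  labels <- rep(c("a", "b"), times = c(17, 23))
  sp <- assign_splits(labels, seed = 2)
  expect_equal(sum(sp == "train" & labels == "a"), 15L)  # round(15.3)
  expect_equal(sum(sp == "validation" & labels == "b"), 2L)
  expect_identical(assign_splits(labels, seed = 2), sp)
})

test_that("manifests enforce level and split disjointness", {
  rec <- data.frame(path = c("p1", "p2", "p3"),
                    level = c("medium_cell", "medium_cell", "high"),
                    label = c("1", "2", "malignant"),
                    split = c("train", "validation", "test"))
  man <- build_manifests(rec)
  expect_named(man, c("high", "medium_cell"), ignore.order = TRUE)
  expect_equal(nrow(man$medium_cell), 2L)
  # one path in two levels
  rec2 <- rec; rec2$path[3] <- "p1"
  expect_error(build_manifests(rec2), "multiple levels")
  # one path in two splits within a level
  rec3 <- rbind(rec, data.frame(path = "p1", level = "medium_cell",
                                label = "1", split = "test"))
  expect_error(build_manifests(rec3), "multiple splits")
  expect_equal(length(build_manifests(rec[0, ])), 0L)
  expect_error(build_manifests(data.frame(path = "x")), "columns")
})
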