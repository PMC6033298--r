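# End-to-end synthetic benchmark: a world in which the cell-wise
# medium-level structure is informative for the high-level task. Benign
# proxy patches carry fewer/larger nuclei, malignant proxy patches carry
# more/smaller nuclei -- the same morphology axis the automatic cell-wise
# pseudo-labelling picks up, but drawn from shifted (overlapping)
# distributions and rendered with noise, so the high task is not trivially
# solved by the medium labels.

# stack a list of synthetic patches into an (s, s, 3, N) tensor, block
# averaging down to input_size
patches_to_tensor <- function(pop, input_size) {
  n <- length(pop)
  d <- dim(pop[[1]]$patch)
  factor <- d[1] %/% input_size
  x <- array(0, dim = c(input_size, input_size, 3L, n))
  for (i in seq_len(n))
    x[, , , i] <- downsample_patch(pop[[i]]$patch, factor)
  x
}

#' Generate the synthetic stepwise-training benchmark
#'
#' Builds, from scratch and deterministically per seed: (1) a cell-wise
#' medium-level dataset -- patches are measured with the full morphometry
#' pipeline, filtered, and pseudo-labelled by K-means; (2) a small
#' "well-annotated" high-level dataset with benign/malignant proxy labels
#' drawn from shifted nucleus-morphology distributions.
#'
#' @param seed integer master seed; sub-seeds are derived as seed + stage
#'   index.
#' @param n_medium_per_cluster patches per medium cluster before filtering.
#' @param n_high_train_per_class,n_high_val_per_class,n_high_test_per_class
#'   high-level set sizes per class.
#' @param size rendered patch edge length (64 at desk scale).
#' @param input_size network input edge length after block averaging.
#' @param noise_sd render noise.
#' @param policy exclusion \code{\link{filter_policy}} for the medium set.
#' @return list with \code{medium} (x, y pseudo-labels, features,
#'   truth agreement), \code{high_train}, \code{high_val}, \code{high_test}
#'   (each x, y with 1 = benign, 2 = malignant).
#' @export
synthetic_benchmark <- function(seed,
                                n_medium_per_cluster = 100L,
                                n_high_train_per_class = 15L,
                                n_high_val_per_class = 30L,
                                n_high_test_per_class = 30L,
                                size = 64L, input_size = 32L,
                                noise_sd = 0.05,
                                policy = filter_policy(min_count = 3L)) {
  seed <- as.integer(seed)
  # medium-level population: clear few/large vs many/small contrast
  med_pop <- generate_cellwise_population(
    n_medium_per_cluster,
    cluster1 = cellwise_cluster_params(6, c(5, 8)),
    cluster2 = cellwise_cluster_params(18, c(2.5, 4)),
    size = size, noise_sd = noise_sd, seed = seed + 1L)
  feats <- lapply(med_pop, function(p) measure_nuclei(p$patch))
  features <- data.frame(
    total_area = vapply(feats, function(f) as.numeric(f$total_area), numeric(1)),
    count = vapply(feats, function(f) as.numeric(f$count), numeric(1)),
    mean_h = vapply(feats, function(f) f$mean_h, numeric(1)))
  features$idx <- seq_len(nrow(features))
  part <- filter_patches(features, policy)
  kept <- part$kept
  labels <- cluster_cellwise(kept, k = 2L, seed = seed + 2L)
  truth_kept <- vapply(med_pop[kept$idx], function(p) p$cluster_id, integer(1))
  agreement <- max(mean(labels == truth_kept), mean(labels != truth_kept))
  med_x <- patches_to_tensor(med_pop[kept$idx], input_size)
  # high-level proxy: shifted, overlapping morphology distributions
  high_one <- function(n_per_class, sd_seed) {
    pop <- generate_cellwise_population(
      n_per_class,
      cluster1 = cellwise_cluster_params(8, c(4, 7)),    # benign proxy
      cluster2 = cellwise_cluster_params(14, c(2.5, 4.5)),  # malignant proxy
      size = size, noise_sd = noise_sd, seed = sd_seed)
    list(x = patches_to_tensor(pop, input_size),
         y = vapply(pop, function(p) p$cluster_id, integer(1)))
  }
  list(medium = list(x = med_x, y = labels, features = kept,
                     n_excluded = nrow(part$excluded),
                     cluster_truth_agreement = agreement),
       high_train = high_one(n_high_train_per_class, seed + 3L),
       high_val = high_one(n_high_val_per_class, seed + 4L),
       high_test = high_one(n_high_test_per_class, seed + 5L))
}

#' Compare one-stage and two-stage fine-tuning on the synthetic benchmark
#'
#' Both schemes start from the identical t = 0 initialization. The
#' two-stage scheme fine-tunes on the cell-wise medium pseudo-labels first
#' (its own 90/10 split), then on the high-level training set; the
#' one-stage baseline trains on the high-level set only. Reported AUCs are
#' computed on the high-level validation set with the final
#' (validation-best) model of each scheme.
#'
#' @param seed master seed (drives benchmark generation, initialization and
#'   training shuffles).
#' @param bench optional precomputed \code{\link{synthetic_benchmark}}.
#' @param epochs_medium,epochs_high stage epochs.
#' @param lr,batch_size,momentum optimizer settings.
#' @param input_size,filters backbone settings.
#' @return list with \code{one_stage_auc}, \code{two_stage_auc}, the two
#'   training logs, and the benchmark bookkeeping.
#' @export
benchmark_compare <- function(seed, bench = NULL,
                              epochs_medium = 15L, epochs_high = 20L,
                              lr = 0.1, batch_size = 32L, momentum = 0.9,
                              input_size = 32L, filters = c(8L, 16L, 32L, 32L)) {
  seed <- as.integer(seed)
  if (is.null(bench)) bench <- synthetic_benchmark(seed, input_size = input_size)
  nm <- length(bench$medium$y)
  med_split <- assign_splits(bench$medium$y, 0.9, seed = seed + 6L)
  tr <- med_split == "train"
  medium_stage <- training_stage(
    bench$medium$x[, , , tr, drop = FALSE], bench$medium$y[tr],
    bench$medium$x[, , , !tr, drop = FALSE], bench$medium$y[!tr],
    n_classes = 2L, epochs = epochs_medium, lr = lr,
    batch_size = batch_size, momentum = momentum,
    seed = seed + 7L, name = "t1_medium_cell")
  high_stage <- training_stage(
    bench$high_train$x, bench$high_train$y,
    bench$high_val$x, bench$high_val$y,
    n_classes = 2L, epochs = epochs_high, lr = lr,
    batch_size = batch_size, momentum = momentum,
    seed = seed + 8L, name = "t2_high")
  two <- run_stepwise(stage_schedule(list(medium_stage, high_stage),
                                     init_seed = seed, input_size = input_size,
                                     filters = filters))
  one <- run_stepwise(stage_schedule(list(high_stage),
                                     init_seed = seed, input_size = input_size,
                                     filters = filters))
  val_auc <- function(model) {
    probs <- nn_predict(model, bench$high_val$x)
    roc_auc(probs[2L, ], bench$high_val$y == 2L)
  }
  list(one_stage_auc = val_auc(one$model),
       two_stage_auc = val_auc(two$model),
       one_stage = one, two_stage = two, bench = bench)
}
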