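TISSUE_CLASSES <- c("background", "epithelium", "stroma")

#' Extract tissue-wise patches from an annotation mask
#'
#' Tiles the mask with a non-overlapping grid of \code{patch_size} squares.
#' A grid cell is kept for class \code{c} iff at least \code{purity} of its
#' pixels carry \code{c}; cells straddling class boundaries are discarded.
#'
#' @param class_mask integer matrix with values 0 (background),
#'   1 (epithelium), 2 (stroma).
#' @param image optional image array whose first two dimensions must match
#'   the mask (patches are cut from it when supplied).
#' @param patch_size grid edge length in pixels, default 256.
#' @param purity minimum class fraction, default 0.9.
#' @return data.frame with one row per kept patch: \code{path} (a grid id),
#'   \code{row}, \code{col} (top-left corner), \code{label},
#'   \code{purity_frac}; when \code{image} is given, the cut patches are
#'   attached as the \code{"patches"} attribute.
#' @export
extract_tissue_patches <- function(class_mask, image = NULL,
                                   patch_size = 256L, purity = 0.9) {
  if (!is.matrix(class_mask)) stop("class_mask must be a matrix", call. = FALSE)
  if (!all(class_mask %in% 0:2))
    stop("class_mask values must be 0 (background), 1 (epithelium), 2 (stroma)",
         call. = FALSE)
  if (!is.null(image) && !all(dim(image)[1:2] == dim(class_mask)))
    stop("image and class_mask shapes differ", call. = FALSE)
  patch_size <- as.integer(patch_size)
  nr <- nrow(class_mask) %/% patch_size
  nc <- ncol(class_mask) %/% patch_size
  rows <- integer(0); cols <- integer(0); labs <- character(0); fracs <- numeric(0)
  patches <- list()
  for (gi in seq_len(nr)) {
    for (gj in seq_len(nc)) {
      r0 <- (gi - 1L) * patch_size + 1L
      c0 <- (gj - 1L) * patch_size + 1L
      cell <- class_mask[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
      counts <- tabulate(cell + 1L, nbins = 3L)
      best <- which.max(counts)
      frac <- counts[best] / length(cell)
      if (frac >= purity) {
        rows <- c(rows, r0); cols <- c(cols, c0)
        labs <- c(labs, TISSUE_CLASSES[best]); fracs <- c(fracs, frac)
        if (!is.null(image))
          patches[[length(patches) + 1L]] <-
            image[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L), , drop = FALSE]
      }
    }
  }
  out <- data.frame(path = sprintf("tile_r%d_c%d", rows, cols),
                    row = rows, col = cols, label = labs,
                    purity_frac = fracs, stringsAsFactors = FALSE)
  if (!is.null(image)) attr(out, "patches") <- patches
  out
}

#' Patch exclusion policy for the cell-wise dataset
#'
#' Patches with too few nuclei or too little hematoxylin signal (stain
#' inconformity: the stain cannot be unmixed reliably) are excluded before
#' clustering. The thresholds are package conventions; the criteria
#' themselves come from the dataset construction procedure.
#'
#' @param min_count minimum nucleus count (default 5).
#' @param min_mean_h minimum mean hematoxylin concentration (default 0.02).
#' @return list classed \code{"filter_policy"}.
#' @export
filter_policy <- function(min_count = 5L, min_mean_h = 0.02) {
  if (min_count < 0) stop("min_count must be >= 0", call. = FALSE)
  structure(list(min_count = as.integer(min_count), min_mean_h = min_mean_h),
            class = "filter_policy")
}

#' Partition patches into kept and excluded sets
#'
#' @param features data.frame with columns \code{count}, \code{total_area}
#'   and \code{mean_h} (one row per patch; extra columns pass through).
#' @param policy a \code{\link{filter_policy}}.
#' @return list with data.frames \code{kept} and \code{excluded}; the
#'   excluded table carries a \code{reason} column.
#' @export
filter_patches <- function(features, policy = filter_policy()) {
  stopifnot(is.data.frame(features),
            all(c("count", "mean_h") %in% names(features)))
  too_few <- features$count < policy$min_count
  low_h <- features$mean_h < policy$min_mean_h
  keep <- !too_few & !low_h
  reason <- ifelse(too_few & low_h, "too_few_nuclei;stain_inconformity",
                   ifelse(too_few, "too_few_nuclei",
                          ifelse(low_h, "stain_inconformity", "")))
  excluded <- features[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  else excluded$reason <- character(0)
  list(kept = features[keep, , drop = FALSE], excluded = excluded)
}

# k-means++ initial centers (deterministic given the RNG state)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' Pseudo-label patches by K-means on (total area, count)
#'
#' Features are z-scored (raw area, ~10^3-10^4 px^2, would otherwise swamp
#' the count, ~10^1), then clustered with Lloyd's algorithm initialized by
#' k-means++. Cluster identities follow the morphology semantics of the
#' cell-wise dataset: cluster 1 = fewer, larger nuclei (smaller mean count;
#' ties broken toward larger mean total area), cluster 2 = more, smaller
#' nuclei.
#'
#' @param features data.frame or matrix with columns \code{total_area} and
#'   \code{count}.
#' @param k number of clusters (default 2).
#' @param seed integer seed; fixed seed gives deterministic labels.
#' @param max_iter Lloyd iteration cap.
#' @param nstart independent k-means++ restarts; the solution with the
#'   lowest within-cluster sum of squares is kept (Lloyd's algorithm finds
#'   local optima, so a handful of restarts is standard practice).
#' @return integer vector of cluster labels in \code{1..k}, with the
#'   (z-scored) cluster centers attached as attribute \code{"centers"}.
#' @export
cluster_cellwise <- function(features, k = 2L, seed = NULL, max_iter = 100L,
                             nstart = 10L) {
  x <- as.matrix(as.data.frame(features)[, c("total_area", "count")])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain NA", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    stop(sprintf("need at least %d distinct feature vectors, got %d", k, n_distinct),
         call. = FALSE)
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant column: no information
  z <- z[, , drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  km <- NULL
  for (rep in seq_len(max(1L, nstart))) {
    init <- kmeanspp_centers(z, k)
    cand <- suppressWarnings(
      stats::kmeans(z, centers = init, iter.max = max_iter, algorithm = "Lloyd")
    )
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  cl <- km$cluster
  # reorder clusters by (mean count asc, mean total area desc)
  mean_count <- tapply(x[, "count"], cl, mean)
  mean_area <- tapply(x[, "total_area"], cl, mean)
  ord <- order(mean_count, -mean_area)
  remap <- integer(k)
  remap[as.integer(names(mean_count))[ord]] <- seq_len(k)
  out <- remap[cl]
  attr(out, "centers") <- km$centers[as.integer(names(mean_count))[ord], , drop = FALSE]
  out
}

#' 90/10 train/validation split arithmetic
#'
#' The training count is the rounded (half up) fraction of the total; the
#' remainder goes to validation. With the published cluster sizes 7,672 and
#' 6,457 this reproduces the printed (6,905, 767) and (5,811, 646) rows.
#'
#' @param n_items nonnegative item count.
#' @param train_fraction fraction assigned to training, default 0.9.
#' @return named integer vector \code{c(train = , validation = )}.
#' @export
split_train_val <- function(n_items, train_fraction = 0.9) {
  if (n_items < 0) stop("n_items must be >= 0", call. = FALSE)
  if (train_fraction < 0 || train_fraction > 1)
    stop("train_fraction must lie in [0, 1]", call. = FALSE)
  n_train <- floor(n_items * train_fraction + 0.5)  # round half up
  c(train = as.integer(n_train), validation = as.integer(n_items - n_train))
}

#' Assign stratified train/validation splits
#'
#' Shuffles within each stratum and applies \code{\link{split_train_val}}
#' arithmetic per stratum.
#'
#' @param labels stratum label per item.
#' @param train_fraction see \code{\link{split_train_val}}.
#' @param seed integer seed for the shuffle.
#' @return character vector of "train"/"validation" per item.
#' @export
assign_splits <- function(labels, train_fraction = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  split <- character(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    counts <- split_train_val(length(idx), train_fraction)
    shuffled <- sample(idx)
    split[shuffled[seq_len(counts["train"])]] <- "train"
    if (counts["validation"] > 0)
      split[shuffled[(counts["train"] + 1L):length(idx)]] <- "validation"
  }
  split
}

#' Build per-level dataset manifests with integrity checks
#'
#' Groups patch records by level and asserts the disjointness the dataset
#' design requires: no patch path may appear in more than one level (the
#' medium-level sets must not leak into the high-level set) and no path may
#' carry more than one split assignment.
#'
#' @param records data.frame with columns \code{path}, \code{level}
#'   (\code{medium_tissue}, \code{medium_cell} or \code{high}),
#'   \code{label}, \code{split} (\code{train}, \code{validation},
#'   \code{test}).
#' @return named list of per-level data.frames.
#' @export
build_manifests <- function(records) {
  required <- c("path", "level", "label", "split")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    stop("records must have columns path, level, label, split", call. = FALSE)
  if (nrow(records) == 0)
    return(stats::setNames(list(), character(0)))
  if (!all(records$level %in% c("medium_tissue", "medium_cell", "high")))
    stop("unknown level in records", call. = FALSE)
  if (!all(records$split %in% c("train", "validation", "test")))
    stop("unknown split in records", call. = FALSE)
  lv_per_path <- tapply(records$level, records$path, function(x) length(unique(x)))
  bad <- names(lv_per_path)[lv_per_path > 1]
  if (length(bad))
    stop("integrity error: path(s) present in multiple levels: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  sp_per_path <- tapply(records$split, records$path, function(x) length(unique(x)))
  bad <- names(sp_per_path)[sp_per_path > 1]
  if (length(bad))
    stop("integrity error: path(s) present in multiple splits: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  split(records, records$level, drop = TRUE)
}

#' Write a manifest as tab-separated text
#'
#' @param manifest data.frame of patch records.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
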