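#' Parameters of the Phansalkar local threshold
#'
#' @param k,r,p,q unit-free constants of the threshold formula; the defaults
#'   are the recommended values k = 0.25, r = 0.5, p = 2, q = 10.
#' @param window_radius radius (pixels) of the circular window over which
#'   local mean and standard deviation are computed. The source method does
#'   not fix a window size; 15 px is the package default for 256 x 256
#'   patches.
#' @return parameter list classed \code{"phansalkar_params"}.
#' @export
phansalkar_params <- function(k = 0.25, r = 0.5, p = 2, q = 10,
                              window_radius = 15L) {
  if (r == 0) stop("Phansalkar parameter r must be nonzero", call. = FALSE)
  if (window_radius < 1) stop("window_radius must be >= 1", call. = FALSE)
  structure(list(k = k, r = r, p = p, q = q,
                 window_radius = as.integer(window_radius)),
            class = "phansalkar_params")
}

#' Phansalkar adaptive threshold value
#'
#' Computes \code{T = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))}
#' from the local mean \code{mu} and local standard deviation \code{sigma}.
#' Vectorized over its inputs.
#'
#' @param mu local mean(s), in \code{[0, 1]}.
#' @param sigma local standard deviation(s), nonnegative.
#' @param params a \code{\link{phansalkar_params}} object.
#' @return threshold value(s), same shape as \code{mu}.
#' @export
phansalkar_threshold <- function(mu, sigma, params = phansalkar_params()) {
  if (any(sigma < 0)) stop("sigma must be nonnegative", call. = FALSE)
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]", call. = FALSE)
  mu * (1 + params$p * exp(-params$q * mu) + params$k * (sigma / params$r - 1))
}

#' Binarize a normalized hematoxylin map
#'
#' Each pixel is compared against its local Phansalkar threshold computed
#' over a circular window centered on it (edge replication at borders). In
#' a concentration map nuclei are bright, so foreground is \code{value > T};
#' set \code{dark_foreground = TRUE} for the original bright-background
#' cytology polarity (\code{value < T}).
#'
#' @param h_map numeric matrix in \code{[0, 1]} (see
#'   \code{\link{hematoxylin_map}}).
#' @param params a \code{\link{phansalkar_params}} object.
#' @param dark_foreground polarity flag, default \code{FALSE}.
#' @return logical matrix (the nuclei mask).
#' @export
binarize <- function(h_map, params = phansalkar_params(),
                     dark_foreground = FALSE) {
  if (!is.matrix(h_map)) stop("h_map must be a matrix", call. = FALSE)
  if (any(h_map < 0 | h_map > 1)) stop("h_map must lie in [0, 1]", call. = FALSE)
  if (2L * params$window_radius + 1L > min(dim(h_map)))
    stop("window diameter exceeds image size", call. = FALSE)
  st <- cpp_local_stats(h_map, params$window_radius)
  # guard against ~1e-16 drift from the incremental window sums
  thr <- phansalkar_threshold(pmin(pmax(st$mean, 0), 1), st$sd, params)
  if (dark_foreground) h_map < thr else h_map > thr
}

#' Split touching nuclei by seeded watershed
#'
#' Connected foreground regions are split on the negated Euclidean distance
#' transform: seeds are local maxima of the distance map thinned to a
#' minimum separation, and labels grow outward from the seeds (deepest
#' relief first). Regions smaller than \code{min_area} pixels are discarded
#' as specks and labels are renumbered consecutively.
#'
#' @param mask logical matrix.
#' @param min_seed_sep minimum seed separation in pixels (default 7).
#' @param min_area minimum region area in pixels^2 (default 15).
#' @return integer matrix of labels (background 0).
#' @export
split_touching <- function(mask, min_seed_sep = 7L, min_area = 15L) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  comp <- cpp_label_components(mask, 8L)
  dist <- cpp_distance_transform(mask)
  markers <- cpp_find_peaks(dist, comp, as.integer(min_seed_sep))
  lab <- cpp_watershed(dist, markers, mask)
  if (min_area > 0) {
    tab <- tabulate(lab[lab > 0L])
    small <- which(tab > 0L & tab < min_area)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  # renumber surviving labels 1..K in first-appearance order
  u <- unique(lab[lab > 0L])
  if (length(u)) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Trace outer nucleus contours by border following
#'
#' One outer boundary per label, traced clockwise by Moore border following
#' (the classic border-following scheme for binary images); holes are
#' ignored. The reported area is the filled pixel count of the label, not a
#' polygonal boundary area.
#'
#' @param labels integer matrix of region labels (background 0).
#' @return list of \code{"nucleus_contour"} objects, each with fields
#'   \code{boundary} (n x 2 matrix of (row, col) coordinates), \code{area}
#'   and \code{label}.
#' @export
trace_contours <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  res <- cpp_trace_contours(labels)
  out <- vector("list", length(res$labels))
  for (i in seq_along(out)) {
    out[[i]] <- structure(list(boundary = res$contours[[i]],
                               area = res$areas[i],
                               label = res$labels[i]),
                          class = "nucleus_contour")
  }
  out
}

#' Per-patch nuclei morphometry
#'
#' Full measurement pipeline for one patch: stain separation, hematoxylin
#' normalization, Phansalkar binarization, watershed splitting and contour
#' tracing. The result carries the two-dimensional feature used for
#' cell-wise pseudo-labelling: total nuclear area and nucleus count.
#'
#' @param patch an \code{\link{rgb_patch}}.
#' @param D deconvolution matrix.
#' @param params \code{\link{phansalkar_params}}.
#' @param min_seed_sep,min_area see \code{\link{split_touching}}.
#' @return object of class \code{"nuclei_morphometry"}: list with
#'   \code{contours}, \code{total_area}, \code{count} and \code{mean_h}
#'   (mean nonnegative hematoxylin concentration, used by the stain-quality
#'   filter).
#' @export
measure_nuclei <- function(patch, D = deconvolution_matrix(),
                           params = phansalkar_params(),
                           min_seed_sep = 7L, min_area = 15L) {
  maps <- separate_stains(patch, D)
  h_norm <- hematoxylin_map(maps)
  mask <- binarize(h_norm, params)
  lab <- split_touching(mask, min_seed_sep = min_seed_sep, min_area = min_area)
  contours <- trace_contours(lab)
  areas <- vapply(contours, function(ct) ct$area, integer(1))
  structure(list(contours = contours,
                 total_area = sum(areas),
                 count = length(contours),
                 mean_h = mean(pmax(maps$hematoxylin, 0))),
            class = "nuclei_morphometry")
}

#' @export
print.nuclei_morphometry <- function(x, ...) {
  cat(sprintf("<nuclei_morphometry: %d nuclei, total area %d px^2, mean H %.4f>\n",
              x$count, x$total_area, x$mean_h))
  invisible(x)
}
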