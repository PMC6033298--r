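#' Stain absorption basis for synthetic rendering
#'
#' Row \code{s} of the basis holds the per-channel absorption factors
#' \code{b_c} of stain \code{s} (hematoxylin, eosin, DAB): a pixel carrying
#' concentrations \code{A} transmits \code{I_c = 10^(-sum_s A_s b_{s,c})}.
#' The default basis is the exact inverse of
#' \code{\link{deconvolution_matrix}()} (transposed to row-per-stain), so the
#' renderer and the deconvolution module are exactly adjoint: deconvolving a
#' noiseless rendered patch recovers the rendered concentrations to machine
#' precision.
#'
#' @param m optional 3 x 3 matrix of absorption factors (rows = stains,
#'   columns = RGB); must be invertible.
#' @return 3 x 3 matrix classed \code{"stain_basis"}.
#' @export
stain_basis <- function(m = NULL) {
  if (is.null(m)) m <- t(solve(deconvolution_matrix()))
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || any(!is.finite(m)))
    stop("stain basis must be a finite 3 x 3 matrix", call. = FALSE)
  if (abs(det(m)) < 1e-12)
    stop("stain basis is not invertible (determinant ~ 0)", call. = FALSE)
  dimnames(m) <- list(c("hematoxylin", "eosin", "dab"), c("R", "G", "B"))
  structure(m, class = "stain_basis")
}

#' Specification of one synthetic nucleus
#'
#' @param center numeric length-2, (row, col) pixel coordinates of the
#'   ellipse center.
#' @param semi_axes numeric length-2, semi-axis lengths in pixels (> 0).
#' @param orientation rotation of the first semi-axis, radians.
#' @param hematoxylin nonnegative hematoxylin concentration added inside the
#'   ellipse.
#' @return a list classed \code{"nucleus_spec"}.
#' @export
nucleus_spec <- function(center, semi_axes, orientation = 0, hematoxylin = 0.7) {
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0", call. = FALSE)
  if (hematoxylin < 0) stop("hematoxylin amount must be nonnegative", call. = FALSE)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 hematoxylin = as.numeric(hematoxylin)),
            class = "nucleus_spec")
}

# fill an ellipse into accumulator `conc` and OR it into `umask`
rasterize_ellipse <- function(conc, umask, nuc) {
  h <- nrow(conc); w <- ncol(conc)
  r0 <- nuc$center[1]; c0 <- nuc$center[2]
  rmax <- max(nuc$semi_axes)
  rows <- max(1L, floor(r0 - rmax)):min(h, ceiling(r0 + rmax))
  cols <- max(1L, floor(c0 - rmax)):min(w, ceiling(c0 + rmax))
  if (!length(rows) || !length(cols)) return(list(conc = conc, umask = umask))
  dy <- rows - r0
  dx <- cols - c0
  ct <- cos(nuc$orientation); st <- sin(nuc$orientation)
  # rotated coordinates: u along the first semi-axis, v along the second
  U <- outer(dy, dx, function(y, x) (x * ct + y * st) / nuc$semi_axes[1])
  V <- outer(dy, dx, function(y, x) (-x * st + y * ct) / nuc$semi_axes[2])
  inside <- (U * U + V * V) <= 1
  if (any(inside)) {
    sub <- conc[rows, cols, drop = FALSE]
    sub[inside] <- sub[inside] + nuc$hematoxylin
    conc[rows, cols] <- sub
    um <- umask[rows, cols, drop = FALSE]
    um[inside] <- TRUE
    umask[rows, cols] <- um
  }
  list(conc = conc, umask = umask)
}

#' Render a synthetic H&E patch from nucleus specifications
#'
#' Nuclei are rasterized as filled ellipses that add hematoxylin
#' concentration (overlaps add); a uniform eosin background models
#' cytoplasm/stroma. Transmitted intensity per channel follows Beer-Lambert
#' absorption, \code{I_c = 10^(-sum_s A_s b_{s,c})}, with optional Gaussian
#' intensity noise clipped to \code{[0, 1]}.
#'
#' @param nuclei list of \code{\link{nucleus_spec}} objects (may be empty).
#' @param size integer length-1 or -2 patch dimensions (rows, cols).
#' @param basis a \code{\link{stain_basis}}.
#' @param background_eosin uniform eosin concentration.
#' @param noise_sd standard deviation of additive intensity noise (>= 0).
#' @param seed optional integer seed (noise reproducibility).
#' @param tissue_class one of "background", "epithelium", "stroma", "none".
#' @param cluster_id 1, 2 or NA.
#' @param bands optional numeric vector of band row-centers (epithelium
#'   ground truth, used by anisotropy diagnostics).
#' @return an object of class \code{"synthetic_patch"}: list with fields
#'   \code{patch} (\code{\link{rgb_patch}}), \code{nuclei},
#'   \code{true_count}, \code{true_total_area} (union pixel count, overlaps
#'   counted once), \code{tissue_class}, \code{cluster_id}, \code{bands}.
#' @export
render_patch <- function(nuclei = list(), size = c(256, 256),
                         basis = stain_basis(), background_eosin = 0.3,
                         noise_sd = 0, seed = NULL,
                         tissue_class = "none", cluster_id = NA_integer_,
                         bands = NULL) {
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size <= 0)) stop("patch dimensions must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (!inherits(basis, "stain_basis")) basis <- stain_basis(basis)
  tissue_class <- match.arg(tissue_class,
                            c("none", "background", "epithelium", "stroma"))
  h_conc <- matrix(0, size[1], size[2])
  umask <- matrix(FALSE, size[1], size[2])
  for (nuc in nuclei) {
    if (!inherits(nuc, "nucleus_spec")) stop("nuclei must be nucleus_spec objects", call. = FALSE)
    if (nuc$center[1] < 1 || nuc$center[1] > size[1] ||
        nuc$center[2] < 1 || nuc$center[2] > size[2])
      stop("nucleus center outside patch bounds", call. = FALSE)
    res <- rasterize_ellipse(h_conc, umask, nuc)
    h_conc <- res$conc; umask <- res$umask
  }
  e_conc <- matrix(background_eosin, size[1], size[2])
  img <- array(0, dim = c(size[1], size[2], 3L))
  for (ch in 1:3) {
    od <- h_conc * basis[1, ch] + e_conc * basis[2, ch]
    img[, , ch] <- 10^(-od)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(patch = rgb_patch(img),
                 nuclei = nuclei,
                 true_count = length(nuclei),
                 true_total_area = sum(umask),
                 tissue_class = tissue_class,
                 cluster_id = cluster_id,
                 bands = bands),
            class = "synthetic_patch")
}

#' @export
print.synthetic_patch <- function(x, ...) {
  cat(sprintf("<synthetic_patch %s: %d nuclei, area %d px^2, class=%s cluster=%s>\n",
              paste(dim(x$patch)[1:2], collapse = "x"), x$true_count,
              x$true_total_area, x$tissue_class,
              ifelse(is.na(x$cluster_id), "none", x$cluster_id)))
  invisible(x)
}

#' Cell-wise cluster parameter set
#'
#' @param count_lambda Poisson mean nucleus count per patch.
#' @param axis_range range of the major semi-axis, pixels.
#' @param hema_range range of per-nucleus hematoxylin concentration.
#' @param aspect_range range of minor/major axis ratio.
#' @return parameter list.
#' @export
cellwise_cluster_params <- function(count_lambda, axis_range,
                                    hema_range = c(0.5, 0.9),
                                    aspect_range = c(0.6, 1)) {
  stopifnot(count_lambda > 0, all(axis_range > 0))
  list(count_lambda = count_lambda, axis_range = axis_range,
       hema_range = hema_range, aspect_range = aspect_range)
}

# draw nucleus specs by rejection sampling; non-touching placement keeps
# bounding circles at least `gap` apart. Returns however many fit.
sample_nuclei <- function(n, size, params, non_touching = TRUE, gap = 2) {
  if (n <= 0) return(list())
  placed <- list()
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  attempts <- 0L
  while (length(placed) < n && attempts < 200L * n) {
    attempts <- attempts + 1L
    a <- runif(1, params$axis_range[1], params$axis_range[2])
    b <- a * runif(1, params$aspect_range[1], params$aspect_range[2])
    margin <- a + 1
    if (2 * margin >= min(size)) next
    ctr <- c(runif(1, margin, size[1] - margin), runif(1, margin, size[2] - margin))
    if (non_touching && length(radii)) {
      d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
      if (any(d < radii + a + gap)) next
    }
    placed[[length(placed) + 1L]] <-
      nucleus_spec(ctr, c(a, b), runif(1, 0, pi),
                   runif(1, params$hema_range[1], params$hema_range[2]))
    centers <- rbind(centers, ctr)
    radii <- c(radii, a)
  }
  placed
}

#' Generate a two-cluster cell-wise synthetic population
#'
#' Emulates the morphology contrast the automatic cell-wise dataset builder
#' exploits: cluster 1 patches carry fewer, larger nuclei; cluster 2 patches
#' carry more, smaller nuclei. Ground-truth cluster ids, counts and areas are
#' attached to every patch.
#'
#' @param n_per_cluster patches per cluster (0 gives an empty list).
#' @param cluster1,cluster2 \code{\link{cellwise_cluster_params}}; defaults:
#'   cluster 1 mean 8 nuclei with major semi-axis 7-12 px, cluster 2 mean 40
#'   nuclei with 3-5 px.
#' @param size patch dimensions.
#' @param noise_sd intensity noise.
#' @param eosin_range range of the uniform background eosin concentration.
#' @param non_touching if TRUE (default), nuclei are placed disjointly.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list of \code{"synthetic_patch"} objects, cluster 1 first.
#' @export
generate_cellwise_population <- function(n_per_cluster,
                                         cluster1 = cellwise_cluster_params(8, c(7, 12)),
                                         cluster2 = cellwise_cluster_params(40, c(3, 5)),
                                         size = c(256, 256), noise_sd = 0.02,
                                         eosin_range = c(0.2, 0.4),
                                         non_touching = TRUE, seed = NULL) {
  if (n_per_cluster < 0) stop("n_per_cluster must be >= 0", call. = FALSE)
  if (length(size) == 1L) size <- c(size, size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vector("list", 2L * n_per_cluster)
  i <- 0L
  for (cl in 1:2) {
    params <- if (cl == 1) cluster1 else cluster2
    for (j in seq_len(n_per_cluster)) {
      n <- max(1L, rpois(1, params$count_lambda))
      nuclei <- sample_nuclei(n, size, params, non_touching = non_touching)
      i <- i + 1L
      out[[i]] <- render_patch(nuclei, size = size,
                               background_eosin = runif(1, eosin_range[1], eosin_range[2]),
                               noise_sd = noise_sd, cluster_id = cl)
    }
  }
  out
}

#' Generate a three-class tissue-wise synthetic population
#'
#' Background patches are near-blank (almost no absorber); epithelium
#' patches carry nuclei organized along parallel bands (the ordered lining
#' arrangement of epithelial tissue); stroma patches carry sparse, uniformly
#' scattered nuclei (disordered connective tissue).
#'
#' @param n_per_class patches per tissue class.
#' @param size patch dimensions.
#' @param noise_sd intensity noise.
#' @param seed integer seed.
#' @return list of \code{"synthetic_patch"} objects with \code{tissue_class}
#'   set; epithelium patches also record their band row-centers in
#'   \code{bands}.
#' @export
generate_tissuewise_population <- function(n_per_class, size = c(256, 256),
                                           noise_sd = 0.02, seed = NULL) {
  if (n_per_class < 0) stop("n_per_class must be >= 0", call. = FALSE)
  if (length(size) == 1L) size <- c(size, size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  scale <- min(size) / 256
  out <- list()
  for (cls in c("background", "epithelium", "stroma")) {
    for (j in seq_len(n_per_class)) {
      if (cls == "background") {
        p <- render_patch(list(), size = size,
                          background_eosin = runif(1, 0, 0.05),
                          noise_sd = noise_sd, tissue_class = cls)
      } else if (cls == "epithelium") {
        nb <- sample(2:4, 1)
        bands <- size[1] * (seq_len(nb) - 0.5) / nb +
          rnorm(nb, 0, 0.02 * size[1])
        nuclei <- list()
        ax <- c(5, 8) * scale
        for (b in bands) {
          a <- runif(1, ax[1], ax[2])
          step <- 2 * ax[2] + 3 * scale
          xs <- seq(ax[2] + 2, size[2] - ax[2] - 2, by = step)
          xs <- xs + runif(length(xs), -1, 1) * scale
          for (x in xs) {
            y <- b + rnorm(1, 0, 2 * scale)
            y <- min(max(y, ax[2] + 2), size[1] - ax[2] - 2)
            x <- min(max(x, ax[2] + 2), size[2] - ax[2] - 2)
            nuclei[[length(nuclei) + 1L]] <-
              nucleus_spec(c(y, x), c(runif(1, ax[1], ax[2]), a * runif(1, 0.55, 0.75)),
                           0, runif(1, 0.5, 0.9))
          }
        }
        p <- render_patch(nuclei, size = size,
                          background_eosin = runif(1, 0.2, 0.4),
                          noise_sd = noise_sd, tissue_class = cls, bands = bands)
      } else {
        params <- cellwise_cluster_params(max(1, round(12 * scale^2)),
                                          c(4, 7) * scale)
        n <- max(1L, rpois(1, params$count_lambda))
        nuclei <- sample_nuclei(n, size, params)
        p <- render_patch(nuclei, size = size,
                          background_eosin = runif(1, 0.15, 0.35),
                          noise_sd = noise_sd, tissue_class = cls)
      }
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Ground-truth table of a synthetic population
#'
#' @param pop list of \code{"synthetic_patch"} objects.
#' @param paths optional character vector of per-patch paths/ids.
#' @return data.frame with columns path, tissue_class, cluster_id,
#'   true_count, true_total_area.
#' @export
population_truth <- function(pop, paths = NULL) {
  if (is.null(paths)) paths <- sprintf("patch_%04d.ppm", seq_along(pop))
  data.frame(
    path = paths,
    tissue_class = vapply(pop, function(p) p$tissue_class, character(1)),
    cluster_id = vapply(pop, function(p) as.integer(p$cluster_id), integer(1)),
    true_count = vapply(pop, function(p) p$true_count, integer(1)),
    true_total_area = vapply(pop, function(p) as.integer(p$true_total_area), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic population to disk
#'
#' Writes each patch as ASCII PPM plus a sidecar tab-separated manifest
#' (path, tissue_class, cluster_id, true_count, true_total_area).
#'
#' @param pop list of \code{"synthetic_patch"} objects.
#' @param dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("patch_%04d.ppm", seq_along(pop))
  for (i in seq_along(pop)) write_ppm(pop[[i]]$patch, file.path(dir, paths[i]))
  manifest <- population_truth(pop, paths)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
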