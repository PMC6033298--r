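#' The fixed H&E(+DAB) color deconvolution matrix
#'
#' Returns the 3 x 3 deconvolution matrix \code{D} used to unmix per-pixel
#' optical-density vectors into (hematoxylin, eosin, DAB) concentrations,
#' \code{C = D \%*\% od}. The default entries are the standard
#' Ruifrok-Johnston H&E-DAB values.
#'
#' @return 3 x 3 numeric matrix, rows named by stain, columns by RGB channel.
#' @export
deconvolution_matrix <- function() {
  matrix(c(1.88, -0.07, -0.60,
           -1.02, 1.13, -0.48,
           -0.55, -0.13, 1.57),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("hematoxylin", "eosin", "dab"), c("R", "G", "B")))
}

#' Convert an RGB patch to optical density
#'
#' Under Beer-Lambert absorption the optical density
#' \code{OD_c = -log10(I_c / I0_c)} is linear in stain concentration, unlike
#' the transmitted intensity. Incident intensity \code{I0_c} is taken as 1
#' (patches are normalized to \code{[0, 1]} on read). Intensities are floored
#' at \code{eps} before the log so saturated black pixels stay finite.
#'
#' @param patch an \code{\link{rgb_patch}} (values in \code{[0, 1]}).
#' @param eps intensity floor applied before the logarithm.
#' @return h x w x 3 array of nonnegative optical densities.
#' @export
optical_density <- function(patch, eps = 1e-6) {
  assert_patch(patch)
  -log10(pmax(unclass(patch), eps))
}

#' Separate stain concentration maps by color deconvolution
#'
#' Applies \code{C = D \%*\% od} at every pixel, where \code{od} is the
#' optical-density vector of the pixel in RGB space. The raw maps are not
#' clamped: slightly negative concentrations are a normal product of the
#' fixed matrix and are handled downstream (see
#' \code{\link{hematoxylin_map}}).
#'
#' @param patch an \code{\link{rgb_patch}}.
#' @param D deconvolution matrix, default \code{\link{deconvolution_matrix}()}.
#' @param eps intensity floor passed to \code{\link{optical_density}}.
#' @return an object of class \code{"stain_maps"}: a list with matrices
#'   \code{hematoxylin}, \code{eosin}, \code{dab} matching the patch shape.
#' @export
separate_stains <- function(patch, D = deconvolution_matrix(), eps = 1e-6) {
  if (!is.matrix(D) || !all(dim(D) == c(3, 3)) || any(!is.finite(D)))
    stop("deconvolution matrix must be a finite 3 x 3 matrix", call. = FALSE)
  od <- optical_density(patch, eps = eps)
  d <- dim(od)
  odm <- t(matrix(od, nrow = d[1] * d[2], ncol = 3))  # 3 x npix
  C <- D %*% odm
  maps <- list(
    hematoxylin = matrix(C[1, ], d[1], d[2]),
    eosin       = matrix(C[2, ], d[1], d[2]),
    dab         = matrix(C[3, ], d[1], d[2])
  )
  structure(maps, class = "stain_maps")
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps %d x %d; mean H %.4f, mean E %.4f>\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin),
              mean(x$hematoxylin), mean(x$eosin)))
  invisible(x)
}

#' Normalized hematoxylin map for thresholding
#'
#' The Phansalkar threshold presumes an image in \code{[0, 1]}, so the raw
#' hematoxylin concentration map is clipped at zero and rescaled by its
#' patch-wise maximum. Values below 1e-9 of the maximum are zeroed first:
#' they are cancellation residue of the matrix product (a hematoxylin-free
#' pixel unmixes to ~1e-17, not exactly 0), and a multiplicative local
#' threshold would otherwise binarize that machine noise. An all-zero map
#' (no absorber) is returned unchanged.
#'
#' @param maps a \code{"stain_maps"} object from \code{\link{separate_stains}}.
#' @return matrix in \code{[0, 1]}.
#' @export
hematoxylin_map <- function(maps) {
  h <- pmax(maps$hematoxylin, 0)
  mx <- max(h)
  if (mx > 0) {
    h[h < 1e-9 * mx] <- 0
    h <- h / mx
  }
  h
}
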