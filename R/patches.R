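#' RGB patch container
#'
#' An RGB patch is a numeric array of dimension height x width x 3 with all
#' intensities in \code{[0, 1]} (incident light is normalized to 1, so a
#' stain-free pixel is pure white). This is the unit of all processing.
#'
#' @param pixels numeric array, height x width x 3, values in \code{[0, 1]}.
#' @return the validated array, classed \code{"rgb_patch"}.
#' @export
rgb_patch <- function(pixels) {
  assert_patch(pixels)
  structure(pixels, class = "rgb_patch")
}

assert_patch <- function(pixels) {
  if (!is.numeric(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("patch must be a numeric height x width x 3 array", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("patch contains non-finite values", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 1))
    stop("patch intensities must lie in [0, 1]", call. = FALSE)
  invisible(pixels)
}

#' @export
print.rgb_patch <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_patch %d x %d, mean intensity %.3f>\n", d[1], d[2], mean(x)))
  invisible(x)
}

#' Read and write patches as plain-text PPM (P3)
#'
#' ASCII PPM is used as the on-disk patch format: it is a standard, fully
#' portable image format that needs no external codec. Intensities are
#' quantized to \code{maxval} levels on write and divided by \code{maxval}
#' on read, so values live in \code{[0, 1]} in memory.
#'
#' @param patch an \code{\link{rgb_patch}} or plain h x w x 3 array.
#' @param path file path.
#' @param maxval maximum sample value (default 255, i.e. 8-bit).
#' @return \code{write_ppm} returns \code{path} invisibly; \code{read_ppm}
#'   returns an \code{\link{rgb_patch}}.
#' @export
write_ppm <- function(patch, path, maxval = 255L) {
  assert_patch(patch)
  d <- dim(patch)
  q <- round(patch * maxval)
  # interleave channels pixel-by-pixel, row-major as PPM requires:
  # channel fastest, then column, then row
  flat <- as.integer(aperm(q, c(3L, 2L, 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), as.character(maxval)), con)
  writeLines(paste(flat, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop("only ASCII PPM (P3) is supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h * 3L) stop("corrupt PPM: wrong sample count", call. = FALSE)
  arr <- aperm(array(vals / maxval, dim = c(3L, w, h)), c(3L, 2L, 1L))
  rgb_patch(arr)
}

#' Downsample a patch by block averaging
#'
#' @param patch h x w x 3 array; both dimensions must be divisible by
#'   \code{factor}.
#' @param factor integer block edge length.
#' @return the downsampled array.
#' @export
downsample_patch <- function(patch, factor) {
  d <- dim(patch)
  if (any(d[1:2] %% factor != 0))
    stop("patch dimensions must be divisible by the downsampling factor", call. = FALSE)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  out <- array(0, dim = c(h2, w2, d[3]))
  for (ch in seq_len(d[3])) {
    m <- patch[, , ch]
    # average factor x factor blocks via two reshapes
    m1 <- array(m, dim = c(factor, h2, d[2]))
    m1 <- apply(m1, c(2, 3), mean)
    m2 <- array(t(m1), dim = c(factor, w2, h2))
    out[, , ch] <- t(apply(m2, c(2, 3), mean))
  }
  out
}
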