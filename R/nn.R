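# Minimal CNN backend. No deep-learning library is assumed: convolutions are
# im2col matrix products, so the whole model is plain R arrays and the
# backward pass is exact (verified against finite differences in the tests).
#
# Architecture: four 3x3 stride-2 convolution blocks with ReLU (stride-2
# convolution doubles as pooling), global average pooling, then a linear
# softmax head. The head is the only part that depends on the class count,
# which is what the stepwise fine-tuning scheme swaps between stages.

# gather indices for im2col of a 3x3 / stride-2 / pad-1 convolution on an
# s x s x cin input; returns a (9*cin) x out^2 matrix of 1-based indices
# into the zero-padded input flattened column-major as (s+2, s+2, cin)
conv_indices <- function(s, cin) {
  out <- (s - 1L) %/% 2L + 1L
  sp <- s + 2L
  i0 <- rep(0:(out - 1L), times = out)
  j0 <- rep(0:(out - 1L), each = out)
  base <- 2L * i0 + sp * (2L * j0)
  dyv <- rep(0:2, times = 3L * cin)
  dxv <- rep(rep(0:2, each = 3L), times = cin)
  civ <- rep(0:(cin - 1L), each = 9L)
  offv <- dyv + sp * dxv + sp * sp * civ
  idx <- outer(offv, base, "+") + 1L
  storage.mode(idx) <- "integer"
  idx
}

#' Construct the small desk-scale CNN
#'
#' @param input_size square input edge length (default 32; patches are
#'   block-averaged down to this size before training).
#' @param in_channels input channels (3 for RGB).
#' @param filters integer vector of per-block filter counts (4 blocks by
#'   default).
#' @param n_classes output classes (>= 2).
#' @param seed integer seed for He-initialized weights.
#' @return a \code{"histostep_model"}: list with \code{arch},
#'   \code{backbone} (per-block \code{W}, \code{b}) and \code{head}.
#' @export
small_cnn <- function(input_size = 32L, in_channels = 3L,
                      filters = c(8L, 16L, 32L, 32L), n_classes = 2L,
                      seed = NULL) {
  if (n_classes < 2) stop("head class count must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- as.integer(input_size)
  cin <- as.integer(in_channels)
  layers <- list()
  backbone <- list()
  for (f in as.integer(filters)) {
    if (s < 2) stop("too many blocks for this input size", call. = FALSE)
    out <- (s - 1L) %/% 2L + 1L
    layers[[length(layers) + 1L]] <-
      list(s_in = s, s_out = out, cin = cin, cout = f, idx = conv_indices(s, cin))
    backbone[[length(backbone) + 1L]] <-
      list(W = matrix(rnorm(9L * cin * f, sd = sqrt(2 / (9 * cin))), 9L * cin, f),
           b = numeric(f))
    s <- out
    cin <- f
  }
  model <- structure(
    list(arch = list(input_size = as.integer(input_size),
                     in_channels = as.integer(in_channels),
                     filters = as.integer(filters),
                     n_classes = as.integer(n_classes),
                     n_features = cin,
                     layers = layers),
         backbone = backbone,
         head = NULL),
    class = "histostep_model")
  init_head(model, as.integer(n_classes))
}

# head initialization scheme: Glorot-scaled Gaussian, zero bias
init_head <- function(model, n_classes) {
  f <- model$arch$n_features
  model$head <- list(W = matrix(rnorm(n_classes * f, sd = sqrt(1 / f)), n_classes, f),
                     b = numeric(n_classes))
  model$arch$n_classes <- n_classes
  model
}

#' Replace the classification head
#'
#' All backbone weights are preserved bit for bit; the head is
#' re-initialized from the declared scheme with the given seed. This is
#' explicitly not a no-op when the class count is unchanged: a fresh head is
#' drawn either way (the stepwise scheme re-initializes the head at every
#' stage boundary).
#'
#' @param model a \code{"histostep_model"}.
#' @param new_class_count new output class count (>= 2).
#' @param seed integer seed for the new head.
#' @return the model with a fresh head.
#' @export
swap_head <- function(model, new_class_count, seed = NULL) {
  if (new_class_count < 2) stop("head class count must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  init_head(model, as.integer(new_class_count))
}

#' @export
print.histostep_model <- function(x, ...) {
  cat(sprintf("<histostep_model: %dx%dx%d input, blocks [%s], %d classes>\n",
              x$arch$input_size, x$arch$input_size, x$arch$in_channels,
              paste(x$arch$filters, collapse = ","), x$arch$n_classes))
  invisible(x)
}

#' Mean training loss over a batch
#'
#' The cost minimized during training is the arithmetic mean of the
#' per-sample losses, \code{L = (1/N) * sum_i l_i}.
#'
#' @param per_sample_losses numeric vector of nonnegative losses (N >= 1).
#' @return the mean loss.
#' @export
mean_loss <- function(per_sample_losses) {
  if (length(per_sample_losses) == 0)
    stop("mean loss of an empty sample set is undefined", call. = FALSE)
  if (any(per_sample_losses < 0))
    stop("per-sample losses must be nonnegative", call. = FALSE)
  sum(per_sample_losses) / length(per_sample_losses)
}

# forward pass; x is (s, s, c, B) or (s, s, c). Returns class probabilities
# (n_classes x B) and, when keep_cache, the intermediates for backprop.
nn_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  B <- dim(x)[4]
  caches <- if (keep_cache) vector("list", length(model$backbone)) else NULL
  a <- x
  for (li in seq_along(model$backbone)) {
    ly <- model$arch$layers[[li]]
    wb <- model$backbone[[li]]
    sp <- ly$s_in + 2L
    xp <- array(0, dim = c(sp, sp, ly$cin, B))
    xp[2:(ly$s_in + 1L), 2:(ly$s_in + 1L), , ] <- a
    dim(xp) <- c(sp * sp * ly$cin, B)
    xcol <- xp[as.vector(ly$idx), , drop = FALSE]
    dim(xcol) <- c(9L * ly$cin, ly$s_out^2 * B)
    z <- crossprod(wb$W, xcol) + wb$b
    relu <- z > 0
    a2 <- z * relu
    if (keep_cache) caches[[li]] <- list(xcol = xcol, relu = relu)
    a <- aperm(array(a2, dim = c(ly$cout, ly$s_out, ly$s_out, B)), c(2, 3, 1, 4))
  }
  o <- model$arch$layers[[length(model$arch$layers)]]$s_out
  cf <- model$arch$n_features
  feat <- matrix(colMeans(matrix(a, o * o, cf * B)), cf, B)
  logits <- model$head$W %*% feat + model$head$b
  m <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, m))
  probs <- sweep(el, 2, colSums(el), "/")
  list(probs = probs, feat = feat, caches = caches, B = B)
}

#' Class probabilities for a batch of inputs
#'
#' @param model a \code{"histostep_model"}.
#' @param x input array \code{(s, s, channels, N)} (or a single
#'   \code{(s, s, channels)} patch).
#' @return \code{n_classes x N} matrix of softmax probabilities.
#' @export
nn_predict <- function(model, x) {
  nn_forward(model, x)$probs
}

# cross-entropy losses and gradients of the MEAN loss over the batch.
# y: integer labels in 1..n_classes.
nn_loss_grad <- function(model, x, y) {
  fw <- nn_forward(model, x, keep_cache = TRUE)
  B <- fw$B
  ncls <- model$arch$n_classes
  if (any(y < 1 | y > ncls)) stop("labels out of range", call. = FALSE)
  p_true <- fw$probs[cbind(y, seq_len(B))]
  losses <- -log(pmax(p_true, 1e-12))
  dlogits <- fw$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  g_headW <- dlogits %*% t(fw$feat)
  g_headb <- rowSums(dlogits)
  dfeat <- t(model$head$W) %*% dlogits
  nl <- length(model$backbone)
  o <- model$arch$layers[[nl]]$s_out
  cf <- model$arch$n_features
  da <- array(rep(as.vector(dfeat), each = o * o) / (o * o), dim = c(o, o, cf, B))
  g_backbone <- vector("list", nl)
  for (li in rev(seq_len(nl))) {
    ly <- model$arch$layers[[li]]
    wb <- model$backbone[[li]]
    cache <- fw$caches[[li]]
    dzm <- matrix(aperm(da, c(3, 1, 2, 4)), ly$cout, ly$s_out^2 * B) * cache$relu
    g_backbone[[li]] <- list(W = cache$xcol %*% t(dzm), b = rowSums(dzm))
    if (li > 1L) {
      dxcol <- wb$W %*% dzm
      dim(dxcol) <- c(9L * ly$cin * ly$s_out^2, B)
      rs <- rowsum(dxcol, group = as.vector(ly$idx))
      sp <- ly$s_in + 2L
      dxp <- matrix(0, sp * sp * ly$cin, B)
      dxp[as.integer(rownames(rs)), ] <- rs
      dim(dxp) <- c(sp, sp, ly$cin, B)
      da <- dxp[2:(ly$s_in + 1L), 2:(ly$s_in + 1L), , , drop = FALSE]
    }
  }
  list(losses = losses,
       grads = list(backbone = g_backbone, head = list(W = g_headW, b = g_headb)))
}

# one SGD-with-momentum update; returns updated model and velocity state
nn_sgd_step <- function(model, grads, state, lr, momentum) {
  if (is.null(state)) {
    state <- list(backbone = lapply(model$backbone, function(wb)
      list(W = wb$W * 0, b = wb$b * 0)),
      head = list(W = model$head$W * 0, b = model$head$b * 0))
  }
  for (li in seq_along(model$backbone)) {
    state$backbone[[li]]$W <- momentum * state$backbone[[li]]$W - lr * grads$backbone[[li]]$W
    state$backbone[[li]]$b <- momentum * state$backbone[[li]]$b - lr * grads$backbone[[li]]$b
    model$backbone[[li]]$W <- model$backbone[[li]]$W + state$backbone[[li]]$W
    model$backbone[[li]]$b <- model$backbone[[li]]$b + state$backbone[[li]]$b
  }
  state$head$W <- momentum * state$head$W - lr * grads$head$W
  state$head$b <- momentum * state$head$b - lr * grads$head$b
  model$head$W <- model$head$W + state$head$W
  model$head$b <- model$head$b + state$head$b
  list(model = model, state = state)
}

# order-insensitive fingerprint of a weight set (backbone preservation tests)
weight_checksum <- function(part) {
  v <- unlist(part, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v * v))
}
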