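#' Declarative layer specification
#'
#' @param kind One of `conv`, `maxpool`, `lrn`, `fc`, `relu`, `dropout`,
#'   `softmax`.
#' @param name Layer name (e.g. `"conv1"`).
#' @param kernel,stride,padding Geometry for conv/pool layers (pixels).
#' @param out_channels Conv filter count.
#' @param out_units Fully connected width.
#' @param dropout_p Dropout probability.
#' @param size,alpha,beta Local-response-normalization window and constants.
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(kind, name = kind, kernel = NULL, stride = NULL,
                       padding = 0L, out_channels = NULL, out_units = NULL,
                       dropout_p = NULL, size = NULL, alpha = NULL,
                       beta = NULL) {
  if (kind %in% c("conv", "maxpool")) {
    if (is.null(kernel) || kernel < 1) stop("kernel must be >= 1", call. = FALSE)
    if (is.null(stride) || stride < 1) stop("stride must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, name = name, kernel = kernel, stride = stride,
                 padding = padding, out_channels = out_channels,
                 out_units = out_units, dropout_p = dropout_p, size = size,
                 alpha = alpha, beta = beta),
            class = "layer_spec")
}

#' The default NBI-Net architecture
#'
#' A compact five-stage network for 64 x 64 RGB texture patches:
#' `conv1` (64 filters, 7x7, stride 2) widens the first-layer receptive
#' field; overlapping max pooling (3x3, stride 2, so stride < window)
#' regularizes; local response normalization follows `pool1`; `conv2`
#' (256 filters, 3x3, stride 1) captures higher abstraction with a smaller
#' kernel; a second overlapping pool feeds three fully connected layers of
#' widths 1024, 128, and 3 (`fc1`-`fc3`) with ReLU and dropout 0.5 after
#' `fc1` and `fc2`, and softmax as the output function. The conv1 stride of
#' 2 and zero padding are forced by the blob-shape table (64 -> 29 under
#' floor rounding with a 7-px kernel).
#'
#' @param cropping If TRUE the input is the 56 x 56 center/shifted crop
#'   instead of the full 64 x 64 patch.
#' @param lrn Include the LRN layer after pool1 (window 5, alpha 1e-4,
#'   beta 0.75).
#' @return An object of class `nbi_net_spec`.
#' @export
nbi_net_spec <- function(cropping = FALSE, lrn = TRUE) {
  side <- if (cropping) 56L else 64L
  layers <- list(
    layer_spec("conv", "conv1", kernel = 7L, stride = 2L, padding = 0L,
               out_channels = 64L),
    layer_spec("relu", "relu1"),
    layer_spec("maxpool", "pool1", kernel = 3L, stride = 2L),
    if (lrn) layer_spec("lrn", "lrn1", size = 5L, alpha = 1e-4, beta = 0.75),
    layer_spec("conv", "conv2", kernel = 3L, stride = 1L, padding = 0L,
               out_channels = 256L),
    layer_spec("relu", "relu2"),
    layer_spec("maxpool", "pool2", kernel = 3L, stride = 2L),
    layer_spec("fc", "fc1", out_units = 1024L),
    layer_spec("relu", "relu_fc1"),
    layer_spec("dropout", "drop1", dropout_p = 0.5),
    layer_spec("fc", "fc2", out_units = 128L),
    layer_spec("relu", "relu_fc2"),
    layer_spec("dropout", "drop2", dropout_p = 0.5),
    layer_spec("fc", "fc3", out_units = 3L),
    layer_spec("softmax", "softmax")
  )
  structure(list(input_shape = c(3L, side, side),
                 layers = Filter(Negate(is.null), layers)),
            class = "nbi_net_spec")
}

#' @export
build_default_spec <- nbi_net_spec

#' Deterministic blob-shape inference
#'
#' Walks the layer list applying the shape arithmetic: conv output side
#' `floor((in + 2 pad - kernel) / stride) + 1`, pool output side
#' `ceil((in - kernel) / stride) + 1`; ReLU/LRN/dropout preserve shape and
#' fc layers flatten. For the default spec this reproduces the reference
#' blob shapes for both the 64-px input (29, 14, 12, 6 spatial sides) and
#' the 56-px cropped input (25, 12, 10, 5).
#'
#' @param spec An `nbi_net_spec`.
#' @return Tibble with one row per layer: `layer, kind, channels, height,
#'   width, units, blob`.
#' @export
infer_shapes <- function(spec) {
  shp <- spec$input_shape
  cin <- shp[1]; h <- shp[2]; w <- shp[3]
  spatial <- TRUE
  units <- NA_integer_
  rows <- list(tibble::tibble(layer = "input", kind = "input", channels = cin,
                              height = h, width = w, units = NA_integer_,
                              blob = sprintf("%d x %d x %d", cin, h, w)))
  for (ls in spec$layers) {
    if (ls$kind == "conv") {
      h <- conv_out_side(h, ls$kernel, ls$stride, ls$padding)
      w <- conv_out_side(w, ls$kernel, ls$stride, ls$padding)
      cin <- ls$out_channels
      if (h < 1 || w < 1) {
        stop(sprintf("layer %s: non-positive output side", ls$name),
             call. = FALSE)
      }
    } else if (ls$kind == "maxpool") {
      h <- pool_out_side(h, ls$kernel, ls$stride)
      w <- pool_out_side(w, ls$kernel, ls$stride)
      if (h < 1 || w < 1) {
        stop(sprintf("layer %s: non-positive output side", ls$name),
             call. = FALSE)
      }
    } else if (ls$kind == "fc") {
      units <- ls$out_units
      spatial <- FALSE
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = ls$name, kind = ls$kind,
      channels = if (spatial) cin else NA_integer_,
      height = if (spatial) h else NA_integer_,
      width = if (spatial) w else NA_integer_,
      units = if (spatial) NA_integer_ else units,
      blob = if (spatial) sprintf("%d x %d x %d", cin, h, w)
             else sprintf("%d", units))
  }
  dplyr::bind_rows(rows)
}

#' Training configuration for NBI-Net
#'
#' Momentum SGD on the cross-entropy loss with the two-step learning-rate
#' schedule: the initial rate (0.01, or 0.005 for noisier data) is decreased
#' tenfold twice, at 50% and 75% of the epoch budget. Per-channel mean
#' removal is the only input preprocessing, computed on the training split
#' only.
#'
#' @param initial_lr Initial learning rate.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param lr_decay_at Epoch fractions at which the tenfold decays occur.
#' @param seed Seed controlling initialization, shuffling, and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, epochs = 50L, batch_size = 64L,
                         momentum = 0.9, weight_decay = 5e-4,
                         lr_decay_at = c(0.5, 0.75), seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (initial_lr <= 0) stop("initial_lr must be > 0", call. = FALSE)
  structure(list(initial_lr = initial_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, lr_decay_at = lr_decay_at,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Internal: stack a patch tibble into a D x N matrix with per-channel mean
# removed (mean supplied or computed).
stack_patches <- function(patches, side, channel_mean = NULL) {
  n <- nrow(patches)
  X <- matrix(0, side * side * 3, n)
  for (i in seq_len(n)) {
    p <- patches$pixels[[i]]
    if (dim(p)[1] != side || dim(p)[2] != side) {
      stop(sprintf("patch side %d does not match network input %d",
                   dim(p)[1], side), call. = FALSE)
    }
    X[, i] <- as.vector(p)
  }
  if (is.null(channel_mean)) {
    channel_mean <- vapply(1:3, function(ch) {
      mean(X[((ch - 1) * side^2 + 1):(ch * side^2), ])
    }, 0)
  }
  for (ch in 1:3) {
    rows <- ((ch - 1) * side^2 + 1):(ch * side^2)
    X[rows, ] <- X[rows, ] - channel_mean[ch]
  }
  list(X = X, channel_mean = channel_mean)
}

#' Train NBI-Net on a set of labeled patches
#'
#' @param patches Patch tibble with a `label` column; patch side must equal
#'   the spec's input side. At least two classes must be present.
#' @param config A [train_config].
#' @param spec An [nbi_net_spec].
#' @return A fitted network of class `nbi_net` holding the spec, weights,
#'   training channel means and per-epoch loss history. Deterministic for a
#'   fixed seed.
#' @export
nbi_train <- function(patches, config = train_config(), spec = nbi_net_spec()) {
  check_labels(patches$label)
  counts <- table(factor(patches$label, levels = ipcl_classes))
  present <- names(counts)[counts > 0]
  if (length(present) < 2) {
    stop("training data must contain at least 2 classes; got classes with ",
         "zero samples: ", paste(names(counts)[counts == 0], collapse = ", "),
         call. = FALSE)
  }
  side <- spec$input_shape[2]
  st <- stack_patches(patches, side)
  X <- st$X
  y <- match(patches$label, ipcl_classes)
  n <- ncol(X)
  compiled <- compile_net(spec)
  fc3_idx <- max(which(vapply(compiled$layers, `[[`, "", "kind") == "fc"))
  Y <- matrix(0, 3, n)
  Y[cbind(y, seq_len(n))] <- 1
  loss_hist <- numeric(config$epochs)
  with_seed(config$seed, {
    params <- lapply(compile_net(spec)$layers, function(l) NULL)
    params <- init_params(compiled, seed = sample.int(2^30, 1))
    vel <- lapply(params, function(p) {
      if (is.null(p)) NULL
      else list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b)))
    })
    decay_epochs <- floor(config$epochs * config$lr_decay_at)
    for (epoch in seq_len(config$epochs)) {
      lr <- config$initial_lr * 0.1^(sum(epoch > decay_epochs))
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        sel <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
        Xb <- X[, sel, drop = FALSE]
        Yb <- Y[, sel, drop = FALSE]
        fwd <- net_forward(Xb, compiled, params, train = TRUE, upto = fc3_idx)
        probs <- softmax_cols(fwd$out)
        batch_losses[bi] <- -mean(log(pmax(colSums(probs * Yb), 1e-12)))
        dlogits <- (probs - Yb) / length(sel)
        grads <- net_backward(dlogits, compiled, params, fwd$caches, fc3_idx)
        for (li in seq_along(params)) {
          if (is.null(params[[li]])) next
          g <- grads[[li]]
          # in-place update; params/vel are owned solely by this loop
          nn_sgd_step(params[[li]]$W, vel[[li]]$W, g$dW, lr,
                      config$momentum, config$weight_decay)
          nn_sgd_step(params[[li]]$b, vel[[li]]$b, g$db, lr,
                      config$momentum, 0)
        }
      }
      loss_hist[epoch] <- mean(batch_losses)
    }
    structure(list(spec = spec, compiled = compiled, params = params,
                   training_mean = st$channel_mean, loss_history = loss_hist,
                   config = config, classes = ipcl_classes),
              class = "nbi_net")
  })
}

#' @export
print.nbi_net <- function(x, ...) {
  cat(sprintf("<nbi_net: input %s, %d parameters, trained %d epochs, final loss %.4f>\n",
              paste(x$spec$input_shape, collapse = "x"), n_parameters(x$spec),
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' Total trainable parameter count of a spec
#'
#' @param spec An [nbi_net_spec] (or a fitted `nbi_net`).
#' @return Integer parameter count (weights + biases).
#' @export
n_parameters <- function(spec) {
  if (inherits(spec, "nbi_net")) spec <- spec$spec
  compiled <- compile_net(spec)
  sum(vapply(compiled$layers, function(l) {
    if (l$kind == "conv") l$K * l$cout + l$cout
    else if (l$kind == "fc") l$din * l$dout + l$dout
    else 0
  }, 0))
}

# Internal batched forward in evaluation mode (dropout off).
net_eval_forward <- function(net, patches, upto = NULL, chunk = 256L) {
  side <- net$spec$input_shape[2]
  n <- nrow(patches)
  out <- NULL
  for (s in seq(1, n, by = chunk)) {
    sel <- s:min(s + chunk - 1, n)
    X <- stack_patches(patches[sel, ], side, net$training_mean)$X
    o <- net_forward(X, net$compiled, net$params, train = FALSE, upto = upto)$out
    out <- cbind(out, o)
  }
  out
}

#' Per-patch softmax class probabilities
#'
#' @param net A fitted [nbi_train()] network.
#' @param patches Patch tibble.
#' @return Tibble with probability columns `p_A, p_B1, p_B2_B3` (each row a
#'   probability vector) and the argmax `.pred_class`.
#' @export
predict_softmax <- function(net, patches) {
  probs <- t(net_eval_forward(net, patches))
  colnames(probs) <- paste0("p_", ipcl_classes)
  out <- tibble::as_tibble(probs)
  out$.pred_class <- ipcl_classes[max.col(probs, ties.method = "first")]
  out
}

#' Extract fully connected layer activations as a feature matrix
#'
#' Features are taken after the layer's affine transform and its ReLU where
#' present (`fc1`, `fc2`); `fc3` activations are the pre-softmax logits.
#' Dropout is disabled, so extraction is deterministic.
#'
#' @param net A fitted network.
#' @param patches Patch tibble.
#' @param layer `"fc1"` (1024-d), `"fc2"` (128-d), or `"fc3"` (3-d).
#' @return Numeric matrix, one row per patch.
#' @export
extract_features <- function(net, patches, layer = c("fc1", "fc2", "fc3")) {
  layer <- match.arg(layer)
  names_ <- vapply(net$compiled$layers, `[[`, "", "name")
  idx <- which(names_ == layer)
  if (length(idx) != 1) stop(sprintf("unknown layer '%s'", layer), call. = FALSE)
  # include the ReLU directly following the fc layer, if any
  if (idx < length(names_) && net$compiled$layers[[idx + 1]]$kind == "relu") {
    idx <- idx + 1
  }
  t(net_eval_forward(net, patches, upto = idx))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nbi_net <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
glance.nbi_net <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss_history),
                 final_loss = tail(x$loss_history, 1),
                 n_parameters = n_parameters(x$spec),
                 input_side = x$spec$input_shape[2])
}
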