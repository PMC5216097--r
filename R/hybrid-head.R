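#' Soft-margin SVM head configuration
#'
#' The classifier head solves the usual soft-margin problem
#' `min 1/2 w'w + C sum(xi)` subject to `y_i (w'x_i + b) >= 1 - xi_i`,
#' `xi_i >= 0`, optionally through a kernel. Multiclass prediction uses the
#' one-against-one strategy: one binary classifier per unordered class pair,
#' the class with the most votes winning.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Penalty parameter trading margin width against training error.
#' @param gamma RBF kernel width; defaults to `1/dim` at fit time.
#' @param standardize Center/scale features using training statistics
#'   (default on: CNN activations are nonnegative and scale-skewed).
#' @param pca Optional retained-variance fraction in (0, 1]; PCA is off by
#'   default and, like standardization, is fit on training rows only.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), C = 1, gamma = NULL,
                       standardize = TRUE, pca = NULL) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.null(pca) && (pca <= 0 || pca > 1)) {
    stop("pca must be a retained-variance fraction in (0, 1]", call. = FALSE)
  }
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 standardize = isTRUE(standardize), pca = pca),
            class = "svm_config")
}

#' Fit a one-against-one SVM head
#'
#' Trains `k(k-1)/2` binary soft-margin SVMs (dual solver, tolerance 1e-3),
#' one per unordered pair of the classes present. Standardization and PCA
#' parameters are estimated from the training rows only.
#'
#' @param features Numeric feature matrix, one row per sample (fc-layer
#'   activations or classical descriptors).
#' @param labels Class label per row.
#' @param config An [svm_config].
#' @return An object of class `ipcl_ovo`.
#' @export
fit_ovo <- function(features, labels, config = svm_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  check_labels(labels)
  classes <- intersect(ipcl_classes, unique(labels))
  if (length(classes) < 2) {
    stop("need at least 2 classes to fit the SVM head", call. = FALSE)
  }
  scaler <- NULL
  X <- features
  if (config$standardize) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    # near-constant features (e.g. dead ReLU units) carry no signal on the
    # training rows but can take large values on new rows; dividing by their
    # tiny sd would let them dominate the kernel, so they are left unscaled
    sdev[sdev < 1e-3 * max(sdev, 1e-12) | sdev < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    scaler <- list(center = mu, scale = sdev)
  }
  rotation <- NULL
  if (!is.null(config$pca)) {
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    keep <- seq_len(max(1L, which(cum >= config$pca)[1]))
    rotation <- pc$rotation[, keep, drop = FALSE]
    X <- X %*% rotation
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    yf <- factor(labels[sel], levels = pr)
    e1071::svm(X[sel, , drop = FALSE], yf, kernel = config$kernel,
               cost = config$C, gamma = gamma, scale = FALSE,
               tolerance = 1e-3)
  })
  structure(list(models = models, pairs = pairs, classes = classes,
                 scaler = scaler, rotation = rotation, config = config,
                 dim = ncol(features)),
            class = "ipcl_ovo")
}

#' @export
print.ipcl_ovo <- function(x, ...) {
  cat(sprintf("<ipcl_ovo: %d pairwise %s-kernel SVMs over %s (input dim %d)>\n",
              length(x$models), x$config$kernel,
              paste(x$classes, collapse = "/"), x$dim))
  invisible(x)
}

# Internal: apply stored standardization/PCA to new rows.
ovo_transform <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != model$dim) {
    stop(sprintf("feature dimension %d does not match the fitted head (%d)",
                 ncol(X), model$dim), call. = FALSE)
  }
  if (!is.null(model$scaler)) {
    X <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  }
  if (!is.null(model$rotation)) X <- X %*% model$rotation
  X
}

#' Predict with majority voting over the pairwise classifiers
#'
#' Every pairwise classifier casts one vote per sample; the label is the
#' class with the most votes. Vote ties are broken by the largest summed
#' absolute decision value accumulated by the tied classes, then by the
#' lowest class index in the `A < B1 < B2_B3` ordering.
#'
#' @param model An [fit_ovo()] head.
#' @param features Feature matrix with the dimensionality the head was fit
#'   on.
#' @return Tibble with `.pred_class`, one `votes_<class>` column per class,
#'   and the per-class summed absolute decision values `margin_<class>`.
#' @export
predict_votes <- function(model, features) {
  X <- ovo_transform(model, features)
  n <- nrow(X)
  k <- length(model$classes)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$classes))
  dsum <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  for (m in seq_along(model$models)) {
    pr <- model$pairs[[m]]
    pred <- predict(model$models[[m]], X, decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    win <- as.character(pred)
    for (cl in pr) {
      hit <- win == cl
      votes[hit, cl] <- votes[hit, cl] + 1L
      dsum[hit, cl] <- dsum[hit, cl] + abs(dv[hit])
    }
  }
  pick <- vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[dsum[i, top] == max(dsum[i, top])]
      top <- best[1]                       # lowest class index last
    }
    model$classes[top[1]]
  }, "")
  out <- tibble::tibble(.pred_class = pick)
  for (cl in model$classes) out[[paste0("votes_", cl)]] <- unname(votes[, cl])
  for (cl in model$classes) out[[paste0("margin_", cl)]] <- unname(dsum[, cl])
  out
}

#' @export
tidy.ipcl_ovo <- function(x, ...) {
  tibble::tibble(
    pair = vapply(x$pairs, paste, "", collapse = " vs "),
    n_support_vectors = vapply(x$models, function(m) m$tot.nSV, 0L),
    kernel = x$config$kernel,
    C = x$config$C
  )
}

#' @export
glance.ipcl_ovo <- function(x, ...) {
  tibble::tibble(n_classifiers = length(x$models),
                 n_classes = length(x$classes),
                 kernel = x$config$kernel, C = x$config$C,
                 standardized = !is.null(x$scaler),
                 pca_components = if (is.null(x$rotation)) NA_integer_
                                  else ncol(x$rotation))
}

#' Compare the softmax head with an SVM head on held-out patches
#'
#' Fits a linear SVM on fc-layer features of the training patches and
#' evaluates both heads on the same test patches, reporting both accuracies
#' and their difference (the "classifier boosting" of swapping softmax for
#' an SVM).
#'
#' @param net A fitted [nbi_train()] network.
#' @param train_patches,test_patches Patch tibbles with `label` columns.
#' @param layers fc layers to compare on.
#' @param config An [svm_config] for the SVM head.
#' @return Tibble with one row per layer: `layer, acc_softmax, acc_svm,
#'   boost`.
#' @export
compare_heads <- function(net, train_patches, test_patches,
                          layers = "fc1", config = svm_config()) {
  soft <- predict_softmax(net, test_patches)
  acc_soft <- mean(soft$.pred_class == test_patches$label)
  rows <- lapply(layers, function(ly) {
    tr <- extract_features(net, train_patches, ly)
    te <- extract_features(net, test_patches, ly)
    head_ <- fit_ovo(tr, train_patches$label, config)
    acc_svm <- mean(predict_votes(head_, te)$.pred_class ==
                      test_patches$label)
    tibble::tibble(layer = ly, acc_softmax = acc_soft, acc_svm = acc_svm,
                   boost = acc_svm - acc_soft)
  })
  dplyr::bind_rows(rows)
}
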