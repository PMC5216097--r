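#' Continuous Gaussian patch weight
#'
#' The weight a patch vote carries at distance `d` (pixels) from the patch
#' center: `exp(-d^2 / (2 sigma^2))`. The default width `sigma = w/4` makes
#' votes strongly center-weighted; at the geometric patch corner
#' (`d = w sqrt(2) / 2`) the weight falls to about 2e-4 of the center value.
#'
#' @param d Distance from the patch center in pixels.
#' @param sigma Gaussian width in pixels.
#' @return Weight in (0, 1].
#' @export
gaussian_patch_weight <- function(d, sigma) exp(-d^2 / (2 * sigma^2))

# Discrete w x w kernel sampled at pixel centers (symmetric).
gaussian_kernel <- function(w, sigma) {
  off <- (seq_len(w) - 0.5) - w / 2
  g1 <- gaussian_patch_weight(off, sigma)
  outer(g1, g1)
}

#' Accumulate Gaussian-weighted patch votes into a vote map
#'
#' Every patch adds, over its own `w x w` footprint, a Gaussian weight
#' centered on the patch to the score plane of its predicted class and to
#' the total-weight plane. Accumulation is additive, hence
#' order-independent. With `predictions` given as a probability matrix the
#' vote is split across classes ("soft" voting); with a label vector each
#' patch casts a hard vote for its predicted class.
#'
#' @param predictions Character vector of predicted labels (length
#'   `nrow(patches)`), or a numeric matrix of per-class probabilities with
#'   columns in [ipcl_classes] order.
#' @param patches Patch tibble carrying the footprint coordinates `x, y`
#'   (0-based upper-left, in the frame of `image_shape`).
#' @param image_shape `c(height, width)` of the target frame.
#' @param sigma Gaussian width; default `w/4`.
#' @return An object of class `ipcl_votemap`: list of `scores`
#'   (`H x W x 3`), `weight_total` (`H x W`), and `sigma`.
#' @export
accumulate_votes <- function(predictions, patches, image_shape,
                             sigma = NULL) {
  h <- image_shape[1]; w_img <- image_shape[2]
  n <- nrow(patches)
  if (n > 0) {
    w <- dim(patches$pixels[[1]])[1]
  } else {
    w <- 64L
  }
  if (is.null(sigma)) sigma <- w / 4
  probs <- if (is.matrix(predictions)) {
    if (nrow(predictions) != n || ncol(predictions) != 3) {
      stop("probability matrix must be n x 3", call. = FALSE)
    }
    predictions
  } else {
    if (length(predictions) != n) {
      stop("one prediction per patch is required", call. = FALSE)
    }
    check_labels(predictions, "prediction")
    m <- matrix(0, n, 3)
    m[cbind(seq_len(n), match(predictions, ipcl_classes))] <- 1
    m
  }
  scores <- array(0, c(h, w_img, 3))
  weight_total <- matrix(0, h, w_img)
  if (n > 0) {
    G <- gaussian_kernel(w, sigma)
    for (i in seq_len(n)) {
      x <- patches$x[i]; y <- patches$y[i]
      if (x < 0 || y < 0 || x + w > w_img || y + w > h) {
        stop(sprintf("patch %d footprint outside image bounds", i),
             call. = FALSE)
      }
      rows <- (y + 1):(y + w); cols <- (x + 1):(x + w)
      for (cl in 1:3) {
        if (probs[i, cl] > 0) {
          scores[rows, cols, cl] <- scores[rows, cols, cl] + G * probs[i, cl]
        }
      }
      weight_total[rows, cols] <- weight_total[rows, cols] + G
    }
  }
  structure(list(scores = scores, weight_total = weight_total, sigma = sigma),
            class = "ipcl_votemap")
}

#' Map augmented-frame patch coordinates back to the base frame
#'
#' Patches generated from rescaled and/or rotated images carry coordinates
#' in the transformed frame. For synthesis in the original frame, the patch
#' center is pushed through the inverse rotation/flip and inverse rescale,
#' and the footprint is re-anchored as an axis-aligned square of the patch
#' side around the mapped center (rotations are multiples of 90 degrees, so
#' the footprint stays axis-aligned; only rescaling is approximated by
#' keeping the nominal patch side).
#'
#' @param patches Patch tibble (columns `x, y, scale_mode, rotflip_mode`).
#' @param base_shape `c(height, width)` of the base frame.
#' @param rescale_cfg The [rescale_config] used during augmentation.
#' @param base_mode Scale mode of the base frame.
#' @return The patch tibble with `x, y` rewritten in base-frame coordinates
#'   (clipped to bounds) and modes reset.
#' @export
map_patches_to_base <- function(patches, base_shape,
                                rescale_cfg = rescale_config(),
                                base_mode = 5L) {
  if (nrow(patches) == 0) return(patches)
  w <- dim(patches$pixels[[1]])[1]
  h0 <- base_shape[1]; w0 <- base_shape[2]
  for (i in seq_len(nrow(patches))) {
    r <- rescale_cfg$k^(patches$scale_mode[i] - base_mode)
    ht <- round(h0 * r); wt <- round(w0 * r)
    cx <- patches$x[i] + w / 2; cy <- patches$y[i] + w / 2
    f <- patches$rotflip_mode[i]
    # invert the rotation part (f %% 4 CCW quarter-turns), then the flip
    for (q in seq_len((4 - f %% 4) %% 4)) {
      tmp <- cx; cx <- cy; cy <- wt - tmp
      wt_ <- wt; wt <- ht; ht <- wt_
    }
    if (f >= 4) cx <- wt - cx
    cx <- cx / r; cy <- cy / r
    patches$x[i] <- as.integer(min(max(round(cx - w / 2), 0), w0 - w))
    patches$y[i] <- as.integer(min(max(round(cy - w / 2), 0), h0 - w))
  }
  patches$scale_mode <- as.integer(base_mode)
  patches$rotflip_mode <- 0L
  patches
}

#' Colorize a vote map into an RGBA overlay
#'
#' The argmax class at every covered pixel is painted green (A), blue (B1),
#' or red (B2_B3); pixels with zero accumulated weight stay transparent.
#' Score ties are broken in the fixed order A > B1 > B2_B3.
#'
#' @param votemap An [accumulate_votes()] result.
#' @param alpha Opacity of covered pixels.
#' @return `H x W x 4` RGBA array in `[0, 1]`.
#' @export
colorize <- function(votemap, alpha = 1) {
  h <- dim(votemap$scores)[1]; w <- dim(votemap$scores)[2]
  out <- array(0, c(h, w, 4))
  covered <- votemap$weight_total > 0
  flat <- matrix(votemap$scores, h * w, 3)
  best <- max.col(flat, ties.method = "first")   # first = A > B1 > B2_B3
  chan <- c(2, 3, 1)                             # A->G, B1->B, B2_B3->R
  for (cl in 1:3) {
    plane <- matrix(0, h, w)
    plane[covered & matrix(best == cl, h, w)] <- 1
    out[, , chan[cl]] <- plane
  }
  out[, , 4][covered] <- alpha
  out
}

#' Assign cases to cross-validation folds
#'
#' Folds are sliced at the case (patient) level: images of one case share
#' texture characteristics and patches overlap within an image, so
#' patch-level slicing would leak test information into training. Cases are
#' shuffled with a seeded RNG and dealt round-robin within each class
#' label (stratification), and every patch later inherits its case's fold.
#'
#' @param cases Data frame with columns `case_id` and `label` (one row per
#'   case; duplicated rows are collapsed).
#' @param k Number of folds; must not exceed the number of cases.
#' @param seed RNG seed.
#' @return A tibble `case_id, label, fold` of class `ipcl_foldplan`.
#' @export
make_folds <- function(cases, k = 5L, seed = 1L) {
  cases <- dplyr::distinct(tibble::as_tibble(cases[c("case_id", "label")]))
  if (anyDuplicated(cases$case_id)) {
    stop("a case_id appears under two labels", call. = FALSE)
  }
  if (k > nrow(cases)) {
    stop(sprintf("k = %d exceeds the %d available cases", k, nrow(cases)),
         call. = FALSE)
  }
  with_seed(derive_seed(seed, "folds"), {
    out <- list()
    offset <- 0L
    for (lb in unique(cases$label)) {
      ids <- cases$case_id[cases$label == lb]
      ids <- sample(ids)
      fold <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- offset + length(ids)
      out[[lb]] <- tibble::tibble(case_id = ids, label = lb, fold = fold)
    }
    structure(dplyr::bind_rows(out), class = c("ipcl_foldplan",
                                               class(tibble::tibble())))
  })
}

#' Pooled cross-validation metrics
#'
#' Aggregated accuracy pools the held-out predictions of all folds before
#' computing the fraction correct. Per-class average precision ranks all
#' samples by the class score and averages the precision at each positive's
#' rank (no interpolation), one-vs-rest; macro AP is the unweighted mean
#' over classes.
#'
#' @param predictions Character vector of predicted labels.
#' @param labels True labels, same length.
#' @param scores Optional `n x 3` score matrix (columns in [ipcl_classes]
#'   order) for average precision.
#' @return An object of class `ipcl_metrics`: accuracy, confusion matrix
#'   (rows = truth), per-class AP, macro AP, n.
#' @export
evaluate_predictions <- function(predictions, labels, scores = NULL) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  check_labels(labels)
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  conf <- table(factor(labels, ipcl_classes), factor(predictions, ipcl_classes))
  acc <- sum(diag(conf)) / length(labels)
  ap <- rep(NA_real_, 3)
  names(ap) <- ipcl_classes
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    for (cl in seq_along(ipcl_classes)) {
      pos <- labels == ipcl_classes[cl]
      if (!any(pos)) next
      ord <- order(scores[, cl], decreasing = TRUE)
      hits <- pos[ord]
      prec_at <- cumsum(hits) / seq_along(hits)
      ap[cl] <- mean(prec_at[hits])
    }
  }
  structure(list(accuracy = acc, confusion = unclass(conf),
                 average_precision = ap,
                 macro_ap = mean(ap, na.rm = TRUE),
                 n = length(labels)),
            class = "ipcl_metrics")
}

#' @export
print.ipcl_metrics <- function(x, ...) {
  cat(sprintf("<ipcl_metrics: n = %d, accuracy = %.3f", x$n, x$accuracy))
  if (!all(is.na(x$average_precision))) {
    cat(sprintf(", macro AP = %.3f", x$macro_ap))
  }
  cat(">\n")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.ipcl_metrics <- function(x, ...) {
  tibble::tibble(class = ipcl_classes,
                 n_true = rowSums(x$confusion),
                 n_predicted = colSums(x$confusion),
                 n_correct = diag(x$confusion),
                 average_precision = unname(x$average_precision))
}

#' @export
glance.ipcl_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_ap = x$macro_ap, n = x$n)
}

#' Write an overlay PNG (and per-pixel class TIFF) for a vote map
#'
#' @param votemap An [accumulate_votes()] result.
#' @param png_path Output RGBA PNG path.
#' @param tiff_path Optional per-pixel class-index TIFF (0 = uncovered,
#'   1..3 = class index).
#' @return `png_path`, invisibly.
#' @export
write_overlay <- function(votemap, png_path, tiff_path = NULL) {
  rgba <- colorize(votemap)
  png::writePNG(rgba, png_path)
  if (!is.null(tiff_path)) {
    h <- dim(votemap$scores)[1]; w <- dim(votemap$scores)[2]
    flat <- matrix(votemap$scores, h * w, 3)
    cls <- max.col(flat, ties.method = "first")
    cls[as.vector(votemap$weight_total) == 0] <- 0
    tiff::writeTIFF(matrix(cls / 255, h, w), tiff_path)
  }
  invisible(png_path)
}
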