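#' Classical texture descriptor configurations
#'
#' Three conventional baselines with closed-form dimensions:
#'
#' * PHOW: dense SIFT descriptors at several scales, quantized against a
#'   learned codebook of visual words and histogrammed over a 2-level
#'   spatial pyramid of 2x2 and 4x4 cells; dimension
#'   `n_words * (4 + 16) = 4000` at the default 200 words.
#' * Uniform-58 LBP: 8-neighbor radius-1 local binary patterns restricted
#'   to the 58 patterns with at most two circular transitions, histogrammed
#'   per 16x16 cell; dimension `(64/16)^2 * 58 = 928` on a 64-px patch.
#' * PHOG: gradient-orientation histograms with 8 angle bins over a 4-level
#'   pyramid of 1x1, 2x2, 4x4 and 8x8 cells; dimension
#'   `8 * (1 + 4 + 16 + 64) = 680`.
#'
#' @param n_words Codebook size (visual words).
#' @param pyramid Integer vector of cell-grid sides, coarse to fine.
#' @param sift_bins Dense-SIFT spatial bin sizes (px), one scale each.
#' @param step Dense-SIFT keypoint stride (px).
#' @return A config list of the corresponding class.
#' @name classic_configs
NULL

#' @rdname classic_configs
#' @export
phow_config <- function(n_words = 200L, pyramid = c(2L, 4L),
                        sift_bins = c(4L, 6L, 8L), step = 4L) {
  structure(list(n_words = as.integer(n_words), pyramid = as.integer(pyramid),
                 sift_bins = as.integer(sift_bins), step = as.integer(step)),
            class = "phow_config")
}

#' @rdname classic_configs
#' @param n_bins Orientation bin count over \[0, 360) degrees.
#' @export
phog_config <- function(n_bins = 8L, pyramid = c(1L, 2L, 4L, 8L)) {
  structure(list(n_bins = as.integer(n_bins), pyramid = as.integer(pyramid)),
            class = "phog_config")
}

#' @rdname classic_configs
#' @param cell_side LBP histogram cell side (px).
#' @export
lbp_config <- function(cell_side = 16L) {
  structure(list(cell_side = as.integer(cell_side), n_patterns = 58L),
            class = "lbp_config")
}

#' Closed-form descriptor dimensions
#'
#' @param config Descriptor configuration.
#' @param patch_side Patch side in pixels (LBP only).
#' @return Integer dimension of one descriptor row.
#' @export
phow_dim <- function(config = phow_config()) {
  as.integer(config$n_words * sum(config$pyramid^2))
}

#' @rdname phow_dim
#' @export
phog_dim <- function(config = phog_config()) {
  as.integer(config$n_bins * sum(config$pyramid^2))
}

#' @rdname phow_dim
#' @export
lbp_dim <- function(config = lbp_config(), patch_side = 64L) {
  if (patch_side %% config$cell_side != 0) {
    stop("patch side must be divisible by the LBP cell side", call. = FALSE)
  }
  as.integer((patch_side %/% config$cell_side)^2 * config$n_patterns)
}

# luminance grayscale conversion
to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# ---- dense SIFT ------------------------------------------------------------

# Dense SIFT at one spatial bin size: descriptors are 4x4 spatial bins of
# `bin` px, 8 orientation bins each (128-d), L2-normalized with the usual
# 0.2 clamp and renormalization; all-flat windows give a zero descriptor.
# Orientation-plane integral images make each of the 128 block sums O(1).
dense_sift_scale <- function(gray, bin, step) {
  h <- nrow(gray); w <- ncol(gray)
  win <- 4L * bin
  if (h < win || w < win) {
    return(list(desc = matrix(0, 0, 128), cx = numeric(), cy = numeric()))
  }
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ang / (2 * pi) * 8), 7)
  # per-orientation integral images
  ints <- lapply(0:7, function(o) {
    m <- mag * (obin == o)
    cs <- apply(m, 2, cumsum)
    cs <- t(apply(cs, 1, cumsum))
    ii <- matrix(0, h + 1, w + 1)
    ii[-1, -1] <- cs
    ii
  })
  xs <- seq(0L, w - win, by = step)   # 0-based window corners
  ys <- seq(0L, h - win, by = step)
  kp <- expand.grid(x = xs, y = ys)
  nk <- nrow(kp)
  desc <- matrix(0, nk, 128)
  rect_sum <- function(ii, x0, y0, x1, y1) {
    ii[cbind(y1 + 1, x1 + 1)] - ii[cbind(y0 + 1, x1 + 1)] -
      ii[cbind(y1 + 1, x0 + 1)] + ii[cbind(y0 + 1, x0 + 1)]
  }
  col <- 1L
  for (by in 0:3) for (bx in 0:3) {
    x0 <- kp$x + bx * bin; y0 <- kp$y + by * bin
    for (o in 1:8) {
      desc[, col] <- rect_sum(ints[[o]], x0, y0, x0 + bin, y0 + bin)
      col <- col + 1L
    }
  }
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 1e-10
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  desc[desc > 0.2] <- 0.2
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 1e-10
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  list(desc = desc, cx = kp$x + win / 2, cy = kp$y + win / 2)
}

# All dense-SIFT descriptors of one patch, across configured scales.
dense_sift <- function(px, config) {
  gray <- to_gray(px)
  out <- lapply(config$sift_bins, function(b) {
    dense_sift_scale(gray, b, config$step)
  })
  list(desc = do.call(rbind, lapply(out, `[[`, "desc")),
       cx = unlist(lapply(out, `[[`, "cx")),
       cy = unlist(lapply(out, `[[`, "cy")))
}

#' Learn a PHOW visual-word codebook
#'
#' K-means over dense-SIFT descriptors pooled from (training) patches.
#' Fitting the codebook on training folds only avoids information leakage
#' into held-out folds.
#'
#' @param patches Patch tibble.
#' @param config A [phow_config].
#' @param seed RNG seed for descriptor subsampling and k-means.
#' @param max_descriptors Cap on pooled descriptors before clustering.
#' @return Matrix of `n_words` cluster centers (class `phow_codebook`).
#' @export
train_codebook <- function(patches, config = phow_config(), seed = 1L,
                           max_descriptors = 20000L) {
  descs <- do.call(rbind, lapply(patches$pixels, function(px) {
    d <- dense_sift(px, config)$desc
    d[rowSums(d^2) > 1e-10, , drop = FALSE]
  }))
  if (nrow(descs) < config$n_words) {
    stop("not enough non-flat descriptors to train the codebook", call. = FALSE)
  }
  with_seed(seed, {
    if (nrow(descs) > max_descriptors) {
      descs <- descs[sample.int(nrow(descs), max_descriptors), , drop = FALSE]
    }
    km <- kmeans(descs, centers = config$n_words, iter.max = 30L, nstart = 1L)
    structure(km$centers, class = c("phow_codebook", "matrix"))
  })
}

#' Extract PHOW descriptors
#'
#' Per spatial cell of the pyramid, the histogram of nearest-visual-word
#' assignments over the dense-SIFT descriptors whose centers fall in the
#' cell; cells are concatenated coarse-to-fine and L1-normalized per cell
#' (a cell with no descriptors stays a zero vector).
#'
#' @param patches Patch tibble.
#' @param config A [phow_config].
#' @param codebook Trained [train_codebook()] centers.
#' @return Feature matrix, one row per patch, width [phow_dim()].
#' @export
extract_phow <- function(patches, config = phow_config(), codebook) {
  if (missing(codebook) || is.null(codebook)) {
    stop("a trained codebook is required", call. = FALSE)
  }
  k <- nrow(codebook)
  cb2 <- rowSums(codebook^2)
  t(vapply(patches$pixels, function(px) {
    side <- dim(px)[1]
    ds <- dense_sift(px, config)
    keep <- rowSums(ds$desc^2) > 1e-10     # flat windows carry no signal
    ds$desc <- ds$desc[keep, , drop = FALSE]
    ds$cx <- ds$cx[keep]; ds$cy <- ds$cy[keep]
    word <- if (nrow(ds$desc) > 0) {
      # nearest center by Euclidean distance
      d2 <- outer(rep(1, nrow(ds$desc)), cb2) - 2 * ds$desc %*% t(codebook)
      max.col(-d2, ties.method = "first")
    } else integer()
    out <- numeric(phow_dim(config))
    off <- 0L
    for (g in config$pyramid) {
      cellx <- pmin(floor(ds$cx / side * g), g - 1)
      celly <- pmin(floor(ds$cy / side * g), g - 1)
      cell <- celly * g + cellx          # row-major cell index, 0-based
      for (ci in 0:(g^2 - 1)) {
        hh <- tabulate(word[cell == ci], nbins = k)
        tot <- sum(hh)
        if (tot > 0) hh <- hh / tot
        out[(off + 1):(off + k)] <- hh
        off <- off + k
      }
    }
    out
  }, numeric(phow_dim(config))))
}

# ---- uniform LBP -----------------------------------------------------------

# 256-entry lookup: code -> uniform-pattern bin (1..58) or NA (discarded).
uniform_lbp_table <- function() {
  transitions <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }
  codes <- 0:255
  uni <- vapply(codes, transitions, 0L) <= 2L
  tab <- rep(NA_integer_, 256)
  tab[uni] <- seq_len(sum(uni))
  tab
}

#' Extract uniform-58 LBP descriptors
#'
#' Eight neighbors at radius 1 are sampled (bilinearly for the diagonal
#' positions) and thresholded at the center value, ties counting as >=.
#' Per 16x16 cell, the 58-bin histogram of uniform patterns (at most two
#' circular transitions; non-uniform patterns are discarded) is
#' L1-normalized; cells are concatenated row-major.
#'
#' @param patches Patch tibble.
#' @param config An [lbp_config].
#' @return Feature matrix, one row per patch, width [lbp_dim()].
#' @export
extract_lbp <- function(patches, config = lbp_config()) {
  tab <- uniform_lbp_table()
  side <- dim(patches$pixels[[1]])[1]
  dim_out <- lbp_dim(config, side)
  angles <- 2 * pi * (0:7) / 8
  dx <- cos(angles); dy <- sin(angles)
  t(vapply(patches$pixels, function(px) {
    gray <- to_gray(px)
    h <- nrow(gray); w <- ncol(gray)
    rows <- 2:(h - 1); cols <- 2:(w - 1)   # 1-px border cannot sample r=1
    center <- gray[rows, cols]
    code <- matrix(0L, length(rows), length(cols))
    for (kk in 1:8) {
      xo <- dx[kk]; yo <- dy[kk]
      if (abs(xo - round(xo)) < 1e-9 && abs(yo - round(yo)) < 1e-9) {
        nb <- gray[rows + round(yo), cols + round(xo)]
      } else {
        x0 <- floor(xo); y0 <- floor(yo)
        fx <- xo - x0; fy <- yo - y0
        nb <- (1 - fy) * (1 - fx) * gray[rows + y0, cols + x0] +
              (1 - fy) * fx       * gray[rows + y0, cols + x0 + 1] +
              fy       * (1 - fx) * gray[rows + y0 + 1, cols + x0] +
              fy       * fx       * gray[rows + y0 + 1, cols + x0 + 1]
      }
      # >= with a small tolerance so exact ties survive bilinear rounding
      code <- code + (nb >= center - 1e-9) * 2L^(kk - 1)
    }
    bin <- matrix(tab[code + 1L], nrow(code), ncol(code))
    g <- side %/% config$cell_side
    out <- numeric(dim_out)
    off <- 0L
    for (cy in 0:(g - 1)) for (cx in 0:(g - 1)) {
      # cell extent in full-patch coordinates, clipped by the 1-px border
      rr <- intersect((cy * config$cell_side + 1):((cy + 1) * config$cell_side),
                      rows) - 1L
      cc <- intersect((cx * config$cell_side + 1):((cx + 1) * config$cell_side),
                      cols) - 1L
      hh <- tabulate(bin[rr, cc], nbins = 58L)
      tot <- sum(hh)
      if (tot > 0) hh <- hh / tot
      out[(off + 1):(off + 58L)] <- hh
      off <- off + 58L
    }
    out
  }, numeric(dim_out)))
}

# ---- PHOG ------------------------------------------------------------------

#' Extract PHOG descriptors
#'
#' Gradient orientations (signed, over \[0, 360) degrees) are histogrammed
#' into `n_bins` bins weighted by gradient magnitude, per cell at each
#' pyramid level; levels are concatenated coarse-to-fine and each level is
#' L1-normalized.
#'
#' @param patches Patch tibble.
#' @param config A [phog_config].
#' @return Feature matrix, one row per patch, width [phog_dim()].
#' @export
extract_phog <- function(patches, config = phog_config()) {
  nb <- config$n_bins
  t(vapply(patches$pixels, function(px) {
    gray <- to_gray(px)
    h <- nrow(gray); w <- ncol(gray)
    gx <- matrix(0, h, w); gy <- matrix(0, h, w)
    gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
    gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% (2 * pi)
    obin <- pmin(floor(ang / (2 * pi) * nb), nb - 1)
    out <- numeric(phog_dim(config))
    off <- 0L
    for (g in config$pyramid) {
      cellx <- pmin(floor((col(gray) - 1) / w * g), g - 1)
      celly <- pmin(floor((row(gray) - 1) / h * g), g - 1)
      idx <- (celly * g + cellx) * nb + obin + 1   # cell-major, bin-minor
      level <- numeric(g^2 * nb)
      rs <- rowsum(as.vector(mag), group = as.vector(idx))
      level[as.integer(rownames(rs))] <- rs
      tot <- sum(level)
      if (tot > 0) level <- level / tot
      out[(off + 1):(off + g^2 * nb)] <- level
      off <- off + g^2 * nb
    }
    out
  }, numeric(phog_dim(config))))
}
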