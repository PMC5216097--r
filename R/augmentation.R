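#' Rescaling pyramid configuration
#'
#' Images are rescaled on a spatial pyramid where the side length of mode
#' `S_i` relative to the base mode `S_j` is `k^(i - j)`. The factor defaults
#' to `sqrt(2)`; mode 5 is the native scale and modes 3-7 span a 4x range
#' of magnification.
#'
#' @param k Scale base, `> 1`.
#' @param base_mode Integer index of the native scale.
#' @param modes Integer set of modes the pyramid may produce.
#' @return A list of class `rescale_config`.
#' @export
rescale_config <- function(k = sqrt(2), base_mode = 5L, modes = 3:7) {
  if (k <= 1) stop("k must be > 1", call. = FALSE)
  structure(list(k = k, base_mode = as.integer(base_mode),
                 modes = as.integer(modes)),
            class = "rescale_config")
}

#' Rescale an annotated image to a pyramid mode
#'
#' Pixel data is resampled bilinearly; region masks are resampled with
#' nearest-neighbor interpolation and re-binarized so labels stay crisp.
#' Output dimensions are `round(side * k^(i - j))` where `j` is the image's
#' current `scale_mode`.
#'
#' @param image An [annotated_image].
#' @param target_mode Integer pyramid mode `i`.
#' @param config A [rescale_config].
#' @param min_side Smallest admissible output side (the patch side); a
#'   smaller result raises a degenerate-scale error.
#' @return The rescaled [annotated_image] with `scale_mode = target_mode`.
#' @export
rescale <- function(image, target_mode, config = rescale_config(),
                    min_side = 64L) {
  r <- config$k^(target_mode - image$scale_mode)
  d <- dim(image$pixels)
  nh <- round(d[1] * r); nw <- round(d[2] * r)
  if (nh < min_side || nw < min_side) {
    stop(sprintf("degenerate scale: mode %d gives %dx%d < %d px",
                 target_mode, nh, nw, min_side), call. = FALSE)
  }
  if (nh == d[1] && nw == d[2]) {
    image$scale_mode <- as.integer(target_mode)
    return(image)
  }
  px <- EBImage::resize(image$pixels, w = nh, h = nw, filter = "bilinear")
  regions <- lapply(image$regions, function(reg) {
    m <- EBImage::resize(reg$mask * 1, w = nh, h = nw, filter = "none") > 0.5
    labeled_region(m, reg$label)
  })
  annotated_image(clamp(px), regions, image$case_id, image$image_id,
                  scale_mode = as.integer(target_mode),
                  rotflip_mode = image$rotflip_mode)
}

# ---- rotation / flip modes -------------------------------------------------

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
hflip <- function(m) m[, ncol(m):1, drop = FALSE]

apply_rotflip_matrix <- function(m, mode) {
  if (mode >= 4) m <- hflip(m)
  for (i in seq_len(mode %% 4)) m <- rot90ccw(m)
  m
}

apply_rotflip_array <- function(a, mode) {
  planes <- lapply(seq_len(dim(a)[3]),
                   function(ch) apply_rotflip_matrix(a[, , ch], mode))
  out <- array(0, c(dim(planes[[1]]), dim(a)[3]))
  for (ch in seq_along(planes)) out[, , ch] <- planes[[ch]]
  out
}

#' Apply one of the eight rotation/flip modes
#'
#' Modes 0-3 rotate counterclockwise by 0/90/180/270 degrees; modes 4-7
#' first flip horizontally and then rotate by 0/90/180/270 degrees. The
#' eight modes realize the dihedral group of the square, so every mode has
#' an inverse among the eight. Region masks are transformed identically to
#' the pixels and labels are preserved.
#'
#' @param x An [annotated_image], a patch tibble, a matrix, or an
#'   `H x W x C` array.
#' @param mode Integer in 0-7.
#' @return Transformed object of the same type, with `rotflip_mode`
#'   recorded where the type carries it.
#' @export
apply_rotflip <- function(x, mode) {
  mode <- as.integer(mode)
  if (mode < 0 || mode > 7) stop("mode must be in 0..7", call. = FALSE)
  if (inherits(x, "annotated_image")) {
    regions <- lapply(x$regions, function(reg) {
      labeled_region(apply_rotflip_matrix(reg$mask, mode), reg$label)
    })
    return(annotated_image(apply_rotflip_array(x$pixels, mode), regions,
                           x$case_id, x$image_id, x$scale_mode,
                           rotflip_mode = mode))
  }
  if (is.data.frame(x)) {
    x$pixels <- lapply(x$pixels, apply_rotflip_array, mode = mode)
    x$rotflip_mode <- mode
    return(x)
  }
  if (is.matrix(x)) return(apply_rotflip_matrix(x, mode))
  apply_rotflip_array(x, mode)
}

# ---- cropping --------------------------------------------------------------

#' Patch cropping configuration
#'
#' Crops `in_side` patches down to `out_side` (the 56/64 proportion used for
#' the network input when cropping is enabled). Training crops shift
#' uniformly at random; test crops are taken at the center. Cropping is
#' disabled in the flagship configuration, whose best model does not use it.
#'
#' @param enabled Logical flag.
#' @param in_side,out_side Input/output patch sides in pixels.
#' @return A list of class `crop_config`.
#' @export
crop_config <- function(enabled = FALSE, in_side = 64L, out_side = 56L) {
  if (out_side > in_side) stop("out_side must be <= in_side", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), in_side = as.integer(in_side),
                 out_side = as.integer(out_side)), class = "crop_config")
}

#' Crop patches for training or testing
#'
#' @param patches Patch tibble with side `in_side`.
#' @param config A [crop_config].
#' @param phase `"train"` (uniform random offsets) or `"test"` (center
#'   offset, floor division).
#' @param seed Optional seed making training crops reproducible.
#' @return Patch tibble with side `out_side` and upper-left corners updated
#'   to source-frame coordinates.
#' @export
crop_patches <- function(patches, config = crop_config(enabled = TRUE),
                         phase = c("train", "test"), seed = NULL) {
  phase <- match.arg(phase)
  ins <- config$in_side; outs <- config$out_side
  slack <- ins - outs
  n <- nrow(patches)
  if (n == 0 || slack == 0) return(patches)
  draw <- function() {
    if (phase == "test") {
      matrix(slack %/% 2L, n, 2)
    } else {
      matrix(sample.int(slack + 1L, 2 * n, replace = TRUE) - 1L, n, 2)
    }
  }
  off <- if (is.null(seed)) draw() else with_seed(seed, draw())
  patches$pixels <- lapply(seq_len(n), function(i) {
    stopifnot(dim(patches$pixels[[i]])[1] == ins)
    patches$pixels[[i]][(off[i, 2] + 1):(off[i, 2] + outs),
                        (off[i, 1] + 1):(off[i, 1] + outs), , drop = FALSE]
  })
  patches$x <- patches$x + off[, 1]
  patches$y <- patches$y + off[, 2]
  patches
}

#' Build an augmented patch set
#'
#' Augmentation operates at the image level: for every image, every
#' requested rescale mode and every rotation/flip mode, the image is
#' transformed and the greedy tiler is re-run, pooling all resulting
#' patches. Each patch records the scale and rotation/flip mode of the frame
#' it was cut from. Image-level augmentation is preferred over patch-level
#' replication because re-running the tiler on the transformed image yields
#' genuinely different patch positions.
#'
#' @param images List of [annotated_image] objects.
#' @param rescale_modes Integer vector of pyramid modes (e.g. `4:6`).
#' @param rotflip_modes Integer vector from 0-7.
#' @param gpga_config A [gpga_config].
#' @param rescale_cfg A [rescale_config].
#' @param keep_fraction Random patch-level downsampling fraction in (0, 1];
#'   the `[F0-F7]/2` configuration uses 0.5.
#' @param seed Seed for the downsampling draw (unused when
#'   `keep_fraction = 1`).
#' @return A pooled patch tibble.
#' @export
build_augmented_set <- function(images, rescale_modes = 5L,
                                rotflip_modes = 0L,
                                gpga_config = ipclkit::gpga_config(),
                                rescale_cfg = rescale_config(),
                                keep_fraction = 1, seed = 1L) {
  out <- list()
  for (img in images) {
    for (s in rescale_modes) {
      scaled <- rescale(img, s, rescale_cfg, min_side = gpga_config$patch_side)
      for (f in rotflip_modes) {
        timg <- if (f == 0) scaled else apply_rotflip(scaled, f)
        for (reg in timg$regions) {
          out[[length(out) + 1]] <- generate_patches(reg, timg, gpga_config)
        }
      }
    }
  }
  patches <- dplyr::bind_rows(out)
  if (keep_fraction < 1 && nrow(patches) > 0) {
    keep <- with_seed(derive_seed(seed, "downsample"),
                      runif(nrow(patches)) < keep_fraction)
    patches <- patches[keep, , drop = FALSE]
  }
  patches
}
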