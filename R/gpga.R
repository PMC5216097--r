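#' Configuration for the greedy patch-generating algorithm
#'
#' Labeled regions are tiled with fixed-size square patches under two rules:
#' Rule 1, at least a fraction `containment_min` of each patch must lie
#' inside the region mask (default 95%); Rule 2, the area overlap between
#' any two accepted patches must not exceed `overlap_max` (default 75%).
#' Candidate upper-left corners are scanned on a `grid_step`-px grid in
#' raster order (row-major, top-left first) and accepted greedily; positions
#' that would over-overlap an accepted patch form the "gray area" and are
#' skipped.
#'
#' @param patch_side Patch width/height in pixels.
#' @param containment_min Rule 1 threshold, fraction in (0, 1].
#' @param overlap_max Rule 2 threshold, fraction in [0, 1).
#' @param grid_step Candidate grid stride in pixels. At the default 8 px on
#'   64-px patches the grid itself would allow up to 87.5% linear overlap,
#'   so Rule 2 binds before the grid does.
#' @return A list of class `gpga_config`.
#' @export
gpga_config <- function(patch_side = 64L, containment_min = 0.95,
                        overlap_max = 0.75, grid_step = 8L) {
  cfg <- list(patch_side = as.integer(patch_side),
              containment_min = as.numeric(containment_min),
              overlap_max = as.numeric(overlap_max),
              grid_step = as.integer(grid_step))
  if (cfg$patch_side < 1) stop("patch_side must be >= 1", call. = FALSE)
  if (cfg$containment_min <= 0 || cfg$containment_min > 1) {
    stop("containment_min must be in (0, 1]", call. = FALSE)
  }
  if (cfg$overlap_max < 0 || cfg$overlap_max >= 1) {
    stop("overlap_max must be in [0, 1)", call. = FALSE)
  }
  if (cfg$grid_step < 1 || cfg$grid_step > cfg$patch_side) {
    stop("grid_step must be in [1, patch_side]", call. = FALSE)
  }
  structure(cfg, class = "gpga_config")
}

#' Fraction of a patch covered by a region mask
#'
#' @param upper_left `(x, y)` 0-based upper-left corner of the patch.
#' @param w Patch side in pixels.
#' @param mask Logical/binary region mask.
#' @return Fraction in `[0, 1]` of the `w^2` patch pixels inside the mask.
#' @export
containment_fraction <- function(upper_left, w, mask) {
  x <- upper_left[1]; y <- upper_left[2]
  if (x < 0 || y < 0 || x + w > ncol(mask) || y + w > nrow(mask)) {
    stop("patch out of image bounds", call. = FALSE)
  }
  sum(mask[(y + 1):(y + w), (x + 1):(x + w)]) / w^2
}

#' Area overlap fraction of two equal axis-aligned square patches
#'
#' Closed form `max(0, w - |dx|) * max(0, w - |dy|) / w^2`; symmetric in its
#' arguments.
#'
#' @param a,b `(x, y)` upper-left corners.
#' @param w Patch side in pixels.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, w) {
  max(0, w - abs(a[1] - b[1])) * max(0, w - abs(a[2] - b[2])) / w^2
}

#' Is a candidate corner inside the gray area of accepted patches?
#'
#' True iff the candidate patch would overlap some already-accepted patch by
#' more than `o`. Equivalent to testing membership in the painted gray
#' regions around each accepted upper-left point.
#'
#' @param candidate `(x, y)` candidate upper-left corner.
#' @param accepted Matrix with one `(x, y)` row per accepted patch (or an
#'   empty/NULL value).
#' @param w Patch side.
#' @param o Maximum allowed overlap fraction.
#' @return Logical flag.
#' @export
is_gray <- function(candidate, accepted, w, o) {
  if (is.null(accepted) || NROW(accepted) == 0) return(FALSE)
  accepted <- matrix(accepted, ncol = 2)
  ov <- pmax(0, w - abs(candidate[1] - accepted[, 1])) *
        pmax(0, w - abs(candidate[2] - accepted[, 2])) / w^2
  any(ov > o)
}

# Internal: summed-area table so any window sum is four lookups.
integral_image <- function(mask) {
  cs <- apply(mask, 2, cumsum)            # cumulative down rows
  cs <- t(apply(cs, 1, cumsum))           # then across columns
  ii <- matrix(0, nrow(mask) + 1, ncol(mask) + 1)
  ii[-1, -1] <- cs
  ii
}

# Window sum of mask over rows y+1..y+w, cols x+1..x+w (x, y 0-based vectors).
window_sums <- function(ii, x, y, w) {
  ii[cbind(y + w + 1, x + w + 1)] - ii[cbind(y + 1, x + w + 1)] -
    ii[cbind(y + w + 1, x + 1)] + ii[cbind(y + 1, x + 1)]
}

#' Greedily tile a labeled region with patches
#'
#' Scans the candidate grid in raster order and accepts every candidate that
#' (i) is not in the gray area of already-accepted patches and (ii) has
#' containment at least `containment_min`. The output order is the
#' acceptance order, and the result is deterministic.
#'
#' @param region A [labeled_region] (defaults to the image's first region).
#' @param image An [annotated_image] whose dimensions are at least the patch
#'   side.
#' @param config A [gpga_config].
#' @return A patch tibble (see [patch_tbl()]); zero rows if no candidate
#'   satisfies both rules.
#' @export
generate_patches <- function(region = NULL, image, config = gpga_config()) {
  if (is.null(region)) region <- image$regions[[1]]
  w <- config$patch_side
  h_img <- dim(image$pixels)[1]; w_img <- dim(image$pixels)[2]
  if (h_img < w || w_img < w) stop("image smaller than patch side", call. = FALSE)
  g <- config$grid_step
  xs <- seq(0L, w_img - w, by = g)
  ys <- seq(0L, h_img - w, by = g)
  ii <- integral_image(region$mask)
  # containment for every grid candidate, row-major over (y rows, x cols)
  cand <- expand.grid(x = xs, y = ys)      # x varies fastest = raster order
  contain <- window_sums(ii, cand$x, cand$y, w) / w^2
  ok <- contain >= config$containment_min
  acc <- matrix(0L, 0, 2)
  for (i in which(ok)) {
    p <- c(cand$x[i], cand$y[i])
    if (!is_gray(p, acc, w, config$overlap_max)) acc <- rbind(acc, p)
  }
  if (nrow(acc) == 0) return(empty_patch_tbl())
  pix <- lapply(seq_len(nrow(acc)), function(i) {
    image$pixels[(acc[i, 2] + 1):(acc[i, 2] + w),
                 (acc[i, 1] + 1):(acc[i, 1] + w), , drop = FALSE]
  })
  patch_tbl(pix, region$label, image$image_id, image$case_id,
            x = acc[, 1], y = acc[, 2],
            scale_mode = image$scale_mode, rotflip_mode = image$rotflip_mode)
}

#' Verify GPGA rule compliance of a patch set (brute force)
#'
#' Independent checker: re-measures every patch's containment directly on
#' the mask and every pairwise overlap with the closed form, without reusing
#' any of the tiler's intermediate state.
#'
#' @param patches Patch tibble.
#' @param mask Region mask the patches were generated from.
#' @param config The [gpga_config] used.
#' @return TRUE if all rules hold, otherwise a character vector of violations.
#' @export
check_gpga_rules <- function(patches, mask, config = gpga_config()) {
  w <- config$patch_side
  bad <- character()
  n <- nrow(patches)
  for (i in seq_len(n)) {
    cf <- containment_fraction(c(patches$x[i], patches$y[i]), w, mask)
    if (cf < config$containment_min) {
      bad <- c(bad, sprintf("patch %d containment %.3f", i, cf))
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ov <- overlap_fraction(c(patches$x[i], patches$y[i]),
                             c(patches$x[j], patches$y[j]), w)
      if (ov > config$overlap_max) {
        bad <- c(bad, sprintf("patches %d,%d overlap %.3f", i, j, ov))
      }
    }
  }
  if (length(bad) == 0) TRUE else bad
}
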