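#' Construct a labeled region
#'
#' A labeled region couples a binary mask with a morphological type label and,
#' optionally, the closed polygon the mask was rasterized from. All
#' coordinates in this package are 0-based with `(x, y) = (column, row)`.
#'
#' @param mask Logical or 0/1 matrix (`H x W`); must contain at least one
#'   foreground pixel.
#' @param label One of [ipcl_classes].
#' @param polygon Optional `n x 2` matrix of `(x, y)` vertices of a closed
#'   polygon. When supplied it must rasterize exactly to `mask`.
#' @return An object of class `labeled_region`.
#' @seealso [rasterize_polygon()], [annotated_image()]
#' @export
labeled_region <- function(mask, label, polygon = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask > 0
  if (!any(mask)) stop("mask has no foreground pixels", call. = FALSE)
  check_labels(label)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    ras <- rasterize_polygon(polygon, nrow(mask), ncol(mask))
    if (!identical(ras, mask)) {
      stop("polygon does not rasterize to the supplied mask", call. = FALSE)
    }
  }
  structure(list(mask = mask, label = as.character(label), polygon = polygon),
            class = "labeled_region")
}

#' Construct an annotated image
#'
#' The unit of input to the pipeline: an RGB image together with one or more
#' labeled regions and the identity of the patient case it belongs to. Images
#' from one case share texture characteristics, which is why cross-validation
#' folds are assigned at the case level.
#'
#' @param pixels Numeric `H x W x 3` array with values in `[0, 1]`.
#' @param regions List of [labeled_region] objects whose masks match the
#'   image dimensions.
#' @param case_id,image_id Character identifiers.
#' @param scale_mode Integer index into the rescaling pyramid; mode 5 is the
#'   native scale.
#' @param rotflip_mode Integer 0-7 recording any rotation/flip applied.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, regions, case_id, image_id,
                            scale_mode = 5L, rotflip_mode = 0L) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  for (r in regions) {
    if (!inherits(r, "labeled_region")) {
      stop("regions must be labeled_region objects", call. = FALSE)
    }
    if (!identical(dim(r$mask), d[1:2])) {
      stop("region mask dimensions must match the image", call. = FALSE)
    }
  }
  structure(list(pixels = pixels, regions = regions,
                 case_id = as.character(case_id),
                 image_id = as.character(image_id),
                 scale_mode = as.integer(scale_mode),
                 rotflip_mode = as.integer(rotflip_mode)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image %s [case %s]: %dx%d, %d region(s): %s>\n",
              x$image_id, x$case_id, d[1], d[2], length(x$regions),
              paste(vapply(x$regions, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

#' Rasterize a closed polygon to a binary mask
#'
#' Uses the even-odd rule evaluated at pixel centers `(x + 0.5, y + 0.5)` on
#' the half-open pixel grid, so an axis-aligned square with corners `(0, 0)`
#' and `(s, s)` covers exactly `s^2` pixels. Coordinates are 0-based,
#' `(x, y) = (column, row)`.
#'
#' @param polygon `n x 2` matrix of `(x, y)` vertices (closed implicitly).
#' @param height,width Output mask dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_polygon <- function(polygon, height, width) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3) {
    stop("polygon must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  xs <- seq_len(width) - 0.5   # pixel-center x for column j = j - 0.5
  ys <- seq_len(height) - 0.5
  n <- nrow(polygon)
  px <- polygon[, 1]; py <- polygon[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  crossings <- matrix(0L, height, width)
  for (e in seq_len(n)) {
    if (py[e] == qy[e]) next  # horizontal edge never crosses a center ray
    spans <- (py[e] > ys) != (qy[e] > ys)
    if (!any(spans)) next
    xint <- px[e] + (ys - py[e]) * (qx[e] - px[e]) / (qy[e] - py[e])
    # ray cast in +x: edge crosses strictly right of the pixel center
    crossings[spans, ] <- crossings[spans, , drop = FALSE] +
      outer(xint[spans], xs, ">")
  }
  crossings %% 2L == 1L
}

#' Read an annotated image from disk
#'
#' @param image_path Path to a PNG (or TIFF) RGB image.
#' @param region_source One path or a list of paths; each either a region
#'   JSON file (`{"label", "case_id", "polygon"}` or
#'   `{"label", "case_id", "mask_path"}`) or a binary mask PNG
#'   (0 = background, 255 = region), in which case `label` must be given.
#' @param label Region label, required when `region_source` is a raw mask.
#' @param case_id,image_id Identifiers; default to the JSON's `case_id` and
#'   the image file name.
#' @return An [annotated_image].
#' @export
read_annotated_image <- function(image_path, region_source, label = NULL,
                                 case_id = NULL, image_id = NULL) {
  pixels <- read_rgb(image_path)
  if (!is.list(region_source)) region_source <- as.list(region_source)
  regions <- list()
  for (src in region_source) {
    if (grepl("\\.json$", src, ignore.case = TRUE)) {
      meta <- jsonlite::read_json(src, simplifyVector = TRUE)
      if (is.null(case_id) && !is.null(meta$case_id)) case_id <- meta$case_id
      if (!is.null(meta$polygon)) {
        poly <- matrix(as.numeric(unlist(meta$polygon)), ncol = 2,
                       byrow = !is.matrix(meta$polygon))
        if (is.matrix(meta$polygon)) poly <- meta$polygon
        mask <- rasterize_polygon(poly, dim(pixels)[1], dim(pixels)[2])
        regions <- c(regions, list(labeled_region(mask, meta$label, poly)))
      } else if (!is.null(meta$mask_path)) {
        mpath <- meta$mask_path
        if (!file.exists(mpath)) mpath <- file.path(dirname(src), mpath)
        regions <- c(regions, list(labeled_region(read_mask(mpath), meta$label)))
      } else {
        stop("region JSON needs a 'polygon' or 'mask_path' field", call. = FALSE)
      }
    } else {
      if (is.null(label)) {
        stop("a raw mask region_source requires a 'label'", call. = FALSE)
      }
      regions <- c(regions, list(labeled_region(read_mask(src), label)))
    }
  }
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(image_path))
  if (is.null(case_id)) case_id <- image_id
  annotated_image(pixels, regions, case_id, image_id)
}

# Internal image readers; PNG via the png package, TIFF via tiff.
read_rgb <- function(path) {
  a <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE]
}

read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Assemble patch records into a patch tibble
#'
#' Patches are represented throughout the package as a tibble with one row
#' per patch: identifiers, label, 0-based upper-left corner `(x, y)` in the
#' coordinates of the (possibly rescaled/rotated) source frame, the
#' augmentation modes, and the pixel data as a list-column of
#' `w x w x 3` arrays.
#'
#' @param pixels List of `w x w x 3` arrays (all the same side).
#' @param label Character vector of labels, one per patch.
#' @param image_id,case_id Character vectors, recycled if length 1.
#' @param x,y Integer upper-left coordinates (0-based).
#' @param scale_mode,rotflip_mode Integer augmentation modes.
#' @return A tibble with columns `image_id, case_id, label, x, y, scale_mode,
#'   rotflip_mode, pixels`.
#' @export
patch_tbl <- function(pixels, label, image_id, case_id, x, y,
                      scale_mode = 5L, rotflip_mode = 0L) {
  n <- length(pixels)
  tibble::tibble(
    image_id = rep_len(as.character(image_id), n),
    case_id = rep_len(as.character(case_id), n),
    label = rep_len(as.character(label), n),
    x = rep_len(as.integer(x), n),
    y = rep_len(as.integer(y), n),
    scale_mode = rep_len(as.integer(scale_mode), n),
    rotflip_mode = rep_len(as.integer(rotflip_mode), n),
    pixels = pixels
  )
}

empty_patch_tbl <- function() {
  patch_tbl(list(), character(), character(), character(), integer(), integer())
}

#' Write a patch manifest (and optionally the patch images)
#'
#' @param patches Patch tibble as produced by [generate_patches()] or
#'   [build_augmented_set()].
#' @param path Output CSV path.
#' @param patch_dir Optional directory; when given, each patch is written as
#'   `<image_id>_<row>.png` and referenced from the manifest's `patch_file`
#'   column.
#' @return Number of rows written, invisibly.
#' @export
write_patch_manifest <- function(patches, path, patch_dir = NULL) {
  df <- patches[setdiff(names(patches), "pixels")]
  df$patch_file <- NA_character_
  if (!is.null(patch_dir) && nrow(patches) > 0) {
    dir.create(patch_dir, recursive = TRUE, showWarnings = FALSE)
    df$patch_file <- sprintf("%s_%05d.png", df$image_id, seq_len(nrow(df)))
    for (i in seq_len(nrow(df))) {
      png::writePNG(clamp(patches$pixels[[i]]),
                    file.path(patch_dir, df$patch_file[i]))
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(nrow(df))
}

#' Read a patch manifest written by [write_patch_manifest()]
#'
#' @param path Manifest CSV path.
#' @param patch_dir Directory holding patch PNGs; when given, the `pixels`
#'   list-column is populated.
#' @return A patch tibble (with `pixels = NULL` entries if no `patch_dir`).
#' @export
read_patch_manifest <- function(path, patch_dir = NULL) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(image_id = "character",
                                                  case_id = "character")))
  if (nrow(df) == 0) {
    out <- empty_patch_tbl()
    out$patch_file <- character()
    return(out)
  }
  pix <- if (!is.null(patch_dir)) {
    lapply(df$patch_file, function(f) read_rgb(file.path(patch_dir, f)))
  } else {
    rep(list(NULL), nrow(df))
  }
  df$pixels <- pix
  df
}
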