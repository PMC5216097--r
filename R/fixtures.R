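#' Configuration for the synthetic annotated-image generator
#'
#' The generator emulates the structure of an annotated magnification-
#' endoscopy dataset: patient cases containing several images each, one
#' irregular labeled lesion region per image, three visually distinct
#' procedural vessel textures (sparse dots for type A, closed loops of
#' varying diameter for B1, elongated branching strokes for B2_B3), a
#' brown-on-pink hemoglobin-like palette, a linear illumination gradient,
#' additive camera noise, and per-image magnification (scale) jitter.
#' Images from one case share color and texture parameters, so patches from
#' the same case are correlated - the property that motivates case-level
#' cross-validation.
#'
#' @param seed Integer master seed; identical configurations generate
#'   byte-identical datasets.
#' @param n_cases_per_class Cases simulated per class.
#' @param images_per_case Integer range `c(min, max)` of images per case.
#' @param image_size `c(height, width)` in pixels.
#' @param region_area_fraction Range of the labeled-region area as a
#'   fraction of the image area.
#' @param texture_params Named list (`A`, `B1`, `B2_B3`) of per-class texture
#'   parameters: `element_density` (elements per region pixel),
#'   `stroke_thickness` (px), `loop_radius` (px; loop/dot radius scale), and
#'   `branch_count` (forks per branching structure).
#' @param noise_sd Additive Gaussian noise standard deviation, 8-bit
#'   intensity units.
#' @param illumination_gradient_amplitude Peak-to-center relative amplitude
#'   of the linear illumination gradient.
#' @param scale_jitter Range of per-image linear texture scale factors,
#'   emulating varying endoscope magnification.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_cases_per_class = 4L,
                           images_per_case = c(3L, 3L),
                           image_size = c(400L, 400L),
                           region_area_fraction = c(0.1, 0.4),
                           texture_params = default_texture_params(),
                           noise_sd = 8,
                           illumination_gradient_amplitude = 0.25,
                           scale_jitter = c(0.85, 1.18)) {
  cfg <- list(seed = as.integer(seed),
              n_cases_per_class = as.integer(n_cases_per_class),
              images_per_case = as.integer(rep_len(images_per_case, 2)),
              image_size = as.integer(rep_len(image_size, 2)),
              region_area_fraction = as.numeric(region_area_fraction),
              texture_params = texture_params,
              noise_sd = as.numeric(noise_sd),
              illumination_gradient_amplitude =
                as.numeric(illumination_gradient_amplitude),
              scale_jitter = as.numeric(rep_len(scale_jitter, 2)))
  bad <- function(field, msg) {
    stop(sprintf("invalid fixture_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  if (cfg$n_cases_per_class < 1) bad("n_cases_per_class", "must be >= 1")
  if (any(cfg$images_per_case < 1) ||
      cfg$images_per_case[1] > cfg$images_per_case[2]) {
    bad("images_per_case", "must be an increasing range of positive integers")
  }
  if (any(cfg$image_size < 64)) bad("image_size", "must be at least 64 px")
  f <- cfg$region_area_fraction
  if (length(f) != 2 || f[1] <= 0 || f[2] >= 1 || f[1] > f[2]) {
    bad("region_area_fraction", "must be a range inside (0, 1)")
  }
  if (!all(ipcl_classes %in% names(cfg$texture_params))) {
    bad("texture_params", "must name all three classes")
  }
  for (cl in ipcl_classes) {
    tp <- cfg$texture_params[[cl]]
    need <- c("element_density", "stroke_thickness", "loop_radius",
              "branch_count")
    if (!all(need %in% names(tp))) {
      bad("texture_params", sprintf("class %s must supply %s", cl,
                                    paste(need, collapse = ", ")))
    }
    if (tp$element_density <= 0) bad("texture_params", "element_density > 0")
    if (tp$stroke_thickness <= 0) bad("texture_params", "stroke_thickness > 0")
  }
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (cfg$scale_jitter[1] <= 0 || cfg$scale_jitter[1] > cfg$scale_jitter[2]) {
    bad("scale_jitter", "must be a positive increasing range")
  }
  structure(cfg, class = "fixture_config")
}

#' @rdname fixture_config
#' @export
default_texture_params <- function() {
  list(
    A = list(element_density = 0.004, stroke_thickness = 1.5,
             loop_radius = 1.6, branch_count = 0),
    B1 = list(element_density = 0.0012, stroke_thickness = 2.0,
              loop_radius = 8.0, branch_count = 0),
    B2_B3 = list(element_density = 4e-4, stroke_thickness = 3.5,
                 loop_radius = 0, branch_count = 3)
  )
}

# ---- procedural texture painting ------------------------------------------

# Stamp a filled disc of radius r at float center (cx, cy), 0-based coords.
paint_disc <- function(canvas, cx, cy, r) {
  h <- nrow(canvas); w <- ncol(canvas)
  r0 <- max(1, floor(cy - r)); r1 <- min(h, ceiling(cy + r + 1))
  c0 <- max(1, floor(cx - r)); c1 <- min(w, ceiling(cx + r + 1))
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  dy2 <- (rows - 0.5 - cy)^2
  dx2 <- (cols - 0.5 - cx)^2
  hit <- outer(dy2, dx2, `+`) <= r^2
  canvas[rows, cols][hit] <- 1
  canvas
}

# Stamp a ring (annulus) of radius r and stroke thickness t.
paint_ring <- function(canvas, cx, cy, r, t) {
  h <- nrow(canvas); w <- ncol(canvas)
  rr <- r + t
  r0 <- max(1, floor(cy - rr)); r1 <- min(h, ceiling(cy + rr + 1))
  c0 <- max(1, floor(cx - rr)); c1 <- min(w, ceiling(cx + rr + 1))
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - 0.5 - cy)^2, (cols - 0.5 - cx)^2, `+`))
  hit <- abs(d - r) <= t / 2
  canvas[rows, cols][hit] <- 1
  canvas
}

# Random-walk branching stroke: a main walker plus forked sub-walkers.
paint_branches <- function(canvas, cx, cy, thickness, n_forks, n_steps) {
  walkers <- list(list(x = cx, y = cy, dir = runif(1, 0, 2 * pi),
                       steps = n_steps))
  fork_at <- if (n_forks > 0) sort(sample(seq(5, n_steps - 5), n_forks))
             else integer()
  step_len <- 1.5
  k <- 0
  while (length(walkers) > 0) {
    wk <- walkers[[1]]; walkers <- walkers[-1]
    for (s in seq_len(wk$steps)) {
      k <- k + 1
      wk$x <- wk$x + step_len * cos(wk$dir)
      wk$y <- wk$y + step_len * sin(wk$dir)
      wk$dir <- wk$dir + rnorm(1, 0, 0.28)
      canvas <- paint_disc(canvas, wk$x, wk$y, thickness / 2)
      if (s %in% fork_at && wk$steps == n_steps) {  # fork only from the trunk
        walkers <- c(walkers, list(list(
          x = wk$x, y = wk$y,
          dir = wk$dir + sample(c(-1, 1), 1) * runif(1, 0.7, 1.3),
          steps = ceiling(wk$steps / 2))))
      }
    }
  }
  canvas
}

# Paint the class texture onto a canvas, restricted to the region mask.
# Element centers are sampled uniformly over region pixels; element size and
# count follow the per-class parameters scaled by the magnification factor.
paint_texture <- function(mask, label, tp, scale = 1) {
  canvas <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0) return(canvas)
  n_elem <- max(1L, round(tp$element_density / scale^2 * length(fg)))
  idx <- fg[sample.int(length(fg), n_elem, replace = TRUE)]
  cy <- (idx - 1) %% nrow(mask) + 0.5 + runif(n_elem, -2, 2)
  cx <- (idx - 1) %/% nrow(mask) + 0.5 + runif(n_elem, -2, 2)
  t <- tp$stroke_thickness * scale
  for (e in seq_len(n_elem)) {
    if (label == "A") {
      canvas <- paint_disc(canvas, cx[e], cy[e],
                           tp$loop_radius * scale * runif(1, 0.7, 1.3))
    } else if (label == "B1") {
      r <- tp$loop_radius * scale * runif(1, 0.6, 1.4)
      canvas <- paint_ring(canvas, cx[e], cy[e], r, t)
    } else {
      canvas <- paint_branches(canvas, cx[e], cy[e], t, tp$branch_count,
                               n_steps = round(40 * scale) + sample.int(20, 1))
    }
  }
  canvas * mask
}

# ---- region geometry -------------------------------------------------------

# Draw an irregular star polygon whose rasterized area lies within the
# configured fraction range; scales radially until the bound is met.
random_region_polygon <- function(h, w, frac_range) {
  lo <- frac_range[1]; hi <- frac_range[2]
  target <- runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
  r0 <- sqrt(target * h * w / pi)
  m <- 14L
  ang <- sort(runif(m, 0, 2 * pi))
  rad <- r0 * runif(m, 0.75, 1.25)
  cx <- runif(1, min(1.3 * r0, w / 2), max(w - 1.3 * r0, w / 2))
  cy <- runif(1, min(1.3 * r0, h / 2), max(h - 1.3 * r0, h / 2))
  for (iter in 1:10) {
    poly <- cbind(clamp(cx + rad * cos(ang), 1, w - 1),
                  clamp(cy + rad * sin(ang), 1, h - 1))
    mask <- rasterize_polygon(poly, h, w)
    frac <- mean(mask)
    if (frac >= lo && frac <= hi) break
    rad <- rad * sqrt(target / max(frac, 1e-6))
  }
  list(polygon = poly, mask = mask)
}

# ---- case and dataset generation ------------------------------------------

#' Generate all images of one synthetic patient case
#'
#' Every image of a case shares its foreground/background colors and texture
#' parameters (with only per-image magnification jitter), so patches drawn
#' from different images of one case are visually correlated.
#'
#' @param config A [fixture_config].
#' @param class_label One of [ipcl_classes].
#' @param case_id Character case identifier.
#' @return A list of [annotated_image] objects sharing `case_id`.
#' @export
generate_case <- function(config, class_label, case_id) {
  if (!inherits(config, "fixture_config")) config <- do.call(fixture_config, config)
  check_labels(class_label, "class_label")
  h <- config$image_size[1]; w <- config$image_size[2]
  with_seed(derive_seed(config$seed, class_label, case_id), {
    fg <- clamp(c(120, 60, 50) / 255 + rnorm(3, 0, 10 / 255))
    bg <- clamp(c(210, 160, 150) / 255 + rnorm(3, 0, 10 / 255))
    tp <- config$texture_params[[class_label]]
    tp$element_density <- tp$element_density * runif(1, 0.8, 1.25)
    tp$stroke_thickness <- max(0.8, tp$stroke_thickness + rnorm(1, 0, 0.2))
    tp$loop_radius <- tp$loop_radius * runif(1, 0.9, 1.1)
    n_img <- if (config$images_per_case[1] == config$images_per_case[2]) {
      config$images_per_case[1]
    } else {
      sample(seq(config$images_per_case[1], config$images_per_case[2]), 1)
    }
    lapply(seq_len(n_img), function(i) {
      reg <- random_region_polygon(h, w, config$region_area_fraction)
      s <- runif(1, config$scale_jitter[1], config$scale_jitter[2])
      vessel <- paint_texture(reg$mask, class_label, tp, scale = s)
      img <- array(0, c(h, w, 3))
      for (ch in 1:3) img[, , ch] <- bg[ch] * (1 - vessel) + fg[ch] * vessel
      phi <- runif(1, 0, 2 * pi)
      grad <- 1 + config$illumination_gradient_amplitude *
        outer((seq_len(h) / h - 0.5) * sin(phi),
              (seq_len(w) / w - 0.5) * cos(phi), `+`) * 2
      img <- img * as.vector(grad)
      img <- img + rnorm(length(img), 0, config$noise_sd / 255)
      img <- round(clamp(img) * 255) / 255  # 8-bit quantization
      annotated_image(img,
                      list(labeled_region(reg$mask, class_label, reg$polygon)),
                      case_id = case_id,
                      image_id = sprintf("%s_img%d", case_id, i))
    })
  })
}

#' Generate a full synthetic dataset on disk
#'
#' Writes `images/*.png`, `masks/*.png` (8-bit, 0 = background,
#' 255 = region), `regions/*.json` (polygon vertices, label, case id), and a
#' `manifest.csv` with one row per image.
#'
#' @param config A [fixture_config].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble with columns
#'   `case_id, image_id, image, mask, region, label`.
#' @export
generate_dataset <- function(config, out_dir) {
  if (!inherits(config, "fixture_config")) config <- do.call(fixture_config, config)
  for (d in file.path(out_dir, c("images", "masks", "regions"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  for (cl in ipcl_classes) {
    for (ci in seq_len(config$n_cases_per_class)) {
      case_id <- sprintf("case_%s_%02d", cl, ci)
      for (img in generate_case(config, cl, case_id)) {
        reg <- img$regions[[1]]
        paths <- c(image = file.path("images", paste0(img$image_id, ".png")),
                   mask = file.path("masks", paste0(img$image_id, ".png")),
                   region = file.path("regions", paste0(img$image_id, ".json")))
        png::writePNG(img$pixels, file.path(out_dir, paths["image"]))
        png::writePNG(reg$mask * 1, file.path(out_dir, paths["mask"]))
        jsonlite::write_json(
          list(label = reg$label, case_id = case_id,
               polygon = unname(apply(reg$polygon, 1, function(v) c(v[1], v[2]),
                                      simplify = FALSE))),
          file.path(out_dir, paths["region"]), auto_unbox = TRUE, digits = 8)
        rows[[length(rows) + 1]] <- tibble::tibble(
          case_id = case_id, image_id = img$image_id,
          image = unname(paths["image"]), mask = unname(paths["mask"]),
          region = unname(paths["region"]), label = cl)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Load every image of a dataset manifest into memory
#'
#' @param manifest Manifest tibble from [generate_dataset()] (or read from
#'   its CSV).
#' @param root Dataset root directory the manifest paths are relative to.
#' @return List of [annotated_image] objects.
#' @export
load_dataset <- function(manifest, root) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_annotated_image(file.path(root, manifest$image[i]),
                         file.path(root, manifest$region[i]),
                         case_id = manifest$case_id[i],
                         image_id = manifest$image_id[i])
  })
}
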