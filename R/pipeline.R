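#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the full workflow
#' (simulate -> tile -> augment -> train CNN -> extract features -> train
#' SVM head -> predict -> synthesize -> evaluate) with a single master seed
#' that propagates to every stochastic stage.
#'
#' @param out_root Output root directory; each stage writes to its own
#'   subdirectory with a stage manifest.
#' @param seed Master seed.
#' @param fixtures Arguments for [fixture_config()] (seed is supplied from
#'   the master seed).
#' @param gpga Arguments for [gpga_config()].
#' @param augmentation List with `rescale_modes`, `rotflip_modes`,
#'   `keep_fraction` (see [build_augmented_set()]).
#' @param crop Arguments for [crop_config()].
#' @param train Arguments for [train_config()].
#' @param svm Arguments for [svm_config()].
#' @param folds List with `k`.
#' @param feature_layer fc layer feeding the SVM head.
#' @param synthesis List with `sigma` (NULL = patch side / 4) and
#'   `n_images` (overlays written per class).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_root = "ipcl_run", seed = 1L,
                            fixtures = list(), gpga = list(),
                            augmentation = list(rescale_modes = 5L,
                                                rotflip_modes = 0L,
                                                keep_fraction = 1),
                            crop = list(enabled = FALSE),
                            train = list(epochs = 10L),
                            svm = list(), folds = list(k = 3L),
                            feature_layer = "fc1",
                            synthesis = list(sigma = NULL, n_images = 1L)) {
  structure(list(out_root = out_root, seed = as.integer(seed),
                 fixtures = fixtures, gpga = gpga,
                 augmentation = augmentation, crop = crop, train = train,
                 svm = svm, folds = folds, feature_layer = feature_layer,
                 synthesis = synthesis),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Fields found in the file override [pipeline_config()] defaults.
#'
#' @param path Configuration file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown pipeline config field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

# Stage bookkeeping: a stage is complete when its marker holds the same
# parameter hash; re-runs then skip it unless forced.
stage_marker <- function(dir) file.path(dir, ".stage.json")

stage_done <- function(dir, hash) {
  f <- stage_marker(dir)
  file.exists(f) &&
    identical(jsonlite::read_json(f)$hash, hash)
}

mark_stage <- function(dir, hash, info = list()) {
  jsonlite::write_json(c(list(hash = hash, time = format(Sys.time())), info),
                       stage_marker(dir), auto_unbox = TRUE)
}

#' Run the full pipeline (or a subset of its stages)
#'
#' Stages execute in order; each writes its artifacts and a stage manifest
#' under `out_root/<stage>/`. Completed stages are skipped on re-runs with
#' identical parameters unless `force = TRUE`. One master seed makes the
#' whole run reproducible.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to execute (dependencies must already have run).
#' @param force Re-run stages whose outputs are already present.
#' @return A run-report tibble (stage, status, n_out) with the pooled
#'   metrics attached as attribute `"metrics"` when the evaluate stage ran.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "patches", "folds", "train",
                                    "synthesize", "evaluate"),
                         force = FALSE) {
  root <- config$out_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  note <- function(stage, status, n = NA_integer_) {
    report[[length(report) + 1]] <<- tibble::tibble(stage = stage,
                                                    status = status,
                                                    n_out = n)
  }
  fix_cfg <- do.call(fixture_config,
                     c(list(seed = derive_seed(config$seed, "fixtures")),
                       config$fixtures))
  gp_cfg <- do.call(gpga_config, config$gpga)
  sim_dir <- file.path(root, "fixtures")
  patch_dir <- file.path(root, "patches")
  fold_dir <- file.path(root, "folds")
  train_dir <- file.path(root, "train")
  synth_dir <- file.path(root, "synthesis")
  eval_dir <- file.path(root, "metrics")

  if ("simulate" %in% stages) {
    hash <- rlang::hash(fix_cfg)
    if (!force && stage_done(sim_dir, hash)) {
      note("simulate", "skipped")
    } else {
      dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)
      manifest <- generate_dataset(fix_cfg, sim_dir)
      mark_stage(sim_dir, hash, list(n_images = nrow(manifest)))
      note("simulate", "done", nrow(manifest))
    }
  }

  if ("patches" %in% stages) {
    aug <- config$augmentation
    hash <- rlang::hash(list(fix_cfg, gp_cfg, aug))
    if (!force && stage_done(patch_dir, hash)) {
      note("patches", "skipped")
    } else {
      dir.create(patch_dir, showWarnings = FALSE, recursive = TRUE)
      manifest <- tibble::as_tibble(read.csv(file.path(sim_dir, "manifest.csv"),
                                             stringsAsFactors = FALSE))
      images <- load_dataset(manifest, sim_dir)
      patches <- build_augmented_set(
        images,
        rescale_modes = aug$rescale_modes %||% 5L,
        rotflip_modes = aug$rotflip_modes %||% 0L,
        gpga_config = gp_cfg,
        keep_fraction = aug$keep_fraction %||% 1,
        seed = derive_seed(config$seed, "augment"))
      saveRDS(patches, file.path(patch_dir, "patches.rds"))
      write_patch_manifest(patches, file.path(patch_dir, "patch_manifest.csv"))
      mark_stage(patch_dir, hash, list(n_patches = nrow(patches)))
      note("patches", "done", nrow(patches))
    }
  }

  if ("folds" %in% stages) {
    k <- config$folds$k %||% 3L
    hash <- rlang::hash(list(fix_cfg, k, config$seed))
    if (!force && stage_done(fold_dir, hash)) {
      note("folds", "skipped")
    } else {
      dir.create(fold_dir, showWarnings = FALSE, recursive = TRUE)
      patches <- readRDS(file.path(patch_dir, "patches.rds"))
      plan <- make_folds(patches[c("case_id", "label")], k = k,
                         seed = derive_seed(config$seed, "folds"))
      write.csv(plan, file.path(fold_dir, "folds.csv"), row.names = FALSE)
      mark_stage(fold_dir, hash, list(k = k))
      note("folds", "done", k)
    }
  }

  if ("train" %in% stages) {
    hash <- rlang::hash(list(fix_cfg, gp_cfg, config$augmentation,
                             config$train, config$svm, config$crop,
                             config$feature_layer, config$folds, config$seed))
    if (!force && stage_done(train_dir, hash)) {
      note("train", "skipped")
    } else {
      dir.create(train_dir, showWarnings = FALSE, recursive = TRUE)
      patches <- readRDS(file.path(patch_dir, "patches.rds"))
      plan <- read.csv(file.path(fold_dir, "folds.csv"),
                       stringsAsFactors = FALSE)
      crop_cfg <- do.call(crop_config, config$crop)
      spec <- nbi_net_spec(cropping = crop_cfg$enabled)
      sv_cfg <- do.call(svm_config, config$svm)
      preds <- list()
      for (f in sort(unique(plan$fold))) {
        test_cases <- plan$case_id[plan$fold == f]
        tr <- patches[!(patches$case_id %in% test_cases), ]
        te <- patches[patches$case_id %in% test_cases, ]
        if (crop_cfg$enabled) {
          tr <- crop_patches(tr, crop_cfg, "train",
                             seed = derive_seed(config$seed, "crop", f))
          te <- crop_patches(te, crop_cfg, "test")
        }
        tc <- do.call(train_config,
                      c(config$train,
                        list(seed = derive_seed(config$seed, "train", f))))
        net <- nbi_train(tr, tc, spec)
        soft <- predict_softmax(net, te)
        feat_tr <- extract_features(net, tr, config$feature_layer)
        feat_te <- extract_features(net, te, config$feature_layer)
        head_ <- fit_ovo(feat_tr, tr$label, sv_cfg)
        svm_pred <- predict_votes(head_, feat_te)
        preds[[f]] <- tibble::tibble(
          fold = f, image_id = te$image_id, case_id = te$case_id,
          label = te$label, x = te$x, y = te$y,
          scale_mode = te$scale_mode, rotflip_mode = te$rotflip_mode,
          pred_softmax = soft$.pred_class, pred_svm = svm_pred$.pred_class,
          p_A = soft$p_A, p_B1 = soft$p_B1, p_B2_B3 = soft$p_B2_B3)
      }
      preds <- dplyr::bind_rows(preds)
      write.csv(preds, file.path(train_dir, "predictions.csv"),
                row.names = FALSE)
      mark_stage(train_dir, hash, list(n_predictions = nrow(preds)))
      note("train", "done", nrow(preds))
    }
  }

  if ("synthesize" %in% stages) {
    hash <- rlang::hash(list(config$seed, config$synthesis))
    if (!force && stage_done(synth_dir, hash)) {
      note("synthesize", "skipped")
    } else {
      dir.create(synth_dir, showWarnings = FALSE, recursive = TRUE)
      patches <- readRDS(file.path(patch_dir, "patches.rds"))
      preds <- read.csv(file.path(train_dir, "predictions.csv"),
                        stringsAsFactors = FALSE)
      manifest <- read.csv(file.path(sim_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
      n_img <- config$synthesis$n_images %||% 1L
      shown <- 0L
      for (cl in ipcl_classes) {
        ids <- unique(preds$image_id[preds$label == cl])
        for (id in head(ids, n_img)) {
          sel <- preds[preds$image_id == id &
                         preds$scale_mode == 5L & preds$rotflip_mode == 0L, ]
          if (nrow(sel) == 0) next
          psel <- patches[patches$image_id == id &
                            patches$scale_mode == 5L &
                            patches$rotflip_mode == 0L, ]
          img_path <- manifest$image[manifest$image_id == id][1]
          dims <- dim(read_rgb(file.path(sim_dir, img_path)))[1:2]
          vm <- accumulate_votes(sel$pred_svm, psel, dims,
                                 sigma = config$synthesis$sigma)
          write_overlay(vm, file.path(synth_dir, paste0(id, "_overlay.png")),
                        file.path(synth_dir, paste0(id, "_classes.tif")))
          shown <- shown + 1L
        }
      }
      mark_stage(synth_dir, hash, list(n_overlays = shown))
      note("synthesize", "done", shown)
    }
  }

  metrics <- NULL
  if ("evaluate" %in% stages) {
    dir.create(eval_dir, showWarnings = FALSE, recursive = TRUE)
    preds <- read.csv(file.path(train_dir, "predictions.csv"),
                      stringsAsFactors = FALSE)
    scores <- as.matrix(preds[c("p_A", "p_B1", "p_B2_B3")])
    metrics <- evaluate_predictions(preds$pred_svm, preds$label, scores)
    soft_metrics <- evaluate_predictions(preds$pred_softmax, preds$label,
                                         scores)
    out <- list(
      accuracy_svm = metrics$accuracy,
      accuracy_softmax = soft_metrics$accuracy,
      classifier_boosting = metrics$accuracy - soft_metrics$accuracy,
      macro_ap = metrics$macro_ap,
      average_precision = as.list(metrics$average_precision),
      confusion_svm = metrics$confusion,
      n_patches = metrics$n)
    jsonlite::write_json(out, file.path(eval_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    note("evaluate", "done", metrics$n)
  }

  out <- dplyr::bind_rows(report)
  attr(out, "metrics") <- metrics
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
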