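# Shared helpers: small, deterministic objects built in code at test time.

# A compact fixture configuration for fast unit tests (larger regions so a
# 64-px patch always fits).
tiny_fixture_config <- function(seed = 1L, ...) {
  fixture_config(seed = seed, n_cases_per_class = 2L,
                 images_per_case = c(1L, 1L), image_size = c(192L, 192L),
                 region_area_fraction = c(0.3, 0.45), ...)
}

# Trivially hue-separable 64-px patches: each class dominates one channel.
toy_hue_patches <- function(n_per_class = 20L, seed = 42L, side = 64L) {
  ipclkit:::with_seed(seed, {
    pix <- unlist(lapply(seq_along(ipcl_classes), function(ch) {
      lapply(seq_len(n_per_class), function(i) {
        a <- array(runif(side * side * 3) * 0.2, c(side, side, 3))
        a[, , ch] <- a[, , ch] + 0.5
        a
      })
    }), recursive = FALSE)
    patch_tbl(pix, rep(ipcl_classes, each = n_per_class),
              image_id = "toy", case_id = "toy", x = 0L, y = 0L)
  })
}

# A random blob mask (union of discs) for GPGA property tests.
random_blob_mask <- function(h, w, seed) {
  ipclkit:::with_seed(seed, {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(sample(2:4, 1))) {
      cy <- runif(1, h * 0.25, h * 0.75)
      cx <- runif(1, w * 0.25, w * 0.75)
      r <- runif(1, min(h, w) * 0.2, min(h, w) * 0.45)
      d <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
      m <- m | (d <= r^2)
    }
    m
  })
}

# An asymmetric test image (no rotation/flip symmetry).
asymmetric_array <- function(side = 16L, seed = 7L) {
  ipclkit:::with_seed(seed, array(runif(side * side * 3), c(side, side, 3)))
}

# The default study conditions (4 cases/class x 3 images, 400 px) are
# expensive to build, so they are generated once per test session and shared
# between the fixture-invariant and acceptance tests.
default_fixture_cache <- new.env(parent = emptyenv())

default_fixture_patches <- function() {
  if (is.null(default_fixture_cache$patches)) {
    cfg <- fixture_config(seed = 1)
    imgs <- unlist(lapply(ipcl_classes, function(cl) {
      lapply(seq_len(cfg$n_cases_per_class), function(i) {
        generate_case(cfg, cl, sprintf("case_%s_%02d", cl, i))
      })
    }), recursive = FALSE)
    imgs <- unlist(imgs, recursive = FALSE)
    default_fixture_cache$patches <- build_augmented_set(imgs)
    default_fixture_cache$plan <- make_folds(
      default_fixture_cache$patches[c("case_id", "label")], k = 3, seed = 1)
  }
  list(patches = default_fixture_cache$patches,
       plan = default_fixture_cache$plan)
}

# Case-level cross-validated accuracy of a feature matrix + linear SVM.
case_cv_accuracy <- function(feats, patches, plan) {
  hit <- 0; tot <- 0
  for (f in sort(unique(plan$fold))) {
    te <- patches$case_id %in% plan$case_id[plan$fold == f]
    head_ <- fit_ovo(feats[!te, , drop = FALSE], patches$label[!te])
    pred <- predict_votes(head_, feats[te, , drop = FALSE])$.pred_class
    hit <- hit + sum(pred == patches$label[te])
    tot <- tot + sum(te)
  }
  hit / tot
}

# Per-fold training seed for the cross-validated acceptance run.
derive_fold_seed <- function(f) ipclkit:::derive_seed(1L, "acceptance", f)

`%||%` <- function(a, b) if (is.null(a)) b else a
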