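test_that("rescaling follows the k^(i-j) side law with rounding", {
  img <- annotated_image(array(0.5, c(400, 400, 3)),
                         list(labeled_region(matrix(TRUE, 400, 400), "A")),
                         "c", "i", scale_mode = 5L)
  same <- rescale(img, 5)
  expect_equal(dim(same$pixels), c(400, 400, 3))
  up <- rescale(img, 6)
  expect_equal(dim(up$pixels)[1:2], c(566, 566))      # round(400 * sqrt(2))
  down <- rescale(img, 4)
  expect_equal(dim(down$pixels)[1:2], c(283, 283))    # round(400 / sqrt(2))
  expect_equal(dim(down$regions[[1]]$mask), c(283, 283))
  expect_equal(up$scale_mode, 6L)
  # masks stay binary after nearest-neighbor resampling
  expect_true(is.logical(down$regions[[1]]$mask))
  # pairwise side ratios follow the law within +-1 px
  for (i in 3:7) {
    ri <- rescale(img, i)
    expect_lte(abs(dim(ri$pixels)[1] - 400 * sqrt(2)^(i - 5)), 1)
  }
  expect_error(rescale(annotated_image(array(0.5, c(80, 80, 3)),
                                       list(labeled_region(matrix(TRUE, 80, 80),
                                                           "A")), "c", "i"),
                       3), "degenerate")
})

test_that("the eight rot/flip modes realize the dihedral group of the square", {
  a <- asymmetric_array(16)
  outs <- lapply(0:7, function(m) apply_rotflip(a, m))
  # mode 0 is the identity; mode 2 is an involution
  expect_identical(outs[[1]], a)
  expect_identical(apply_rotflip(outs[[3]], 2), a)
  # all 8 images pairwise distinct on a generic input
  for (i in 1:7) for (j in (i + 1):8) {
    expect_false(identical(outs[[i]], outs[[j]]),
                 info = sprintf("modes %d vs %d", i - 1, j - 1))
  }
  # every mode has an inverse among the eight (group closure under inverse)
  for (m in 0:7) {
    inverted <- any(vapply(0:7, function(m2) {
      identical(apply_rotflip(outs[[m + 1]], m2), a)
    }, TRUE))
    expect_true(inverted, info = paste("mode", m))
  }
  expect_error(apply_rotflip(a, 8), "0..7")
})

test_that("rot/flip transforms masks with the pixels and preserves labels", {
  m <- matrix(FALSE, 12, 12); m[2:5, 7:11] <- TRUE
  img <- annotated_image(asymmetric_array(12), list(labeled_region(m, "B1")),
                         "c", "i")
  t3 <- apply_rotflip(img, 3)
  expect_identical(t3$regions[[1]]$mask, apply_rotflip(m, 3))
  expect_identical(t3$regions[[1]]$label, "B1")
  expect_equal(t3$rotflip_mode, 3L)
})

test_that("cropping takes the 56/64 center crop at test time", {
  px <- asymmetric_array(64)
  pt <- patch_tbl(list(px), "A", "i", "c", x = 10L, y = 20L)
  te <- crop_patches(pt, crop_config(enabled = TRUE), "test")
  expect_equal(dim(te$pixels[[1]]), c(56, 56, 3))
  expect_equal(c(te$x, te$y), c(14L, 24L))            # offset (4, 4)
  expect_equal(te$pixels[[1]], px[5:60, 5:60, ])
  # identity when out_side = in_side
  id <- crop_patches(pt, crop_config(enabled = TRUE, out_side = 64L), "train")
  expect_identical(id$pixels[[1]], px)
  # train crops are reproducible under a seed and within bounds
  tr1 <- crop_patches(pt, phase = "train", seed = 99)
  tr2 <- crop_patches(pt, phase = "train", seed = 99)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$x - pt$x <= 8 & tr1$x - pt$x >= 0))
  expect_error(crop_config(in_side = 56, out_side = 64), "out_side")
})

test_that("the baseline augmentation configuration reproduces plain tiling", {
  cfg <- tiny_fixture_config(seed = 13)
  img <- generate_case(cfg, "B1", "case_x")[[1]]
  plain <- generate_patches(image = img)
  aug <- build_augmented_set(list(img), rescale_modes = 5L, rotflip_modes = 0L)
  expect_equal(aug[c("x", "y", "label")], plain[c("x", "y", "label")])
  expect_equal(nrow(aug), nrow(plain))
})

test_that("8 rot/flip modes on a square full-frame mask give 8x the patches", {
  img <- annotated_image(array(0.5, c(160, 160, 3)),
                         list(labeled_region(matrix(TRUE, 160, 160), "A")),
                         "c", "i")
  base <- nrow(build_augmented_set(list(img)))
  all8 <- build_augmented_set(list(img), rotflip_modes = 0:7)
  expect_equal(nrow(all8), 8 * base)
  expect_setequal(unique(all8$rotflip_mode), 0:7)
  # every patch carries its source label regardless of mode
  expect_true(all(all8$label == "A"))
})

test_that("every augmented patch satisfies the tiling rules in its own frame", {
  cfg <- tiny_fixture_config(seed = 21)
  img <- generate_case(cfg, "B2_B3", "case_y")[[1]]
  aug <- build_augmented_set(list(img), rescale_modes = 4:5,
                             rotflip_modes = c(0L, 2L))
  gp <- gpga_config()
  for (s in 4:5) for (f in c(0L, 2L)) {
    sub <- aug[aug$scale_mode == s & aug$rotflip_mode == f, ]
    if (nrow(sub) == 0) next
    frame <- apply_rotflip(rescale(img, s), f)
    expect_true(isTRUE(check_gpga_rules(sub, frame$regions[[1]]$mask, gp)),
                info = sprintf("S%d F%d", s, f))
  }
})

test_that("random patch-level downsampling keeps about the requested fraction", {
  img <- annotated_image(array(0.5, c(200, 200, 3)),
                         list(labeled_region(matrix(TRUE, 200, 200), "A")),
                         "c", "i")
  full <- build_augmented_set(list(img), rotflip_modes = 0:7)
  half1 <- build_augmented_set(list(img), rotflip_modes = 0:7,
                               keep_fraction = 0.5, seed = 8)
  half2 <- build_augmented_set(list(img), rotflip_modes = 0:7,
                               keep_fraction = 0.5, seed = 8)
  expect_identical(half1$x, half2$x)       # seeded determinism
  expect_gt(nrow(half1), 0.25 * nrow(full))
  expect_lt(nrow(half1), 0.75 * nrow(full))
})
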