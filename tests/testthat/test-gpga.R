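test_that("containment_fraction matches closed-form cases", {
  full <- matrix(TRUE, 128, 128)
  expect_equal(containment_fraction(c(0, 0), 64, full), 1)
  expect_equal(containment_fraction(c(32, 32), 64, !full), 0)
  half <- matrix(FALSE, 128, 128); half[, 1:64] <- TRUE   # half-plane at x=64
  expect_equal(containment_fraction(c(32, 10), 64, half), 0.5)
  expect_error(containment_fraction(c(100, 0), 64, full), "bounds")
})

test_that("overlap_fraction has the bilinear closed form and is symmetric", {
  w <- 64
  expect_equal(overlap_fraction(c(5, 9), c(5, 9), w), 1)
  expect_equal(overlap_fraction(c(0, 0), c(32, 0), w), 0.5)
  expect_equal(overlap_fraction(c(0, 0), c(64, 64), w), 0)
  for (i in 1:20) {
    a <- sample(0:80, 2); b <- sample(0:80, 2)
    expect_equal(overlap_fraction(a, b, w), overlap_fraction(b, a, w))
    expect_equal(overlap_fraction(a, b, w),
                 max(0, w - abs(a[1] - b[1])) *
                   max(0, w - abs(a[2] - b[2])) / w^2)
  }
})

test_that("gray-area predicate fires exactly above the overlap threshold", {
  expect_true(is_gray(c(10, 10), rbind(c(10, 10)), 64, 0.75))
  expect_false(is_gray(c(0, 0), rbind(c(64, 64)), 64, 0.75))
  # offset (8, 0): overlap 56*64/4096 = 0.875 > 0.75
  expect_equal(overlap_fraction(c(8, 0), c(0, 0), 64), 0.875)
  expect_true(is_gray(c(8, 0), rbind(c(0, 0)), 64, 0.75))
  # boundary is inclusive: exactly 0.75 overlap is allowed
  expect_false(is_gray(c(16, 0), rbind(c(0, 0)), 64, 0.75))
  expect_equal(overlap_fraction(c(16, 0), c(0, 0), 64), 0.75)
  expect_false(is_gray(c(5, 5), NULL, 64, 0.75))
})

test_that("a full-frame mask with stride w tiles exactly", {
  img <- annotated_image(array(0.5, c(128, 128, 3)),
                         list(labeled_region(matrix(TRUE, 128, 128), "A")),
                         "c", "i")
  p <- generate_patches(image = img, config = gpga_config(grid_step = 64))
  expect_equal(nrow(p), 4)
  expect_equal(p$x, c(0L, 64L, 0L, 64L))    # raster acceptance order
  expect_equal(p$y, c(0L, 0L, 64L, 64L))
  expect_true(all(p$label == "A"))
})

test_that("a mask too small for Rule 1 yields no patches", {
  m <- matrix(FALSE, 128, 128)
  m[40:70, 40:70] <- TRUE                  # 31x31 < 0.95 * 64^2 everywhere
  img <- annotated_image(array(0.5, c(128, 128, 3)),
                         list(labeled_region(m, "B1")), "c", "i")
  expect_equal(nrow(generate_patches(image = img)), 0)
})

test_that("both rules hold on every output for randomized masks (brute force)", {
  cfg <- gpga_config()
  for (seed in 1:30) {
    m <- random_blob_mask(200, 200, seed)
    img <- annotated_image(array(0.5, c(200, 200, 3)),
                           list(labeled_region(m, "A")), "c", "i")
    p <- generate_patches(img$regions[[1]], img, cfg)
    if (nrow(p) > 0) {
      expect_true(isTRUE(check_gpga_rules(p, m, cfg)), info = paste("seed", seed))
    }
  }
})

test_that("greedy tiling is maximal on the candidate grid", {
  cfg <- gpga_config()
  for (seed in c(3, 11, 27)) {
    m <- random_blob_mask(200, 200, seed)
    img <- annotated_image(array(0.5, c(200, 200, 3)),
                           list(labeled_region(m, "A")), "c", "i")
    p <- generate_patches(image = img, config = cfg)
    acc <- cbind(p$x, p$y)
    xs <- seq(0, 200 - cfg$patch_side, by = cfg$grid_step)
    for (y in xs) for (x in xs) {
      ok_rule1 <- containment_fraction(c(x, y), cfg$patch_side, m) >=
        cfg$containment_min
      if (ok_rule1 && nrow(p) > 0) {
        expect_true(is_gray(c(x, y), acc, cfg$patch_side, cfg$overlap_max) ||
                      any(acc[, 1] == x & acc[, 2] == y),
                    info = sprintf("seed %d candidate (%d,%d)", seed, x, y))
      }
    }
  }
})

test_that("relaxing either rule never reduces the patch count", {
  m <- random_blob_mask(200, 200, 5)
  img <- annotated_image(array(0.5, c(200, 200, 3)),
                         list(labeled_region(m, "A")), "c", "i")
  base <- nrow(generate_patches(image = img, config = gpga_config()))
  lower_c <- nrow(generate_patches(image = img,
                                   config = gpga_config(containment_min = 0.8)))
  higher_o <- nrow(generate_patches(image = img,
                                    config = gpga_config(overlap_max = 0.9)))
  expect_gte(lower_c, base)
  expect_gte(higher_o, base)
})

test_that("config invariants are validated", {
  expect_error(gpga_config(containment_min = 0), "containment")
  expect_error(gpga_config(overlap_max = 1), "overlap")
  expect_error(gpga_config(grid_step = 100), "grid_step")
})
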