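make_patch_at <- function(x, y, w = 64L) {
  patch_tbl(list(array(0.5, c(w, w, 3))), "A", "i", "c",
            x = as.integer(x), y = as.integer(y))
}

test_that("a single patch paints its own class everywhere in its footprint", {
  pt <- make_patch_at(10, 20)
  vm <- accumulate_votes("B1", pt, c(128, 128))
  flat <- matrix(vm$scores, 128 * 128, 3)
  covered <- as.vector(vm$weight_total) > 0
  expect_true(all(max.col(flat[covered, , drop = FALSE]) == 2))
  # support equals exactly the patch footprint
  expect_equal(sum(covered), 64^2)
  sup <- matrix(FALSE, 128, 128); sup[21:84, 11:74] <- TRUE
  expect_identical(vm$weight_total > 0, sup)
  expect_error(accumulate_votes("B1", make_patch_at(100, 0), c(128, 128)),
               "bounds")
})

test_that("coincident opposing votes tie and resolve A > B1 > B2_B3", {
  pt <- dplyr::bind_rows(make_patch_at(0, 0), make_patch_at(0, 0))
  vm <- accumulate_votes(c("B1", "A"), pt, c(64, 64))
  expect_equal(vm$scores[, , 1], vm$scores[, , 2])   # exact tie by symmetry
  rgba <- colorize(vm)
  expect_true(all(rgba[, , 2] == 1))                 # green = A wins ties
  expect_true(all(rgba[, , 3] == 0))
})

test_that("the Gaussian weight has the stated center-to-corner ratio", {
  w <- 64; sigma <- w / 4
  d_corner <- w * sqrt(2) / 2
  expect_equal(gaussian_patch_weight(0, sigma) /
                 gaussian_patch_weight(d_corner, sigma),
               exp(d_corner^2 / (2 * sigma^2)))
  # discrete kernel: symmetric, peaked at the center, matching the
  # continuous law at pixel centers
  G <- ipclkit:::gaussian_kernel(w, sigma)
  expect_equal(G, G[w:1, ]); expect_equal(G, G[, w:1])
  d_pix <- sqrt(2) * (w / 2 - 0.5)
  expect_equal(G[w / 2, w / 2] / G[1, 1],
               gaussian_patch_weight(sqrt(2) * 0.5, sigma) /
                 gaussian_patch_weight(d_pix, sigma))
})

test_that("vote accumulation is additive and order-independent", {
  p1 <- make_patch_at(0, 0); p2 <- make_patch_at(32, 16)
  both <- dplyr::bind_rows(p1, p2)
  vm_ab <- accumulate_votes(c("A", "B2_B3"), both, c(128, 128))
  vm_ba <- accumulate_votes(c("B2_B3", "A"), both[2:1, ], c(128, 128))
  expect_equal(vm_ab$scores, vm_ba$scores)
  expect_equal(vm_ab$weight_total, vm_ba$weight_total)
  # probability-weighted votes split mass across classes
  probs <- rbind(c(0.5, 0.5, 0), c(0, 0, 1))
  vms <- accumulate_votes(probs, both, c(128, 128))
  expect_equal(vms$scores[, , 1], vms$scores[, , 2])
  expect_true(all(vms$scores >= 0))
})

test_that("colorize maps classes to green/blue/red and leaves gaps transparent", {
  for (cl in 1:3) {
    vm <- accumulate_votes(ipcl_classes[cl], make_patch_at(0, 0), c(96, 96))
    rgba <- colorize(vm)
    chan <- c(2, 3, 1)[cl]                  # A -> G, B1 -> B, B2_B3 -> R
    expect_true(all(rgba[1:64, 1:64, chan] == 1))
    expect_true(all(rgba[1:64, 1:64, setdiff(1:3, chan)] == 0))
    expect_true(all(rgba[65:96, , 4] == 0))  # uncovered: transparent
    expect_true(all(rgba[1:64, 1:64, 4] == 1))
  }
  empty <- accumulate_votes(character(0), patch_tbl(list(), character(),
                                                    character(), character(),
                                                    integer(), integer()),
                            c(32, 32))
  expect_true(all(colorize(empty)[, , 4] == 0))
})

test_that("overlay files are written for covered pixels", {
  dir <- withr::local_tempdir()
  vm <- accumulate_votes("B1", make_patch_at(0, 0), c(96, 96))
  write_overlay(vm, file.path(dir, "o.png"), file.path(dir, "c.tif"))
  rgba <- png::readPNG(file.path(dir, "o.png"))
  expect_equal(dim(rgba), c(96, 96, 4))
  cls <- tiff::readTIFF(file.path(dir, "c.tif")) * 255
  expect_equal(sum(round(cls) == 2), 64^2)
})

test_that("fold plans partition cases without leakage, stratified by label", {
  cases <- tibble::tibble(case_id = sprintf("c%02d", 1:12),
                          label = rep(ipcl_classes, each = 4))
  plan <- make_folds(cases, k = 3, seed = 2)
  expect_equal(sort(table(plan$fold)), sort(c(4L, 4L, 4L)), ignore_attr = TRUE)
  expect_equal(anyDuplicated(plan$case_id), 0)
  expect_setequal(plan$case_id, cases$case_id)
  # stratification: at k = 3 with 4 cases per class no fold is class-starved
  tab <- table(plan$label, plan$fold)
  expect_true(all(tab >= 1))
  # determinism and seed sensitivity
  expect_identical(plan, make_folds(cases, k = 3, seed = 2))
  # some other seed yields a different case-to-fold assignment
  assignment <- function(p) p$fold[order(p$case_id)]
  expect_true(any(vapply(3:8, function(s) {
    !identical(assignment(plan), assignment(make_folds(cases, k = 3,
                                                       seed = s)))
  }, TRUE)))
  expect_error(make_folds(cases, k = 13), "exceeds")
  expect_error(make_folds(tibble::tibble(case_id = c("a", "a"),
                                         label = c("A", "B1")), k = 1),
               "two labels")
})

test_that("metrics: accuracy, confusion, and average precision", {
  labs <- rep(ipcl_classes, each = 10)
  perfect <- evaluate_predictions(labs, labs,
                                  scores = {
                                    m <- matrix(0, 30, 3)
                                    m[cbind(1:30, rep(1:3, each = 10))] <- 1
                                    m
                                  })
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$average_precision), rep(1, 3))
  expect_equal(perfect$macro_ap, 1)
  expect_equal(sum(diag(perfect$confusion)), 30)
  # trace / total = accuracy by construction
  set.seed(9)
  preds <- sample(labs)
  m <- evaluate_predictions(preds, labs)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / m$n)
  expect_equal(rowSums(m$confusion), table(labs), ignore_attr = TRUE)
  # random predictions on many samples sit near chance
  big_labs <- rep(ipcl_classes, each = 400)
  big_preds <- ipclkit:::with_seed(3, sample(big_labs))
  acc <- evaluate_predictions(big_preds, big_labs)$accuracy
  expect_lt(abs(acc - 1 / 3), 0.05)        # ~4 binomial sd for n = 1200
  expect_error(evaluate_predictions(labs[1:5], labs), "length")
  # broom accessors
  expect_equal(nrow(tidy(m)), 3)
  expect_named(glance(m), c("accuracy", "macro_ap", "n"))
})

test_that("augmented-frame coordinates map back into the base frame", {
  cfg <- tiny_fixture_config(seed = 31)
  img <- generate_case(cfg, "B1", "case_m")[[1]]
  mask <- img$regions[[1]]$mask
  for (s in c(5L, 6L)) for (f in c(0L, 1L, 5L)) {
    frame <- apply_rotflip(rescale(img, s), f)
    p <- generate_patches(image = frame)
    if (nrow(p) == 0) next
    back <- map_patches_to_base(p, dim(img$pixels)[1:2])
    expect_true(all(back$x >= 0 & back$y >= 0))
    expect_true(all(back$x + 64 <= ncol(mask) & back$y + 64 <= nrow(mask)))
    # mapped footprints still lie mostly inside the base region
    frac <- vapply(seq_len(nrow(back)), function(i) {
      containment_fraction(c(back$x[i], back$y[i]), 64, mask)
    }, 0)
    expect_gt(mean(frac), 0.75)
  }
})
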