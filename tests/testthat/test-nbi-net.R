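test_that("the default spec matches the published architecture", {
  spec <- nbi_net_spec()
  sh <- infer_shapes(spec)
  # channel sequence input -> conv1 -> pool1 -> conv2 -> pool2
  expect_equal(sh$channels[sh$layer %in% c("input", "conv1", "pool1",
                                           "conv2", "pool2")],
               c(3, 64, 64, 256, 256))
  # fc widths 1024 / 128 / 3
  expect_equal(sh$units[sh$layer %in% c("fc1", "fc2", "fc3")],
               c(1024, 128, 3))
  # dropout 0.5 after both hidden fc layers
  drops <- Filter(function(l) l$kind == "dropout", spec$layers)
  expect_equal(vapply(drops, `[[`, 0, "dropout_p"), c(0.5, 0.5))
  # pool1 is overlapping: stride < window
  pool1 <- Filter(function(l) identical(l$name, "pool1"), spec$layers)[[1]]
  expect_lt(pool1$stride, pool1$kernel)
})

test_that("shape inference reproduces both blob-shape rows exactly", {
  sh64 <- infer_shapes(nbi_net_spec())
  got <- sh64$height[match(c("conv1", "pool1", "conv2", "pool2"), sh64$layer)]
  expect_equal(got, c(29, 14, 12, 6))
  sh56 <- infer_shapes(nbi_net_spec(cropping = TRUE))
  got56 <- sh56$height[match(c("conv1", "pool1", "conv2", "pool2"),
                             sh56$layer)]
  expect_equal(got56, c(25, 12, 10, 5))
  # the floor/ceil convention is the only consistent pair:
  # ceil-conv would give conv1 -> 30; floor-pool would give pool2 -> 5
  expect_equal(ceiling((64 - 7) / 2) + 1, 30)
  expect_equal(floor((12 - 3) / 2) + 1, 5)
  # identity conv preserves the side
  id <- structure(list(input_shape = c(1L, 9L, 9L), layers = list(
    layer_spec("conv", "c", kernel = 1L, stride = 1L, out_channels = 2L))),
    class = "nbi_net_spec")
  expect_equal(infer_shapes(id)$height[2], 9)
  # non-positive sides are reported with the layer name
  bad <- structure(list(input_shape = c(1L, 4L, 4L), layers = list(
    layer_spec("conv", "conv_bad", kernel = 7L, stride = 1L,
               out_channels = 2L))), class = "nbi_net_spec")
  expect_error(infer_shapes(bad), "conv_bad")
})

test_that("the default parameter count is the spec-derived constant", {
  # conv1 7*7*3*64+64, conv2 3*3*64*256+256, fc 9216*1024+1024,
  # 1024*128+128, 128*3+3
  expect_equal(n_parameters(nbi_net_spec()), 9726979)
})

test_that("training reduces the loss, is seed-deterministic, and masters
          trivially separable patches", {
  pt <- toy_hue_patches(n_per_class = 25)
  cfg <- train_config(epochs = 8, batch_size = 25, seed = 3)
  net <- nbi_train(pt, cfg)
  expect_lt(tail(net$loss_history, 1), net$loss_history[1])
  expect_equal(length(net$loss_history), 8)
  # class = dominant hue is linearly separable: perfect training accuracy
  pred <- predict_softmax(net, pt)
  expect_equal(mean(pred$.pred_class == pt$label), 1)
  # identical seed reproduces the loss trajectory exactly
  net2 <- nbi_train(pt, cfg)
  expect_identical(net$loss_history, net2$loss_history)
  # training mean is per-channel and computed from the training data
  expect_length(net$training_mean, 3)
  # broom-style accessors
  expect_equal(nrow(tidy(net)), 8)
  expect_equal(glance(net)$n_parameters, 9726979)
})

test_that("single-class training data is rejected", {
  pt <- toy_hue_patches(n_per_class = 4)
  expect_error(nbi_train(pt[pt$label == "A", ], train_config(epochs = 1)),
               "zero samples")
})

test_that("softmax rows are probability vectors and deterministic", {
  pt <- toy_hue_patches(n_per_class = 6)
  net <- nbi_train(pt, train_config(epochs = 1, batch_size = 18, seed = 1))
  pr <- predict_softmax(net, pt)
  probs <- as.matrix(pr[paste0("p_", ipcl_classes)])
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, nrow(pt)), tolerance = 1e-6)
  # duplicated patch gives identical rows
  dup <- pt[c(1, 1), ]
  prd <- predict_softmax(net, dup)
  expect_identical(prd[1, ], prd[2, ])
  # uniform logits give the uniform distribution
  expect_equal(ipclkit:::softmax_cols(matrix(0, 3, 1))[, 1], rep(1 / 3, 3))
})

test_that("feature extraction returns the documented widths, ReLU applied", {
  pt <- toy_hue_patches(n_per_class = 5)
  net <- nbi_train(pt, train_config(epochs = 1, batch_size = 15, seed = 2))
  f1 <- extract_features(net, pt, "fc1")
  f2 <- extract_features(net, pt, "fc2")
  f3 <- extract_features(net, pt, "fc3")
  expect_equal(ncol(f1), 1024)
  expect_equal(ncol(f2), 128)
  expect_equal(ncol(f3), 3)
  expect_equal(nrow(f1), nrow(pt))
  # fc1/fc2 are post-ReLU (nonnegative); fc3 logits are signed
  expect_true(all(f1 >= 0))
  expect_true(all(f2 >= 0))
  expect_true(any(f3 < 0))
  # extraction is deterministic (dropout disabled)
  expect_identical(f1, extract_features(net, pt, "fc1"))
  expect_error(extract_features(net, pt, "fc9"), "fc1")
})
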