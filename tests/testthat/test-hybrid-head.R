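test_that("three classes yield exactly three pairwise classifiers", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 5), 10),
             matrix(rnorm(20, 10), 10))
  y <- rep(ipcl_classes, each = 10)
  m <- fit_ovo(X, y)
  expect_s3_class(m, "ipcl_ovo")
  expect_length(m$models, 3)               # C(3, 2)
  expect_equal(glance(m)$n_classifiers, 3)
  expect_equal(nrow(tidy(m)), 3)
  expect_error(fit_ovo(X[1:10, ], y[1:10]), "2 classes")
})

test_that("separable two-class data is fit to perfect training accuracy", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0, 0.5), 20), matrix(rnorm(40, 8, 0.5), 20))
  y <- rep(c("A", "B1"), each = 20)
  m <- fit_ovo(X, y, svm_config(C = 10))
  pred <- predict_votes(m, X)
  expect_equal(mean(pred$.pred_class == y), 1)
})

test_that("the dual solver matches a brute-force primal search on 6 points", {
  # hand-placed separable 2-D instance
  X <- rbind(c(0, 0), c(1, 0.5), c(0.4, 1.2),
             c(3, 2.5), c(4, 2), c(3.5, 3.2))
  y <- rep(c("A", "B1"), each = 3)
  # brute force: maximize the margin over hyperplane directions
  best <- list(margin = -Inf)
  for (th in seq(0, pi, length.out = 4001)) {
    d <- c(cos(th), sin(th))
    p <- X %*% d
    m1 <- max(p[1:3]); m2 <- min(p[4:6])
    margin <- (m2 - m1) / 2
    if (margin > best$margin) {
      best <- list(margin = margin, w = d, b = -(m1 + m2) / 2, flip = 1)
    }
    margin2 <- (min(p[1:3]) - max(p[4:6])) / 2  # other orientation
    if (margin2 > best$margin) {
      best <- list(margin = margin2, w = -d, b = (min(p[1:3]) +
                                                    max(p[4:6])) / 2,
                   flip = -1)
    }
  }
  # near-hard-margin SVM on the same points (no standardization)
  m <- fit_ovo(X, y, svm_config(C = 1e4, standardize = FALSE))
  sv <- m$models[[1]]
  w <- drop(t(sv$coefs) %*% sv$SV)
  b <- -sv$rho
  geom_margin <- 1 / sqrt(sum(w^2))
  expect_equal(geom_margin, best$margin, tolerance = 0.01)
  # same hyperplane direction up to sign/scale
  cosang <- abs(sum(w * best$w)) / sqrt(sum(w^2))
  expect_gt(cosang, 0.999)
  expect_equal(mean(predict_votes(m, X)$.pred_class == y), 1)
})

test_that("vote tallies always sum to the number of pairwise classifiers", {
  set.seed(4)
  X <- rbind(matrix(rnorm(80, 0), 20), matrix(rnorm(80, 4), 20),
             matrix(rnorm(80, 8), 20))
  y <- rep(ipcl_classes, each = 20)
  m <- fit_ovo(X, y)
  pred <- predict_votes(m, matrix(rnorm(120, 4), 30))
  tot <- pred$votes_A + pred$votes_B1 + pred$votes_B2_B3
  expect_true(all(tot == 3))
  # a sample deep inside one class's region collects both its votes
  deep <- matrix(colMeans(X[y == "A", ]), 1)
  pd <- predict_votes(m, deep)
  expect_equal(pd$votes_A, 2)
  expect_identical(pd$.pred_class, "A")
})

test_that("vote ties resolve deterministically by margin then class order", {
  # three symmetric blobs around the origin; the centroid ties the vote
  set.seed(6)
  ang <- c(pi / 2, pi * 7 / 6, pi * 11 / 6)
  X <- do.call(rbind, lapply(ang, function(a) {
    cbind(rnorm(15, 5 * cos(a), 0.3), rnorm(15, 5 * sin(a), 0.3))
  }))
  y <- rep(ipcl_classes, each = 15)
  m <- fit_ovo(X, y, svm_config(standardize = FALSE))
  center <- matrix(0, 1, 2)
  p1 <- predict_votes(m, center)
  p2 <- predict_votes(m, center)
  expect_identical(p1, p2)                 # deterministic
  votes <- c(p1$votes_A, p1$votes_B1, p1$votes_B2_B3)
  margins <- c(p1$margin_A, p1$margin_B1, p1$margin_B2_B3)
  top <- which(votes == max(votes))
  # the tie-break rule: among max-vote classes, largest margin sum wins,
  # then the lowest class index
  winners <- top[margins[top] == max(margins[top])]
  expect_identical(p1$.pred_class, ipcl_classes[winners[1]])
})

test_that("standardization and PCA are fit on training rows and applied on predict", {
  set.seed(8)
  X <- cbind(matrix(rnorm(80, 0, 100), 40), matrix(rnorm(80, 0, 0.01), 40))
  X[21:40, 1] <- X[21:40, 1] + 500
  y <- rep(c("A", "B2_B3"), each = 20)
  m <- fit_ovo(X, y, svm_config(pca = 0.95, standardize = FALSE))
  expect_false(is.null(m$rotation))
  expect_lt(ncol(m$rotation), ncol(X))
  expect_equal(mean(predict_votes(m, X)$.pred_class == y), 1)
  expect_error(predict_votes(m, X[, 1:2]), "dimension")
})

test_that("compare_heads reports two accuracies and their difference", {
  pt <- toy_hue_patches(n_per_class = 12, seed = 9)
  idx_te <- rep(c(TRUE, FALSE, FALSE), 12)
  net <- nbi_train(pt[!idx_te, ], train_config(epochs = 2, batch_size = 24,
                                               seed = 5))
  rep <- compare_heads(net, pt[!idx_te, ], pt[idx_te, ],
                       layers = c("fc1", "fc2"))
  expect_equal(nrow(rep), 2)
  expect_named(rep, c("layer", "acc_softmax", "acc_svm", "boost"))
  expect_equal(rep$boost, rep$acc_svm - rep$acc_softmax)
  expect_true(all(rep$acc_softmax >= 0 & rep$acc_softmax <= 1))
  # on these easy patches the two heads are close: |boost| < 20 points
  expect_true(all(abs(rep$boost) < 0.2))
})
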