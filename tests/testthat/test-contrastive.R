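# Contrastive module: augmentations, loss, EMA target updates, training
# mechanics, and feature extraction contracts.

test_that("identity policy reproduces the input view", {
  pol <- aug_policy(brightness = 0, contrast = c(1, 1), rotate = 0,
                    aspect = c(1, 1), flip_p = 0, crop_area = c(1, 1),
                    out_hw = c(64, 64))
  img <- matrix(runif(64 * 64), 64, 64)
  v <- augment(img, pol)
  expect_equal(v$view1, img, tolerance = 1e-12)
  expect_equal(v$view2, img, tolerance = 1e-12)
})

test_that("pure brightness shift acts as a clipped additive constant", {
  pol <- aug_policy(brightness = 0.2, contrast = c(1, 1), rotate = 0,
                    aspect = c(1, 1), flip_p = 0, crop_area = c(1, 1),
                    out_hw = c(64, 64))
  img <- matrix(0.9, 64, 64)
  set.seed(2)
  v <- augment(img, pol)
  expect_equal(diff(range(v$view1)), 0)  # stays constant
  expect_true(all(v$view1 >= 0 & v$view1 <= 1))
  b <- v$view1[1, 1] - 0.9
  expect_true(abs(b) <= 0.2 + 1e-12)
})

test_that("augmented views respect the B-scan contract and are seeded", {
  pol <- aug_policy(out_hw = c(64, 64))
  img <- matrix(runif(64 * 64), 64, 64)
  set.seed(31)
  for (i in 1:20) {
    v <- augment(img, pol)
    expect_equal(dim(v$view1), c(64L, 64L))
    expect_true(all(v$view1 >= 0 & v$view1 <= 1))
    expect_true(all(v$view2 >= 0 & v$view2 <= 1))
  }
  v1 <- local({ set.seed(5); augment(img, pol) })
  v2 <- local({ set.seed(5); augment(img, pol) })
  expect_identical(v1, v2)
})

test_that("loss hits its closed-form anchors on aligned vectors", {
  v <- c(0.3, -1.2, 2.0)
  expect_equal(byol_loss(v, v), 0)
  expect_equal(byol_loss(c(1, 0), c(0, 1)), 2)
  expect_equal(byol_loss(v, -v), 4)
  expect_error(byol_loss(c(0, 0), c(1, 0)), "zero")
})

test_that("loss is bounded and scale invariant over random inputs", {
  set.seed(17)
  for (i in 1:50) {
    p <- rnorm(16); z <- rnorm(16)
    l <- byol_loss(p, z)
    expect_true(l >= 0 && l <= 4)
    expect_equal(byol_loss(runif(1, 0.1, 9) * p, runif(1, 0.1, 9) * z), l,
                 tolerance = 1e-10)
  }
})

test_that("EMA update matches its closed form on vectors and nested lists", {
  expect_equal(ema_update(1.0, 0.0, 0.9), 0.9)
  expect_equal(ema_update(c(1, 2), c(3, 4), 0), c(3, 4))
  tg <- list(a = matrix(1, 2, 2), b = list(c = rep(2, 3)))
  on <- list(a = matrix(5, 2, 2), b = list(c = rep(0, 3)))
  up <- ema_update(tg, on, 0.5)
  expect_equal(up$a, matrix(3, 2, 2))
  expect_equal(up$b$c, rep(1, 3))
  expect_error(ema_update(list(a = 1:2), list(a = 1:3), 0.5), "do not match")
})

test_that("a single training step changes parameters and logs the loss", {
  imgs <- tiny_run()$images
  st <- train_byol(imgs[, , 1:16], aug_policy(out_hw = c(64, 64)),
                   byol_config(steps = 1, batch_size = 8, seed = 2))
  expect_s3_class(st, "byol_state")
  expect_equal(nrow(st$log), 1)
  expect_true(is.finite(st$log$loss))
  # after one Adam step the online weights have moved off the (EMA-frozen)
  # target copy of the shared initialization
  expect_false(identical(st$online$enc[[1]]$W, st$target$enc[[1]]$W))
})

test_that("training is deterministic given the seed", {
  imgs <- tiny_run()$images
  s1 <- train_byol(imgs[, , 1:24], aug_policy(out_hw = c(64, 64)),
                   byol_config(steps = 5, batch_size = 8, seed = 9))
  s2 <- train_byol(imgs[, , 1:24], aug_policy(out_hw = c(64, 64)),
                   byol_config(steps = 5, batch_size = 8, seed = 9))
  expect_identical(s1$online, s2$online)
  expect_identical(s1$log, s2$log)
})

test_that("extraction is deterministic, batch-size independent, and typed", {
  tr <- tiny_run()
  imgs <- tr$images[, , 1:40]
  f32 <- extract_features(tr$state, imgs, batch_size = 32)
  f1 <- extract_features(tr$state, imgs, batch_size = 1)
  expect_equal(dim(f32), c(40L, 64L))
  expect_true(all(is.finite(f32)))
  expect_equal(f32, f1, tolerance = 1e-5)
  # duplicate image -> identical feature rows
  dup <- imgs[, , c(1, 1, 2)]
  fd <- extract_features(tr$state, dup)
  expect_equal(fd[1, ], fd[2, ])
  expect_error(extract_features(tr$state, array(0.5, c(32, 32, 2))), "expects")
})

test_that("training improves two-view feature alignment over initialization", {
  # alignment is measured relative to unrelated images: with ReLU features
  # even a random network gives near-unit cosine between ANY two inputs, so
  # the meaningful pre/post quantity is the within-image (two-view) minus
  # between-image cosine gap
  run <- desk_run()
  imgs <- run$images
  pol <- aug_policy(out_hw = c(64, 64))
  init <- train_byol(imgs[, , 1:64], pol,
                     byol_config(steps = 1, batch_size = 4, seed = 1))
  alignment_gap <- function(state, idx) {
    set.seed(99)
    X <- imgs[, , idx]
    feats <- vapply(seq_along(idx), function(i) {
      v <- augment(X[, , i], pol)
      f <- extract_features(state, array(c(v$view1, v$view2), c(64, 64, 2)))
      c(sum(f[1, ] * f[2, ]) / sqrt(sum(f[1, ]^2) * sum(f[2, ]^2)), f[1, ])
    }, numeric(1 + 64))
    within <- mean(feats[1, ])
    F1 <- t(feats[-1, ])
    F1 <- F1 / sqrt(rowSums(F1^2))
    G <- tcrossprod(F1)
    between <- mean(G[upper.tri(G)])
    within - between
  }
  idx <- seq(1, 2000, by = 25)  # held-out-style sample across the cohort
  expect_gt(alignment_gap(run$state, idx), alignment_gap(init, idx))
})

test_that("trained features do not collapse", {
  run <- desk_run()
  sds <- apply(run$features[1:200, ], 2, sd)
  expect_true(all(sds > 1e-3))
  # between-image spread exceeds the two-view (within-image) spread
  pol <- aug_policy(out_hw = c(64, 64))
  set.seed(7)
  idx <- sample(2000, 40)
  within <- mean(vapply(idx, function(i) {
    v <- augment(run$images[, , i], pol)
    f <- extract_features(run$state, array(c(v$view1, v$view2), c(64, 64, 2)))
    sqrt(sum((f[1, ] - f[2, ])^2))
  }, numeric(1)))
  between <- mean(dist(run$features[idx, ]))
  expect_gt(between, within)
})

test_that("features are more linearly class-separable than raw pixels", {
  run <- desk_run()
  cls <- as.integer(factor(run$cohort$truth$class))
  k <- max(cls)
  set.seed(15)
  tr <- sample(length(cls), 1000)
  px <- t(matrix(run$images, 64 * 64, length(cls)))
  pf <- fit_linear_probe(run$features[tr, ], cls[tr], k = k)
  pp <- fit_linear_probe(px[tr, ], cls[tr], k = k, max_epochs = 150)
  acc_f <- mean(predict(pf, run$features[-tr, ]) == cls[-tr])
  acc_p <- mean(predict(pp, px[-tr, ]) == cls[-tr])
  expect_gt(acc_f, acc_p)
})
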