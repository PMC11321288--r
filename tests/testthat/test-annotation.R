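# Annotation artifacts: stage-cluster conditional probabilities, linear
# probe, GradCAM maps, review panels, and the summary table.

test_that("stage-cluster rows are label frequencies over labeled images", {
  a <- c(rep(1, 10), rep(2, 4))
  lab <- c(rep("MNV", 8), rep("healthy", 2), rep(NA, 4))
  M <- stage_cluster_matrix(a, lab, k = 2)
  expect_equal(M["C1", "MNV"], 0.8)
  expect_equal(M["C1", "healthy"], 0.2)
  expect_equal(sum(M["C1", ]), 1)
  expect_true(all(is.na(M["C2", ])))
  expect_equal(attr(M, "flagged"), 2L)
  expect_error(stage_cluster_matrix(a, rep("bogus", 14)), "unknown grading label")
})

test_that("rows with labels sum to one across random inputs", {
  set.seed(3)
  a <- sample(1:6, 500, replace = TRUE)
  lab <- sample(c(grading_labels(), NA), 500, replace = TRUE)
  M <- stage_cluster_matrix(a, lab, k = 6)
  n <- attr(M, "n_labeled")
  expect_true(all(abs(rowSums(M)[n > 0] - 1) < 1e-12))
})

test_that("shuffled labels converge to the global label frequencies", {
  set.seed(4)
  n <- 10000
  a <- sample(1:5, n, replace = TRUE)
  lab <- sample(grading_labels(), n, replace = TRUE,
                prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
  lab <- sample(lab)  # permutation null
  M <- stage_cluster_matrix(a, lab, k = 5)
  glob <- table(factor(lab, grading_labels())) / n
  for (c in 1:5) expect_true(all(abs(M[c, ] - glob) < 0.05))
})

test_that("the linear probe solves separable blobs and chance on noise", {
  set.seed(5)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  y <- rep(1:2, each = 50)
  pr <- fit_linear_probe(X, y, k = 2)
  expect_equal(pr$train_accuracy, 1.0)
  expect_equal(predict(pr, X), y)
  # permuted labels on many more samples than parameters -> near chance
  set.seed(6)
  Xr <- matrix(rnorm(3000 * 4), 3000, 4)
  yr <- sample(1:5, 3000, replace = TRUE)
  prr <- fit_linear_probe(Xr, yr, k = 5, max_epochs = 200)
  expect_lt(prr$train_accuracy, 1 / 5 + 0.08)
  expect_error(fit_linear_probe(X, rep(1L, 100)), "degenerate")
})

test_that("probe predictions agree with nearest-centroid assignments", {
  run <- tiny_run()
  f <- extract_features(run$state, run$images)
  m <- kmeans_fit(f, k = 4, seed = 1)
  m <- order_clusters_by_va(m, run$cohort$manifest$letters)
  a <- cluster_assign(f, m)
  pr <- fit_linear_probe(f, a, k = 4)
  expect_gte(mean(predict(pr, f) == a), 0.9)
})

test_that("GradCAM maps satisfy the shape/positivity contract", {
  run <- tiny_run()
  f <- extract_features(run$state, run$images)
  m <- kmeans_fit(f, k = 3, seed = 1)
  pr <- fit_linear_probe(f, cluster_assign(f, m), k = 3)
  am <- gradcam_attribution(run$state, pr, run$images[, , 1], 2)
  expect_equal(dim(am), c(64L, 64L))
  expect_true(min(am) >= 0)
  expect_equal(max(am), 1)
  # a probe logit independent of the features backs a zero map
  pr0 <- pr
  pr0$W[, 3] <- 0
  expect_warning(am0 <- gradcam_attribution(run$state, pr0,
                                            run$images[, , 1], 3),
                 "all-zero")
  expect_true(all(am0 == 0))
  expect_true(attr(am0, "degenerate"))
})

test_that("review panels draw 20 distinct patients or truncate with warning", {
  set.seed(8)
  a <- rep(1L, 60)
  pats <- paste0("P", rep(1:25, length.out = 60))
  p <- sample_review_panels(a, pats, n_each = 10)
  ids <- c(p[[1]]$seen, p[[1]]$unseen)
  expect_equal(length(ids), 20)
  expect_equal(length(unique(pats[ids])), 20)
  expect_equal(length(intersect(p[[1]]$seen, p[[1]]$unseen)), 0)
  # truncation
  a2 <- rep(1L, 12)
  pats2 <- paste0("P", 1:12)
  expect_warning(p2 <- sample_review_panels(a2, pats2), "truncated")
  expect_equal(length(c(p2[[1]]$seen, p2[[1]]$unseen)), 12)
  # determinism
  p3 <- local({ set.seed(9); sample_review_panels(a, pats) })
  p4 <- local({ set.seed(9); sample_review_panels(a, pats) })
  expect_identical(p3, p4)
})

test_that("summary table reproduces image/patient ratios and totals", {
  a <- c(rep(1L, 6), rep(2L, 4))
  pats <- c("A", "A", "B", "C", "C", "C", "D", "E", "F", "F")
  tab <- cluster_summary_table(a, pats)
  expect_equal(tab$ratio[1], 2.0)   # 6 images / 3 patients
  expect_equal(tab$ratio[2], 1.3)   # 4 / 3
  expect_equal(tab$n_images[3], 10)
  expect_equal(sum(tab$n_images[1:2]), tab$n_images[3])
  # n images from n patients -> 1.0
  tab2 <- cluster_summary_table(rep(1L, 5), paste0("P", 1:5))
  expect_equal(tab2$ratio[1], 1.0)
  expect_error(cluster_summary_table(a, c(pats[-10], NA)), "missing patient id")
})

test_that("probe predictions agree with an independent multinomial fit", {
  set.seed(9)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 4), 40, 2),
             matrix(rnorm(80, -4), 40, 2))
  y <- rep(1:3, each = 40)
  pr <- fit_linear_probe(X, y, k = 3)
  mn <- nnet::multinom(cls ~ ., data = data.frame(cls = factor(y), X),
                       trace = FALSE)
  agree <- mean(predict(pr, X) == as.integer(predict(mn)))
  expect_gte(agree, 0.95)
})
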