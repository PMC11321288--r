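# Prognostic benchmark machinery: outcome construction, patient-wise
# folds, per-system fits, MAE, and acuity stratification.

make_visits <- function(n_pat = 12, n_vis = 3, interval = 0.5) {
  df <- expand.grid(visit_index = seq_len(n_vis), patient = seq_len(n_pat))
  data.frame(patient_id = sprintf("P%02d", df$patient),
             eye_id = sprintf("P%02d_E1", df$patient),
             visit_years = (df$visit_index - 1) * interval,
             age = 75, sex = "F", letters = 70,
             grading_label = "healthy", stringsAsFactors = FALSE)
}

test_that("time-to-event arithmetic, eligibility, and late-AMD rule", {
  v <- data.frame(patient_id = "P1", eye_id = "E1", visit_years = 0,
                  age = 70, sex = "F", letters = 80, stringsAsFactors = FALSE)
  conv <- data.frame(eye_id = "E1", time_mnv = 1.5, time_crora = 2.5)
  o <- build_outcomes(v, conv)
  expect_equal(o$time_to_mnv, 1.5)
  expect_equal(o$time_to_crora, 2.5)
  expect_equal(o$time_to_late, 1.5)
  # missing cRORA event excludes the visit from that task only
  conv2 <- data.frame(eye_id = "E1", time_mnv = 1.5, time_crora = NA)
  o2 <- build_outcomes(v, conv2)
  expect_true(is.na(o2$time_to_crora))
  expect_equal(o2$time_to_late, 1.5)
  # visits after the event are ineligible
  v3 <- rbind(v, within(v, visit_years <- 2))
  o3 <- build_outcomes(v3, conv2)
  expect_true(is.na(o3$time_to_mnv[2]))
  # event before the first visit drops the eye with a warning
  v4 <- within(v, visit_years <- 3)
  expect_warning(o4 <- build_outcomes(v4, conv), "before the first visit")
  expect_equal(nrow(o4), 0)
})

test_that("folds are patient-disjoint 80/20 draws and seeded", {
  pats <- sprintf("P%02d", rep(1:10, each = 4))
  folds <- make_folds(pats, n_folds = 10, seed = 3)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(length(f$test), 2)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), unique(pats))
  }
  expect_identical(folds, make_folds(pats, n_folds = 10, seed = 3))
  expect_error(make_folds(sprintf("P%d", 1:5), n_folds = 10), "at least 10")
})

test_that("a noiseless linear target in the similarity space is realizable", {
  set.seed(11)
  n <- 400
  S <- matrix(rexp(n * 6), n, 6)
  S <- S / rowSums(S)
  colnames(S) <- paste0("sim_", 1:6)
  beta <- c(3, -2, 1, 0, 0, 2)
  d <- data.frame(patient_id = sprintf("P%03d", rep(1:100, each = 4)),
                  y = as.vector(S %*% beta), S, check.names = FALSE)
  tr <- d[1:300, ]; te <- d[301:400, ]
  pred <- fit_predict("clusters", tr, te, "y")
  expect_lt(mae(pred, te$y), 1e-3)
})

test_that("the demographic OLS recovers a noiseless linear age effect", {
  d <- data.frame(age = seq(50, 90, length.out = 40),
                  sex = rep(c("F", "M"), 20))
  d$y <- 10 - 0.1 * d$age + 0.5 * (d$sex == "M")
  pred <- fit_predict("demographic", d[1:30, ], d[31:40, ], "y")
  expect_lt(mae(pred, d$y[31:40]), 1e-8)
})

test_that("constant training targets fall back to the mean with a warning", {
  d <- make_visits()
  d$y <- 5
  expect_warning(pred <- fit_predict("demographic", d, d, "y"), "constant")
  expect_equal(unique(pred), 5)
})

test_that("MAE is zero for perfect predictions and row-order invariant", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 4), c(2, 2)), 1.5)
  set.seed(13)
  p <- rnorm(50); y <- rnorm(50)
  o <- sample(50)
  expect_equal(mae(p, y), mae(p[o], y[o]))
  expect_equal(mae(c(1, NA, 3), c(1, 5, 4)), 0.5)
})

test_that("inner-CV Lasso recovers sparse supports at moderate SNR", {
  res <- lasso_support_recovery(n = 300, k = 12, support_size = 3, snr = 5,
                                n_reps = 5, seed = 2)
  expect_gte(res$rate, 0.6)
})

test_that("acuity stratification: degenerate CIs, root-n shrinkage, ordering", {
  v <- va_stratification(rep(1L, 4), c(60, 60, 60, 60))
  expect_equal(v$mean[1], 60)
  expect_equal(v$ci_hi[1] - v$ci_lo[1], 0)
  s1 <- va_stratification(c(1L, 2L), c(70, 80))
  expect_true(all(s1$flagged))
  # CI width shrinks like 1/sqrt(n)
  set.seed(14)
  widths <- vapply(c(25, 100, 400), function(n) {
    x <- rnorm(n, 70, 5)
    v <- va_stratification(rep(1L, n), x)
    v$ci_hi[1] - v$ci_lo[1]
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
  # means reported in ordered-cluster index order with a trend statistic
  a <- rep(1:3, each = 30)
  lt <- c(rnorm(30, 80, 2), rnorm(30, 70, 2), rnorm(30, 60, 2))
  vs <- va_stratification(a, lt)
  expect_equal(vs$cluster, 1:3)
  expect_lt(attr(vs, "trend_tau"), 0)
})
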