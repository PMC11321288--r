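# Synthetic layered-retina generator: geometry, planting, rendering,
# cohort assembly, and the ground-truth guarantees downstream stages rely on.

test_that("layer geometry is ordered, bounded, and band-limited", {
  set.seed(1)
  for (i in 1:25) {
    g <- generate_retina_layers(64, 64, depth_offset = runif(1, -4, 4))
    expect_true(all(g$ilm < g$rpe))
    expect_true(all(g$rpe < g$bm))
    expect_true(all(g$bm < g$csj))
    expect_true(all(g$ilm >= 1) && all(g$csj <= 63))
  }
  expect_error(generate_retina_layers(32, 64), "invalid dimensions")
})

test_that("zero pit depth gives a flat ILM and seeds reproduce geometry", {
  set.seed(3)
  g <- generate_retina_layers(64, 64, pit_depth = 0, wiggle = 0)
  expect_equal(diff(range(g$ilm)), 0)
  g1 <- local({ set.seed(11); generate_retina_layers(64, 64) })
  g2 <- local({ set.seed(11); generate_retina_layers(64, 64) })
  expect_identical(g1, g2)
})

test_that("physical width bookkeeping uses the 23.4 um mediolateral pitch", {
  expect_equal(px_to_um(256), 5990.4)
  expect_equal(um_to_px(63), 3L)
  expect_equal(um_to_px(1000), 43L)
})

test_that("planted lesion masks cover exactly round(size / 23.4) columns", {
  set.seed(5)
  for (case in list(c("drusen_large", 63), c("drusen_large", 120),
                    c("subretinal_fluid", 350), c("atrophy_complete", 600),
                    c("scarring", 400))) {
    g <- generate_retina_layers(64, 64)
    pl <- plant_biomarker(g, biomarker_spec(case[1], as.numeric(case[2])))
    cols <- unique(which(pl$mask == 1, arr.ind = TRUE)[, 2])
    expect_equal(length(cols), round(as.numeric(case[2]) / 23.4),
                 info = paste(case, collapse = " "))
    validate_geometry(pl$geometry)
  }
})

test_that("healthy planting is the identity; oversized lesions are rejected", {
  set.seed(6)
  g <- generate_retina_layers(64, 64)
  pl <- plant_biomarker(g, biomarker_spec("healthy"))
  expect_equal(sum(pl$mask), 0)
  expect_equal(pl$geometry$rpe, g$rpe)
  expect_equal(pl$geometry$ilm, g$ilm)
  expect_error(plant_biomarker(g, biomarker_spec("scarring", size_um = 2000)),
               "wider than image")
})

test_that("complete atrophy thins the retina and flags hypertransmission", {
  set.seed(8)
  g <- generate_retina_layers(64, 64)
  pl <- plant_biomarker(g, biomarker_spec("atrophy_complete", size_um = 1000,
                                          location = 32))
  cols <- which(pl$geometry$hypertrans)
  expect_equal(length(cols), 43)
  # RPE elevated (smaller depth -> thinner retina) exactly on lesion columns
  expect_true(all(pl$geometry$rpe[cols] < g$rpe[cols]))
  off <- setdiff(seq_len(64), cols)
  expect_equal(pl$geometry$rpe[off], g$rpe[off])
  expect_true(all(pl$geometry$rpe - pl$geometry$ilm > 0))
})

test_that("noiseless render is piecewise constant at the band reflectivities", {
  set.seed(9)
  g <- generate_retina_layers(64, 64, wiggle = 0, pit_depth = 0)
  img <- render_bscan(g, noise = 0)
  expect_setequal(unique(round(as.vector(unclass(img)), 9)),
                  c(0.03, 0.45, 0.85, 0.25, 0.08))
  col <- img[, 10]
  expect_equal(col[seq_len(floor(g$ilm[10]))], rep(0.03, floor(g$ilm[10])))
})

test_that("hypertransmission brightens the choroid under lesion columns", {
  set.seed(10)
  g <- generate_retina_layers(64, 64)
  pl <- plant_biomarker(g, biomarker_spec("atrophy_complete", location = 32))
  img <- render_bscan(pl$geometry, noise = 0)
  ht <- pl$geometry$hypertrans
  choroid_mean <- function(cc) {
    mean(unlist(lapply(cc, function(c) {
      img[which(seq_len(64) > pl$geometry$bm[c] &
                  seq_len(64) <= pl$geometry$csj[c]), c]
    })))
  }
  expect_gt(choroid_mean(which(ht)), choroid_mean(which(!ht)))
})

test_that("renders are deterministic under a fixed seed and bounded", {
  g <- local({ set.seed(12); generate_retina_layers(64, 64) })
  i1 <- local({ set.seed(13); render_bscan(g, noise = 0.15) })
  i2 <- local({ set.seed(13); render_bscan(g, noise = 0.15) })
  expect_identical(i1, i2)
  expect_true(min(i1) >= 0 && max(i1) <= 1)
})

test_that("cohort counts, determinism, and metadata contracts hold", {
  co <- generate_cohort(cohort_config(n_patients = 10, eyes_per_patient = 1,
                                      visits_per_eye = 3, seed = 4))
  expect_equal(dim(co$images)[3], 30)
  expect_equal(nrow(co$manifest), 30)
  expect_equal(length(unique(co$manifest$eye_id)), 10)
  expect_true(all(co$manifest$letters >= 5 & co$manifest$letters <= 95))
  expect_true(all(is.na(co$manifest$grading_label) |
                    co$manifest$grading_label %in% grading_labels()))
  co2 <- generate_cohort(cohort_config(n_patients = 10, eyes_per_patient = 1,
                                       visits_per_eye = 3, seed = 4))
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$images, co2$images)
  expect_error(cohort_config(mixture = c(0.5, 0.2)), "one proportion per class")
  expect_error(cohort_config(classes = c("healthy", "PED"), mixture = c(0.7, 0.2)),
               "sum to 1")
})

test_that("masks are nonzero exactly for lesion classes", {
  co <- generate_cohort(cohort_config(n_patients = 30, visits_per_eye = 1,
                                      classes = c("healthy", "poor_quality",
                                                  "PED", "scarring"),
                                      mixture = rep(0.25, 4), seed = 6))
  mask_px <- apply(co$truth$masks, 3, sum)
  lesion <- !co$truth$class %in% c("healthy", "poor_quality")
  expect_true(all(mask_px[lesion] > 0))
  expect_true(all(mask_px[!lesion] == 0))
})

test_that("generated class proportions match the mixture at n = 2000", {
  cf <- cohort_config(n_patients = 2000, visits_per_eye = 1, seed = 2)
  co <- generate_cohort(cf)
  prop <- table(factor(co$truth$class, levels = cf$classes)) / 2000
  expect_true(all(abs(prop - cf$mixture) < 0.05))
})

test_that("per-visit acuity tracks the severity ordering of planted classes", {
  co <- generate_cohort(cohort_config(n_patients = 400, visits_per_eye = 1,
                                      seed = 9))
  med <- tapply(co$manifest$letters, co$truth$class, median)
  expect_gt(med["healthy"], med["PED"])
  expect_gt(med["PED"], med["atrophy_complete"])
  expect_gt(med["atrophy_complete"], med["scarring"])
})

test_that("a nearest-centroid classifier separates noiseless renders", {
  render_one <- function(cls) {
    g <- generate_retina_layers(64, 64)
    as.vector(unclass(render_bscan(plant_biomarker(g, biomarker_spec(cls))$geometry,
                                   noise = 0)))
  }
  ncc_acc <- function(classes, n_per = 12) {
    X <- sapply(rep(classes, each = n_per), render_one)
    lab <- rep(classes, each = n_per)
    centroids <- sapply(classes, function(cl) rowMeans(X[, lab == cl, drop = FALSE]))
    d2 <- outer(colSums(X^2), rep(1, length(classes))) -
      2 * t(X) %*% centroids + outer(rep(1, ncol(X)), colSums(centroids^2))
    mean(classes[apply(d2, 1, which.min)] == lab)
  }
  # the study's class set is perfectly recoverable in pixel space, so any
  # failure of downstream cluster recovery is the pipeline's, not the data's
  set.seed(21)
  expect_equal(ncc_acc(cohort_config()$classes), 1.0)
  # the full vocabulary includes a deliberately fine-grained drusen-size
  # continuum (55 vs 120 um) where single confusions are tolerated
  set.seed(22)
  expect_gte(ncc_acc(oct_classes()), 0.95)
})
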