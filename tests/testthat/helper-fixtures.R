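# Shared fixtures, memoized so expensive objects are built once per session.

# Desk-scale study run: 2000 synthetic 64x64 B-scans (200 patients x 10
# visits, 8 planted classes), small conv backbone trained 2000 BYOL steps.
desk_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- file.path(tempdir(), "octopheno_desk_run.rds")
    if (file.exists(path)) {
      cache <<- readRDS(path)
      return(cache)
    }
    cohort <- generate_cohort(cohort_config(seed = 1))
    images <- standardize_images(cohort$images)
    state <- train_byol(images, aug_policy(out_hw = c(64L, 64L)),
                        byol_config(steps = 2000L, seed = 1L))
    features <- extract_features(state, images)
    cache <<- list(cohort = cohort, images = images, state = state,
                   features = features)
    saveRDS(cache, path)
    cache
  }
})

# A small cohort and briefly-trained encoder for cheap mechanical tests.
tiny_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(cohort_config(n_patients = 40L,
                                            visits_per_eye = 2L, seed = 7L))
    images <- standardize_images(cohort$images)
    state <- train_byol(images, aug_policy(out_hw = c(64L, 64L)),
                        byol_config(steps = 30L, batch_size = 32L, seed = 7L,
                                    log_every = 10L))
    cache <<- list(cohort = cohort, images = images, state = state)
    cache
  }
})

# Brute-force k-means oracle for k = 2: exhaustive search over all
# 2-partitions, returning the minimal within-cluster sum of squares.
kmeans2_bruteforce <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (all(lab == 0) || all(lab == 1)) next
    wss <- 0
    for (g in 0:1) {
      sub <- X[lab == g, , drop = FALSE]
      wss <- wss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (wss < best) best <- wss
  }
  best
}
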