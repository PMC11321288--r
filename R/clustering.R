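# Partition the self-supervised feature space with k-means, order clusters
# clinically by median visual acuity, and represent each image by a
# normalized similarity vector over the ordered clusters.

# k-means++ seeding
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j, ] <- X[sample.int(n, 1), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

.sq_dist <- function(X, C) {
  # (n x k) squared Euclidean distances
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * tcrossprod(X, C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

#' Fit the cluster model on self-supervised features
#'
#' Per-dimension z-scoring followed by k-means (Lloyd iterations, at most
#' `iter_max`, best of `nstart` k-means++ seedings by within-cluster sum of
#' squares). The default `k = 30` matches the cluster count used for the
#' full-scale cohort; for synthetic recovery runs set `k` to the number of
#' planted classes.
#'
#' @param features `N x D` feature matrix ([extract_features()]).
#' @param k number of clusters (`N >= k`).
#' @param seed integer seed for the restarts.
#' @param nstart number of k-means++ restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @param standardize z-score each feature dimension before clustering.
#' @return object of class `"oct_clusters"`: centroids (in standardized
#'   space), training assignments (raw and ordered), the ordering
#'   permutation (identity until [order_clusters_by_va()] is applied), the
#'   standardization parameters, and the softmax temperature used by
#'   [similarity_vector()] (the mean squared nearest-centroid distance on
#'   the training set).
#' @export
kmeans_fit <- function(features, k = 30L, seed = 1L, nstart = 10L,
                       iter_max = 300L, standardize = TRUE) {
  stopifnot(is.matrix(features), all(is.finite(features)))
  N <- nrow(features)
  if (N < k) stop(sprintf("need at least k = %d rows, got %d", k, N))
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  if (!standardize) {
    mu <- rep(0, ncol(features)); sdv <- rep(1, ncol(features))
  }
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      fit <- NULL
      for (try in 1:5) {
        init <- .kmeanspp_init(X, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  d2 <- .sq_dist(X, best$centers)
  temperature <- mean(apply(d2, 1, min))
  if (temperature <= 0) temperature <- 1
  structure(list(centers = best$centers, k = as.integer(k),
                 assign_raw = as.integer(best$cluster),
                 ordering = seq_len(k), mu = mu, sd = sdv,
                 temperature = temperature,
                 tot_withinss = best$tot.withinss),
            class = "oct_clusters")
}

#' Order clusters by median visual acuity
#'
#' Reorders clusters so that ordered cluster 1 has the best (highest) median
#' letter score and cluster k the worst, mirroring the C1 (best vision) to
#' C30 (worst vision) naming. Ties are broken in favour of the larger
#' cluster, then the lower original index; clusters with no visual-acuity
#' data are placed last with a warning.
#'
#' @param model an `"oct_clusters"` fit.
#' @param letters per-image letter scores aligned with the training rows.
#' @return the model with its `ordering` permutation set;
#'   `model$ordering[j]` is the raw cluster index of ordered cluster `j`.
#' @export
order_clusters_by_va <- function(model, letters) {
  stopifnot(inherits(model, "oct_clusters"),
            length(letters) == length(model$assign_raw))
  k <- model$k
  med <- vapply(seq_len(k), function(c) {
    v <- letters[model$assign_raw == c]
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  size <- tabulate(model$assign_raw, nbins = k)
  if (anyNA(med)) {
    warning("cluster(s) with no visual-acuity data placed last: ",
            paste(which(is.na(med)), collapse = ", "))
  }
  perm <- order(-med, -size, seq_len(k), na.last = TRUE)
  model$ordering <- as.integer(perm)
  model$median_letters <- med[perm]
  model
}

# standardize new features with the model's parameters
.model_standardize <- function(features, model) {
  sweep(sweep(features, 2, model$mu), 2, model$sd, "/")
}

#' Assign images to ordered clusters
#'
#' Nearest-centroid rule in the standardized feature space, reported as
#' ordered cluster ids; distance ties go to the lower ordered index.
#'
#' @param features `N x D` feature matrix.
#' @param model a fitted (and usually VA-ordered) `"oct_clusters"`.
#' @return integer vector of ordered cluster ids in `1..k`.
#' @export
cluster_assign <- function(features, model) {
  stopifnot(inherits(model, "oct_clusters"), all(is.finite(features)))
  X <- .model_standardize(features, model)
  d2 <- .sq_dist(X, model$centers[model$ordering, , drop = FALSE])
  as.integer(apply(d2, 1, which.min))
}

#' Cluster-similarity vector of an image
#'
#' Length-k representation used by the prognostic models: a softmax over
#' negative squared Euclidean distances to the ordered centroids, with the
#' temperature fixed at fit time to the mean squared nearest-centroid
#' distance of the training set. Entries are nonnegative, sum to 1, and the
#' argmax is the assigned cluster.
#'
#' @param features feature vector (length D) or `N x D` matrix.
#' @param model a fitted `"oct_clusters"`.
#' @param kind `"softmax"` (default) or `"negdist"` (raw negative squared
#'   distances, unnormalized).
#' @return numeric vector of length k, or an `N x k` matrix.
#' @export
similarity_vector <- function(features, model, kind = c("softmax", "negdist")) {
  kind <- match.arg(kind)
  if (is.null(dim(features))) {
    return(drop(similarity_vector(matrix(features, 1), model, kind)))
  }
  if (any(!is.finite(features))) stop("non-finite feature values")
  X <- .model_standardize(features, model)
  d2 <- .sq_dist(X, model$centers[model$ordering, , drop = FALSE])
  if (kind == "negdist") return(-d2)
  logit <- -d2 / model$temperature
  logit <- logit - apply(logit, 1, max)
  e <- exp(logit)
  unname(e / rowSums(e))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; the synthetic-recovery metric comparing
#' cluster assignments with planted classes.
#' @param a,b two label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' @export
print.oct_clusters <- function(x, ...) {
  cat(sprintf("k-means cluster model: k = %d, D = %d, total WSS = %.2f\n",
              x$k, ncol(x$centers), x$tot_withinss))
  if (!is.null(x$median_letters)) {
    cat("  ordered by median visual acuity (letters):\n  ")
    cat(paste0("C", seq_len(x$k), "=", round(x$median_letters, 1)), fill = 70)
  }
  invisible(x)
}
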