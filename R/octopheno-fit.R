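# The modelling front end: one fitting function wrapping contrastive
# pretraining, feature extraction, clustering and visual-acuity ordering
# into a single classed model with the usual methods.

#' Fit a self-supervised OCT phenotype model
#'
#' Trains the contrastive feature extractor on the supplied B-scans (no
#' labels used), extracts pooled features, partitions them with k-means,
#' and — when letter scores are given — orders the clusters from best to
#' worst median visual acuity. Images are first passed through the
#' pipeline's per-image min-max intensity standardization
#' ([standardize_images()]); `predict()` applies the same step to new data. The result is a reusable model: `predict()`
#' assigns new images to clusters or returns similarity vectors, `plot()`
#' shows the visual-acuity stratification, `summary()` the per-cluster
#' composition.
#'
#' @param images `(H x W x N)` array (or list of matrices) of standardized
#'   B-scans with intensities in `[0, 1]`.
#' @param letters optional per-image visual-acuity letter scores used only
#'   to order the clusters for presentation; `NULL` keeps the raw order.
#' @param k number of clusters (30 at full scale; use the number of
#'   expected phenotypes at desk scale).
#' @param policy an [aug_policy()]; defaults to the OCT augmentation family
#'   at the image size.
#' @param config a [byol_config()].
#' @param seed master seed (overrides `config$seed`).
#' @param verbose log training progress.
#' @return An object of class `"octopheno"` with components `encoder`
#'   (the `"byol_state"`), `clusters` (the `"oct_clusters"` model),
#'   `features`, `assignments` (ordered ids for the training images), and
#'   `letters`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_config(n_patients = 30, visits_per_eye = 2))
#' fit <- octopheno(co$images, co$manifest$letters, k = 8,
#'                  config = byol_config(steps = 50, seed = 1))
#' table(fitted(fit), co$truth$class)
#' }
#' @export
octopheno <- function(images, letters = NULL, k = 30L,
                      policy = NULL, config = byol_config(),
                      seed = NULL, verbose = FALSE) {
  im <- .images_to_matrix(images)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(policy)) policy <- aug_policy(out_hw = im$hw)
  if (!is.null(letters) && length(letters) != ncol(im$X)) {
    stop("letters must have one entry per image")
  }
  if (is.array(images) && length(dim(images)) == 3) {
    images <- standardize_images(images)
  }
  encoder <- train_byol(images, policy, config, verbose = verbose)
  features <- extract_features(encoder, images)
  clusters <- kmeans_fit(features, k = k, seed = config$seed)
  if (!is.null(letters)) clusters <- order_clusters_by_va(clusters, letters)
  structure(list(encoder = encoder, clusters = clusters, features = features,
                 assignments = cluster_assign(features, clusters),
                 letters = letters, k = as.integer(k), call = match.call()),
            class = "octopheno")
}

#' @export
print.octopheno <- function(x, ...) {
  cat("Self-supervised OCT phenotype model\n")
  cat(sprintf("  %d training images, feature width %d, k = %d clusters%s\n",
              nrow(x$features), ncol(x$features), x$k,
              if (is.null(x$letters)) "" else " (ordered by visual acuity)"))
  cat(sprintf("  final contrastive loss %.4f; within-cluster SS %.1f\n",
              utils::tail(x$encoder$log$loss, 1), x$clusters$tot_withinss))
  invisible(x)
}

#' @export
summary.octopheno <- function(object, patient_ids = NULL, ...) {
  sizes <- tabulate(object$assignments, nbins = object$k)
  out <- data.frame(cluster = seq_len(object$k), n_images = sizes)
  if (!is.null(object$letters)) {
    va <- va_stratification(object$assignments, object$letters)
    out$mean_letters <- va$mean
    out$ci_lo <- va$ci_lo
    out$ci_hi <- va$ci_hi
  }
  if (!is.null(patient_ids)) {
    st <- cluster_summary_table(object$assignments, patient_ids)
    out$n_patients <- st$n_patients[seq_len(object$k)]
    out$ratio <- st$ratio[seq_len(object$k)]
  }
  class(out) <- c("summary.octopheno", "data.frame")
  out
}

#' @export
print.summary.octopheno <- function(x, ...) {
  cat("Per-cluster summary (ordered clusters)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict method for octopheno models
#'
#' @param object an [octopheno()] fit.
#' @param newdata `(H x W x N)` array of images at the training size;
#'   omitted for the training assignments.
#' @param type `"cluster"` for ordered cluster ids, `"similarity"` for the
#'   length-k similarity vectors, `"features"` for the raw features.
#' @param ... unused.
#' @return integer vector, or an `N x k` / `N x D` matrix.
#' @export
predict.octopheno <- function(object, newdata = NULL,
                              type = c("cluster", "similarity", "features"),
                              ...) {
  type <- match.arg(type)
  if (!is.null(newdata) && is.array(newdata) && length(dim(newdata)) == 3) {
    newdata <- standardize_images(newdata)
  }
  feats <- if (is.null(newdata)) object$features
           else extract_features(object$encoder, newdata)
  switch(type,
         cluster = cluster_assign(feats, object$clusters),
         similarity = {
           s <- similarity_vector(feats, object$clusters)
           colnames(s) <- paste0("C", seq_len(object$k))
           s
         },
         features = feats)
}

#' @export
fitted.octopheno <- function(object, ...) object$assignments

#' Plot the visual-acuity stratification of a fitted model
#'
#' Bar chart of mean letter score per ordered cluster with 95% confidence
#' intervals, the cluster analogue of a grading-system stratification plot.
#'
#' @param x an [octopheno()] fit with letter scores.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.octopheno <- function(x, ...) {
  if (is.null(x$letters)) stop("model was fitted without letter scores")
  va <- va_stratification(x$assignments, x$letters)
  bp <- graphics::barplot(va$mean, names.arg = paste0("C", va$cluster),
                          ylab = "visual acuity (letters)",
                          xlab = "ordered cluster",
                          ylim = c(0, max(va$ci_hi, na.rm = TRUE) * 1.05), ...)
  ok <- !is.na(va$ci_lo)
  graphics::arrows(bp[ok], va$ci_lo[ok], bp[ok], va$ci_hi[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(va)
}
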