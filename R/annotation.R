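# Cluster annotation artifacts for specialist review: grading-stage
# conditional probabilities, a linear probe routing GradCAM attribution,
# seen/unseen review panels, and the per-cluster summary table.

#' Stage-cluster conditional probability matrix
#'
#' Entry (c, s) is `P(grading label s | cluster c)` estimated from the
#' labeled images in cluster c; unlabeled images are excluded from the
#' denominators. Rows of clusters containing no labeled image are set to
#' `NA` and flagged in the `"flagged"` attribute rather than silently
#' zeroed.
#'
#' @param assignments ordered cluster ids (`1..k`).
#' @param labels grading labels from [grading_labels()], `NA` for unlabeled.
#' @param k number of clusters.
#' @return `k x S` matrix with rows summing to 1 (where defined), with
#'   attributes `n_labeled` (per-cluster labeled counts) and `flagged`.
#' @export
stage_cluster_matrix <- function(assignments, labels, k = max(assignments)) {
  stopifnot(length(assignments) == length(labels))
  vocab <- grading_labels()
  bad <- stats::na.omit(setdiff(unique(labels), vocab))
  if (length(bad)) stop("unknown grading label(s): ", paste(bad, collapse = ", "))
  if (all(is.na(labels))) stop("need at least one labeled image")
  keep <- !is.na(labels)
  counts <- table(factor(assignments[keep], levels = seq_len(k)),
                  factor(labels[keep], levels = vocab))
  counts <- matrix(counts, k, length(vocab),
                   dimnames = list(paste0("C", seq_len(k)), vocab))
  n <- rowSums(counts)
  out <- counts / ifelse(n > 0, n, 1)
  out[n == 0, ] <- NA_real_
  attr(out, "n_labeled") <- n
  attr(out, "flagged") <- unname(which(n == 0))
  out
}

#' Fit a linear probe from features to cluster assignments
#'
#' A single linear layer (multinomial softmax, cross-entropy, no
#' regularization) trained with full-batch Adam until the loss change falls
#' below `tol` or `max_epochs` is reached. The probe exists to route
#' gradients for GradCAM: its weights live in the encoder's pooled-feature
#' space (after the probe's own z-scoring), so cluster logits are
#' differentiable functions of the encoder activations.
#'
#' @param features `N x D` feature matrix.
#' @param assignments ordered cluster ids in `1..k`.
#' @param k number of clusters.
#' @param max_epochs,tol,lr optimization controls.
#' @return object of class `"linear_probe"`: weights `W` (D x k), bias `b`,
#'   standardization `mu`/`sd`, training accuracy, convergence flag.
#' @export
fit_linear_probe <- function(features, assignments, k = max(assignments),
                             max_epochs = 500L, tol = 1e-6, lr = 0.05) {
  stopifnot(is.matrix(features), nrow(features) == length(assignments))
  if (length(unique(assignments)) < 2) {
    stop("degenerate input: need at least two distinct clusters")
  }
  N <- nrow(features); D <- ncol(features)
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  Y <- matrix(0, N, k)
  Y[cbind(seq_len(N), assignments)] <- 1
  W <- matrix(0, D, k); b <- rep(0, k)
  st <- adam_init(list(W = W, b = b))
  pars <- list(W = W, b = b)
  prev <- Inf; converged <- FALSE
  for (ep in seq_len(max_epochs)) {
    logit <- X %*% pars$W
    logit <- logit + rep(pars$b, each = N)
    logit <- logit - apply(logit, 1, max)
    P <- exp(logit); P <- P / rowSums(P)
    loss <- -mean(log(P[cbind(seq_len(N), assignments)] + 1e-12))
    G <- (P - Y) / N
    gr <- list(W = crossprod(X, G), b = colSums(G))
    upd <- adam_step(pars, gr, st, lr = lr)
    pars <- upd$params; st <- upd$state
    if (abs(prev - loss) < tol) { converged <- TRUE; break }
    prev <- loss
  }
  logit <- X %*% pars$W + rep(pars$b, each = N)
  pred <- max.col(logit, ties.method = "first")
  structure(list(W = pars$W, b = pars$b, mu = mu, sd = sdv, k = as.integer(k),
                 train_accuracy = mean(pred == assignments),
                 converged = converged),
            class = "linear_probe")
}

#' @export
predict.linear_probe <- function(object, newdata, ...) {
  X <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  logit <- X %*% object$W + rep(object$b, each = nrow(X))
  max.col(logit, ties.method = "first")
}

#' GradCAM attribution map for a cluster assignment
#'
#' Computes gradient-weighted class activation maps of the probe's cluster
#' logit with respect to the final two convolutional layers of the encoder
#' (channel weights are the spatially averaged gradients; maps are the
#' rectified weighted activation sums), upsamples both to image resolution,
#' combines them, and max-normalizes to `[0, 1]`.
#'
#' @param state trained `"byol_state"` encoder.
#' @param probe a [fit_linear_probe()] result.
#' @param image input matrix at the encoder's input size.
#' @param cluster_id the (ordered) cluster whose evidence to localize.
#' @param combine `"mean"` or `"max"` over the two layer maps.
#' @return an `"attribution_map"`: nonnegative matrix the size of the input
#'   with max 1 (all-zero with attribute `degenerate = TRUE` when the
#'   rectified maps vanish, e.g. for a probe logit independent of the
#'   features).
#' @export
gradcam_attribution <- function(state, probe, image, cluster_id,
                                combine = c("mean", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(state, "byol_state"), inherits(probe, "linear_probe"),
            cluster_id >= 1, cluster_id <= probe$k)
  arch <- state$arch
  X <- matrix(as.vector(image), ncol = 1)
  fw <- enc_forward(arch, state$online$enc, X, training = FALSE,
                    running = state$running, keep_cache = TRUE, keep_acts = TRUE)
  # d logit / d pooled-feature, through the probe's standardization
  dPooled <- matrix(probe$W[, cluster_id] / probe$sd, 1)
  bw <- enc_backward(arch, state$online$enc, fw, dPooled, keep_act_grads = TRUE)
  nl <- length(arch$channels)
  layers <- if (nl >= 2) c(nl - 1L, nl) else nl
  H <- arch$input_hw[1]; W <- arch$input_hw[2]
  maps <- lapply(layers, function(l) {
    A <- fw$acts[[l]][, 1, ]                    # (P x C)
    G <- bw$act_grads[[l]][, 1, ]
    alpha <- colMeans(G)
    m <- pmax(as.vector(A %*% alpha), 0)
    g <- arch$geoms[[l]]
    mm <- matrix(m, g$Ho, g$Wo)
    Aff <- cbind(g$Ho / H, 0, 0, g$Wo / W, (g$Ho + 1) / 2, (g$Wo + 1) / 2)
    matrix(nn_warp(matrix(as.vector(mm), ncol = 1), g$Ho, g$Wo, Aff, H, W), H, W)
  })
  out <- if (length(maps) == 1) maps[[1]]
         else if (combine == "mean") (maps[[1]] + maps[[2]]) / 2
         else pmax(maps[[1]], maps[[2]])
  mx <- max(out)
  degenerate <- mx <= 0
  if (degenerate) {
    warning("all-zero attribution map after rectification")
    out[] <- 0
  } else {
    out <- out / mx
  }
  structure(out, class = c("attribution_map", "matrix", "array"),
            cluster_id = as.integer(cluster_id), degenerate = degenerate)
}

#' Assemble seen/unseen review panels
#'
#' For each cluster, samples up to 20 images from 20 distinct patients
#' uniformly without replacement at patient level: the first 10 form the
#' "seen" panel shown during specialist interviews, the next 10 the
#' "unseen" validation panel. Clusters with fewer than 20 patients are
#' truncated with a warning.
#'
#' @param assignments ordered cluster ids.
#' @param patient_ids per-image patient ids.
#' @param image_ids per-image ids (defaults to the row index).
#' @param n_each images per panel half.
#' @return list (one element per cluster) of lists with `cluster`, `seen`,
#'   `unseen` image-id vectors and the corresponding `patients`.
#' @export
sample_review_panels <- function(assignments, patient_ids,
                                 image_ids = seq_along(assignments),
                                 n_each = 10L) {
  stopifnot(length(assignments) == length(patient_ids),
            length(assignments) == length(image_ids))
  k <- max(assignments)
  lapply(seq_len(k), function(c) {
    in_c <- which(assignments == c)
    pats <- unique(patient_ids[in_c])
    want <- 2L * n_each
    if (length(pats) < want) {
      warning(sprintf("cluster %d: only %d distinct patients; panel truncated",
                      c, length(pats)))
    }
    pick <- pats[sample.int(length(pats), min(want, length(pats)))]
    imgs <- vapply(pick, function(p) {
      cand <- in_c[patient_ids[in_c] == p]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    n_seen <- min(n_each, length(imgs))
    list(cluster = c,
         seen = image_ids[imgs[seq_len(n_seen)]],
         unseen = if (length(imgs) > n_seen)
           image_ids[imgs[(n_seen + 1):length(imgs)]] else image_ids[0],
         patients = pick)
  })
}

#' Per-cluster summary table
#'
#' Number of images, number of unique contributing patients, and their
#' ratio (rounded to one decimal) per cluster, with a totals row. A low
#' ratio indicates the cluster's feature arose independently across many
#' patients rather than in a few heavily imaged ones.
#'
#' @param assignments ordered cluster ids.
#' @param patient_ids per-image patient ids (no missing values).
#' @return `data.frame` with columns cluster, n_images, n_patients, ratio.
#' @export
cluster_summary_table <- function(assignments, patient_ids) {
  stopifnot(length(assignments) == length(patient_ids))
  if (anyNA(patient_ids)) stop("missing patient id")
  k <- max(assignments)
  rows <- lapply(seq_len(k), function(c) {
    in_c <- assignments == c
    ni <- sum(in_c); np <- length(unique(patient_ids[in_c]))
    data.frame(cluster = as.character(c), n_images = ni, n_patients = np,
               ratio = if (np > 0) round(ni / np, 1) else NA_real_)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(cluster = "total", n_images = length(assignments),
                      n_patients = length(unique(patient_ids)),
                      ratio = round(length(assignments) /
                                      length(unique(patient_ids)), 1))
  rbind(out, total)
}
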