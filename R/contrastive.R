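# Self-supervised contrastive pretraining (BYOL-style online/target
# networks) with the OCT augmentation family: global brightness and
# contrast jitter, rotation, aspect-ratio change, horizontal flip, and a
# randomly sized and located crop.

#' Augmentation policy for contrastive pretraining
#'
#' Defines the family of label-preserving transformations from which the two
#' views of each B-scan are drawn. The augmentations deliberately model
#' nuisance variation (brightness, contrast, pose, crop) that carries no
#' biomarker information, so the trained features learn to discount it.
#'
#' @param brightness additive brightness shift range, as a fraction of the
#'   intensity scale; shifts are drawn from `U(-brightness, brightness)`.
#' @param contrast multiplicative contrast range `c(lo, hi)`; the image is
#'   scaled about its mean intensity.
#' @param rotate rotation range in degrees (`U(-rotate, rotate)`).
#' @param aspect aspect-ratio scale range `c(lo, hi)`.
#' @param flip_p probability of a horizontal flip.
#' @param crop_area crop area fraction range `c(lo, hi)` in `(0, 1]`; the
#'   crop location is uniform over positions that fit.
#' @param out_hw output view size `c(height, width)` in pixels.
#' @return An object of class `"aug_policy"`.
#' @examples
#' pol <- aug_policy(out_hw = c(64, 64))
#' img <- matrix(runif(64 * 64), 64, 64)
#' v <- augment(img, pol)
#' dim(v$view1)
#' @export
aug_policy <- function(brightness = 0.2, contrast = c(0.8, 1.25), rotate = 10,
                       aspect = c(0.9, 1.1), flip_p = 0.5,
                       crop_area = c(0.4, 1.0), out_hw = c(64L, 64L)) {
  stopifnot(is.finite(brightness), brightness >= 0,
            length(contrast) == 2, all(is.finite(contrast)), contrast[1] <= contrast[2],
            is.finite(rotate), rotate >= 0,
            length(aspect) == 2, all(is.finite(aspect)), aspect[1] <= aspect[2],
            length(crop_area) == 2, crop_area[1] > 0, crop_area[2] <= 1,
            crop_area[1] <= crop_area[2],
            length(out_hw) == 2, all(out_hw >= 8))
  if (flip_p < 0 || flip_p > 1) stop("flip_p must be in [0, 1]")
  structure(list(brightness = brightness, contrast = contrast, rotate = rotate,
                 aspect = aspect, flip_p = flip_p, crop_area = crop_area,
                 out_hw = as.integer(out_hw)),
            class = "aug_policy")
}

# Draw per-image affine parameters and return the (B x 6) matrix consumed
# by nn_warp, plus photometric jitters.
.draw_aug_params <- function(policy, H, W, B) {
  s <- stats::runif(B, policy$crop_area[1], policy$crop_area[2])
  a <- stats::runif(B, policy$aspect[1], policy$aspect[2])
  th <- stats::runif(B, -policy$rotate, policy$rotate) * pi / 180
  fl <- ifelse(stats::runif(B) < policy$flip_p, -1, 1)
  cw <- pmin(W, W * sqrt(s) * sqrt(a))
  ch <- pmin(H, H * sqrt(s) / sqrt(a))
  if (any(cw > W + 1e-9) || any(ch > H + 1e-9)) stop("crop larger than image")
  cx <- stats::runif(B, cw / 2 + 0.5, W - cw / 2 + 0.5)
  cy <- stats::runif(B, ch / 2 + 0.5, H - ch / 2 + 0.5)
  Ho <- policy$out_hw[1]; Wo <- policy$out_hw[2]
  sy <- ch / Ho; sx <- cw / Wo * fl
  # compose rotation about the crop center with the crop scaling
  A <- cbind(cos(th) * sy, -sin(th) * sx, sin(th) * sy, cos(th) * sx, cy, cx)
  list(A = A,
       bright = stats::runif(B, -policy$brightness, policy$brightness),
       gain = stats::runif(B, policy$contrast[1], policy$contrast[2]))
}

# Vectorized two-view augmentation of a whole batch. X: (H*W x B).
augment_batch <- function(X, H, W, policy) {
  B <- ncol(X)
  Ho <- policy$out_hw[1]; Wo <- policy$out_hw[2]
  one_view <- function() {
    p <- .draw_aug_params(policy, H, W, B)
    V <- nn_warp(X, H, W, p$A, Ho, Wo)
    m <- colMeans(V)
    V <- .col_affine(V, p$gain, m * (1 - p$gain) + p$bright)
    V[V < 0] <- 0
    V[V > 1] <- 1
    V
  }
  list(view1 = one_view(), view2 = one_view())
}

#' Create two augmented views of a B-scan
#'
#' Draws two independent transformations from an [aug_policy()] and applies
#' them to one standardized image. Uses R's global random number generator;
#' call `set.seed()` for reproducible views.
#'
#' @param image numeric matrix with intensities in `[0, 1]`.
#' @param policy an [aug_policy()].
#' @return list with elements `view1` and `view2`, each a matrix of the
#'   policy's output size with intensities in `[0, 1]`.
#' @export
augment <- function(image, policy) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  v <- augment_batch(matrix(as.vector(image), ncol = 1),
                     nrow(image), ncol(image), policy)
  list(view1 = matrix(v$view1, policy$out_hw[1], policy$out_hw[2]),
       view2 = matrix(v$view2, policy$out_hw[1], policy$out_hw[2]))
}

#' BYOL loss between an online prediction and a target projection
#'
#' The normalized squared distance `2 - 2 cos(p, z)` between the online
#' network's prediction and the (gradient-stopped) target projection. Bounded
#' in `[0, 4]` and invariant to positive rescaling of either argument.
#'
#' @param p,z nonzero numeric vectors of equal length.
#' @return scalar loss in `[0, 4]`.
#' @examples
#' byol_loss(c(1, 0), c(0, 1))  # orthogonal: 2
#' @export
byol_loss <- function(p, z) {
  stopifnot(length(p) == length(z), all(is.finite(p)), all(is.finite(z)))
  np <- sqrt(sum(p * p)); nz <- sqrt(sum(z * z))
  if (np == 0 || nz == 0) stop("byol_loss is undefined for zero vectors")
  2 - 2 * sum(p * z) / (np * nz)
}

# Batch loss and gradient. P, Z: (B x d). Returns mean loss and dL/dP.
.byol_loss_batch <- function(P, Z) {
  np <- sqrt(rowSums(P * P)); nz <- sqrt(rowSums(Z * Z))
  cosv <- rowSums(P * Z) / (np * nz)
  B <- nrow(P)
  dP <- -2 / B * (Z / (np * nz) - (cosv / (np * np)) * P)
  list(loss = mean(2 - 2 * cosv), dP = dP)
}

#' Exponential moving average update of target parameters
#'
#' Elementwise `target' = tau * target + (1 - tau) * online`, applied
#' recursively over nested parameter lists. This is the slow-moving target
#' network update of the BYOL objective.
#'
#' @param target,online numeric arrays, or nested lists of them with
#'   identical structure.
#' @param tau decay in `[0, 1)`.
#' @return updated target of the same structure.
#' @export
ema_update <- function(target, online, tau) {
  stopifnot(length(tau) == 1, tau >= 0, tau < 1)
  check <- function(a, b) {
    if (is.list(a) != is.list(b) ||
        (!is.list(a) && length(a) != length(b))) {
      stop("target and online parameter shapes do not match")
    }
    if (is.list(a)) {
      if (length(a) != length(b)) stop("target and online parameter shapes do not match")
      for (i in seq_along(a)) check(a[[i]], b[[i]])
    }
    invisible(NULL)
  }
  check(target, online)
  if (is.list(target)) {
    param_map2(target, online, function(t, o) tau * t + (1 - tau) * o)
  } else {
    tau * target + (1 - tau) * online
  }
}

#' Training configuration for contrastive pretraining
#'
#' The optimizer family and the printed constants of the full-scale recipe
#' (Adam with first-moment momentum 0.9, weight decay 1.5e-6; 120 000 steps
#' and learning rate 5e-4 with EMA decay 0.996 for the ResNet50(4x)-class
#' backbone) are kept; the default learning rate (3e-3) and EMA decay
#' (0.98) are the desk-scale recipe for the small conv backbone, where the
#' full-scale constants leave training far from convergence within a
#' 2000-step budget. Both are plain arguments.
#'
#' @param steps number of optimizer steps (120 000 at full scale).
#' @param batch_size images per step.
#' @param lr learning rate (5e-4 in the full-scale recipe).
#' @param weight_decay L2 weight decay.
#' @param beta1,beta2 Adam moment decays; `beta1` is the printed momentum.
#' @param ema_decay target-network EMA decay in `[0, 1)` (0.996 at full
#'   scale).
#' @param channels conv backbone channel widths; the last entry is the
#'   feature width D (2048 for the full-scale backbone, 64 desk-scale).
#' @param proj_hidden,proj_dim projector/predictor MLP widths.
#' @param log_every record the loss every this many steps.
#' @param seed integer seed controlling initialization, batch order and
#'   augmentation draws.
#' @return object of class `"byol_config"`.
#' @export
byol_config <- function(steps = 2000L, batch_size = 64L, lr = 3e-3,
                        weight_decay = 1.5e-6, beta1 = 0.9, beta2 = 0.999,
                        ema_decay = 0.98, channels = c(8L, 16L, 32L, 64L),
                        proj_hidden = 256L, proj_dim = 64L,
                        log_every = 50L, seed = 1L) {
  stopifnot(steps >= 1, batch_size >= 2, lr > 0, ema_decay >= 0, ema_decay < 1,
            weight_decay >= 0)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, ema_decay = ema_decay,
                 channels = as.integer(channels),
                 proj_hidden = as.integer(proj_hidden),
                 proj_dim = as.integer(proj_dim),
                 log_every = as.integer(log_every), seed = as.integer(seed)),
            class = "byol_config")
}

# Accept images as (H x W x N) array, list of matrices, or (H*W x N) matrix
# with known hw.
.images_to_matrix <- function(images, hw = NULL) {
  if (is.array(images) && length(dim(images)) == 3) {
    d <- dim(images)
    return(list(X = matrix(images, d[1] * d[2], d[3]), hw = d[1:2]))
  }
  if (is.list(images)) {
    hw <- dim(images[[1]])
    return(list(X = vapply(images, as.vector, numeric(prod(hw))), hw = hw))
  }
  if (is.matrix(images) && !is.null(hw)) {
    return(list(X = images, hw = as.integer(hw)))
  }
  stop("images must be an (H x W x N) array or a list of matrices")
}

#' Train the self-supervised feature extractor
#'
#' Trains an online conv encoder + projector + predictor to predict a
#' slowly-moving (EMA) target network's projection of a second augmented view
#' of the same B-scan, symmetrized over the two view orderings. No labels of
#' any kind are used.
#'
#' @param images `(H x W x N)` array or list of matrices, intensities in
#'   `[0, 1]`.
#' @param policy an [aug_policy()]; its output size fixes the encoder input.
#' @param config a [byol_config()].
#' @param verbose print the loss at each logging point.
#' @return An object of class `"byol_state"`: the trained online and target
#'   parameters, architecture, running batch-norm statistics, augmentation
#'   policy, config, and a training log (`data.frame` of step and loss).
#' @seealso [extract_features()], [byol_loss()], [ema_update()]
#' @export
train_byol <- function(images, policy = aug_policy(), config = byol_config(),
                       verbose = FALSE) {
  im <- .images_to_matrix(images)
  X <- im$X
  N <- ncol(X)
  if (N < 2) stop("need at least 2 images for contrastive training")
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9) stop("image intensities must lie in [0, 1]")
  H <- im$hw[1]; W <- im$hw[2]
  with_seed(config$seed, {
    arch <- encoder_arch(policy$out_hw, config$channels,
                         proj_hidden = config$proj_hidden,
                         proj_dim = config$proj_dim)
    online <- list(enc = init_conv_params(arch),
                   proj = init_mlp_params(arch$D, config$proj_hidden, config$proj_dim),
                   pred = init_mlp_params(config$proj_dim, config$proj_hidden,
                                          config$proj_dim))
    target <- list(enc = online$enc, proj = online$proj)
    running <- init_running_stats(arch)
    opt <- adam_init(online)
    log_steps <- integer(0); log_loss <- numeric(0)
    for (step in seq_len(config$steps)) {
      idx <- sample.int(N, config$batch_size, replace = N < config$batch_size)
      views <- augment_batch(X[, idx, drop = FALSE], H, W, policy)
      # symmetrized loss in one pass: the online network sees [v1 | v2],
      # the target network the swapped ordering [v2 | v1]
      v_on <- cbind(views$view1, views$view2)
      v_tg <- cbind(views$view2, views$view1)
      fe <- enc_forward(arch, online$enc, v_on, training = TRUE, keep_cache = TRUE)
      fp <- mlp_forward(online$proj, fe$out, keep_cache = TRUE)
      fq <- mlp_forward(online$pred, fp$out, keep_cache = TRUE)
      te <- enc_forward(arch, target$enc, v_tg, training = TRUE)
      tp <- mlp_forward(target$proj, te$out)
      lb <- .byol_loss_batch(fq$out, tp$out)
      loss <- lb$loss
      if (!is.finite(loss)) {
        stop(sprintf("non-finite contrastive loss at step %d; see training log", step))
      }
      bq <- mlp_backward(online$pred, fq$cache, lb$dP)
      bp <- mlp_backward(online$proj, fp$cache, bq$dX)
      be <- enc_backward(arch, online$enc, fe, bp$dX)
      grads <- list(enc = be$grads, proj = bp$grads, pred = bq$grads)
      upd <- adam_step(online, grads, opt, lr = config$lr, beta1 = config$beta1,
                       beta2 = config$beta2, weight_decay = config$weight_decay)
      online <- upd$params
      opt <- upd$state
      target <- ema_update(target, list(enc = online$enc, proj = online$proj),
                           config$ema_decay)
      for (l in seq_along(running)) {
        running[[l]]$mean <- 0.9 * running[[l]]$mean + 0.1 * fe$bstats[[l]]$mean
        running[[l]]$var <- 0.9 * running[[l]]$var + 0.1 * fe$bstats[[l]]$var
      }
      if (step == 1 || step %% config$log_every == 0 || step == config$steps) {
        log_steps <- c(log_steps, step); log_loss <- c(log_loss, loss)
        if (verbose) message(sprintf("step %6d  loss %.5f", step, loss))
      }
    }
    structure(list(arch = arch, online = online, target = target,
                   running = running, policy = policy, config = config,
                   log = data.frame(step = log_steps, loss = log_loss)),
              class = "byol_state")
  })
}

#' Extract self-supervised features
#'
#' Runs the trained online encoder in inference mode (batch-norm running
#' statistics, no augmentation) and returns the penultimate
#' global-average-pooled representation of each image; the projector and
#' predictor heads are dropped, mirroring the removal of the final layer of
#' the backbone before feature extraction. Deterministic; the result does
#' not depend on the batching.
#'
#' Because the contrastive loss compares feature *directions* only (it is
#' invariant to rescaling), vector magnitudes are unconstrained by training;
#' by default rows are therefore L2-normalized, the conventional form for
#' downstream analysis of such embeddings.
#'
#' @param state a trained `"byol_state"`.
#' @param images `(H x W x N)` array or list of matrices, at the encoder's
#'   input size.
#' @param batch_size images per forward pass.
#' @param normalize L2-normalize each feature row (default `TRUE`).
#' @return `N x D` feature matrix (`D = state$arch$D`), rows aligned with the
#'   input order.
#' @export
extract_features <- function(state, images, batch_size = 256L,
                             normalize = TRUE) {
  stopifnot(inherits(state, "byol_state"))
  im <- .images_to_matrix(images)
  if (!all(im$hw == state$arch$input_hw)) {
    stop(sprintf("images are %dx%d but the encoder expects %dx%d",
                 im$hw[1], im$hw[2], state$arch$input_hw[1], state$arch$input_hw[2]))
  }
  N <- ncol(im$X)
  out <- matrix(NA_real_, N, state$arch$D)
  for (start in seq(1, N, by = batch_size)) {
    ii <- start:min(start + batch_size - 1, N)
    fw <- enc_forward(state$arch, state$online$enc, im$X[, ii, drop = FALSE],
                      training = FALSE, running = state$running)
    out[ii, ] <- fw$out
  }
  if (any(!is.finite(out))) stop("non-finite features extracted")
  if (normalize) {
    nrm <- sqrt(rowSums(out * out))
    nrm[nrm < 1e-12] <- 1
    out <- out / nrm
  }
  out
}

#' @export
print.byol_state <- function(x, ...) {
  cat("Self-supervised OCT feature extractor (BYOL-style)\n")
  cat(sprintf("  input %dx%d, conv channels %s, feature width D = %d\n",
              x$arch$input_hw[1], x$arch$input_hw[2],
              paste(x$arch$channels, collapse = "-"), x$arch$D))
  cat(sprintf("  trained %d steps (batch %d); final logged loss %.4f\n",
              x$config$steps, x$config$batch_size, utils::tail(x$log$loss, 1)))
  invisible(x)
}

# Evaluate the scoped expression under a fixed RNG seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
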