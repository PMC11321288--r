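# Prognostic benchmark: predict time to conversion (MNV, cRORA, late AMD)
# and current visual acuity from cluster-similarity vectors, against
# demographic, grading-system, and fully supervised baselines, under
# patient-wise cross-validation.

#' Build the per-visit outcome table
#'
#' Joins visits to per-eye conversion events. Time-to-event is the event
#' time minus the visit time in years; a visit enters a conversion task only
#' if that event is recorded for the eye and lies strictly after the visit.
#' Time to late AMD is the earlier of the two events. Eyes whose recorded
#' event precedes their first visit are excluded with a warning.
#'
#' @param visits `data.frame` with patient_id, eye_id, visit_years, age,
#'   sex, letters, grading_label (the cohort manifest works as is).
#' @param conversions `data.frame` with eye_id, time_mnv, time_crora (years
#'   from baseline; `NA` when the event is not recorded).
#' @return `data.frame` of eligible visits with columns `time_to_mnv`,
#'   `time_to_crora`, `time_to_late` (`NA` where ineligible) plus the
#'   predictor columns carried through.
#' @export
build_outcomes <- function(visits, conversions) {
  need <- c("patient_id", "eye_id", "visit_years", "age", "sex", "letters")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visits is missing column(s): ", paste(miss, collapse = ", "))
  m <- match(visits$eye_id, conversions$eye_id)
  t_mnv <- conversions$time_mnv[m]
  t_crora <- conversions$time_crora[m]
  first_visit <- stats::ave(visits$visit_years, visits$eye_id, FUN = min)
  bad <- (!is.na(t_mnv) & t_mnv < first_visit) |
         (!is.na(t_crora) & t_crora < first_visit)
  if (any(bad)) {
    warning(sprintf("excluding %d eye(s) with a conversion before the first visit",
                    length(unique(visits$eye_id[bad]))))
  }
  out <- visits[!bad, , drop = FALSE]
  t_mnv <- t_mnv[!bad]; t_crora <- t_crora[!bad]
  ttm <- ifelse(!is.na(t_mnv) & t_mnv > out$visit_years,
                t_mnv - out$visit_years, NA_real_)
  ttc <- ifelse(!is.na(t_crora) & t_crora > out$visit_years,
                t_crora - out$visit_years, NA_real_)
  out$time_to_mnv <- ttm
  out$time_to_crora <- ttc
  out$time_to_late <- pmin(ttm, ttc, na.rm = TRUE)
  out$time_to_late[is.na(ttm) & is.na(ttc)] <- NA_real_
  out
}

#' Patient-wise cross-validation folds
#'
#' Ten independent random 80/20 partitions of the patients; every fold's
#' test patients are disjoint from its training patients, so no patient
#' contributes images to both sides of any fold.
#'
#' @param patient_ids per-row patient ids.
#' @param n_folds number of folds.
#' @param test_frac fraction of patients held out per fold.
#' @param seed integer seed.
#' @return list of `n_folds` lists with `train` and `test` patient-id sets.
#' @export
make_folds <- function(patient_ids, n_folds = 10L, test_frac = 0.2, seed = 1L) {
  pats <- unique(patient_ids)
  if (length(pats) < n_folds) {
    stop(sprintf("need at least %d patients, got %d", n_folds, length(pats)))
  }
  n_test <- max(1L, round(test_frac * length(pats)))
  with_seed(seed, {
    lapply(seq_len(n_folds), function(f) {
      test <- pats[sample.int(length(pats), n_test)]
      list(train = setdiff(pats, test), test = test)
    })
  })
}

.benchmark_systems <- c("demographic", "grading", "clusters", "fully_supervised")
.benchmark_tasks <- c("time_to_late", "time_to_mnv", "time_to_crora", "letters")

# design matrix per system; rows with unavailable predictors are dropped
.system_design <- function(system, data) {
  if (system == "demographic") {
    x <- cbind(age = data$age, sexM = as.numeric(data$sex == "M"))
  } else if (system == "grading") {
    lab <- factor(data$grading_label, levels = grading_labels())
    keep <- !is.na(lab)
    x <- matrix(0, nrow(data), length(grading_labels()),
                dimnames = list(NULL, grading_labels()))
    x[cbind(which(keep), as.integer(lab[keep]))] <- 1
    x[!keep, ] <- NA
  } else if (system == "clusters") {
    x <- as.matrix(data[, grep("^sim_", names(data)), drop = FALSE])
  } else if (system == "fully_supervised") {
    x <- as.matrix(data[, grep("^feat_", names(data)), drop = FALSE])
  } else {
    stop("unknown system: ", system)
  }
  x
}

#' Fit one prognostic system and predict a test fold
#'
#' Systems: `clusters` and `grading` use L1-regularized (Lasso) linear
#' regression with the penalty chosen by inner 5-fold cross-validation on
#' the training rows; `demographic` uses ordinary least squares on age and
#' sex; `fully_supervised` uses linear support-vector regression (cost 1)
#' directly on the feature space.
#'
#' @param system one of `"demographic"`, `"grading"`, `"clusters"`,
#'   `"fully_supervised"`.
#' @param train,test outcome-table rows carrying `sim_*` and `feat_*`
#'   columns as needed.
#' @param task outcome column name.
#' @return numeric predictions for the test rows (`NA` where the system's
#'   predictors are unavailable).
#' @export
fit_predict <- function(system, train, test, task) {
  system <- match.arg(system, .benchmark_systems)
  y <- train[[task]]
  Xtr <- .system_design(system, train)
  Xte <- .system_design(system, test)
  ok <- !is.na(y) & stats::complete.cases(Xtr)
  Xtr <- Xtr[ok, , drop = FALSE]; y <- y[ok]
  pred <- rep(NA_real_, nrow(test))
  te_ok <- stats::complete.cases(Xte)
  if (length(y) < 10) stop(sprintf("too few eligible training rows (%d)", length(y)))
  if (stats::sd(y) < 1e-12) {
    warning("constant training target; predicting the training mean")
    pred[te_ok] <- mean(y)
    return(pred)
  }
  if (system %in% c("clusters", "grading")) {
    # explicit path down to ~unpenalized: glmnet's early stopping would
    # otherwise truncate the path and bias a (near-)noiseless fit
    lmax <- max(glmnet::glmnet(Xtr, y, alpha = 1, nlambda = 5)$lambda)
    lams <- exp(seq(log(lmax), log(lmax * 1e-8), length.out = 100))
    cv <- glmnet::cv.glmnet(Xtr, y, alpha = 1, nfolds = 5, lambda = lams)
    pred[te_ok] <- as.vector(stats::predict(cv, Xte[te_ok, , drop = FALSE],
                                            s = "lambda.min"))
  } else if (system == "demographic") {
    df <- data.frame(y = y, Xtr)
    fit <- stats::lm(y ~ ., data = df)
    pred[te_ok] <- as.vector(stats::predict(fit, data.frame(Xte[te_ok, , drop = FALSE])))
  } else {
    # scale = FALSE: the feature rows arrive L2-normalized, so per-dimension
    # rescaling would only amplify low-signal dimensions
    fit <- e1071::svm(Xtr, y, type = "eps-regression", kernel = "linear",
                      cost = 1, scale = FALSE)
    pred[te_ok] <- as.vector(stats::predict(fit, Xte[te_ok, , drop = FALSE]))
  }
  pred
}

#' Mean absolute error
#' @param pred,truth numeric vectors; pairs with `NA` are dropped.
#' @return scalar MAE.
#' @export
mae <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  mean(abs(pred[ok] - truth[ok]))
}

#' Run the prognostic benchmark
#'
#' For each seed the experiment is repeated from clustering onward: the
#' cluster model is refit on the features, similarity vectors are rebuilt,
#' and every task x system pair is evaluated over patient-wise folds.
#' Reported MAEs are means and standard deviations over folds x seeds.
#' Patient-wise disjointness is asserted in every fold.
#'
#' @param features `N x D` feature matrix aligned with `outcomes` rows.
#' @param outcomes a [build_outcomes()] table.
#' @param k number of clusters for the similarity representation.
#' @param n_seeds number of repetitions (7 at full scale).
#' @param n_folds folds per seed.
#' @param systems,tasks subsets to run.
#' @param min_rows tasks with fewer eligible rows are skipped with a warning.
#' @return object of class `"oct_benchmark"`: the full `grid` (seed, fold,
#'   task, system, mae, n_test) and a `summary` table of mean +/- SD.
#' @export
run_benchmark <- function(features, outcomes, k = 8L, n_seeds = 7L,
                          n_folds = 10L, systems = .benchmark_systems,
                          tasks = .benchmark_tasks, min_rows = 30L) {
  stopifnot(nrow(features) == nrow(outcomes))
  systems <- match.arg(systems, .benchmark_systems, several.ok = TRUE)
  tasks <- match.arg(tasks, .benchmark_tasks, several.ok = TRUE)
  grid <- list()
  for (s in seq_len(n_seeds)) {
    model <- kmeans_fit(features, k = k, seed = 1000L + s)
    model <- order_clusters_by_va(model, outcomes$letters)
    sim <- similarity_vector(features, model)
    colnames(sim) <- paste0("sim_", seq_len(k))
    feat <- features
    colnames(feat) <- paste0("feat_", seq_len(ncol(features)))
    data <- cbind(outcomes, sim, feat)
    folds <- make_folds(data$patient_id, n_folds = n_folds, seed = 2000L + s)
    for (f in seq_along(folds)) {
      tr <- data[data$patient_id %in% folds[[f]]$train, , drop = FALSE]
      te <- data[data$patient_id %in% folds[[f]]$test, , drop = FALSE]
      if (length(intersect(tr$patient_id, te$patient_id)) > 0) {
        stop("patient leakage between train and test")  # defensive; by construction disjoint
      }
      for (task in tasks) {
        n_ok <- sum(!is.na(te[[task]]))
        if (sum(!is.na(tr[[task]])) < min_rows || n_ok == 0) {
          warning(sprintf("task %s skipped in fold %d (too few eligible rows)",
                          task, f))
          next
        }
        for (sys in systems) {
          pred <- fit_predict(sys, tr, te, task)
          grid[[length(grid) + 1]] <- data.frame(
            seed = s, fold = f, task = task, system = sys,
            mae = mae(pred, te[[task]]),
            n_test = sum(!is.na(pred) & !is.na(te[[task]])))
        }
      }
    }
  }
  grid <- do.call(rbind, grid)
  agg_m <- stats::aggregate(mae ~ task + system, grid, mean)
  agg_s <- stats::aggregate(mae ~ task + system, grid, stats::sd)
  summary <- merge(agg_m, agg_s, by = c("task", "system"),
                   suffixes = c("_mean", "_sd"))
  summary$system <- factor(summary$system, levels = .benchmark_systems)
  summary <- summary[order(summary$task, summary$system), ]
  structure(list(grid = grid, summary = summary, k = k,
                 n_seeds = n_seeds, n_folds = n_folds),
            class = "oct_benchmark")
}

#' @export
print.oct_benchmark <- function(x, ...) {
  cat(sprintf("Prognostic benchmark: %d seeds x %d patient-wise folds\n",
              x$n_seeds, x$n_folds))
  s <- x$summary
  for (task in unique(s$task)) {
    cat(sprintf("  %s (MAE):\n", task))
    sub <- s[s$task == task, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-17s %6.3f +/- %.3f\n", sub$system[i],
                  sub$mae_mean[i], sub$mae_sd[i]))
    }
  }
  invisible(x)
}

#' Visual-acuity stratification by ordered cluster
#'
#' Per ordered cluster: mean letter score with a normal-approximation 95%
#' confidence interval (mean +/- 1.96 SE), plus a monotone-trend statistic
#' (Kendall correlation between cluster index and cluster mean). Clusters
#' of size 1 get an undefined CI and are flagged.
#'
#' @param assignments ordered cluster ids.
#' @param letters per-image letter scores.
#' @return `data.frame`: cluster, n, mean, ci_lo, ci_hi, flagged; the trend
#'   statistic is attached as attribute `"trend_tau"`.
#' @export
va_stratification <- function(assignments, letters) {
  stopifnot(length(assignments) == length(letters))
  k <- max(assignments)
  rows <- lapply(seq_len(k), function(c) {
    v <- letters[assignments == c & !is.na(letters)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(cluster = c, n = n, mean = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               flagged = n < 2)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$mean)
  tau <- if (sum(ok) > 2) {
    suppressWarnings(stats::cor(out$cluster[ok], out$mean[ok], method = "kendall"))
  } else NA_real_
  attr(out, "trend_tau") <- tau
  out
}

#' Lasso support-recovery experiment on similarity-style features
#'
#' Measures how reliably the inner-CV Lasso used by the cluster system
#' recovers a known sparse signal: simulated similarity vectors (softmax of
#' Gaussian logits over k clusters), an outcome linear in a small subset of
#' dimensions at a given signal-to-noise ratio, and a success when the
#' selected support is a superset of the true one.
#'
#' @param n rows per replicate.
#' @param k similarity-vector length.
#' @param support_size number of active dimensions.
#' @param snr signal-to-noise variance ratio.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return list with `rate` (fraction of replicates recovering a superset)
#'   and the per-replicate results.
#' @export
lasso_support_recovery <- function(n = 1000L, k = 30L, support_size = 4L,
                                   snr = 5, n_reps = 20L, seed = 1L) {
  with_seed(seed, {
    hits <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      logits <- matrix(stats::rnorm(n * k), n, k)
      X <- exp(logits) / rowSums(exp(logits))
      support <- sample.int(k, support_size)
      beta <- stats::runif(support_size, 2, 4) * sample(c(-1, 1), support_size,
                                                        replace = TRUE)
      signal <- X[, support, drop = FALSE] %*% beta
      noise_sd <- sqrt(stats::var(as.vector(signal)) / snr)
      y <- as.vector(signal) + stats::rnorm(n, 0, noise_sd)
      cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5)
      sel <- which(as.vector(stats::coef(cv, s = "lambda.min"))[-1] != 0)
      hits[r] <- all(support %in% sel)
    }
    list(rate = mean(hits), hits = hits)
  })
}
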