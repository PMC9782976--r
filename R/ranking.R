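#' Feature-importance ranking from a tree-ensemble learner
#'
#' Fits a random forest (`ranger`) or gradient-boosting machine
#' (`xgboost`) under stratified cross-validation and ranks all features by
#' out-of-fold permutation importance: for each feature, its values are
#' shuffled `n_perm` times within every test fold, and the importance is
#' the average drop in pooled out-of-fold AUC.  This importance metric is
#' deterministic given the seed and learner-agnostic, unlike the learners'
#' internal impurity measures.  Ties are broken lexically by feature name
#' so ranks always form a dense permutation `1..J`.
#'
#' @param cohort An [as_cohort()] object (raw or discretized; the tree
#'   ensembles accept either).
#' @param learner `"rf"` or `"gbm"`.
#' @param folds,repeats Cross-validation layout (default 5 x 1).
#' @param n_perm Shuffles per feature (default 20).
#' @param seed Integer seed.
#' @param num_trees Trees for the RF (default 500).
#' @param nrounds,max_depth,eta Boosting parameters for the GBM (default
#'   100 rounds, depth 3, learning rate 0.1).
#' @return An `ekbn_ranking` tibble `(feature, importance, rank)` carrying
#'   `model_id` and the pooled cross-validated `auc` as attributes.
#' @export
importance_list <- function(cohort, learner = c("rf", "gbm"), folds = 5L,
                            repeats = 1L, n_perm = 20L, seed = 1L,
                            num_trees = 500L, nrounds = 100L, max_depth = 3L,
                            eta = 0.1) {
  learner <- match.arg(learner)
  outcome <- cohort_outcome(cohort)
  feats <- cohort_features(cohort)
  y <- as_binary_labels(cohort[[outcome]])
  x <- feature_matrix(cohort, feats)
  n <- length(y)
  n_min <- min(table(y))
  if (n_min < 2L) abort_ekbn("outcome too imbalanced for CV spec")
  if (n_min < folds) {
    warn_ekbn(paste0("minority class smaller than folds; reducing folds to ", n_min))
    folds <- as.integer(n_min)
  }
  base_scores <- matrix(NA_real_, n, repeats)
  perm_scores <- array(NA_real_, c(n, length(feats), n_perm))
  for (rep_i in seq_len(repeats)) {
    fold_of <- withr::with_seed(derive_seed(seed, paste0("imp/fold/", rep_i)), {
      f <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        idx <- idx[order(cohort$unit_id[idx])]
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f
    })
    for (k in seq_len(folds)) {
      test <- which(fold_of == k)
      train <- which(fold_of != k)
      fit <- fit_learner(learner, x[train, , drop = FALSE], y[train],
                         seed = derive_seed(seed, paste0("imp/fit/", rep_i, "/", k)),
                         num_trees = num_trees, nrounds = nrounds,
                         max_depth = max_depth, eta = eta)
      base_scores[test, rep_i] <- predict_learner(fit, x[test, , drop = FALSE])
      if (rep_i == 1L) {
        # batched permutation predictions: one call per feature
        withr::with_seed(derive_seed(seed, paste0("imp/perm/", k)), {
          for (j in seq_along(feats)) {
            big <- x[rep(test, n_perm), , drop = FALSE]
            for (s in seq_len(n_perm)) {
              rowsel <- (s - 1L) * length(test) + seq_along(test)
              big[rowsel, j] <- x[test[sample.int(length(test))], j]
            }
            pred <- predict_learner(fit, big)
            for (s in seq_len(n_perm)) {
              rowsel <- (s - 1L) * length(test) + seq_along(test)
              perm_scores[test, j, s] <- pred[rowsel]
            }
          }
        })
      }
    }
  }
  auc <- mean(vapply(seq_len(repeats), function(r) roc_auc(base_scores[, r], y),
                     numeric(1)))
  base_auc <- roc_auc(base_scores[, 1L], y)
  importance <- vapply(seq_along(feats), function(j) {
    drops <- vapply(seq_len(n_perm), function(s) {
      base_auc - roc_auc(perm_scores[, j, s], y)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  ord <- order(-importance, feats)
  rank <- integer(length(feats))
  rank[ord] <- seq_along(feats)
  out <- tibble::tibble(feature = feats, importance = importance, rank = rank)
  out <- dplyr::arrange(out, .data$rank)
  structure(out, class = c("ekbn_ranking", class(out)),
            model_id = learner, auc = auc)
}

feature_matrix <- function(cohort, feats) {
  cols <- lapply(cohort[feats], function(col) {
    if (is.numeric(col)) as.numeric(col) else as.numeric(factor(as.character(col)))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- feats
  m
}

fit_learner <- function(learner, x, y, seed, num_trees, nrounds, max_depth, eta) {
  if (learner == "rf") {
    df <- as.data.frame(x)
    df$.y <- factor(y, levels = c(0L, 1L))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = num_trees, seed = seed, num.threads = 1L,
      respect.unordered.factors = "ignore"
    )
    list(kind = "rf", fit = fit)
  } else {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    fit <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0
    ))
    list(kind = "gbm", fit = fit)
  }
}

predict_learner <- function(fit, x) {
  if (fit$kind == "rf") {
    p <- stats::predict(fit$fit, data = as.data.frame(x), num.threads = 1L)$predictions
    unname(p[, "1"])
  } else {
    as.numeric(stats::predict(fit$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  }
}

#' Integrate ranking lists by the AUC-weighted ranking score
#'
#' Fuses K per-model ranking lists into one integrated list: feature j
#' receives the weighted ranking score
#' `WRS_j = sum_k N_j(L^k) * (sum_k' AUC^k') / AUC^k`,
#' i.e. each model's ranks enter with weight `sum(AUC)/AUC^k` (the literal
#' reading of the aggregation rule; note it gives *lower*-AUC models the
#' larger multiplier).  `weighting = "proportional"` instead uses
#' `w_k = AUC^k / sum(AUC)` for sensitivity analysis.  The integrated
#' order is ascending in WRS — the feature with the minimal score ranks at
#' the top — with ties broken lexically by feature name.  With K = 1, or
#' with equal AUCs (where the weights cancel into a Borda count), the
#' order reduces to the obvious one.
#'
#' @param lists List of [importance_list()] rankings (or any tibbles with
#'   `feature` and `rank` plus an `auc` attribute).
#' @param weighting `"inverse"` (default, the literal rule) or
#'   `"proportional"`.
#' @param aucs Optional numeric vector overriding the lists' `auc`
#'   attributes.
#' @return An `ekbn_integrated` tibble `(feature, wrs, rank)` with the
#'   per-model AUCs and the weighting as attributes.
#' @export
integrate_rankings <- function(lists, weighting = c("inverse", "proportional"),
                               aucs = NULL) {
  weighting <- match.arg(weighting)
  if (inherits(lists, "ekbn_ranking")) lists <- list(lists)
  stopifnot(length(lists) >= 1L)
  aucs <- aucs %||% vapply(lists, function(l) attr(l, "auc"), numeric(1))
  if (any(!is.finite(aucs)) || any(aucs <= 0)) {
    abort_ekbn("all model AUCs must be positive")
  }
  feats <- sort(lists[[1L]]$feature)
  for (l in lists[-1L]) {
    diff <- c(setdiff(feats, l$feature), setdiff(l$feature, feats))
    if (length(diff) > 0) {
      abort_ekbn(paste0("ranking lists cover different features: ",
                        paste(sort(unique(diff)), collapse = ", ")))
    }
  }
  w <- if (weighting == "inverse") sum(aucs) / aucs else aucs / sum(aucs)
  wrs <- stats::setNames(rep(0, length(feats)), feats)
  for (k in seq_along(lists)) {
    l <- lists[[k]]
    wrs[l$feature] <- wrs[l$feature] + l$rank * w[[k]]
  }
  ord <- order(wrs, feats)
  rank <- integer(length(feats))
  rank[ord] <- seq_along(feats)
  out <- tibble::tibble(feature = feats, wrs = unname(wrs), rank = rank)
  out <- dplyr::arrange(out, .data$rank)
  structure(out, class = c("ekbn_integrated", class(out)),
            weighting = weighting, aucs = aucs)
}
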