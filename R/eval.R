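#' Area under the ROC curve
#'
#' Mann-Whitney form: the proportion of (event, non-event) pairs in which
#' the event unit scores higher, ties counting one half.  Computed from
#' midranks, so it is exact under ties.
#'
#' @param scores Numeric risk scores (higher = more event-like).
#' @param labels Binary labels (0/1, logical, or a factor with levels
#'   `"0" < "1"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) abort_ekbn("both outcome classes must be present")
  stopifnot(length(scores) == length(y))
  r <- rank(scores)
  m <- sum(y == 1L)
  n <- sum(y == 0L)
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) labels <- as.integer(labels == "1")
  as.integer(labels)
}

# DeLong placement values: list(v10 = per-event, v01 = per-non-event)
delong_placements <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  m <- length(pos)
  n <- length(neg)
  all_r <- rank(c(pos, neg))
  pos_r <- rank(pos)
  neg_r <- rank(neg)
  v10 <- (all_r[seq_len(m)] - pos_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Bootstrap / DeLong confidence interval for an AUC
#'
#' Default: percentile interval from `B` stratified bootstrap resamples of
#' the (score, label) pairs — resampling events and non-events separately
#' so every resample keeps both classes (a degenerate resample is redrawn,
#' at most 10 times).  `method = "delong"` uses the asymptotic normal
#' interval with DeLong's variance, truncated to `[0, 1]`.
#'
#' @param x Numeric scores, or an [cv_auc()] evaluation object.
#' @param labels Binary labels (ignored when `x` is an evaluation).
#' @param level Confidence level (default 0.95).
#' @param method `"bootstrap"` (default) or `"delong"`.
#' @param B Bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling.
#' @return Numeric `c(lo, hi)`.
#' @export
auc_ci <- function(x, labels = NULL, level = 0.95,
                   method = c("bootstrap", "delong"), B = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "ekbn_eval")) {
    labels <- x$labels
    x <- x$scores
  }
  y <- as_binary_labels(labels)
  a <- (1 - level) / 2
  if (method == "delong") {
    pl <- delong_placements(x, y)
    v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
    z <- stats::qnorm(1 - a)
    return(pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(v))))
  }
  ip <- which(y == 1L)
  inn <- which(y == 0L)
  aucs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      for (attempt in 1:10) {
        idx <- c(ip[sample.int(length(ip), length(ip), replace = TRUE)],
                 inn[sample.int(length(inn), length(inn), replace = TRUE)])
        if (length(unique(y[idx])) == 2L) break
      }
      roc_auc(x[idx], y[idx])
    }, numeric(1))
  })
  unname(stats::quantile(aucs, c(a, 1 - a), type = 7))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scoring rules evaluated on the *same* units
#' (paired design) via the covariance of their placement values.  Returns
#' the z statistic and the two-sided p-value.  Swapping the two scores
#' negates z and leaves p unchanged; identical scores give z = 0, p = 1.
#'
#' @param a,b Numeric score vectors, or two [cv_auc()] evaluations scored
#'   on identical units and labels.
#' @param labels Binary labels (required when `a`, `b` are vectors).
#' @return A one-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(a, b, labels = NULL) {
  if (inherits(a, "ekbn_eval") && inherits(b, "ekbn_eval")) {
    if (!identical(a$unit_id, b$unit_id) || !identical(a$labels, b$labels)) {
      abort_ekbn("the two evaluations must cover identical units and labels")
    }
    labels <- a$labels
    a <- a$scores
    b <- b$scores
  }
  y <- as_binary_labels(labels)
  stopifnot(length(a) == length(b), length(a) == length(y))
  pa <- delong_placements(a, y)
  pb <- delong_placements(b, y)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  z <- if (v <= 0) 0 else d / sqrt(v)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, z = z,
                 p_value = if (v <= 0 && d == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Repeated stratified cross-validated AUC
#'
#' Evaluates a model-building pipeline by repeated stratified k-fold
#' cross-validation: `model_builder` is refit on every training fold (so
#' any feature selection or structure learning it performs happens inside
#' the fold, without leakage), out-of-fold scores are pooled within each
#' repeat, the pooled AUC is averaged over repeats, and a confidence
#' interval is attached via [auc_ci()] on the repeat-averaged out-of-fold
#' scores.
#'
#' @param cohort An [as_cohort()] object (discretized).
#' @param model_builder `function(train_cohort, seed)` returning a scorer
#'   `function(newdata) -> numeric`.
#' @param folds Number of folds (default 5); reduced with a warning when
#'   the minority class is smaller than `folds`.
#' @param repeats Number of repetitions with reshuffled folds (default 10).
#' @param seed Integer seed controlling fold assignment and the builder
#'   sub-seeds.
#' @param ci Attach a bootstrap CI (default TRUE; skipping it saves time
#'   in inner loops).
#' @return An `ekbn_eval`: `auc`, `ci`, per-unit averaged out-of-fold
#'   `scores`, `labels`, `unit_id`, `fold_assignment` (n x repeats),
#'   `per_repeat_auc` and a config echo.
#' @export
cv_auc <- function(cohort, model_builder, folds = 5L, repeats = 10L, seed = 1L,
                   ci = TRUE) {
  outcome <- cohort_outcome(cohort)
  y <- as_binary_labels(cohort[[outcome]])
  n <- length(y)
  n_min <- min(table(y))
  if (n_min < folds) {
    warn_ekbn(paste0("minority class smaller than folds; reducing folds to ", n_min))
    folds <- max(2L, as.integer(n_min))
  }
  if (n_min < 2L) abort_ekbn("outcome too imbalanced for CV spec")
  assign_mat <- matrix(0L, n, repeats)
  score_mat <- matrix(NA_real_, n, repeats)
  for (rep_i in seq_len(repeats)) {
    fold_of <- withr::with_seed(derive_seed(seed, paste0("cv/fold/", rep_i)), {
      f <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        idx <- idx[order(cohort$unit_id[idx])]  # row-order invariant
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f
    })
    assign_mat[, rep_i] <- fold_of
    for (k in seq_len(folds)) {
      test <- fold_of == k
      train <- cohort[!test, , drop = FALSE]
      train <- structure(train, class = class(cohort)) |>
        `attr<-`("outcome", outcome) |>
        `attr<-`("roles", cohort_roles(cohort)) |>
        `attr<-`("outcome_levels", attr(cohort, "outcome_levels"))
      fit_seed <- derive_seed(seed, paste0("cv/fit/", rep_i, "/", k))
      score_mat[test, rep_i] <- withr::with_seed(fit_seed, {
        scorer <- model_builder(train, fit_seed)
        scorer(cohort[test, , drop = FALSE])
      })
    }
  }
  per_repeat <- vapply(seq_len(repeats), function(r) roc_auc(score_mat[, r], y),
                       numeric(1))
  scores <- rowMeans(score_mat)
  res <- structure(
    list(auc = mean(per_repeat),
         ci = c(NA_real_, NA_real_),
         scores = scores, labels = y, unit_id = cohort$unit_id,
         fold_assignment = assign_mat, per_repeat_auc = per_repeat,
         config = list(folds = folds, repeats = repeats, seed = seed)),
    class = "ekbn_eval"
  )
  if (ci) res$ci <- auc_ci(scores, y, seed = derive_seed(seed, "cv/ci"))
  res
}

#' @export
print.ekbn_eval <- function(x, ...) {
  cat(sprintf("<ekbn_eval> AUC = %.3f (95%% CI %.3f-%.3f), %d units, %dx%d-fold CV\n",
              x$auc, x$ci[[1]], x$ci[[2]], length(x$labels),
              x$config$repeats, x$config$folds))
  invisible(x)
}
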