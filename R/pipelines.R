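#' Structure-learning configuration
#'
#' Collects the tunables of the network-building step shared by both
#' pipelines.  `R` and `threshold` control the bootstrap model averaging
#' of the final reported network; `r_cv` controls how many bootstrap
#' replicates are used when the pipeline is refit *inside* a
#' cross-validation fold (default 1, i.e. a single tabu search — fold
#' models are throwaway evaluations, the averaged network is what gets
#' reported).
#'
#' @param tabu_len,max_iter,max_parents Tabu-search controls (see
#'   [tabu_search()]).
#' @param R Bootstrap replicates for the reported network (default 200).
#' @param r_cv Bootstrap replicates inside CV folds (default 1).
#' @param threshold Arc-strength threshold for [averaged_network()].
#' @param ess Dirichlet equivalent sample size for [fit_cpts()].
#' @return A list of class `sl_config`.
#' @export
sl_config <- function(tabu_len = 10L, max_iter = 100L, max_parents = 4L,
                      R = 200L, r_cv = 1L, threshold = 0.5, ess = 1) {
  structure(list(tabu_len = tabu_len, max_iter = max_iter,
                 max_parents = max_parents, R = R, r_cv = r_cv,
                 threshold = threshold, ess = ess), class = "sl_config")
}

# learn a network over `features` + outcome and keep only the outcome's
# connected component; R = 1 collapses to a single tabu search
learn_net <- function(data, features, outcome, sl, seed, R = sl$r_cv) {
  nodes <- c(features, outcome)
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data, nodes)
  if (R <= 1L) {
    g <- tabu_search(coded, features = nodes, tabu_len = sl$tabu_len,
                     max_iter = sl$max_iter, max_parents = sl$max_parents)
    strengths <- NULL
  } else {
    strengths <- bootstrap_arc_strength(coded, features = nodes, R = R,
                                        seed = seed, tabu_len = sl$tabu_len,
                                        max_iter = sl$max_iter,
                                        max_parents = sl$max_parents)
    g <- averaged_network(strengths, threshold = sl$threshold)
  }
  keep <- connected_component(g, outcome)
  g <- dag(keep, g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ])
  bn <- fit_cpts(coded, g, ess = sl$ess, strengths = strengths)
  attr(bn, "outcome") <- outcome
  bn
}

# scorer factory for a *fixed* candidate feature set: structure learning
# and CPTs are refit on each training fold
bn_builder <- function(features, outcome, sl) {
  force(features); force(outcome); force(sl)
  function(train, seed) {
    if (length(features) == 0L) return(prior_scorer(train, outcome))
    bn <- learn_net(train, features, outcome, sl, seed)
    if (length(bn$dag$nodes) == 1L) return(prior_scorer(train, outcome))
    function(newdata) predict(bn, newdata, outcome = outcome)
  }
}

# no-information scorer.  Deliberately a *fixed* constant rather than the
# training-fold prevalence: out-of-fold pooling of fold-specific constants
# anti-correlates with the test fold's event density and biases the pooled
# AUC below 0.5, whereas a shared constant gives exactly 0.5 (all ties).
prior_scorer <- function(train, outcome) {
  function(newdata) rep(0.5, nrow(newdata))
}

check_discretized <- function(cohort) {
  bad <- cohort_features(cohort)[!vapply(cohort[cohort_features(cohort)],
                                         function(x) is.factor(x) || is.character(x),
                                         logical(1))]
  if (length(bad) > 0) {
    abort_ekbn(paste0("continuous feature(s) present: ",
                      paste(utils::head(bad, 5), collapse = ", "),
                      "; run discretize() first"))
  }
  invisible(cohort)
}

#' Pure data-driven Bayesian network pipeline (PD-BN)
#'
#' The two-step baseline: (1) feature selection — the outcome's Markov
#' blanket over all candidate features; (2) structure building —
#' bootstrap-averaged tabu search over the selected features plus the
#' outcome, with Dirichlet-smoothed CPTs.  The cross-validated evaluation
#' refits the whole pipeline (blanket and structure) inside every training
#' fold so no selection information leaks into the held-out folds.  When
#' the blanket is empty the model degenerates to the prior-marginal
#' predictor (expected AUC 0.5) with a warning.
#'
#' @param cohort A discretized [as_cohort()] object.
#' @param alpha Significance level of the blanket search.
#' @param sl An [sl_config()].
#' @param folds,repeats Cross-validation layout (default 5 x 2).
#' @param seed Integer seed.
#' @param leak_selection `TRUE` reuses the full-data blanket inside the
#'   folds — a deliberately leaky variant kept only to demonstrate (in the
#'   regression tests) why the fold-internal refit matters.  Never use it
#'   for reported results.
#' @return An `ekbn_pdbn`: final `bn`, `eval`, the full-data blanket `mb`,
#'   arc `strengths`, and the config echo.
#' @export
pd_bn_fit <- function(cohort, alpha = 0.05, sl = sl_config(), folds = 5L,
                      repeats = 2L, seed = 1L, leak_selection = FALSE) {
  check_discretized(cohort)
  outcome <- cohort_outcome(cohort)
  feats <- cohort_features(cohort)

  select_then_score <- function(train, sub_seed) {
    mb <- markov_blanket(as.data.frame(train)[c(feats, outcome)], outcome,
                         candidates = feats, alpha = alpha)
    bn_builder(mb$members, outcome, sl)(train, sub_seed)
  }
  full_mb <- markov_blanket(as.data.frame(cohort)[c(feats, outcome)], outcome,
                            candidates = feats, alpha = alpha)
  if (length(full_mb$members) == 0L) {
    warn_ekbn("empty Markov blanket: PD-BN degenerates to the prior-marginal predictor")
  }
  builder <- if (leak_selection) {
    function(train, sub_seed) bn_builder(full_mb$members, outcome, sl)(train, sub_seed)
  } else {
    select_then_score
  }
  eval <- cv_auc(cohort, builder, folds = folds, repeats = repeats,
                 seed = derive_seed(seed, "pdbn/cv"))
  bn <- learn_net(cohort, full_mb$members, outcome, sl,
                  seed = derive_seed(seed, "pdbn/structure"), R = sl$R)
  structure(
    list(bn = bn, eval = eval, mb = full_mb, strengths = bn$strengths,
         config = list(alpha = alpha, sl = sl, folds = folds,
                       repeats = repeats, seed = seed,
                       leak_selection = leak_selection)),
    class = "ekbn_pdbn"
  )
}

#' @export
print.ekbn_pdbn <- function(x, ...) {
  cat(sprintf("<ekbn_pdbn> MB size %d, network %d nodes / %d arcs, CV AUC %.3f (%.3f-%.3f)\n",
              length(x$mb$members), length(x$bn$dag$nodes), nrow(x$bn$dag$edges),
              x$eval$auc, x$eval$ci[[1]], x$eval$ci[[2]]))
  invisible(x)
}

#' Initial top-list fraction from the faithfulness dimension
#'
#' The initial human-in-the-loop window takes the top `n` percent of the
#' integrated ranking, with `n = 100 * D / N`: `D` is the feature
#' dimension the blanket algorithms can support faithfully at the given
#' sample size, `N` the total feature count, so the top set has exactly
#' `D` features by construction.
#'
#' @param n_features Total number of ranked features N.
#' @param d Faithfulness dimension D (1 <= D <= N).
#' @return The percentage `n` (numeric).
#' @export
initial_fraction <- function(n_features, d) {
  if (d < 1 || d > n_features) abort_ekbn("D must satisfy 1 <= D <= N")
  100 * d / n_features
}

#' Evaluate (and prune) a fixed candidate feature set
#'
#' Shared by the initial model and every incremental step: learns the
#' network on the candidate set, drops features disconnected from the
#' outcome, then greedily removes features whose deletion improves — or
#' preserves within `epsilon` — the cross-validated AUC ("less important
#' features are eliminated to maximize prediction performance").
#' Structure and CPTs are refit inside every CV fold; the candidate set
#' itself is the object under evaluation.
#'
#' @keywords internal
fit_and_eval <- function(cohort, features, outcome, config, cv_seed,
                         elim_candidates = features) {
  eval_set <- function(fs) {
    cv_auc(cohort, bn_builder(fs, outcome, config$sl),
           folds = config$folds, repeats = config$repeats,
           seed = cv_seed, ci = FALSE)
  }
  features <- sort(features)
  if (length(features) > 0L) {
    net0 <- learn_net(cohort, features, outcome, config$sl,
                      seed = derive_seed(cv_seed, "net0"))
    features <- sort(setdiff(net0$dag$nodes, outcome))
  }
  eval <- eval_set(features)
  # greedy backward elimination on CV AUC
  repeat {
    cand <- intersect(features, elim_candidates)
    if (length(cand) == 0L) break
    trials <- lapply(cand, function(f) eval_set(setdiff(features, f)))
    aucs <- vapply(trials, `[[`, numeric(1), "auc")
    best <- which.max(aucs)
    if (aucs[[best]] >= eval$auc - config$epsilon) {
      features <- setdiff(features, cand[[best]])
      eval <- trials[[best]]
    } else break
  }
  net <- if (length(features) > 0L) {
    learn_net(cohort, features, outcome, config$sl,
              seed = derive_seed(cv_seed, "net"))
  } else NULL
  eval$ci <- auc_ci(eval$scores, eval$labels, seed = derive_seed(cv_seed, "ci"))
  list(features = features, net = net, eval = eval)
}

#' Held-out evaluation of a fitted pipeline
#'
#' Scores a *frozen* model (the final network of a [pd_bn_fit()] or
#' [hitl_bn_run()] fit) on an independent cohort, once — the unbiased
#' "testing dataset" analogue.
#'
#' @param fit An `ekbn_pdbn` or `ekbn_hitl` object.
#' @param newdata A discretized cohort with the same outcome.
#' @return An `ekbn_eval` (scores, labels, AUC and bootstrap CI).
#' @export
heldout_eval <- function(fit, newdata) {
  bn <- if (inherits(fit, "ekbn_hitl")) fit$bn else fit$bn
  outcome <- cohort_outcome(newdata)
  y <- as_binary_labels(newdata[[outcome]])
  scores <- if (is.null(bn) || length(bn$dag$nodes) <= 1L) {
    rep(0.5, nrow(newdata))
  } else {
    predict(bn, newdata, outcome = outcome)
  }
  structure(
    list(auc = roc_auc(scores, y),
         ci = auc_ci(scores, y, seed = 1L),
         scores = scores, labels = y, unit_id = newdata$unit_id,
         fold_assignment = NULL, per_repeat_auc = NULL,
         config = list(kind = "heldout")),
    class = "ekbn_eval"
  )
}
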