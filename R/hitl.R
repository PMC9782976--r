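#' Configuration of the human-in-the-loop pipeline
#'
#' Every tunable of [hitl_bn_run()] with its default.  A run's config echo
#' (stored on the result) reproduces the run exactly.
#'
#' @param alpha Blanket-search significance level.
#' @param D Faithfulness dimension (initial window size); default
#'   `min(10, floor(n_units / 10))`, chosen when the run starts.
#' @param epsilon Minimum cross-validated AUC improvement for accepting a
#'   step (default 0.001).
#' @param learners Importance-ranking learners (default RF and GBM).
#' @param weighting WRS weighting rule, see [integrate_rankings()].
#' @param folds,repeats Cross-validation layout for step evaluation.
#' @param sl An [sl_config()].
#' @param target_auc Stop as soon as the incumbent reaches this AUC
#'   (`NULL` = never; `0` stops right after the initial model).
#' @param patience Stop after this many consecutive rejected steps
#'   (default `Inf`, i.e. exhaust the EKF list).
#' @param exclude_ekfs EKFs to skip (e.g. not available in practice).
#' @param mb_window `"top_d"` restricts the initial non-EKF blanket search
#'   to the window, `"full"` uses the whole ranked list.
#' @param ask Optional callback `function(info) -> TRUE/FALSE` consulted
#'   before each incremental step (the interactive human layer); `NULL`
#'   (batch mode) evaluates every step and decides on AUC alone.
#' @param n_perm,num_trees,nrounds Importance-ranking controls, see
#'   [importance_list()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `hitl_config`.
#' @export
hitl_config <- function(alpha = 0.05, D = NULL, epsilon = 0.001,
                        learners = c("rf", "gbm"),
                        weighting = c("inverse", "proportional"),
                        folds = 5L, repeats = 2L, sl = sl_config(),
                        target_auc = NULL, patience = Inf,
                        exclude_ekfs = character(0),
                        mb_window = c("top_d", "full"), ask = NULL,
                        n_perm = 20L, num_trees = 500L, nrounds = 100L,
                        seed = 1L) {
  structure(
    list(alpha = alpha, D = D, epsilon = epsilon, learners = learners,
         weighting = match.arg(weighting), folds = folds, repeats = repeats,
         sl = sl, target_auc = target_auc, patience = patience,
         exclude_ekfs = exclude_ekfs, mb_window = match.arg(mb_window),
         ask = ask, n_perm = n_perm, num_trees = num_trees,
         nrounds = nrounds, seed = seed),
    class = "hitl_config"
  )
}

# positions of the (non-excluded) EKFs inside the integrated list
ekf_positions <- function(cohort, ranking, exclude = character(0)) {
  ekfs <- setdiff(cohort_ekfs(cohort), exclude)
  pos <- ranking[ranking$feature %in% ekfs, c("feature", "rank")]
  pos <- dplyr::arrange(pos, .data$rank)
  pos$i <- seq_len(nrow(pos))
  pos
}

#' Initial human-in-the-loop model
#'
#' Builds HITL-BN(i) from the top-D window of the integrated ranking:
#' the window's most relevant EKFs are identified from the outcome's
#' Markov blanket over the window; given those EKFs, window non-EKFs that
#' are strongly related to them are collected from each EKF's blanket
#' over the window's non-EKFs; the network is then learned on the kept
#' features and pruned by backward elimination.  If the window contains
#' no EKF it is extended to the first EKF in the list, with a warning.
#'
#' @param cohort A discretized cohort.
#' @param ranking An [integrate_rankings()] list over the cohort features.
#' @param config An [hitl_config()].
#' @return An `hitl_state`: selected features, network, evaluation, the
#'   EKF order and the current EKF index, `D` and `n_pct`.
#' @export
initial_model <- function(cohort, ranking, config = hitl_config()) {
  check_discretized(cohort)
  outcome <- cohort_outcome(cohort)
  N <- nrow(ranking)
  D <- config$D %||% min(10L, floor(nrow(cohort) / 10))
  if (D > N) abort_ekbn("D must satisfy 1 <= D <= N")
  n_pct <- initial_fraction(N, D)
  ekfs <- ekf_positions(cohort, ranking, config$exclude_ekfs)
  if (nrow(ekfs) == 0L) {
    abort_ekbn("HITL-BN requires at least one expert-knowledge feature")
  }
  window_end <- D
  if (!any(ekfs$rank <= D)) {
    window_end <- min(ekfs$rank)
    warn_ekbn(paste0("no EKF in the top-", D,
                     " window; extending it to rank ", window_end))
  }
  window <- ranking$feature[ranking$rank <= window_end]
  window_ekfs <- intersect(window, ekfs$feature)
  window_non <- setdiff(window, ekfs$feature)

  df <- as.data.frame(cohort)
  kept_ekfs <- intersect(
    markov_blanket(df[c(window, outcome)], outcome, candidates = window,
                   alpha = config$alpha)$members,
    window_ekfs
  )
  non_pool <- if (config$mb_window == "top_d") window_non else
    setdiff(ranking$feature, ekfs$feature)
  kept_non <- character(0)
  for (e in kept_ekfs) {
    pool <- setdiff(non_pool, e)
    if (length(pool) == 0L) next
    mb_e <- markov_blanket(df[c(pool, e)], e, candidates = pool,
                           alpha = config$alpha)$members
    kept_non <- union(kept_non, mb_e)
  }
  selected <- sort(union(kept_ekfs, kept_non))
  fe <- fit_and_eval(cohort, selected, outcome, config,
                     cv_seed = derive_seed(config$seed, "hitl/cv"))
  structure(
    list(ranking = ranking, ekf_order = ekfs,
         ekf_index = sum(ekfs$rank <= window_end),
         selected = fe$features, net = fe$net, eval = fe$eval,
         D = D, n_pct = n_pct, outcome = outcome),
    class = "hitl_state"
  )
}

#' Non-EKF candidates between two consecutive EKFs
#'
#' When the incremental evaluation moves from the i-th to the (i+1)-th
#' EKF of the integrated list, the non-EKFs ranked strictly between them
#' form the set S; of those, only the ones appearing in the Markov
#' blanket of a selected EKF or of the incoming EKF — each blanket
#' computed over the data restricted to S plus that EKF — are retained
#' as S*.  S is empty (hence S* too) when the two EKFs are consecutive
#' in the list.
#'
#' @param state An [initial_model()] state.
#' @param cohort The discretized cohort.
#' @param next_ekf_index The index i+1 (must be `state$ekf_index + 1` at
#'   most `I`).
#' @param config An [hitl_config()].
#' @return List with `s` (the between-ranks non-EKFs) and `s_star`.
#' @export
candidate_nonekfs <- function(state, cohort, next_ekf_index,
                              config = hitl_config()) {
  ekfs <- state$ekf_order
  if (next_ekf_index < 1L || next_ekf_index > nrow(ekfs)) {
    abort_ekbn("next_ekf_index out of range")
  }
  r_hi <- ekfs$rank[[next_ekf_index]]
  r_lo <- if (next_ekf_index == 1L) 0L else ekfs$rank[[next_ekf_index - 1L]]
  rk <- state$ranking
  between <- rk$feature[rk$rank > r_lo & rk$rank < r_hi]
  s <- sort(setdiff(between, ekfs$feature))
  if (length(s) == 0L) return(list(s = character(0), s_star = character(0)))
  df <- as.data.frame(cohort)
  anchors <- union(intersect(state$selected, ekfs$feature),
                   ekfs$feature[[next_ekf_index]])
  s_star <- character(0)
  for (e in anchors) {
    mb_e <- markov_blanket(df[c(s, e)], e, candidates = s,
                           alpha = config$alpha)$members
    s_star <- union(s_star, intersect(mb_e, s))
  }
  list(s = s, s_star = sort(s_star))
}

#' One incremental human-in-the-loop step
#'
#' Proposes the (i+1)-th EKF together with its associated non-EKFs S*,
#' re-runs structure learning and elimination on the enlarged candidate
#' set, and accepts the new model only if its cross-validated AUC
#' (computed on the same fold splits as the incumbent's) improves by more
#' than `epsilon`; otherwise the incumbent is kept and the step recorded
#' as rejected.  The EKF index always advances.
#'
#' @inheritParams candidate_nonekfs
#' @return List `(state, accepted, step)` where `step` is a one-row
#'   trace tibble.
#' @export
hitl_step <- function(state, cohort, next_ekf_index, config = hitl_config()) {
  cand <- candidate_nonekfs(state, cohort, next_ekf_index, config)
  new_ekf <- state$ekf_order$feature[[next_ekf_index]]
  proposal <- sort(union(state$selected, c(new_ekf, cand$s_star)))
  new_feats <- setdiff(proposal, state$selected)
  fe <- fit_and_eval(cohort, proposal, state$outcome, config,
                     cv_seed = derive_seed(config$seed, "hitl/cv"),
                     elim_candidates = new_feats)
  accepted <- is.finite(config$epsilon) &&
    fe$eval$auc > state$eval$auc + config$epsilon
  step <- tibble::tibble(
    i = next_ekf_index, ekf = new_ekf,
    s = list(cand$s), s_star = list(cand$s_star),
    candidate_auc = fe$eval$auc, incumbent_auc = state$eval$auc,
    accepted = accepted,
    selected = list(if (accepted) fe$features else state$selected)
  )
  if (accepted) {
    state$selected <- fe$features
    state$net <- fe$net
    state$eval <- fe$eval
  }
  state$ekf_index <- next_ekf_index
  list(state = state, accepted = accepted, step = step)
}

#' Run the full human-in-the-loop pipeline
#'
#' End to end: per-learner importance rankings, WRS integration, the
#' initial top-D model, then one [hitl_step()] per remaining EKF in
#' integrated-list order.  The run stops when the EKF list is exhausted,
#' when `target_auc` is reached, or after `patience` consecutive
#' rejections.  The final selected model is refit on the full data with
#' bootstrap arc-strength averaging (`sl$R` replicates).  The returned
#' trace replays deterministically from the config echo.
#'
#' @param cohort A discretized [as_cohort()] with at least one EKF.
#' @param config An [hitl_config()].
#' @return An `ekbn_hitl`: `trace` (one row per step), final `state`,
#'   final averaged `bn`, per-learner `rankings`, integrated `ranking`,
#'   and the `config` echo.
#' @export
hitl_bn_run <- function(cohort, config = hitl_config()) {
  check_discretized(cohort)
  if (length(setdiff(cohort_ekfs(cohort), config$exclude_ekfs)) == 0L) {
    abort_ekbn("HITL-BN requires at least one expert-knowledge feature")
  }
  rankings <- lapply(config$learners, function(l) {
    importance_list(cohort, learner = l,
                    seed = derive_seed(config$seed, paste0("rank/", l)),
                    n_perm = config$n_perm, num_trees = config$num_trees,
                    nrounds = config$nrounds)
  })
  names(rankings) <- config$learners
  ranking <- integrate_rankings(rankings, weighting = config$weighting)

  state <- initial_model(cohort, ranking, config)
  trace <- list()
  rejections <- 0L
  stopped <- "exhausted"
  target_hit <- function() {
    !is.null(config$target_auc) && state$eval$auc >= config$target_auc
  }
  if (target_hit()) {
    stopped <- "target_auc"
  } else {
    I <- nrow(state$ekf_order)
    while (state$ekf_index < I) {
      nxt <- state$ekf_index + 1L
      if (!is.null(config$ask)) {
        info <- list(i = nxt, ekf = state$ekf_order$feature[[nxt]],
                     selected = state$selected, auc = state$eval$auc)
        if (!isTRUE(config$ask(info))) {
          state$ekf_index <- nxt
          next
        }
      }
      res <- hitl_step(state, cohort, nxt, config)
      state <- res$state
      trace[[length(trace) + 1L]] <- res$step
      rejections <- if (res$accepted) 0L else rejections + 1L
      if (target_hit()) { stopped <- "target_auc"; break }
      if (rejections >= config$patience) { stopped <- "patience"; break }
    }
  }
  bn <- if (length(state$selected) > 0L) {
    learn_net(cohort, state$selected, state$outcome, config$sl,
              seed = derive_seed(config$seed, "hitl/final"), R = config$sl$R)
  } else NULL
  structure(
    list(trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(i = integer(), ekf = character(), s = list(),
                     s_star = list(), candidate_auc = numeric(),
                     incumbent_auc = numeric(), accepted = logical(),
                     selected = list()),
      state = state, bn = bn, rankings = rankings, ranking = ranking,
      stopped = stopped, config = config),
    class = "ekbn_hitl"
  )
}

#' @export
print.ekbn_hitl <- function(x, ...) {
  acc <- sum(x$trace$accepted)
  cat(sprintf(paste0("<ekbn_hitl> %d selected feature(s), CV AUC %.3f ",
                     "(%.3f-%.3f); %d step(s), %d accepted; stopped: %s\n"),
              length(x$state$selected), x$state$eval$auc,
              x$state$eval$ci[[1]], x$state$eval$ci[[2]],
              nrow(x$trace), acc, x$stopped))
  invisible(x)
}
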