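#' Scenario specification for synthetic imbalanced cohorts
#'
#' Defines a ground-truth discrete Bayesian network around a binary
#' outcome: `n_mb` features form the outcome's true Markov blanket
#' (covering all three roles — parents, at least one child, and at least
#' one spouse, i.e. a co-parent of a child), `n_redundant` features are
#' noisy copies of blanket members (dependent on the outcome marginally
#' but conditionally independent of it given their source), and `n_noise`
#' features are marginally independent coin flips.  The outcome CPT is
#' calibrated analytically so the marginal event probability equals
#' `prevalence` exactly.
#'
#' `effect` is the conditional-probability contrast per arc: a single
#' parent flips the event probability by up to `effect` around its base,
#' and a child's level-1 probability moves by `effect` per parent state
#' (so the extreme configurations differ by `2 * effect`).
#'
#' @param n_units Number of units to sample by default.
#' @param prevalence Marginal event probability in (0, 1).
#' @param n_mb True Markov blanket size (>= 3 so all roles are covered).
#' @param n_redundant Number of noisy shadow features.
#' @param n_noise Number of independent noise features.
#' @param ekf_true,ekf_decoy How many true-blanket members and how many
#'   non-informative decoys carry the expert-knowledge flag.  Defaults:
#'   every blanket member plus half that many decoys — imperfect expert
#'   knowledge, one third of flagged features being uninformative.
#' @param effect CPT contrast per arc in (0, 0.5]; default 0.3.
#' @param n_during Number of (noise/shadow) features tagged as
#'   during-treatment, named with the `D_` prefix (default 0).
#' @param outcome_name Name of the outcome column.
#' @param flip Shadow-feature corruption probability (default 0.15).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_units = 100L, prevalence = 0.25, n_mb = 4L,
                          n_redundant = 4L, n_noise = 12L,
                          ekf_true = n_mb, ekf_decoy = ceiling(n_mb / 2),
                          effect = 0.3, n_during = 0L,
                          outcome_name = "event", flip = 0.15) {
  if (prevalence <= 0 || prevalence >= 1) abort_ekbn("prevalence must be in (0,1)")
  if (effect <= 0 || effect > 0.5) abort_ekbn("effect must be in (0, 0.5]")
  if (n_mb < 3L) abort_ekbn("n_mb must be >= 3 (parents, a child and a spouse)")
  if (ekf_true > n_mb) abort_ekbn("ekf_true cannot exceed n_mb")
  if (ekf_decoy > n_redundant + n_noise) abort_ekbn("not enough non-blanket features for decoys")
  structure(
    list(n_units = as.integer(n_units), prevalence = prevalence,
         n_mb = as.integer(n_mb), n_redundant = as.integer(n_redundant),
         n_noise = as.integer(n_noise), ekf_true = as.integer(ekf_true),
         ekf_decoy = as.integer(ekf_decoy), effect = effect,
         n_during = as.integer(n_during), outcome_name = outcome_name,
         flip = flip),
    class = "scenario_spec"
  )
}

#' Preset scenarios mirroring the clinical study conditions
#'
#' `"ialbi_like"`: a liver-toxicity-like endpoint — 81 units, event
#' prevalence 23/81 (about 28%), 69 features of which 12 carry the
#' expert-knowledge flag, 45 features pre-treatment / 24 during-treatment.
#' `"lc_like"`: a local-control-like endpoint — 104 units, event (local
#' failure) prevalence 4/104 (about 4%), 93 features of which 13 are
#' EKFs, 68 pre / 25 during.  Blanket/redundant/noise splits: 4 + 8 + 57
#' and 5 + 9 + 79 respectively.
#'
#' @param name `"ialbi_like"` or `"lc_like"`.
#' @return A [scenario_spec()].
#' @export
preset_scenario <- function(name = c("ialbi_like", "lc_like")) {
  name <- match.arg(name)
  if (name == "ialbi_like") {
    scenario_spec(n_units = 81L, prevalence = 23 / 81, n_mb = 4L,
                  n_redundant = 8L, n_noise = 57L, ekf_true = 4L,
                  ekf_decoy = 8L, effect = 0.3, n_during = 24L,
                  outcome_name = "I_ALBI")
  } else {
    scenario_spec(n_units = 104L, prevalence = 4 / 104, n_mb = 5L,
                  n_redundant = 9L, n_noise = 79L, ekf_true = 5L,
                  ekf_decoy = 8L, effect = 0.3, n_during = 25L,
                  outcome_name = "LC_failure")
  }
}

#' Build the ground-truth network of a scenario
#'
#' The outcome gets `n_mb - 2` parents, one child and one spouse (a second
#' parent of the child).  Parents, spouses and noise features are fair
#' coins; the outcome CPT is `clamp(b + effect * s)` where `s` in `[-1, 1]`
#' is the scaled sum of parent states, with the intercept `b` solved
#' numerically so that the analytic marginal event probability equals the
#' requested prevalence (to ~1e-12; an error reports the attainable range
#' if the prevalence is infeasible for the given effect).  Shadow features
#' copy their source with corruption probability `flip`, making them
#' conditionally independent of the outcome given the source.
#'
#' @param spec A [scenario_spec()].
#' @return A `ground_truth` list: `dag`, `cpts` (an `ekbn_bn` over all
#'   features), `true_mb`, `roles`, and the spec.
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_par <- spec$n_mb - 2L
  parents <- paste0("mb_parent", seq_len(n_par))
  child <- "mb_child1"
  spouse <- "mb_spouse1"
  out <- spec$outcome_name
  shadows <- if (spec$n_redundant > 0) paste0("shadow", seq_len(spec$n_redundant)) else character(0)
  noise <- if (spec$n_noise > 0) paste0("noise", seq_len(spec$n_noise)) else character(0)
  true_mb <- c(parents, child, spouse)

  # shadow sources cycle through the blanket members (deterministic)
  src <- rep(true_mb, length.out = spec$n_redundant)

  # during-treatment tagging: the tail of the noise block gets the D_ prefix
  if (spec$n_during > length(noise)) {
    abort_ekbn("n_during exceeds the number of noise features")
  }
  during <- if (spec$n_during > 0) utils::tail(noise, spec$n_during) else character(0)
  renamed <- ifelse(noise %in% during, paste0("D_", noise), noise)
  during_named <- paste0("D_", during)
  noise <- renamed

  feats <- c(parents, child, spouse, shadows, noise)
  nodes <- c(feats, out)
  edges <- dplyr::bind_rows(
    tibble::tibble(from = parents, to = out),
    tibble::tibble(from = c(out, spouse), to = child),
    if (length(shadows)) tibble::tibble(from = src, to = shadows)
  )
  g <- dag(nodes, edges)

  # outcome CPT: prevalence-calibrated intercept
  clamp <- function(p) pmin(0.995, pmax(0.005, p))
  cfg <- as.matrix(expand.grid(rep(list(0:1), n_par)))
  s_of <- if (n_par > 0) (2 * rowMeans(cfg) - 1) else 0
  marginal <- function(b) mean(clamp(b + spec$effect * s_of))
  lo <- marginal(-2)
  hi <- marginal(2)
  if (spec$prevalence < lo || spec$prevalence > hi) {
    abort_ekbn(sprintf(
      "prevalence %.4f unattainable with effect %.2f: attainable range [%.4f, %.4f]",
      spec$prevalence, spec$effect, lo, hi))
  }
  b <- stats::uniroot(function(b) marginal(b) - spec$prevalence,
                      c(-2, 2), tol = 1e-14)$root
  p_out <- clamp(b + spec$effect * s_of)

  levs2 <- c("0", "1")
  cpts <- list()
  for (p in c(parents, spouse)) {
    cpts[[p]] <- array(c(0.5, 0.5), dim = 2, dimnames = stats::setNames(list(levs2), p))
  }
  # outcome given parents
  out_dims <- c(2L, rep(2L, n_par))
  out_dn <- c(list(levs2), rep(list(levs2), n_par))
  names(out_dn) <- c(out, parents)
  out_tab <- array(0, dim = out_dims, dimnames = out_dn)
  for (r in seq_len(nrow(cfg))) {
    idx <- as.list(cfg[r, ] + 1L)
    out_tab[do.call(cbind, c(list(1:2), idx))] <- c(1 - p_out[[r]], p_out[[r]])
  }
  cpts[[out]] <- out_tab
  # child given outcome and spouse
  ch_dn <- stats::setNames(list(levs2, levs2, levs2), c(child, out, spouse))
  ch_tab <- array(0, dim = c(2, 2, 2), dimnames = ch_dn)
  for (o in 0:1) for (s in 0:1) {
    p1 <- clamp(0.5 + spec$effect * ((2 * o - 1) + (2 * s - 1)) / 2)
    ch_tab[, o + 1L, s + 1L] <- c(1 - p1, p1)
  }
  cpts[[child]] <- ch_tab
  # shadows given their source
  for (i in seq_along(shadows)) {
    dn <- stats::setNames(list(levs2, levs2), c(shadows[[i]], src[[i]]))
    cpts[[shadows[[i]]]] <- array(c(1 - spec$flip, spec$flip,
                                    spec$flip, 1 - spec$flip),
                                  dim = c(2, 2), dimnames = dn)
  }
  for (x in noise) {
    cpts[[x]] <- array(c(0.5, 0.5), dim = 2, dimnames = stats::setNames(list(levs2), x))
  }
  cpts <- cpts[nodes]
  bn <- structure(list(dag = g, cpts = cpts,
                       levels = stats::setNames(rep(list(levs2), length(nodes)), nodes),
                       strengths = NULL),
                  class = "ekbn_bn")
  attr(bn, "outcome") <- out

  # EKF flags: true-blanket members, then decoys split between redundant
  # shadows (plausible-but-redundant expertise) and pure noise
  # (mistaken expertise)
  n_sh <- min(length(shadows), floor(spec$ekf_decoy / 2))
  ekf <- c(utils::head(true_mb, spec$ekf_true),
           utils::head(shadows, n_sh),
           utils::head(noise, spec$ekf_decoy - n_sh))
  roles <- tibble::tibble(
    feature = feats,
    is_ekf = feats %in% ekf,
    phase = ifelse(feats %in% during_named, "during", "pre"),
    outcomes = rep(list(character(0)), length(feats))
  )
  structure(
    list(dag = g, bn = bn, true_mb = true_mb, roles = roles, spec = spec,
         outcome = out, intercept = b),
    class = "ground_truth"
  )
}

#' Sample a cohort from a ground truth by ancestral sampling
#'
#' Nodes are sampled in topological order from their CPTs; EKF flags and
#' phase tags are copied from the scenario.  Deterministic given the seed.
#'
#' @param truth A [make_ground_truth()] object.
#' @param n_units Number of units (default: the scenario's).
#' @param seed Integer seed.
#' @return An [as_cohort()] object with factor feature columns.
#' @export
sample_dataset <- function(truth, n_units = truth$spec$n_units, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  bn <- truth$bn
  ord <- topo_order_pl(parent_list(bn$dag))
  nodes <- bn$dag$nodes[ord]
  pl <- parent_list(bn$dag)
  cols <- list()
  withr::with_seed(as.integer(seed), {
    for (nd in nodes) {
      tab <- bn$cpts[[nd]]
      vars <- names(dimnames(tab))
      parents <- vars[-1L]
      if (length(parents) == 0L) {
        p1 <- tab[[2L]]
        cols[[nd]] <- stats::rbinom(n_units, 1L, p1)
      } else {
        idx <- rep(1L, n_units)
        mult <- 2L
        for (p in parents) {
          idx <- idx + cols[[p]] * mult
          mult <- mult * 2L
        }
        # idx points at the level-0 cell for each parent config
        p1 <- as.numeric(tab)[idx + 1L]
        cols[[nd]] <- stats::rbinom(n_units, 1L, p1)
      }
    }
  })
  df <- tibble::as_tibble(lapply(cols[bn$dag$nodes], function(v) {
    factor(as.character(v), levels = c("0", "1"))
  }))
  as_cohort(df, outcome = truth$outcome, roles = truth$roles)
}

#' Gaussian emission wrapper for discrete features
#'
#' Replaces chosen discrete feature columns with continuous draws — one
#' Gaussian per category (mean = category index, common `sd`) — to
#' exercise the discretizer on realistic mixed-type tables.
#'
#' @param cohort A sampled cohort.
#' @param features Which columns to make continuous (default: all
#'   features).
#' @param sd Within-category standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return The cohort with the chosen columns numeric.
#' @export
continuous_emission <- function(cohort, features = cohort_features(cohort),
                                sd = 0.5, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    for (f in features) {
      lev <- as.integer(factor(as.character(cohort[[f]])))
      cohort[[f]] <- stats::rnorm(length(lev), mean = lev, sd = sd)
    }
  })
  cohort
}

# analytic joint of a ground truth (enumeration; for tests and calibration)
truth_joint <- function(truth) joint_enumeration(truth$bn)
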