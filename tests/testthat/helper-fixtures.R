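# Fixtures are generated in code; nothing is read from disk.

# tiny 4-unit cohort with two features
toy_cohort <- function() {
  as_cohort(
    data.frame(
      outcome = c(0, 0, 1, 1),
      f1 = factor(c("a", "a", "b", "b")),
      f2 = factor(c("x", "y", "x", "y"))
    ),
    outcome = "outcome"
  )
}

# sample a chain X -> Z -> Y of binary variables
sample_chain <- function(n, seed, p_edge = 0.85) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    z <- ifelse(rbinom(n, 1, p_edge) == 1, x, 1 - x)
    y <- ifelse(rbinom(n, 1, p_edge) == 1, z, 1 - z)
    data.frame(x = factor(x), z = factor(z), y = factor(y))
  })
}

# the canonical 5-node blanket structure: P1 -> T <- P2, T -> C <- S,
# plus `n_noise` independent coins
sample_mb_net <- function(n, seed, n_noise = 0, beta = 0.25) {
  withr::with_seed(seed, {
    p1 <- rbinom(n, 1, 0.5)
    p2 <- rbinom(n, 1, 0.5)
    pt <- 0.5 + beta * (2 * p1 - 1) + beta * (2 * p2 - 1)
    t <- rbinom(n, 1, pmin(0.95, pmax(0.05, pt)))
    s <- rbinom(n, 1, 0.5)
    pc <- 0.5 + beta * (2 * t - 1) + beta * (2 * s - 1)
    c_ <- rbinom(n, 1, pmin(0.95, pmax(0.05, pc)))
    df <- data.frame(P1 = p1, P2 = p2, T = t, C = c_, S = s)
    for (j in seq_len(n_noise)) df[[paste0("N", j)]] <- rbinom(n, 1, 0.5)
    as.data.frame(lapply(df, function(v) factor(v, levels = 0:1)))
  })
}

# random DAG over k binary nodes with per-arc contrast `beta`; returns
# the sampled data and the true parent sets
sample_random_dag <- function(k, n, seed, p_edge = 0.35, beta = 0.3) {
  withr::with_seed(seed, {
    nodes <- paste0("V", seq_len(k))
    pl <- stats::setNames(vector("list", k), nodes)
    for (j in seq_len(k)) {
      pars <- if (j == 1) integer(0) else which(runif(j - 1) < p_edge)
      pl[[j]] <- nodes[pars]
    }
    cols <- list()
    for (j in seq_len(k)) {
      pars <- pl[[j]]
      if (length(pars) == 0) {
        cols[[nodes[j]]] <- rbinom(n, 1, 0.5)
      } else {
        eta <- 0.5
        for (p in pars) {
          eta <- eta + beta * (2 * cols[[p]] - 1) / sqrt(length(pars))
        }
        cols[[nodes[j]]] <- rbinom(n, 1, pmin(0.95, pmax(0.05, eta)))
      }
    }
    list(
      data = as.data.frame(lapply(cols, function(v) factor(v, levels = 0:1))),
      parents = pl,
      nodes = nodes
    )
  })
}

# true Markov blanket of `target` from known parent sets
true_mb_of <- function(parents, target) {
  kids <- names(parents)[vapply(parents, function(p) target %in% p, logical(1))]
  spouses <- unique(unlist(parents[kids]))
  setdiff(unique(c(parents[[target]], kids, spouses)), target)
}

# a small, fast scenario used by the pipeline tests
small_scenario <- function(n_units = 150) {
  scenario_spec(n_units = n_units, prevalence = 0.3, n_mb = 4L,
                n_redundant = 2L, n_noise = 6L, ekf_true = 4L, ekf_decoy = 2L,
                effect = 0.3)
}

fast_sl <- function(R = 20L) sl_config(R = R, max_iter = 50L)

fast_hitl <- function(seed, ...) {
  hitl_config(seed = seed, sl = fast_sl(), repeats = 1L, n_perm = 5L,
              num_trees = 150L, nrounds = 50L, ...)
}
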