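#' Fit conditional probability tables on a DAG
#'
#' Bayesian parameter estimation with a symmetric Dirichlet (BDeu) prior of
#' equivalent sample size `ess`: each cell of a node's CPT receives prior
#' weight `ess / (r * q)` where `r` is the node's level count and `q` its
#' number of parent configurations.  With `ess > 0` no probability is ever
#' exactly zero, which keeps posteriors finite at small n; `ess = 0` gives
#' maximum-likelihood frequencies.
#'
#' @param data Data frame of categorical columns containing every node.
#' @param g An [dag()].
#' @param ess Equivalent sample size of the Dirichlet prior (default 1).
#' @param strengths Optional [bootstrap_arc_strength()] table stored as
#'   provenance.
#' @return An `ekbn_bn`: the DAG, per-node CPT arrays (first dimension =
#'   the node, remaining dimensions = parents), and per-node levels.
#' @export
fit_cpts <- function(data, g, ess = 1, strengths = NULL) {
  stopifnot(inherits(g, "ekbn_dag"), ess >= 0)
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data, g$nodes)
  pl <- parent_list(g)
  cpts <- lapply(g$nodes, function(nd) {
    parents <- pl[[nd]]
    r <- coded$nlev[[nd]]
    pi_ <- joint_index(coded, parents)
    q <- pi_$size
    idx <- coded$m[, nd] + r * (pi_$idx - 1L)
    counts <- matrix(tabulate(idx, nbins = r * q), nrow = r)
    prior <- ess / (r * q)
    prob <- counts + prior
    tot <- colSums(prob)
    # a parent configuration never observed and ess = 0: fall back to uniform
    zero <- tot == 0
    prob[, zero] <- 1 / r
    tot[zero] <- 1
    prob <- sweep(prob, 2L, tot, "/")
    dims <- c(r, unlist(coded$nlev[parents], use.names = FALSE))
    dn <- c(list(coded$levels[[nd]]), coded$levels[parents])
    names(dn) <- c(nd, parents)
    array(prob, dim = dims, dimnames = dn)
  })
  names(cpts) <- g$nodes
  structure(
    list(dag = g, cpts = cpts, levels = coded$levels[g$nodes],
         strengths = strengths),
    class = "ekbn_bn"
  )
}

#' @export
print.ekbn_bn <- function(x, ...) {
  cat(sprintf("<ekbn_bn> %d nodes, %d arcs, discrete CPTs\n",
              length(x$dag$nodes), nrow(x$dag$edges)))
  invisible(x)
}

# ---- factor algebra for variable elimination -------------------------------

# a factor: list(vars = character, tab = array with dimnames by vars)
cpt_factor <- function(bn, node) {
  tab <- bn$cpts[[node]]
  list(vars = names(dimnames(tab)), tab = tab)
}

factor_reduce <- function(f, var, level) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  pos <- match(level, dimnames(f$tab)[[i]])
  if (is.na(pos)) return(NULL)  # unseen level: caller marginalizes instead
  idx[[i]] <- pos
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L) {
    return(list(vars = character(0), tab = sum(tab)))
  }
  dn <- dimnames(f$tab)[keep]
  tab <- array(tab, dim = vapply(dn, length, integer(1), USE.NAMES = FALSE),
               dimnames = dn)
  list(vars = f$vars[keep], tab = tab)
}

factor_product <- function(a, b) {
  if (length(a$vars) == 0L) return(list(vars = b$vars, tab = b$tab * as.numeric(a$tab)))
  if (length(b$vars) == 0L) return(list(vars = a$vars, tab = a$tab * as.numeric(b$tab)))
  vars <- union(a$vars, b$vars)
  dn <- c(dimnames(a$tab), dimnames(b$tab))[!duplicated(c(a$vars, b$vars))]
  names(dn) <- vars
  sizes <- vapply(dn, length, integer(1))
  grid_idx <- function(f) {
    # linear index into f's table for every cell of the joint grid over `vars`
    pos <- match(f$vars, vars)
    cell <- arrayInd(seq_len(prod(sizes)), .dim = sizes)
    fi <- cell[, pos, drop = FALSE]
    fm <- cumprod(c(1L, utils::head(vapply(dimnames(f$tab), length, integer(1)), -1L)))
    as.vector(1L + (fi - 1L) %*% fm)
  }
  tab <- array(as.numeric(a$tab)[grid_idx(a)] * as.numeric(b$tab)[grid_idx(b)],
               dim = sizes, dimnames = dn)
  list(vars = vars, tab = tab)
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L) {
    return(list(vars = character(0), tab = sum(f$tab)))
  }
  tab <- apply(f$tab, keep, sum)
  dn <- dimnames(f$tab)[keep]
  tab <- array(tab, dim = vapply(dn, length, integer(1)), dimnames = dn)
  list(vars = f$vars[keep], tab = tab)
}

#' Posterior of the outcome by exact variable elimination
#'
#' Computes `P(outcome = event | evidence)` exactly: evidence values are
#' fixed in every CPT factor, all remaining variables except the outcome
#' are summed out in a minimum-width elimination order, and the result is
#' normalized.  Evidence on features outside the outcome's connected
#' component cannot change the posterior; evidence features absent from
#' the network are ignored with a warning, and evidence levels never seen
#' at fit time are treated as missing (marginalized over).
#'
#' @param bn An [fit_cpts()] network.
#' @param evidence Named list/vector of feature levels.
#' @param outcome Outcome node name (default `"outcome"` attribute-free
#'   guess: the node named by `attr(bn, "outcome")` if present, else must
#'   be supplied).
#' @return Named numeric vector of posterior probabilities over the
#'   outcome's levels.
#' @export
predict_outcome <- function(bn, evidence = list(), outcome = attr(bn, "outcome")) {
  stopifnot(inherits(bn, "ekbn_bn"))
  if (is.null(outcome)) abort_ekbn("supply the outcome node name")
  if (!outcome %in% bn$dag$nodes) abort_ekbn("outcome is not a node of the network")
  evidence <- as.list(evidence)
  if (outcome %in% names(evidence)) abort_ekbn("outcome must not appear in the evidence")
  extra <- setdiff(names(evidence), bn$dag$nodes)
  if (length(extra) > 0) {
    warn_ekbn(paste0("ignoring evidence on non-network feature(s): ",
                     paste(extra, collapse = ", ")))
    evidence <- evidence[setdiff(names(evidence), extra)]
  }
  factors <- lapply(bn$dag$nodes, function(nd) cpt_factor(bn, nd))
  for (v in names(evidence)) {
    lev <- as.character(evidence[[v]])
    if (is.na(lev) || !lev %in% bn$levels[[v]]) next  # missing: marginalize
    factors <- lapply(factors, function(f) {
      r <- factor_reduce(f, v, lev)
      r %||% f
    })
  }
  hidden <- setdiff(bn$dag$nodes, c(outcome,
                                    names(evidence)[vapply(names(evidence), function(v) {
                                      lev <- as.character(evidence[[v]])
                                      !is.na(lev) && lev %in% bn$levels[[v]]
                                    }, logical(1))]))
  # min-width greedy elimination order
  while (length(hidden) > 0) {
    widths <- vapply(hidden, function(v) {
      involved <- Reduce(union, lapply(factors[vapply(factors, function(f) v %in% f$vars, logical(1))], `[[`, "vars"), character(0))
      length(involved)
    }, numeric(1))
    v <- hidden[order(widths, hidden)][[1L]]
    hidden <- setdiff(hidden, v)
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(has_v)) next
    prod_f <- Reduce(factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  out <- as.numeric(res$tab)
  if (length(res$vars) != 1L || res$vars != outcome) {
    # only constant factors remain besides the outcome factor
    i <- match(outcome, res$vars)
    out <- as.numeric(apply(res$tab, i, sum))
  }
  names(out) <- bn$levels[[outcome]]
  out / sum(out)
}

#' Predict event posteriors for new units
#'
#' Applies [predict_outcome()] row-wise: every network feature present in
#' `newdata` (except the outcome itself) is used as evidence.
#'
#' @param object An `ekbn_bn`.
#' @param newdata Data frame of feature columns.
#' @param outcome Outcome node name.
#' @param event Level whose posterior probability is returned (default
#'   `"1"`, the cohort event coding).
#' @param ... Unused.
#' @return Numeric vector of `P(outcome = event | evidence)` per row.
#' @export
predict.ekbn_bn <- function(object, newdata, outcome = attr(object, "outcome"),
                            event = "1", ...) {
  feats <- intersect(setdiff(object$dag$nodes, outcome), names(newdata))
  # fast path: only factors containing the outcome matter when the
  # outcome's parents, children and spouses are all observed
  rel <- vapply(object$dag$nodes, function(nd) {
    outcome %in% names(dimnames(object$cpts[[nd]]))
  }, logical(1))
  rel_factors <- object$cpts[rel]
  need <- setdiff(unique(unlist(lapply(rel_factors, function(t) names(dimnames(t))))),
                  outcome)
  ok_fast <- all(need %in% feats)
  obs <- lapply(stats::setNames(feats, feats), function(f) {
    match(as.character(newdata[[f]]), object$levels[[f]])
  })
  if (ok_fast && length(need) > 0) {
    fast_ok <- rowSums(is.na(do.call(cbind, obs[need]))) == 0
  } else if (ok_fast) {
    fast_ok <- rep(TRUE, nrow(newdata))
  } else {
    fast_ok <- rep(FALSE, nrow(newdata))
  }
  out <- numeric(nrow(newdata))
  if (any(fast_ok)) {
    levs <- object$levels[[outcome]]
    post <- matrix(1, sum(fast_ok), length(levs))
    for (tab in rel_factors) {
      vars <- names(dimnames(tab))
      sizes <- dim(tab)
      for (li in seq_along(levs)) {
        idx <- rep(1L, sum(fast_ok))
        mult <- 1L
        for (d in seq_along(vars)) {
          v <- vars[[d]]
          val <- if (v == outcome) rep(li, sum(fast_ok)) else obs[[v]][fast_ok]
          idx <- idx + (val - 1L) * mult
          mult <- mult * sizes[[d]]
        }
        post[, li] <- post[, li] * as.numeric(tab)[idx]
      }
    }
    out[fast_ok] <- post[, match(event, levs)] / rowSums(post)
  }
  for (i in which(!fast_ok)) {
    ev <- lapply(newdata[i, feats, drop = FALSE], as.character)
    out[[i]] <- unname(predict_outcome(object, ev, outcome = outcome)[[event]])
  }
  out
}

# full-joint enumeration (test oracle, <= ~10 nodes)
joint_enumeration <- function(bn) {
  grid <- expand.grid(bn$levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pl <- parent_list(bn$dag)
  p <- rep(1, nrow(grid))
  for (nd in bn$dag$nodes) {
    tab <- bn$cpts[[nd]]
    vars <- names(dimnames(tab))
    idx <- mapply(function(v) match(grid[[v]], bn$levels[[v]]), vars,
                  SIMPLIFY = FALSE)
    p <- p * tab[as.matrix(as.data.frame(idx))]
  }
  cbind(grid, prob = p)
}
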