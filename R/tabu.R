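#' Score-based DAG search with tabu list
#'
#' Greedy hill climbing over single-arc moves (add, delete, reverse) on the
#' BIC score, with a tabu list of the last `tabu_len` visited structures
#' and the standard allowance of non-improving moves, so the search can
#' step off score plateaus and shallow local maxima.  The best structure
#' encountered is returned.  The search is deterministic given the data
#' and configuration (ties between moves are broken lexically); `seed` is
#' accepted for interface symmetry with the stochastic stages.
#'
#' Internally parent sets are bitmasks and local scores are cached per
#' (node, parent-set), so repeated delta evaluations cost a vector lookup;
#' the node set is capped at 25 for that reason (the selection stages
#' upstream keep networks far smaller).
#'
#' @param data Data frame of categorical columns.
#' @param features Node set of the search (default: all columns).
#' @param tabu_len Length of the tabu list and the number of consecutive
#'   non-improving moves tolerated before stopping (default 10).
#' @param max_iter Maximum number of moves (default 1000).
#' @param max_parents Per-node in-degree cap (default 4); keeps CPTs
#'   estimable at small n.
#' @param blacklist,whitelist Optional `(from, to)` tibbles of forbidden /
#'   required arcs.
#' @param seed Unused (the search has no random component); kept so all
#'   learning stages share one signature.
#' @return An [dag()].
#' @export
tabu_search <- function(data, features = NULL, tabu_len = 10L, max_iter = 1000L,
                        max_parents = 4L, blacklist = NULL, whitelist = NULL,
                        seed = NULL) {
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data, features)
  features <- as.character(features %||% coded$vars)
  stopifnot(all(features %in% coded$vars))
  k <- length(features)
  if (k > 25L) abort_ekbn("tabu search is limited to 25 nodes")
  # order features lexically so tie-breaks are name-order, not input-order
  features <- sort(features)
  bit <- bitwShiftL(1L, seq_len(k) - 1L)

  arc_mask <- function(arcs) {
    m <- matrix(FALSE, k, k, dimnames = list(features, features))
    if (!is.null(arcs) && NROW(arcs) > 0L) {
      arcs <- tibble::as_tibble(arcs)
      if (!all(c(arcs$from, arcs$to) %in% features)) {
        abort_ekbn("blacklist/whitelist endpoints must be search nodes")
      }
      m[cbind(match(arcs$from, features), match(arcs$to, features))] <- TRUE
    }
    m
  }
  bl <- arc_mask(blacklist)
  wl <- arc_mask(whitelist)
  if (any(bl & wl)) abort_ekbn("whitelist conflicts with blacklist")

  # integer columns + level counts for the local score
  cols <- lapply(features, function(f) coded$m[, f])
  nlev <- vapply(features, function(f) coded$nlev[[f]], integer(1))
  n <- coded$n
  logn2 <- log(n) / 2
  score_cache <- lapply(seq_len(k), function(.) new.env(parent = emptyenv()))
  local_score <- function(v, mask) {
    mask_local_score(v, mask, cols, nlev, bit, logn2, score_cache)
  }

  pmask <- integer(k)  # parent bitmask per node
  if (any(wl)) {
    for (v in seq_len(k)) pmask[[v]] <- sum(bit[wl[, v]])
    if (!mask_acyclic(pmask, bit, k)) abort_ekbn("whitelist must be acyclic")
  }
  local <- vapply(seq_len(k), function(v) local_score(v, pmask[[v]]), numeric(1))
  npar <- vapply(seq_len(k), function(v) sum(bitwAnd(pmask[[v]], bit) > 0L),
                 integer(1))
  res <- tabu_loop(pmask, local, npar, k, bit, bl, wl, max_parents,
                   tabu_len, max_iter, cols, nlev, logn2, score_cache)
  best_mask <- res

  edges <- do.call(rbind, lapply(seq_len(k), function(v) {
    pars <- which(bitwAnd(best_mask[[v]], bit) > 0L)
    if (length(pars) == 0L) return(NULL)
    data.frame(from = features[pars], to = features[[v]])
  }))
  dag(features, edges)
}

# reachability matrix: reach[a, b] is TRUE iff a directed path a ~> b exists
mask_reach <- function(pmask, bit, k) {
  a <- matrix(FALSE, k, k)
  for (v in seq_len(k)) a[bitwAnd(pmask[[v]], bit) > 0L, v] <- TRUE
  r <- a
  repeat {
    r2 <- r | (r %*% r > 0)
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

mask_acyclic <- function(pmask, bit, k) {
  !any(diag(mask_reach(pmask, bit, k)))
}

mask_local_score <- function(v, mask, cols, nlev, bit, logn2, score_cache) {
  key <- as.character(mask)
  hit <- score_cache[[v]][[key]]
  if (!is.null(hit)) return(hit)
  pars <- which(bitwAnd(mask, bit) > 0L)
  r <- nlev[[v]]
  idx <- cols[[v]]
  q <- 1L
  for (p in pars) {
    idx <- idx + (r * q) * (cols[[p]] - 1L)
    q <- q * nlev[[p]]
  }
  counts <- matrix(tabulate(idx, nbins = r * q), nrow = r)
  ptot <- colSums(counts)
  nzc <- counts > 0
  ll <- sum(counts[nzc] * log(counts[nzc] / rep(ptot, each = r)[nzc]))
  val <- ll - logn2 * (r - 1) * q
  score_cache[[v]][[key]] <- val
  val
}

# the hill-climbing loop proper; returns the best parent-mask vector
tabu_loop <- function(pmask, local, npar, k, bit, bl, wl, max_parents,
                      tabu_len, max_iter, cols, nlev, logn2, score_cache) {
  best_mask <- pmask
  best_score <- sum(local)
  tabu <- character(max(1L, tabu_len))
  tabu[1L] <- paste(pmask, collapse = ",")
  tpos <- 1L
  stall <- 0L
  iter <- 0L
  cap <- 3L * k * k
  while (iter < max_iter && stall <= tabu_len) {
    iter <- iter + 1L
    reach <- mask_reach(pmask, bit, k)
    mv_u <- integer(cap); mv_v <- integer(cap); mv_t <- integer(cap)
    mv_d <- numeric(cap)
    nmv <- 0L
    for (v in seq_len(k)) {
      pv <- pmask[[v]]
      lv <- local[[v]]
      for (u in seq_len(k)) {
        if (u == v) next
        if (bitwAnd(pv, bit[[u]]) == 0L) {
          if (bl[u, v] || npar[[v]] >= max_parents || reach[v, u]) next
          nmv <- nmv + 1L
          mv_u[[nmv]] <- u; mv_v[[nmv]] <- v; mv_t[[nmv]] <- 1L
          mv_d[[nmv]] <- mask_local_score(v, pv + bit[[u]], cols, nlev, bit,
                                          logn2, score_cache) - lv
        } else {
          if (wl[u, v]) next
          d_del <- mask_local_score(v, pv - bit[[u]], cols, nlev, bit,
                                    logn2, score_cache) - lv
          nmv <- nmv + 1L
          mv_u[[nmv]] <- u; mv_v[[nmv]] <- v; mv_t[[nmv]] <- 2L
          mv_d[[nmv]] <- d_del
          if (!bl[v, u] && npar[[u]] < max_parents) {
            # in a DAG no u ~> v path can reuse the arc u -> v, so the
            # reversal is admissible iff no other child of u reaches v
            other_ch <- which(bitwAnd(pmask, bit[[u]]) > 0L)
            other_ch <- other_ch[other_ch != v]
            if (length(other_ch) == 0L || !any(reach[other_ch, v])) {
              nmv <- nmv + 1L
              mv_u[[nmv]] <- u; mv_v[[nmv]] <- v; mv_t[[nmv]] <- 3L
              mv_d[[nmv]] <- d_del +
                mask_local_score(u, pmask[[u]] + bit[[v]], cols, nlev, bit,
                                 logn2, score_cache) - local[[u]]
            }
          }
        }
      }
    }
    if (nmv == 0L) break
    ord <- order(-mv_d[seq_len(nmv)], mv_u[seq_len(nmv)], mv_v[seq_len(nmv)],
                 mv_t[seq_len(nmv)])
    taken <- FALSE
    for (i in ord) {
      u <- mv_u[[i]]; v <- mv_v[[i]]
      nm <- pmask
      if (mv_t[[i]] == 1L) nm[[v]] <- nm[[v]] + bit[[u]]
      else if (mv_t[[i]] == 2L) nm[[v]] <- nm[[v]] - bit[[u]]
      else { nm[[v]] <- nm[[v]] - bit[[u]]; nm[[u]] <- nm[[u]] + bit[[v]] }
      if (paste(nm, collapse = ",") %in% tabu) next
      pmask <- nm
      local[[v]] <- mask_local_score(v, pmask[[v]], cols, nlev, bit, logn2,
                                     score_cache)
      if (mv_t[[i]] == 3L) {
        local[[u]] <- mask_local_score(u, pmask[[u]], cols, nlev, bit, logn2,
                                       score_cache)
      }
      npar[[v]] <- sum(bitwAnd(pmask[[v]], bit) > 0L)
      npar[[u]] <- sum(bitwAnd(pmask[[u]], bit) > 0L)
      taken <- TRUE
      break
    }
    if (!taken) break
    tpos <- tpos %% max(1L, tabu_len) + 1L
    tabu[tpos] <- paste(pmask, collapse = ",")
    sc <- sum(local)
    if (sc > best_score + 1e-9) {
      best_score <- sc
      best_mask <- pmask
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  best_mask
}
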