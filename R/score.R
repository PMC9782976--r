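#' BIC network score for discrete data
#'
#' Decomposable log-likelihood score with the Bayesian information
#' criterion penalty: for each node, the multinomial log-likelihood of the
#' node given its parents minus `log(n)/2` times the number of free
#' parameters `(|node| - 1) * prod(|parents|)`.  The total is the sum of
#' the per-node local scores, which is what makes single-arc move deltas
#' cheap inside the tabu search.
#'
#' @param data Data frame of categorical columns.
#' @param g An [dag()] over a subset of the columns.
#' @param by_node Return the per-node local scores instead of the total.
#' @return The score (a single number), or a named numeric vector.
#' @export
bic_score <- function(data, g, by_node = FALSE) {
  stopifnot(inherits(g, "ekbn_dag"))
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data, g$nodes)
  if (!all(g$nodes %in% coded$vars)) abort_ekbn("all dag nodes must be columns of data")
  pl <- parent_list(g)
  local <- vapply(g$nodes, function(nd) local_bic(coded, nd, pl[[nd]]), numeric(1))
  if (by_node) local else sum(local)
}

local_bic <- function(coded, node, parents, cache = NULL) {
  if (!is.null(cache)) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  r <- coded$nlev[[node]]
  pi_ <- joint_index(coded, parents)
  q <- pi_$size
  idx <- coded$m[, node] + r * (pi_$idx - 1L)
  counts <- matrix(tabulate(idx, nbins = r * q), nrow = r)
  ptot <- colSums(counts)
  nzc <- counts > 0
  ll <- sum(counts[nzc] * log(counts[nzc] / rep(ptot, each = r)[nzc]))
  val <- ll - log(coded$n) / 2 * (r - 1) * q
  if (!is.null(cache)) cache[[key]] <- val
  val
}
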