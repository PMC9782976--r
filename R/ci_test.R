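#' G-squared conditional-independence test
#'
#' Likelihood-ratio test of X independent of Y given a (possibly empty)
#' conditioning set Z on categorical data, the workhorse behind the Markov
#' blanket search and an ingredient of network-score diagnostics.  Degrees
#' of freedom are `(|X|-1)(|Y|-1) * prod(|z|)`.  When the average count per
#' contingency cell falls below `min_avg_cell` the test is flagged
#' `effective = FALSE`; callers (the blanket search in particular) treat
#' such tests as non-rejections, the conservative small-sample convention.
#'
#' @param data Data frame of categorical columns (or an internal coded
#'   object).
#' @param x,y Column names of the two variables under test.
#' @param z Character vector of conditioning column names (default none).
#' @param min_avg_cell Minimum average cell count for the test to be
#'   considered effective (default 5).
#' @return A one-row tibble: `statistic`, `dof`, `p_value`, `effective`.
#' @export
ci_test <- function(data, x, y, z = character(0), min_avg_cell = 5) {
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data)
  if (x == y) abort_ekbn("x and y must differ")
  if (x %in% z || y %in% z) abort_ekbn("x and y must not appear in z")
  res <- ci_test_coded(coded, x, y, z, min_avg_cell)
  tibble::tibble(statistic = res$statistic, dof = res$dof,
                 p_value = res$p_value, effective = res$effective)
}

# fast path used by the search loops; returns a plain list
ci_test_coded <- function(coded, x, y, z = character(0), min_avg_cell = 5) {
  nx <- coded$nlev[[x]]
  ny <- coded$nlev[[y]]
  zi <- joint_index(coded, z)
  nz <- zi$size
  n <- coded$n
  idx <- coded$m[, x] + nx * (coded$m[, y] - 1L) + (nx * ny) * (zi$idx - 1L)
  counts <- tabulate(idx, nbins = nx * ny * nz)
  o <- array(counts, dim = c(nx, ny, nz))
  g2 <- 0
  for (k in seq_len(nz)) {
    ok <- o[, , k, drop = TRUE]
    dim(ok) <- c(nx, ny)
    tot <- sum(ok)
    if (tot == 0) next
    e <- outer(rowSums(ok), colSums(ok)) / tot
    nzc <- ok > 0
    g2 <- g2 + 2 * sum(ok[nzc] * log(ok[nzc] / e[nzc]))
  }
  dof <- max(1L, (nx - 1L) * (ny - 1L) * nz)
  list(
    statistic = g2,
    dof = dof,
    p_value = stats::pchisq(g2, df = dof, lower.tail = FALSE),
    effective = (n / (nx * ny * nz)) >= min_avg_cell
  )
}
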