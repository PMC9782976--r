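#' Bootstrap arc strengths by model averaging
#'
#' Learns a network on each of `R` nonparametric bootstrap resamples of the
#' rows (via [tabu_search()]) and summarizes, for every ordered node pair,
#' the fraction of bootstrap networks containing the arc in either
#' direction (`strength`) and, among those, the fraction oriented this way
#' (`direction`).  `strength` is symmetric in the pair and
#' `direction(u,v) + direction(v,u) = 1` whenever `strength > 0`.
#'
#' @inheritParams tabu_search
#' @param R Number of bootstrap replicates (>= 1).
#' @param seed Integer seed controlling the resamples; results are fully
#'   reproducible given `(data, R, seed, ...)`.
#' @param ... Passed on to [tabu_search()].
#' @return An `ekbn_strength` tibble: `from`, `to`, `strength`,
#'   `direction`, one row per ordered pair that ever appeared; carries `R`
#'   and the node set as attributes.
#' @export
bootstrap_arc_strength <- function(data, features = NULL, R = 200L, seed = 1L,
                                   ...) {
  if (R < 1L) abort_ekbn("R must be >= 1")
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data, features)
  features <- features %||% coded$vars
  p <- length(features)
  dir_counts <- matrix(0L, p, p, dimnames = list(features, features))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(R)) {
      rows <- sample.int(coded$n, coded$n, replace = TRUE)
      boot <- coded
      boot$m <- coded$m[rows, , drop = FALSE]
      g <- tabu_search(boot, features = features, ...)
      if (nrow(g$edges) > 0) {
        ij <- cbind(match(g$edges$from, features), match(g$edges$to, features))
        dir_counts[ij] <- dir_counts[ij] + 1L
      }
    }
  })
  either <- dir_counts + t(dir_counts)
  keep <- which(either > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    from = features[keep[, 1L]],
    to = features[keep[, 2L]],
    strength = either[keep] / R,
    direction = dir_counts[keep] / either[keep]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$strength), .data$from, .data$to)
  structure(out, class = c("ekbn_strength", class(out)),
            R = as.integer(R), nodes = features)
}

#' Model-averaged network from bootstrap arc strengths
#'
#' Keeps the arcs whose strength reaches `threshold`, orienting each by its
#' majority bootstrap direction (exact ties go to the lexically smaller
#' `from` endpoint).  Because per-arc majority orientation can combine into
#' a directed cycle, any cycle in the result is broken by removing its
#' weakest arc (smallest strength, then lexical), with a warning naming the
#' removed arcs; the returned graph is always acyclic.  Raising the
#' threshold can only remove arcs, never add them.
#'
#' @param strengths An [bootstrap_arc_strength()] table.
#' @param threshold Minimum strength in (0, 1] for an arc to be kept
#'   (default 0.5).
#' @return An [dag()] over the node set of `strengths`.
#' @export
averaged_network <- function(strengths, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort_ekbn("threshold must lie in (0, 1]")
  }
  nodes <- attr(strengths, "nodes")
  st <- tibble::as_tibble(strengths)
  # one row per unordered pair, majority orientation
  st <- st[st$from < st$to, , drop = FALSE]
  st <- st[st$strength >= threshold, , drop = FALSE]
  if (nrow(st) > 0) {
    flip <- st$direction < 0.5
    tmp <- st$from[flip]
    st$from[flip] <- st$to[flip]
    st$to[flip] <- tmp
  }
  st <- dplyr::arrange(st, .data$from, .data$to)
  # break any cycles introduced by averaging: drop weakest arc per cycle
  removed <- character(0)
  repeat {
    pl <- edges_to_pl(nodes, st)
    cyc <- find_cycle(pl)
    if (is.null(cyc)) break
    on_cycle <- paste(st$from, st$to) %in% paste(cyc$from, cyc$to)
    cand <- st[on_cycle, , drop = FALSE]
    cand <- dplyr::arrange(cand, .data$strength, .data$from, .data$to)
    worst <- paste(cand$from[[1L]], cand$to[[1L]])
    removed <- c(removed, sub(" ", " -> ", worst))
    st <- st[paste(st$from, st$to) != worst, , drop = FALSE]
  }
  if (length(removed) > 0) {
    warn_ekbn(paste0("cycle(s) broken by removing arc(s): ",
                     paste(removed, collapse = "; ")))
  }
  dag(nodes, st[, c("from", "to")])
}

edges_to_pl <- function(nodes, edges) {
  pl <- stats::setNames(lapply(nodes, function(.) character(0)), nodes)
  for (i in seq_len(NROW(edges))) {
    pl[[edges$to[[i]]]] <- c(pl[[edges$to[[i]]]], edges$from[[i]])
  }
  pl
}

# return the edges of one directed cycle as a tibble, or NULL if acyclic
find_cycle <- function(pl) {
  nodes <- names(pl)
  ch <- children_list(pl)
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  parent_edge <- list()
  cycle <- NULL
  visit <- function(v, path) {
    if (!is.null(cycle)) return()
    color[[v]] <<- 1L
    for (w in ch[[v]]) {
      if (!is.null(cycle)) return()
      if (color[[w]] == 1L) {
        # back edge v -> w closes the cycle w ... v
        cyc <- path[match(w, path):length(path)]
        cycle <<- tibble::tibble(
          from = c(cyc[-length(cyc)], cyc[[length(cyc)]]),
          to = c(cyc[-1L], w)
        )
      } else if (color[[w]] == 0L) {
        visit(w, c(path, w))
      }
    }
    color[[v]] <<- 2L
  }
  for (v in nodes) if (color[[v]] == 0L) visit(v, v)
  cycle
}
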