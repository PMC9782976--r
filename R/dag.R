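#' Directed acyclic graphs over cohort features
#'
#' Lightweight DAG container used by the structure-learning and inference
#' layers: a node set plus an edge tibble `(from, to)`.  Construction
#' validates acyclicity, rejects self-loops and duplicate edges.
#'
#' @param nodes Character vector of node names.
#' @param edges Tibble/data frame with columns `from`, `to` (may be empty).
#' @return An `ekbn_dag`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort_ekbn("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  } else {
    edges <- tibble::as_tibble(edges)[, c("from", "to")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    abort_ekbn("edge endpoints must be nodes")
  }
  if (any(edges$from == edges$to)) abort_ekbn("self-loops are not allowed")
  if (anyDuplicated(paste(edges$from, edges$to))) abort_ekbn("duplicate edges")
  g <- structure(list(nodes = nodes, edges = edges), class = "ekbn_dag")
  if (!is_acyclic(g)) abort_ekbn("graph is cyclic")
  g
}

#' @export
print.ekbn_dag <- function(x, ...) {
  cat(sprintf("<ekbn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @rdname dag
#' @param g An `ekbn_dag` (or a parent list as used internally).
#' @export
is_acyclic <- function(g) {
  pl <- if (inherits(g, "ekbn_dag")) parent_list(g) else g
  is.integer(topo_order_pl(pl))
}

# parent list representation: named list, node -> character vector of parents
parent_list <- function(g) {
  pl <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (nd in g$nodes) pl[[nd]] <- character(0)
  if (nrow(g$edges) > 0) {
    sp <- split(g$edges$from, g$edges$to)
    for (nd in names(sp)) pl[[nd]] <- sp[[nd]]
  }
  pl
}

pl_to_dag <- function(pl) {
  edges <- tibble::tibble(
    from = unlist(pl, use.names = FALSE),
    to = rep(names(pl), lengths(pl))
  )
  if (nrow(edges) > 0) edges <- dplyr::arrange(edges, .data$from, .data$to)
  dag(names(pl), edges)
}

# Kahn topological order on a parent list; FALSE if cyclic
topo_order_pl <- function(pl) {
  nodes <- names(pl)
  indeg <- lengths(pl)
  order <- integer(0)
  avail <- nodes[indeg == 0L]
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) for (p in pl[[nd]]) children[[p]] <- c(children[[p]], nd)
  while (length(avail) > 0) {
    v <- avail[[1L]]
    avail <- avail[-1L]
    order <- c(order, match(v, nodes))
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order) == length(nodes)) as.integer(order) else FALSE
}

# is there a directed path from `a` to `b`?  (used for cycle prevention)
has_path_pl <- function(children, a, b) {
  seen <- character(0)
  stack <- a
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == b) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  FALSE
}

children_list <- function(pl) {
  ch <- stats::setNames(vector("list", length(pl)), names(pl))
  for (nd in names(pl)) ch[[nd]] <- character(0)
  for (nd in names(pl)) for (p in pl[[nd]]) ch[[p]] <- c(ch[[p]], nd)
  ch
}

# nodes in the same connected component (ignoring direction) as `node`
connected_component <- function(g, node) {
  nb <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    f <- g$edges$from[[i]]; t <- g$edges$to[[i]]
    nb[[f]] <- c(nb[[f]], t); nb[[t]] <- c(nb[[t]], f)
  }
  seen <- character(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, nb[[v]])
  }
  sort(seen)
}
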