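#' Export a network to Graphviz DOT
#'
#' @param x An [dag()] or fitted `ekbn_bn`.
#' @param path Output file.
#' @param highlight Node names drawn filled (e.g. the outcome).
#' @return The path, invisibly.
#' @export
write_dot <- function(x, path, highlight = character(0)) {
  g <- if (inherits(x, "ekbn_bn")) x$dag else x
  stopifnot(inherits(g, "ekbn_dag"))
  lines <- c(
    "digraph bn {",
    "  node [shape=ellipse, fontname=\"Helvetica\"];",
    vapply(g$nodes, function(nd) {
      style <- if (nd %in% highlight) " [style=filled, fillcolor=\"#fee0b6\"]" else ""
      sprintf("  \"%s\"%s;", nd, style)
    }, character(1)),
    if (nrow(g$edges) > 0) {
      sprintf("  \"%s\" -> \"%s\";", g$edges$from, g$edges$to)
    },
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export a fitted network to XMLBIF
#'
#' Writes the DAG and its conditional probability tables in the XMLBIF
#' 0.3 interchange format readable by standard Bayesian-network tools.
#'
#' @param bn A [fit_cpts()] network.
#' @param path Output file.
#' @param name Network name attribute.
#' @return The path, invisibly.
#' @export
write_xmlbif <- function(bn, path, name = "ekbn") {
  stopifnot(inherits(bn, "ekbn_bn"))
  pl <- parent_list(bn$dag)
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  var_blocks <- vapply(bn$dag$nodes, function(nd) {
    paste0(
      "  <VARIABLE TYPE=\"nature\">\n",
      "    <NAME>", esc(nd), "</NAME>\n",
      paste0("    <OUTCOME>", esc(bn$levels[[nd]]), "</OUTCOME>\n", collapse = ""),
      "  </VARIABLE>"
    )
  }, character(1))
  def_blocks <- vapply(bn$dag$nodes, function(nd) {
    tab <- bn$cpts[[nd]]
    parents <- pl[[nd]]
    # XMLBIF lists probabilities with the node's levels varying fastest
    perm <- aperm(tab, c(length(dim(tab)):1))
    paste0(
      "  <DEFINITION>\n",
      "    <FOR>", esc(nd), "</FOR>\n",
      paste0(vapply(parents, function(p) paste0("    <GIVEN>", esc(p), "</GIVEN>\n"),
                    character(1)), collapse = ""),
      "    <TABLE>", paste(format(as.numeric(perm), digits = 12, trim = TRUE),
                           collapse = " "), "</TABLE>\n",
      "  </DEFINITION>"
    )
  }, character(1))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<BIF VERSION=\"0.3\">",
    "<NETWORK>",
    paste0("  <NAME>", esc(name), "</NAME>"),
    var_blocks,
    def_blocks,
    "</NETWORK>",
    "</BIF>"
  ), path)
  invisible(path)
}

#' Serialize rankings and arc strengths to CSV
#'
#' @param x An `ekbn_ranking`, `ekbn_integrated` or `ekbn_strength`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_ranking_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
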