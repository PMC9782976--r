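#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style summaries: `tidy()` returns the per-element detail of a
#' result (per-feature ranks, per-arc strengths, per-step trace, per-unit
#' scores), `glance()` a one-row model summary.
#'
#' @param x A fitted ekbn object.
#' @param ... Unused.
#' @return A tibble.
#' @name ekbn-tidiers
NULL

#' @rdname ekbn-tidiers
#' @method tidy ekbn_ranking
#' @export
tidy.ekbn_ranking <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(model_id = attr(x, "model_id"), auc = attr(x, "auc"))
}

#' @rdname ekbn-tidiers
#' @method tidy ekbn_integrated
#' @export
tidy.ekbn_integrated <- function(x, ...) tibble::as_tibble(x)

#' @rdname ekbn-tidiers
#' @method tidy ekbn_mb
#' @export
tidy.ekbn_mb <- function(x, ...) x$trail

#' @rdname ekbn-tidiers
#' @method tidy ekbn_dag
#' @export
tidy.ekbn_dag <- function(x, ...) tibble::as_tibble(x$edges)

#' @rdname ekbn-tidiers
#' @method tidy ekbn_bn
#' @export
tidy.ekbn_bn <- function(x, ...) {
  e <- tibble::as_tibble(x$dag$edges)
  if (!is.null(x$strengths)) {
    st <- tibble::as_tibble(x$strengths)
    e <- dplyr::left_join(e, st, by = c("from", "to"))
  }
  e
}

#' @rdname ekbn-tidiers
#' @method tidy ekbn_eval
#' @export
tidy.ekbn_eval <- function(x, ...) {
  tibble::tibble(unit_id = x$unit_id %||% as.character(seq_along(x$scores)),
                 score = x$scores, label = x$labels)
}

#' @rdname ekbn-tidiers
#' @method glance ekbn_eval
#' @export
glance.ekbn_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lo = x$ci[[1]], ci_hi = x$ci[[2]],
                 n = length(x$labels), n_event = sum(x$labels == 1L),
                 folds = x$config$folds %||% NA_integer_,
                 repeats = x$config$repeats %||% NA_integer_)
}

#' @rdname ekbn-tidiers
#' @method tidy ekbn_hitl
#' @export
tidy.ekbn_hitl <- function(x, ...) {
  dplyr::mutate(x$trace,
                n_s = lengths(.data$s), n_s_star = lengths(.data$s_star),
                n_selected = lengths(.data$selected))
}

#' @rdname ekbn-tidiers
#' @method glance ekbn_hitl
#' @export
glance.ekbn_hitl <- function(x, ...) {
  tibble::tibble(
    auc = x$state$eval$auc, ci_lo = x$state$eval$ci[[1]],
    ci_hi = x$state$eval$ci[[2]],
    n_selected = length(x$state$selected),
    n_steps = nrow(x$trace), n_accepted = sum(x$trace$accepted),
    stopped = x$stopped
  )
}

#' @rdname ekbn-tidiers
#' @method glance ekbn_pdbn
#' @export
glance.ekbn_pdbn <- function(x, ...) {
  tibble::tibble(
    auc = x$eval$auc, ci_lo = x$eval$ci[[1]], ci_hi = x$eval$ci[[2]],
    n_selected = length(x$mb$members),
    n_arcs = nrow(x$bn$dag$edges)
  )
}
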