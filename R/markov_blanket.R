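#' Markov blanket discovery (Inter-IAMB)
#'
#' Incremental-association Markov blanket search with interleaved shrinking:
#' the grow phase adds, among the remaining candidates, the variable with
#' the smallest conditional-independence p-value against the target given
#' the current blanket (provided p < `alpha`); after every addition the
#' shrink phase removes any member that has become independent of the
#' target given the rest of the blanket.  The search terminates when no
#' addition is possible.  Every decision — additions, removals, and skipped
#' candidates — is recorded in an audit trail, which is the explainability
#' deliverable of the selection step.
#'
#' Ineffective tests (average contingency cell count below `min_avg_cell`,
#' see [ci_test()]) are treated as non-rejections, which guards against
#' spurious additions in small cohorts.  No multiple-testing correction is
#' applied inside the search, matching the classical algorithm.  With
#' `interleaved = FALSE` the shrink phase runs only once, after growth
#' stops (plain IAMB).
#'
#' @param data Data frame of categorical columns.
#' @param target Target variable name.
#' @param candidates Candidate feature names (default: all other columns).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param interleaved Shrink after every addition (default) or only at the
#'   end.
#' @param min_avg_cell Small-sample guard passed to the CI test.
#' @return An `ekbn_mb` object: `target`, `members` (character vector) and
#'   `trail`, a tibble of `(step, action, variable, conditioning, p_value,
#'   effective)`.
#' @export
markov_blanket <- function(data, target, candidates = NULL, alpha = 0.05,
                           interleaved = TRUE, min_avg_cell = 5) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_ekbn("alpha must lie in (0, 1)")
  }
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data)
  if (coded$n == 0L) abort_ekbn("empty data")
  if (!target %in% coded$vars) abort_ekbn(paste0("target '", target, "' not in data"))
  candidates <- sort(candidates %||% setdiff(coded$vars, target))
  if (!all(candidates %in% coded$vars)) abort_ekbn("candidates must be columns of data")
  candidates <- setdiff(candidates, target)

  blanket <- character(0)
  trail <- list()
  log_row <- function(action, var, cond, p, eff) {
    trail[[length(trail) + 1L]] <<- tibble::tibble(
      action = action, variable = var,
      conditioning = paste(cond, collapse = ","),
      p_value = p, effective = eff
    )
  }
  shrink <- function() {
    repeat {
      removed <- FALSE
      for (m in blanket) {
        cond <- setdiff(blanket, m)
        tt <- ci_test_coded(coded, target, m, cond, min_avg_cell)
        if (!tt$effective || tt$p_value >= alpha) {
          log_row("remove", m, cond, tt$p_value, tt$effective)
          blanket <<- cond
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
  }

  repeat {
    rest <- setdiff(candidates, blanket)
    if (length(rest) == 0L) break
    pvals <- vapply(rest, function(v) {
      tt <- ci_test_coded(coded, target, v, blanket, min_avg_cell)
      if (tt$effective) tt$p_value else 1
    }, numeric(1))
    best <- rest[which.min(pvals)]   # ties: first in sorted candidate order
    if (pvals[[best]] < alpha) {
      log_row("add", best, blanket, pvals[[best]], TRUE)
      blanket <- sort(c(blanket, best))
      if (interleaved) shrink()
    } else {
      log_row("stop", best, blanket, pvals[[best]], TRUE)
      break
    }
  }
  if (!interleaved) shrink()

  structure(
    list(target = target, members = blanket,
         trail = if (length(trail)) dplyr::bind_rows(trail, .id = "step") else
           tibble::tibble(step = character(), action = character(),
                          variable = character(), conditioning = character(),
                          p_value = numeric(), effective = logical()),
         alpha = alpha),
    class = "ekbn_mb"
  )
}

#' @export
print.ekbn_mb <- function(x, ...) {
  cat(sprintf("<ekbn_mb> MB(%s) = {%s} (alpha = %g, %d decisions)\n",
              x$target, paste(x$members, collapse = ", "), x$alpha,
              nrow(x$trail)))
  invisible(x)
}

#' Exhaustive Markov blanket search (test oracle)
#'
#' Finds the smallest candidate subset S such that the target is accepted
#' as independent of every variable outside S given S, by exhaustive
#' enumeration of conditioning subsets (smallest first, lexical tie-break).
#' Exponential in the number of candidates — limited to 8 — and intended
#' purely as an independent check on [markov_blanket()].
#'
#' @inheritParams markov_blanket
#' @return An `ekbn_mb` object (with an empty trail).
#' @export
brute_force_mb <- function(data, target, candidates = NULL, alpha = 0.05,
                           min_avg_cell = 5) {
  coded <- if (inherits(data, "ekbn_coded")) data else code_data(data)
  candidates <- sort(candidates %||% setdiff(coded$vars, target))
  candidates <- setdiff(candidates, target)
  if (length(candidates) > 8L) abort_ekbn("oracle limited to 8 features")
  indep_given <- function(v, s) {
    tt <- ci_test_coded(coded, target, v, s, min_avg_cell)
    !tt$effective || tt$p_value >= alpha
  }
  sizes <- seq(0L, length(candidates))
  for (k in sizes) {
    subsets <- if (k == 0L) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    for (s in subsets) {
      outside <- setdiff(candidates, s)
      if (all(vapply(outside, indep_given, logical(1), s = s))) {
        return(structure(
          list(target = target, members = sort(s),
               trail = tibble::tibble(step = character(), action = character(),
                                      variable = character(),
                                      conditioning = character(),
                                      p_value = numeric(), effective = logical()),
               alpha = alpha),
          class = "ekbn_mb"
        ))
      }
    }
  }
  structure(list(target = target, members = candidates,
                 trail = tibble::tibble(), alpha = alpha), class = "ekbn_mb")
}
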