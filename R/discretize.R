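#' Discretization specification
#'
#' Controls how continuous feature columns are binned before the discrete
#' conditional-independence tests and CPT fits.  Default: 3 quantile bins
#' (2 when a column has fewer than 5 distinct values) — at cohort sizes
#' around n = 100 this keeps contingency cells adequately populated.
#'
#' @param method `"quantile"` (equal-frequency), `"fixed"` (equal-width) or
#'   `"cuts"` (use `cuts` verbatim).
#' @param bins Number of bins (>= 2).
#' @param cuts Named list of numeric cut points for `method = "cuts"` or
#'   per-feature overrides.
#' @return A `discretization_spec` list.
#' @export
discretization_spec <- function(method = c("quantile", "fixed", "cuts"),
                                bins = 3L, cuts = list()) {
  method <- match.arg(method)
  bins <- as.integer(bins)
  if (bins < 2L) abort_ekbn("bins must be >= 2")
  for (nm in names(cuts)) {
    if (is.unsorted(cuts[[nm]], strictly = TRUE)) {
      abort_ekbn(paste0("cut points for '", nm, "' must be strictly increasing"))
    }
  }
  structure(list(method = method, bins = bins, cuts = cuts),
            class = "discretization_spec")
}

#' Discretize continuous features of a cohort
#'
#' Maps every continuous column to ordered categories (`"b1" < "b2" < ...`).
#' Categorical (factor/character/logical) columns pass through unchanged, so
#' the operation is idempotent on already-discrete tables.  The mapping is
#' deterministic given the data and the spec.  Columns whose quantile cuts
#' collapse because of ties fall back to fewer bins with a warning; a column
#' that collapses to a single category — and any constant categorical
#' column — is dropped with a warning.  Missing feature cells are imputed by
#' the column mode after binning.
#'
#' @param cohort An [as_cohort()] object (or plain data frame).
#' @param spec A [discretization_spec()].
#' @return The cohort with all feature columns as factors.
#' @export
discretize <- function(cohort, spec = discretization_spec()) {
  stopifnot(inherits(spec, "discretization_spec"))
  is_cohort <- inherits(cohort, "ekbn_cohort")
  feats <- if (is_cohort) cohort_features(cohort) else names(cohort)
  out <- cohort
  dropped <- character(0)
  for (f in feats) {
    x <- out[[f]]
    if (is.numeric(x)) {
      out[[f]] <- bin_numeric(x, f, spec)
    } else {
      out[[f]] <- factor(as.character(x))
    }
    if (is.null(out[[f]]) || nlevels(droplevels(out[[f]][!is.na(out[[f]])])) < 2L) {
      dropped <- c(dropped, f)
      next
    }
    if (anyNA(out[[f]])) {
      out[[f]][is.na(out[[f]])] <- stat_mode(out[[f]][!is.na(out[[f]])])
    }
    out[[f]] <- droplevels(out[[f]])
  }
  if (length(dropped) > 0) {
    warn_ekbn(paste0("dropping constant/degenerate feature(s): ",
                     paste(dropped, collapse = ", ")))
    keep <- setdiff(feats, dropped)
    out <- if (is_cohort) cohort_keep_features(out, keep) else out[keep]
  }
  out
}

bin_numeric <- function(x, name, spec) {
  nd <- length(unique(x[!is.na(x)]))
  if (nd < 2L) return(NULL)
  bins <- if (nd < 5L) min(2L, nd) else spec$bins
  cuts <- spec$cuts[[name]]
  if (is.null(cuts)) {
    if (spec$method == "cuts") {
      abort_ekbn(paste0("method 'cuts' but no cut points supplied for '", name, "'"))
    }
    cuts <- if (spec$method == "quantile") {
      unique(stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                             na.rm = TRUE, names = FALSE, type = 7))
    } else {
      r <- range(x, na.rm = TRUE)
      seq(r[1], r[2], length.out = bins + 1L)[-c(1L, bins + 1L)]
    }
    cuts <- cuts[is.finite(cuts)]
    if (length(cuts) < bins - 1L && length(cuts) >= 1L) {
      warn_ekbn(paste0("quantile cuts collapsed for '", name, "', using ",
                       length(cuts) + 1L, " bin(s)"))
    }
    if (length(cuts) == 0L) return(NULL)
  }
  b <- findInterval(x, vec = cuts, left.open = TRUE) + 1L
  factor(paste0("b", b), levels = paste0("b", seq_len(length(cuts) + 1L)))
}
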