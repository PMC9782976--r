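#' Human-readable report of a model-building run
#'
#' Writes a markdown report: the integrated ranking table with EKF-flagged
#' features highlighted in bold (and the finally selected features in
#' italics), the step-by-step trace with accept/reject decisions, the
#' final network arcs, the cross-validated AUC with its confidence
#' interval, and — when a baseline is supplied — the paired DeLong
#' comparison.  Companion artifacts (network DOT file, ROC coordinates,
#' evaluation JSON) are written next to it.
#'
#' @param fit An [hitl_bn_run()] result.
#' @param out_dir Output directory (created if needed).
#' @param cohort The cohort the run was fitted on (for EKF flags).
#' @param baseline Optional [pd_bn_fit()] on the same cohort for a DeLong
#'   comparison.
#' @return Path of the markdown report, invisibly.
#' @export
report <- function(fit, out_dir, cohort, baseline = NULL) {
  stopifnot(inherits(fit, "ekbn_hitl"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- file.path(out_dir, "report.md")
  rk <- tibble::as_tibble(fit$ranking)
  ekfs <- cohort_ekfs(cohort)
  sel <- fit$state$selected
  mark <- function(f) {
    out <- f
    out <- ifelse(f %in% sel, paste0("*", out, "*"), out)
    ifelse(f %in% ekfs, paste0("**", out, "**"), out)
  }
  lines <- c(
    "# Model-building report", "",
    sprintf("- Outcome: `%s`", fit$state$outcome),
    sprintf("- Selected features (%d): %s", length(sel),
            paste(mark(sel), collapse = ", ")),
    sprintf("- Cross-validated AUC: %.3f (95%% CI %.3f-%.3f)",
            fit$state$eval$auc, fit$state$eval$ci[[1]], fit$state$eval$ci[[2]]),
    sprintf("- Steps: %d evaluated, %d accepted; stopping reason: %s",
            nrow(fit$trace), sum(fit$trace$accepted), fit$stopped),
    if (nrow(fit$trace) == 0 || !any(fit$trace$accepted))
      "- No incremental step improved the model: initial model retained.",
    "", "## Integrated feature ranking", "",
    "| Rank | Feature | WRS |", "|---:|---|---:|",
    sprintf("| %d | %s | %.2f |", rk$rank, mark(rk$feature), rk$wrs),
    "", "## Incremental trace", ""
  )
  if (nrow(fit$trace) > 0) {
    tr <- tidy(fit)
    lines <- c(lines,
      "| i | EKF | |S| | |S*| | candidate AUC | incumbent AUC | accepted |",
      "|---:|---|---:|---:|---:|---:|---|",
      sprintf("| %d | %s | %d | %d | %.3f | %.3f | %s |",
              tr$i, tr$ekf, tr$n_s, tr$n_s_star, tr$candidate_auc,
              tr$incumbent_auc, ifelse(tr$accepted, "yes", "no")))
  } else {
    lines <- c(lines, "(no incremental steps were evaluated)")
  }
  if (!is.null(fit$bn)) {
    lines <- c(lines, "", "## Final network", "",
               if (nrow(fit$bn$dag$edges) > 0)
                 sprintf("- `%s -> %s`", fit$bn$dag$edges$from, fit$bn$dag$edges$to)
               else "(no arcs)")
    write_dot(fit$bn, file.path(out_dir, "network.dot"),
              highlight = fit$state$outcome)
    write_xmlbif(fit$bn, file.path(out_dir, "network.xmlbif"))
  }
  if (!is.null(baseline)) {
    dl <- delong_test(fit$state$eval, baseline$eval)
    lines <- c(lines, "", "## Comparison with the data-driven baseline", "",
      "| Model | AUC | 95% CI |", "|---|---:|---|",
      sprintf("| HITL-BN | %.3f | %.3f-%.3f |", fit$state$eval$auc,
              fit$state$eval$ci[[1]], fit$state$eval$ci[[2]]),
      sprintf("| PD-BN | %.3f | %.3f-%.3f |", baseline$eval$auc,
              baseline$eval$ci[[1]], baseline$eval$ci[[2]]),
      "",
      sprintf("DeLong test (paired): z = %.3f, p = %.4f.", dl$z, dl$p_value))
  }
  writeLines(lines[!vapply(lines, is.null, logical(1))], md)
  readr::write_csv(roc_points(fit$state$eval$scores, fit$state$eval$labels),
                   file.path(out_dir, "roc.csv"))
  jsonlite::write_json(
    list(auc = fit$state$eval$auc, ci = fit$state$eval$ci,
         scores = fit$state$eval$scores, labels = fit$state$eval$labels,
         seed = fit$config$seed),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(md)
}
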