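#' Cohort tables
#'
#' An `ekbn_cohort` is a tibble of analysis units (tumors or patients): one
#' `unit_id` column, one binary outcome column, and J feature columns of
#' mixed continuous/categorical type.  Per-feature metadata (expert-knowledge
#' flag, treatment phase, outcome applicability) travels alongside as the
#' `roles` attribute, and the internal event coding is recorded so reports
#' can translate back to the original labels.
#'
#' Internally the outcome is always a factor with levels `"0"` (non-event)
#' and `"1"` (event), the event being the *minority* class of the input
#' regardless of how it was labelled; the original label of each level is
#' kept in the `outcome_levels` attribute.
#'
#' @param data A data frame with one row per unit.
#' @param outcome Name of the binary outcome column.
#' @param roles Optional roles tibble with columns `feature`, `is_ekf`,
#'   `phase` (`"pre"` or `"during"`) and `outcomes` (list column of outcome
#'   names the feature applies to; `character(0)` = applies to all).
#'   Features without a row default to non-EKF / pre / all outcomes.
#' @param id_col Name of the unit-id column, or `NULL` to generate
#'   `u1, u2, ...`.
#' @return An `ekbn_cohort` tibble.
#' @export
as_cohort <- function(data, outcome, roles = NULL, id_col = NULL) {
  data <- tibble::as_tibble(data)
  if (!outcome %in% names(data)) {
    abort_ekbn(paste0("missing outcome column '", outcome, "'"))
  }
  if (is.null(id_col)) {
    data <- dplyr::mutate(data, unit_id = paste0("u", dplyr::row_number()),
                          .before = 1L)
  } else {
    if (!id_col %in% names(data)) abort_ekbn(paste0("missing id column '", id_col, "'"))
    data <- dplyr::rename(data, unit_id = dplyr::all_of(id_col)) |>
      dplyr::relocate("unit_id")
  }
  data$unit_id <- as.character(data$unit_id)
  dup <- data$unit_id[duplicated(data$unit_id)]
  if (length(dup) > 0) {
    abort_ekbn(paste0("duplicate unit id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(data[[outcome]])) {
    n_drop <- sum(is.na(data[[outcome]]))
    warn_ekbn(paste0("dropping ", n_drop, " row(s) with missing outcome"))
    data <- data[!is.na(data[[outcome]]), ]
  }
  y_raw <- as.character(data[[outcome]])
  lev <- sort(unique(y_raw))
  if (length(lev) != 2L) {
    abort_ekbn(paste0("outcome not binary: '", outcome, "' has ",
                      length(lev), " observed level(s)"))
  }
  # minority class is the event and is coded "1"
  counts <- table(factor(y_raw, levels = lev))
  event <- names(counts)[which.min(counts)]
  control <- setdiff(lev, event)
  data[[outcome]] <- factor(ifelse(y_raw == event, "1", "0"), levels = c("0", "1"))

  feats <- setdiff(names(data), c("unit_id", outcome))
  roles <- normalize_roles(roles, feats)

  structure(
    data,
    class = c("ekbn_cohort", class(tibble::tibble()))
  ) |>
    `attr<-`("outcome", outcome) |>
    `attr<-`("roles", roles) |>
    `attr<-`("outcome_levels", c(control = control, event = event))
}

normalize_roles <- function(roles, feats) {
  default <- tibble::tibble(
    feature = feats, is_ekf = FALSE, phase = "pre",
    outcomes = rep(list(character(0)), length(feats))
  )
  if (is.null(roles)) return(default)
  roles <- tibble::as_tibble(roles)
  stopifnot(all(c("feature", "is_ekf", "phase") %in% names(roles)))
  if (!"outcomes" %in% names(roles)) roles$outcomes <- list(character(0))
  if (!is.list(roles$outcomes)) roles$outcomes <- as.list(roles$outcomes)
  extra <- setdiff(feats, roles$feature)
  if (length(extra) > 0) {
    warn_ekbn(paste0("feature(s) missing from metadata, assigned non-EKF/pre: ",
                     paste(extra, collapse = ", ")))
  }
  roles <- dplyr::bind_rows(
    roles[roles$feature %in% feats, ],
    default[default$feature %in% extra, ]
  )
  roles <- roles[match(feats, roles$feature), ]
  if (!all(roles$phase %in% c("pre", "during"))) {
    abort_ekbn("roles$phase must be 'pre' or 'during'")
  }
  roles
}

#' @export
print.ekbn_cohort <- function(x, ...) {
  r <- cohort_roles(x)
  cat(sprintf("<ekbn_cohort> %d units, %d features (%d EKF), outcome '%s' (event = minority '%s')\n",
              nrow(x), nrow(r), sum(r$is_ekf), cohort_outcome(x),
              attr(x, "outcome_levels")[["event"]]))
  NextMethod()
}

#' Accessors for cohort metadata
#'
#' @param cohort An [as_cohort()] object.
#' @return `cohort_outcome()` the outcome column name; `cohort_roles()` the
#'   roles tibble; `cohort_features()` the feature names; `cohort_ekfs()`
#'   the expert-knowledge feature names.
#' @export
cohort_outcome <- function(cohort) attr(cohort, "outcome")

#' @rdname cohort_outcome
#' @export
cohort_roles <- function(cohort) attr(cohort, "roles")

#' @rdname cohort_outcome
#' @export
cohort_features <- function(cohort) cohort_roles(cohort)$feature

#' @rdname cohort_outcome
#' @export
cohort_ekfs <- function(cohort) {
  r <- cohort_roles(cohort)
  r$feature[r$is_ekf]
}

# rebuild a cohort after column subsetting, keeping metadata consistent
cohort_keep_features <- function(cohort, feats) {
  out <- cohort[, c("unit_id", cohort_outcome(cohort), feats)]
  roles <- cohort_roles(cohort)
  structure(out, class = class(cohort)) |>
    `attr<-`("outcome", cohort_outcome(cohort)) |>
    `attr<-`("roles", roles[match(feats, roles$feature), ]) |>
    `attr<-`("outcome_levels", attr(cohort, "outcome_levels"))
}

#' Restrict a cohort to the features applicable to an outcome and phase
#'
#' Pre-treatment views drop all during-treatment features (in clinical use,
#' the `D_`-prefixed change-during-treatment variables); during-treatment
#' views contain every pre-treatment feature plus the during-only ones, so
#' the during view is always a superset of the pre view.  Row count and the
#' outcome vector are never changed.
#'
#' @param cohort An [as_cohort()] object.
#' @param outcome Outcome name the view is for (defaults to the cohort's
#'   outcome column).
#' @param phase `"pre"` or `"during"`.
#' @return An `ekbn_cohort` with the reduced feature set.
#' @export
phase_view <- function(cohort, outcome = cohort_outcome(cohort), phase) {
  if (!phase %in% c("pre", "during")) {
    abort_ekbn(paste0("unknown phase '", phase, "' (use 'pre' or 'during')"))
  }
  roles <- cohort_roles(cohort)
  known <- unique(c(cohort_outcome(cohort), unlist(roles$outcomes)))
  if (!outcome %in% known) {
    abort_ekbn(paste0("unknown outcome '", outcome, "'"))
  }
  ok_phase <- if (phase == "pre") roles$phase == "pre" else rep(TRUE, nrow(roles))
  ok_out <- vapply(roles$outcomes, function(o) length(o) == 0 || outcome %in% o,
                   logical(1))
  cohort_keep_features(cohort, roles$feature[ok_phase & ok_out])
}

#' Read / write a cohort and its feature-role metadata
#'
#' The cohort lives in a delimited text file (comma for `.csv`, tab for
#' `.tsv`/`.txt`) with a header row; the metadata sidecar is YAML (`.yaml`/
#' `.yml`) or JSON with keys `outcome`, `id_col` (optional) and `features`,
#' a list of records `{name, role: ekf|non_ekf, phase: pre|during,
#' outcomes: [...]}`.  Features present in the table but absent from the
#' metadata are assigned non-EKF/pre with a warning.  `write_cohort()`
#' additionally records factor levels so a round trip reproduces the cohort
#' exactly.
#'
#' @param table_path Path to the delimited cohort table.
#' @param metadata_path Path to the YAML/JSON sidecar.
#' @return [read_cohort()] returns an `ekbn_cohort`; [write_cohort()]
#'   invisibly returns the paths written.
#' @export
read_cohort <- function(table_path, metadata_path) {
  delim <- if (grepl("\\.(tsv|txt)$", table_path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(table_path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  meta <- read_metadata(metadata_path)
  if (is.null(meta$outcome)) abort_ekbn("metadata must declare the outcome column")
  feats <- meta$features %||% list()
  roles <- NULL
  if (length(feats) > 0) {
    roles <- tibble::tibble(
      feature = vapply(feats, `[[`, character(1), "name"),
      is_ekf = vapply(feats, function(f) identical(f$role, "ekf"), logical(1)),
      phase = vapply(feats, function(f) f$phase %||% "pre", character(1)),
      outcomes = lapply(feats, function(f) as.character(unlist(f$outcomes %||% character(0))))
    )
  }
  # restore stored factor levels, if the sidecar has them
  for (f in feats) {
    lv <- as.character(unlist(f$levels %||% character(0)))
    if (length(lv) > 0 && f$name %in% names(tab)) {
      tab[[f$name]] <- factor(as.character(tab[[f$name]]), levels = lv)
    }
  }
  as_cohort(tab, outcome = meta$outcome, roles = roles,
            id_col = if (!is.null(meta$id_col) && meta$id_col %in% names(tab)) meta$id_col else NULL)
}

read_metadata <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_cohort
#' @param cohort An `ekbn_cohort` to write.
#' @export
write_cohort <- function(cohort, table_path, metadata_path) {
  roles <- cohort_roles(cohort)
  out <- tibble::as_tibble(cohort)
  meta <- list(
    outcome = cohort_outcome(cohort),
    id_col = "unit_id",
    outcome_levels = as.list(attr(cohort, "outcome_levels")),
    features = purrr::pmap(roles, function(feature, is_ekf, phase, outcomes) {
      rec <- list(name = feature,
                  role = if (is_ekf) "ekf" else "non_ekf",
                  phase = phase,
                  outcomes = as.list(outcomes))
      col <- cohort[[feature]]
      if (is.factor(col)) rec$levels <- as.list(levels(col))
      rec
    })
  )
  delim <- if (grepl("\\.(tsv|txt)$", table_path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, table_path, delim = delim)
  if (grepl("\\.json$", metadata_path, ignore.case = TRUE)) {
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(meta, metadata_path)
  }
  invisible(c(table = table_path, metadata = metadata_path))
}
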