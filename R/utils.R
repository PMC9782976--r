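#' Derive a stage-specific sub-seed from a master seed
#'
#' A single top-level seed fans out to per-stage seeds so that individual
#' pipeline stages (ranking, structure learning, fold assignment, ...) are
#' independently reproducible.  The derivation is a small deterministic hash
#' of the stage name folded into the master seed; the result always lies in
#' `[1, 2^31 - 2]` so it is a valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label, e.g. `"ranking/rf"`.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  out <- (abs(as.numeric(seed)) %% 2147483647 * 7919 + h) %% 2147483629
  as.integer(out + 1)
}

abort_ekbn <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "ekbn_error"))
}

warn_ekbn <- function(msg, class = NULL) {
  rlang::warn(msg, class = c(class, "ekbn_warning"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# statistical mode of a vector, deterministic tie-break by factor level order
stat_mode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}
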