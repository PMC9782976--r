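# Internal integer coding of categorical data.
#
# All conditional-independence tests, network scores and CPT fits run on an
# integer matrix (one column per variable, values 1..nlev) rather than on
# factors; this keeps the inner loops of the tabu search and the Markov
# blanket search cheap.  `code_data()` is the single entry point; everything
# downstream carries the coded object around.

code_data <- function(data, cols = NULL) {
  df <- as.data.frame(data)
  if (!is.null(cols)) df <- df[cols]
  nm <- names(df)
  bad <- nm[!vapply(df, function(x) is.factor(x) || is.character(x) || is.logical(x), logical(1))]
  if (length(bad) > 0) {
    abort_ekbn(paste0(
      "non-categorical column(s): ", paste(bad, collapse = ", "),
      "; run discretize() first"
    ), class = "ekbn_not_categorical")
  }
  levs <- lapply(df, function(x) {
    if (is.factor(x)) levels(droplevels(x)) else sort(unique(as.character(x)))
  })
  m <- matrix(0L, nrow(df), ncol(df), dimnames = list(NULL, nm))
  for (j in seq_along(df)) {
    m[, j] <- match(as.character(df[[j]]), levs[[j]])
  }
  if (anyNA(m)) abort_ekbn("coded data contains missing values; impute before analysis")
  structure(
    list(m = m, nlev = vapply(levs, length, integer(1)), levels = levs,
         vars = nm, n = nrow(df)),
    class = "ekbn_coded"
  )
}

# joint configuration index of a set of coded columns (1-based, radix order)
joint_index <- function(coded, cols) {
  if (length(cols) == 0L) return(list(idx = rep(1L, coded$n), size = 1L))
  idx <- coded$m[, cols[1L]]
  size <- coded$nlev[[cols[1L]]]
  if (length(cols) > 1L) {
    for (v in cols[-1L]) {
      idx <- idx + size * (coded$m[, v] - 1L)
      size <- size * coded$nlev[[v]]
    }
  }
  list(idx = idx, size = as.integer(size))
}
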