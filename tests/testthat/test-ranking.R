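# independent brute-force evaluation of the weighted ranking score
wrs_oracle <- function(rank_lists, aucs, weighting = "inverse") {
  feats <- names(rank_lists[[1]])
  wrs <- numeric(length(feats))
  names(wrs) <- feats
  for (j in feats) {
    for (k in seq_along(rank_lists)) {
      w <- if (weighting == "inverse") sum(aucs) / aucs[[k]] else aucs[[k]] / sum(aucs)
      wrs[[j]] <- wrs[[j]] + rank_lists[[k]][[j]] * w
    }
  }
  wrs
}

as_ranked <- function(ranks, auc, id = "m") {
  out <- tibble::tibble(feature = names(ranks), rank = unname(ranks))
  structure(out, class = c("ekbn_ranking", class(out)), model_id = id, auc = auc)
}

test_that("integrate_rankings reproduces the hand-computed weighted score", {
  # K = 2, AUCs (0.8, 0.6); ranks A:(1,3), B:(2,1), C:(3,2)
  l1 <- as_ranked(c(A = 1, B = 2, C = 3), 0.8)
  l2 <- as_ranked(c(A = 3, B = 1, C = 2), 0.6)
  res <- integrate_rankings(list(l1, l2))
  wrs <- setNames(res$wrs, res$feature)
  expect_equal(wrs[["B"]], 2 * (1.4 / 0.8) + 1 * (1.4 / 0.6), tolerance = 1e-12)
  expect_equal(res$feature[order(res$rank)], c("B", "A", "C"))
})

test_that("single-list and equal-AUC integrations reduce to the obvious orders", {
  l1 <- as_ranked(c(A = 2, B = 1, C = 3), 0.7)
  res <- integrate_rankings(list(l1))
  expect_equal(setNames(res$rank, res$feature)[c("A", "B", "C")],
               c(A = 2, B = 1, C = 3))

  # equal AUCs: weights cancel into a Borda (sum-of-ranks) order
  l2 <- as_ranked(c(A = 1, B = 3, C = 2), 0.7)
  res2 <- integrate_rankings(list(l1, l2), aucs = c(0.7, 0.7))
  borda <- c(A = 3, B = 4, C = 5)
  expect_equal(res2$feature[order(res2$rank)], names(sort(borda)))
})

test_that("integration matches the brute-force oracle on random instances", {
  for (case in 1:40) {
    withr::with_seed(1000 + case, {
      K <- sample(1:4, 1)
      J <- sample(2:20, 1)
      feats <- paste0("f", seq_len(J))
      aucs <- runif(K, 0.5, 1)
      lists <- lapply(seq_len(K), function(k) {
        as_ranked(setNames(sample(J), feats), aucs[[k]], paste0("m", k))
      })
    })
    res <- integrate_rankings(lists)
    oracle <- wrs_oracle(lapply(lists, function(l) setNames(l$rank, l$feature)),
                         aucs)
    expect_equal(setNames(res$wrs, res$feature)[names(oracle)], oracle,
                 tolerance = 1e-12)
    expect_setequal(res$rank, seq_along(oracle))
  }
})

test_that("proportional weighting matches its oracle too", {
  l1 <- as_ranked(c(A = 1, B = 2, C = 3), 0.9)
  l2 <- as_ranked(c(A = 3, B = 1, C = 2), 0.6)
  res <- integrate_rankings(list(l1, l2), weighting = "proportional")
  oracle <- wrs_oracle(list(c(A = 1, B = 2, C = 3), c(A = 3, B = 1, C = 2)),
                       c(0.9, 0.6), "proportional")
  expect_equal(setNames(res$wrs, res$feature)[names(oracle)], oracle)
})

test_that("relabeling features permutes the integrated ranking consistently", {
  l1 <- as_ranked(c(A = 1, B = 2, C = 3, D = 4), 0.8)
  l2 <- as_ranked(c(A = 2, B = 4, C = 1, D = 3), 0.65)
  base <- integrate_rankings(list(l1, l2))
  relab <- c(A = "w", B = "x", C = "y", D = "z")
  rl <- lapply(list(l1, l2), function(l) {
    out <- l
    out$feature <- unname(relab[l$feature])
    out
  })
  perm <- integrate_rankings(rl)
  expect_equal(setNames(perm$wrs, perm$feature)[unname(relab)],
               setNames(setNames(base$wrs, base$feature)[names(relab)],
                        unname(relab)))
})

test_that("scaling all AUCs by a constant leaves the order unchanged", {
  l1 <- as_ranked(c(A = 1, B = 2, C = 3, D = 4), 0.8)
  l2 <- as_ranked(c(A = 4, B = 1, C = 3, D = 2), 0.6)
  r1 <- integrate_rankings(list(l1, l2), aucs = c(0.8, 0.6))
  r2 <- integrate_rankings(list(l1, l2), aucs = c(0.4, 0.3))
  expect_equal(r1$feature[order(r1$rank)], r2$feature[order(r2$rank)])
})

test_that("mismatched feature sets and non-positive AUCs are rejected", {
  l1 <- as_ranked(c(A = 1, B = 2), 0.8)
  l2 <- as_ranked(c(A = 1, C = 2), 0.7)
  expect_error(integrate_rankings(list(l1, l2)), "different features.*[BC]")
  l3 <- as_ranked(c(A = 2, B = 1), 0.7)
  expect_error(integrate_rankings(list(l1, l3), aucs = c(0.8, 0)), "positive")
})

test_that("a planted signal feature is ranked first with high AUC", {
  df <- withr::with_seed(5, {
    y <- rbinom(400, 1, 0.5)
    d <- data.frame(y = y, signal = factor(y, levels = 0:1))
    for (j in 1:12) d[[paste0("n", j)]] <- factor(rbinom(400, 1, 0.5), levels = 0:1)
    d
  })
  co <- as_cohort(df, "y")
  for (lrn in c("rf", "gbm")) {
    rk <- importance_list(co, lrn, folds = 3, n_perm = 5, seed = 11,
                          num_trees = 200, nrounds = 60)
    expect_equal(rk$feature[rk$rank == 1], "signal")
    expect_gt(attr(rk, "auc"), 0.95)
    expect_setequal(rk$rank, 1:13)
  }
})

test_that("pure-noise features give chance-level cross-validated AUC", {
  aucs <- vapply(1:10, function(s) {
    df <- withr::with_seed(300 + s, {
      d <- data.frame(y = rbinom(250, 1, 0.4))
      for (j in 1:8) d[[paste0("n", j)]] <- factor(rbinom(250, 1, 0.5))
      d
    })
    rk <- importance_list(as_cohort(df, "y"), "rf", folds = 3, n_perm = 3,
                          seed = s, num_trees = 100)
    attr(rk, "auc")
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a single-feature table yields rank 1 for that feature", {
  df <- data.frame(y = rep(c(0, 1), 20), only = factor(rep(c("a", "b"), 20)))
  rk <- importance_list(as_cohort(df, "y"), "rf", folds = 2, n_perm = 2,
                        seed = 1, num_trees = 50)
  expect_equal(nrow(rk), 1L)
  expect_equal(rk$rank, 1L)
  expect_equal(rk$feature, "only")
})
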