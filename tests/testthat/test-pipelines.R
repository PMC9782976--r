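test_that("initial_fraction implements the top-percentage rule", {
  expect_equal(initial_fraction(100, 10), 10)
  expect_equal(initial_fraction(69, 10), 100 * 10 / 69)
  expect_equal(ceiling(initial_fraction(69, 10) / 100 * 69), 10)
  expect_equal(initial_fraction(50, 50), 100)
  expect_error(initial_fraction(10, 11), "D must")
  expect_error(initial_fraction(10, 0), "D must")
})

test_that("PD-BN degenerates gracefully on a null cohort and is deterministic", {
  null_co <- withr::with_seed(1, {
    d <- data.frame(y = rbinom(90, 1, 0.3))
    for (j in 1:6) d[[paste0("n", j)]] <- factor(rbinom(90, 1, 0.5), levels = 0:1)
    as_cohort(d, "y")
  })
  expect_warning(f1 <- pd_bn_fit(null_co, sl = fast_sl(), repeats = 1, seed = 4),
                 "empty Markov blanket")
  expect_lt(abs(f1$eval$auc - 0.5), 0.2)
  suppressWarnings(f2 <- pd_bn_fit(null_co, sl = fast_sl(), repeats = 1, seed = 4))
  expect_identical(serialize(f1$bn, NULL), serialize(f2$bn, NULL))
  expect_identical(f1$eval$scores, f2$eval$scores)
})

test_that("PD-BN recovers most of a planted blanket at moderate n", {
  tr <- make_ground_truth(small_scenario())
  hits <- vapply(1:6, function(s) {
    co <- sample_dataset(tr, 600, seed = 500 + s)
    fit <- suppressWarnings(pd_bn_fit(co, sl = fast_sl(), repeats = 1, seed = s))
    sum(tr$true_mb %in% fit$mb$members)
  }, numeric(1))
  expect_gte(mean(hits >= 3), 0.8)
})

test_that("raw continuous features are rejected before modelling", {
  d <- data.frame(y = rep(c(0, 1), 30), v = rnorm(60))
  expect_error(pd_bn_fit(as_cohort(d, "y")), "discretize")
})

test_that("candidate sets between consecutive EKFs follow the ranked window", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 3))
  cfg <- fast_hitl(seed = 2)
  # hand-built integrated ranking: alternate EKFs and non-EKFs
  feats <- cohort_features(co)
  ekfs <- cohort_ekfs(co)
  ord <- c(ekfs[1], setdiff(feats, ekfs)[1:3], ekfs[2], ekfs[3],
           setdiff(feats, c(ekfs, setdiff(feats, ekfs)[1:3])))
  ranking <- tibble::tibble(feature = ord, wrs = seq_along(ord),
                            rank = seq_along(ord))
  state <- list(ranking = ranking,
                ekf_order = ekbn:::ekf_positions(co, ranking),
                selected = ekfs[1], outcome = cohort_outcome(co))
  class(state) <- "hitl_state"
  # between EKF 1 (rank 1) and EKF 2 (rank 5) sit 3 non-EKFs
  cand <- candidate_nonekfs(state, co, 2, cfg)
  expect_equal(length(cand$s), 3L)
  expect_true(all(cand$s_star %in% cand$s))
  # consecutive EKFs (ranks 5 and 6): S is empty
  cand2 <- candidate_nonekfs(state, co, 3, cfg)
  expect_equal(cand2$s, character(0))
  expect_equal(cand2$s_star, character(0))
  expect_error(candidate_nonekfs(state, co, 99, cfg), "out of range")
})

test_that("an infinite acceptance threshold freezes the incumbent model", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 11))
  cfg <- fast_hitl(seed = 11, epsilon = Inf)
  run <- hitl_bn_run(co, cfg)
  expect_true(nrow(run$trace) > 0)
  expect_false(any(run$trace$accepted))
  expect_equal(length(unique(run$trace$incumbent_auc)), 1L)
})

test_that("target_auc = 0 stops immediately after the initial model", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 12))
  run <- hitl_bn_run(co, fast_hitl(seed = 12, target_auc = 0))
  expect_equal(nrow(run$trace), 0L)
  expect_equal(run$stopped, "target_auc")
})

test_that("excluded EKFs are skipped and a run without EKFs errors", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 13))
  ekfs <- cohort_ekfs(co)
  run <- hitl_bn_run(co, fast_hitl(seed = 13, exclude_ekfs = ekfs[1]))
  expect_false(ekfs[1] %in% run$trace$ekf)
  expect_error(hitl_bn_run(co, fast_hitl(seed = 1, exclude_ekfs = ekfs)),
               "at least one expert-knowledge feature")
})

test_that("the interactive callback can veto steps without evaluation", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 14))
  asked <- integer(0)
  cfg <- fast_hitl(seed = 14, ask = function(info) {
    asked <<- c(asked, info$i)
    FALSE
  })
  run <- hitl_bn_run(co, cfg)
  expect_equal(nrow(run$trace), 0L)
  expect_gt(length(asked), 0L)
})

test_that("accepted steps improve the cross-validated AUC monotonically", {
  tr <- make_ground_truth(small_scenario())
  found <- FALSE
  for (s in 21:24) {
    co <- discretize(sample_dataset(tr, 200, seed = s))
    # a deliberately narrow initial window leaves signal for later steps
    run <- hitl_bn_run(co, fast_hitl(seed = s, D = 2L))
    acc <- run$trace[run$trace$accepted, ]
    if (nrow(acc) > 0) {
      found <- TRUE
      expect_true(all(acc$candidate_auc > acc$incumbent_auc + run$config$epsilon))
    }
    aucs <- c(run$trace$incumbent_auc[1],
              ifelse(run$trace$accepted, run$trace$candidate_auc,
                     run$trace$incumbent_auc))
    expect_true(all(diff(cummax(aucs)) >= 0))
  }
  expect_true(found)
})

test_that("a full run replays bit-for-bit from its config echo", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 31))
  cfg <- fast_hitl(seed = 31)
  r1 <- hitl_bn_run(co, cfg)
  r2 <- hitl_bn_run(co, r1$config)
  expect_identical(serialize(r1$trace, NULL), serialize(r2$trace, NULL))
  expect_identical(serialize(r1$bn, NULL), serialize(r2$bn, NULL))
  expect_identical(r1$state$eval$scores, r2$state$eval$scores)
})

test_that("held-out evaluation scores a frozen model on new units", {
  tr <- make_ground_truth(small_scenario())
  co <- sample_dataset(tr, 400, seed = 32)
  fit <- suppressWarnings(pd_bn_fit(co, sl = fast_sl(), repeats = 1, seed = 6))
  new <- sample_dataset(tr, 400, seed = 33)
  ho <- heldout_eval(fit, new)
  expect_s3_class(ho, "ekbn_eval")
  expect_equal(length(ho$scores), 400L)
  expect_gt(ho$auc, 0.55)  # blanket recovered at n=400 carries real signal
})

test_that("tidy/glance/autoplot summarize fitted objects", {
  tr <- make_ground_truth(small_scenario())
  co <- discretize(sample_dataset(tr, 150, seed = 41))
  run <- hitl_bn_run(co, fast_hitl(seed = 41, patience = 1))
  g <- glance(run)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_steps, nrow(run$trace))
  td <- tidy(run)
  expect_true(all(c("i", "ekf", "accepted", "n_s_star") %in% names(td)))
  expect_s3_class(autoplot(run$state$eval), "ggplot")
  expect_s3_class(autoplot(run$ranking, cohort = co), "ggplot")
  if (nrow(run$trace) > 0) expect_s3_class(autoplot(run), "ggplot")
})
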