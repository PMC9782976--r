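test_that("roc_auc handles separation, ties and the hand-counted case", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # labels (0,0,1,1), scores (.2,.8,.4,.9): 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.2, 0.8, 0.4, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("negating scores reflects the AUC around one half", {
  withr::with_seed(42, {
    s <- rnorm(200)
    y <- rbinom(200, 1, plogis(s))
  })
  expect_equal(roc_auc(s, y), 1 - roc_auc(-s, y), tolerance = 1e-12)
})

test_that("roc_auc agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    s <- rnorm(150)
    y <- rbinom(150, 1, plogis(0.8 * s))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("a constant scorer earns exactly chance-level cross-validated AUC", {
  tr <- make_ground_truth(small_scenario())
  co <- sample_dataset(tr, 80, seed = 40)
  builder <- function(train, seed) function(newdata) rep(0.31, nrow(newdata))
  ev <- cv_auc(co, builder, folds = 5, repeats = 2, seed = 1, ci = FALSE)
  expect_equal(ev$auc, 0.5)
})

test_that("an oracle scorer approaches the analytic AUC of the generator", {
  # binormal scores: true AUC = pnorm(delta / sqrt(2))
  delta <- 1.2
  withr::with_seed(77, {
    y <- rbinom(2000, 1, 0.35)
    s <- rnorm(2000, mean = delta * y)
  })
  d <- as_cohort(data.frame(y = y, s = s, f = factor(rbinom(2000, 1, 0.5))), "y")
  builder <- function(train, seed) function(newdata) newdata$s
  ev <- cv_auc(d, builder, folds = 5, repeats = 2, seed = 3, ci = FALSE)
  expect_lt(abs(ev$auc - pnorm(delta / sqrt(2))), 0.03)
})

test_that("cross-validation bookkeeping: stratification, reduction, determinism", {
  tr <- make_ground_truth(small_scenario())
  co <- sample_dataset(tr, 60, seed = 41)
  builder <- function(train, seed) function(newdata) runif(nrow(newdata))
  e1 <- cv_auc(co, builder, folds = 5, repeats = 2, seed = 9, ci = FALSE)
  e2 <- cv_auc(co, builder, folds = 5, repeats = 2, seed = 9, ci = FALSE)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$fold_assignment, e2$fold_assignment)
  e3 <- cv_auc(co, builder, folds = 5, repeats = 2, seed = 10, ci = FALSE)
  expect_false(identical(e1$fold_assignment, e3$fold_assignment))
  # every fold of every repeat keeps both classes
  y <- as.integer(as.character(co[[cohort_outcome(co)]]))
  for (r in 1:2) {
    tab <- table(e1$fold_assignment[, r], y)
    expect_true(all(tab > 0))
  }
  # minority smaller than folds: reduced with a warning
  tiny <- as_cohort(data.frame(y = c(rep(0, 20), rep(1, 3)),
                               f = factor(rbinom(23, 1, 0.5))), "y")
  expect_warning(ev <- cv_auc(tiny, builder, folds = 5, repeats = 1, ci = FALSE),
                 "reducing folds")
  expect_equal(ev$config$folds, 3L)
})

test_that("cv_auc is invariant to row permutation of the cohort", {
  tr <- make_ground_truth(small_scenario())
  co <- sample_dataset(tr, 50, seed = 43)
  builder <- function(train, seed) {
    p <- mean(train$mb_parent1 == "1")
    function(newdata) ifelse(newdata$mb_parent1 == "1", p, 1 - p)
  }
  e1 <- cv_auc(co, builder, folds = 4, repeats = 1, seed = 5, ci = FALSE)
  perm <- withr::with_seed(1, sample(nrow(co)))
  co2 <- structure(co[perm, ], class = class(co)) |>
    `attr<-`("outcome", cohort_outcome(co)) |>
    `attr<-`("roles", cohort_roles(co)) |>
    `attr<-`("outcome_levels", attr(co, "outcome_levels"))
  e2 <- cv_auc(co2, builder, folds = 4, repeats = 1, seed = 5, ci = FALSE)
  expect_equal(e1$auc, e2$auc)
  expect_equal(e1$scores[order(e1$unit_id)], e2$scores[order(e2$unit_id)])
})

test_that("bootstrap CI hits the boundary under separation and shrinks with n", {
  s <- c(rep(0.1, 50), rep(0.9, 50))
  y <- rep(c(0, 1), each = 50)
  ci <- auc_ci(s, y, B = 200, seed = 1)
  expect_equal(ci[[2]], 1)

  width <- vapply(c(100, 1000), function(n) {
    withr::with_seed(n, {
      yy <- rbinom(n, 1, 0.4)
      ss <- rnorm(n, mean = 0.8 * yy)
    })
    ci <- auc_ci(ss, yy, B = 400, seed = 2)
    ci[[2]] - ci[[1]]
  }, numeric(1))
  expect_lt(width[[2]], width[[1]])

  # delong-variance interval in the same ballpark as the bootstrap
  withr::with_seed(4, {
    yy <- rbinom(300, 1, 0.4)
    ss <- rnorm(300, mean = 0.8 * yy)
  })
  b <- auc_ci(ss, yy, B = 1000, seed = 3)
  d <- auc_ci(ss, yy, method = "delong")
  expect_lt(max(abs(b - d)), 0.05)
})

test_that("delong_test is symmetric, null on identical scores, and matches pROC", {
  withr::with_seed(21, {
    y <- rbinom(200, 1, 0.4)
    a <- rnorm(200, mean = y)
    b <- 0.6 * a + rnorm(200, 0.4 * y, 0.8)
  })
  same <- delong_test(a, a, labels = y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  ab <- delong_test(a, b, labels = y)
  ba <- delong_test(b, a, labels = y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<", levels = c(0, 1))
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<", levels = c(0, 1))
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ab$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("delong_test on evaluations requires identical units", {
  ev <- function(ids, scores, labels) {
    structure(list(auc = roc_auc(scores, labels), ci = c(0, 1),
                   scores = scores, labels = labels, unit_id = ids,
                   config = list()),
              class = "ekbn_eval")
  }
  y <- rep(c(0, 1), 10)
  s <- seq(0, 1, length.out = 20)
  e1 <- ev(paste0("u", 1:20), s, y)
  e2 <- ev(paste0("u", 1:20), rev(s), y)
  expect_s3_class(delong_test(e1, e2), "tbl_df")
  e3 <- ev(paste0("w", 1:20), s, y)
  expect_error(delong_test(e1, e3), "identical units")
})
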