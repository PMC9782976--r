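# random CPTs on a given DAG, for oracle comparisons
random_bn <- function(g, data_levels = c("0", "1"), seed = 1) {
  withr::with_seed(seed, {
    pl <- ekbn:::parent_list(g)
    cpts <- lapply(g$nodes, function(nd) {
      pars <- pl[[nd]]
      q <- length(data_levels)^length(pars)
      p1 <- runif(q, 0.05, 0.95)
      dims <- c(2L, rep(2L, length(pars)))
      dn <- c(list(data_levels), rep(list(data_levels), length(pars)))
      names(dn) <- c(nd, pars)
      array(rbind(1 - p1, p1), dim = dims, dimnames = dn)
    })
    names(cpts) <- g$nodes
    structure(list(dag = g, cpts = cpts,
                   levels = stats::setNames(rep(list(data_levels),
                                                length(g$nodes)), g$nodes),
                   strengths = NULL),
              class = "ekbn_bn")
  })
}

# posterior by brute-force enumeration of the full joint
enum_posterior <- function(bn, evidence, outcome) {
  j <- ekbn:::joint_enumeration(bn)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  p <- tapply(j$prob[keep], j[[outcome]][keep], sum)
  as.numeric(p / sum(p))
}

test_that("CPT fitting matches maximum likelihood and Dirichlet posteriors", {
  d <- data.frame(a = factor(c(1, 1, 0, 1), levels = 0:1))
  g <- dag("a")
  mle <- fit_cpts(d, g, ess = 0)
  expect_equal(unname(mle$cpts$a["1"]), 0.75)
  bayes <- fit_cpts(d, g, ess = 1)
  expect_equal(unname(bayes$cpts$a["1"]), (3 + 0.5) / (4 + 1))

  # parentless nodes carry marginal frequencies; rows normalize
  d2 <- sample_mb_net(200, seed = 30)
  g2 <- dag(names(d2), data.frame(from = c("P1", "P2"), to = c("T", "T")))
  bn <- fit_cpts(d2, g2, ess = 1)
  expect_equal(unname(bn$cpts$P1["1"]), (sum(d2$P1 == "1") + 0.5) / (200 + 1))
  csum <- apply(bn$cpts$T, c(2, 3), sum)
  expect_true(all(abs(csum - 1) < 1e-9))
  expect_true(all(unlist(bn$cpts) > 0))
})

test_that("posteriors read directly off the CPT in a two-node net", {
  g <- dag(c("F", "O"), data.frame(from = "F", to = "O"))
  bn <- random_bn(g, seed = 5)
  bn$cpts$O["1", "1"] <- 0.9
  bn$cpts$O["0", "1"] <- 0.1
  post <- predict_outcome(bn, list(F = "1"), outcome = "O")
  expect_equal(unname(post[["1"]]), 0.9, tolerance = 1e-12)

  # no evidence: the prior marginal
  marg <- enum_posterior(bn, list(), "O")
  expect_equal(unname(predict_outcome(bn, outcome = "O")), marg,
               tolerance = 1e-12)
})

test_that("collider posterior matches the hand Bayes computation", {
  g <- dag(c("F1", "F2", "O"),
           data.frame(from = c("F1", "F2"), to = c("O", "O")))
  bn <- random_bn(g, seed = 7)
  post <- predict_outcome(bn, list(F1 = "1", F2 = "0"), outcome = "O")
  # direct CPT lookup: parents fully observed
  expect_equal(unname(post[["1"]]), unname(bn$cpts$O["1", "1", "0"]),
               tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("variable elimination equals full-joint enumeration on random nets", {
  for (case in 1:8) {
    k <- withr::with_seed(case, sample(3:8, 1))
    sim <- sample_random_dag(k, n = 10, seed = 600 + case)
    g <- dag(sim$nodes, do.call(rbind, lapply(sim$nodes, function(nd) {
      if (length(sim$parents[[nd]]) == 0) NULL else
        data.frame(from = sim$parents[[nd]], to = nd)
    })))
    bn <- random_bn(g, seed = case)
    outcome <- sim$nodes[[k]]
    others <- setdiff(sim$nodes, outcome)
    evidence <- withr::with_seed(900 + case, {
      ev_vars <- sample(others, sample(0:length(others), 1))
      stats::setNames(as.list(sample(c("0", "1"), length(ev_vars),
                                     replace = TRUE)), ev_vars)
    })
    got <- predict_outcome(bn, evidence, outcome = outcome)
    want <- enum_posterior(bn, evidence, outcome)
    expect_equal(unname(got), want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("evidence outside the outcome's component does not move the posterior", {
  g <- dag(c("A", "B", "X", "Y"),
           data.frame(from = c("A", "X"), to = c("B", "Y")))
  bn <- random_bn(g, seed = 9)
  p0 <- predict_outcome(bn, list(A = "1"), outcome = "B")
  p1 <- predict_outcome(bn, list(A = "1", X = "0", Y = "1"), outcome = "B")
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("prediction contracts: outcome evidence, extra features, unseen levels", {
  g <- dag(c("F", "O"), data.frame(from = "F", to = "O"))
  bn <- random_bn(g, seed = 11)
  expect_error(predict_outcome(bn, list(O = "1"), outcome = "O"),
               "must not appear")
  expect_warning(predict_outcome(bn, list(F = "1", ghost = "0"), outcome = "O"),
                 "ignoring evidence")
  # unseen level: treated as missing, i.e. the marginal
  p_missing <- predict_outcome(bn, list(F = "weird"), outcome = "O")
  p_marg <- predict_outcome(bn, outcome = "O")
  expect_equal(p_missing, p_marg, tolerance = 1e-12)
})

test_that("row-wise prediction agrees with per-row variable elimination", {
  d <- sample_mb_net(500, seed = 31)
  g <- dag(names(d), data.frame(from = c("P1", "P2", "T", "S"),
                                to = c("T", "T", "C", "C")))
  bn <- fit_cpts(d, g, ess = 1)
  attr(bn, "outcome") <- "T"
  fast <- predict(bn, d[1:20, ])
  slow <- vapply(1:20, function(i) {
    ev <- lapply(d[i, c("P1", "P2", "C", "S")], as.character)
    unname(predict_outcome(bn, ev, outcome = "T")[["1"]])
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})
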