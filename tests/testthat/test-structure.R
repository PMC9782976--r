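test_that("dag constructor enforces acyclicity and well-formedness", {
  g <- dag(c("a", "b", "c"), data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_true(is_acyclic(g))
  expect_error(dag(c("a", "b"), data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cyclic")
  expect_error(dag("a", data.frame(from = "a", to = "a")), "self-loop")
  expect_error(dag(c("a", "b"),
                   data.frame(from = c("a", "a"), to = c("b", "b"))),
               "duplicate")
})

test_that("BIC favours independence under the null and the true arc otherwise", {
  d0 <- withr::with_seed(11, data.frame(x = factor(rbinom(5000, 1, 0.5)),
                                        y = factor(rbinom(5000, 1, 0.5))))
  empty <- dag(c("x", "y"))
  arc <- dag(c("x", "y"), data.frame(from = "x", to = "y"))
  expect_gte(bic_score(d0, empty), bic_score(d0, arc))

  d1 <- withr::with_seed(12, {
    x <- rbinom(5000, 1, 0.5)
    y <- ifelse(rbinom(5000, 1, 0.8) == 1, x, 1 - x)
    data.frame(x = factor(x), y = factor(y))
  })
  expect_gt(bic_score(d1, arc), bic_score(d1, empty))
})

test_that("the BIC total decomposes into per-node local scores", {
  sim <- sample_random_dag(k = 5, n = 600, seed = 8)
  g <- tabu_search(sim$data)
  local <- bic_score(sim$data, g, by_node = TRUE)
  expect_equal(sum(local), bic_score(sim$data, g), tolerance = 1e-9)
  expect_setequal(names(local), sim$nodes)
})

test_that("tabu search returns the empty graph on independent data", {
  d <- withr::with_seed(13, data.frame(a = factor(rbinom(5000, 1, 0.5)),
                                       b = factor(rbinom(5000, 1, 0.5))))
  g <- tabu_search(d)
  expect_equal(nrow(g$edges), 0L)
})

test_that("tabu search orients an identifiable v-structure", {
  d <- withr::with_seed(14, {
    x <- rbinom(5000, 1, 0.5)
    y <- rbinom(5000, 1, 0.5)
    z <- rbinom(5000, 1, 0.15 + 0.35 * (x + y))
    data.frame(x = factor(x), y = factor(y), z = factor(z))
  })
  g <- tabu_search(d)
  e <- paste(g$edges$from, g$edges$to, sep = ">")
  expect_setequal(e, c("x>z", "y>z"))
})

test_that("tabu search respects max_iter, whitelist and blacklist", {
  d <- sample_mb_net(800, seed = 15)
  expect_equal(nrow(tabu_search(d, max_iter = 0)$edges), 0L)
  wl <- data.frame(from = "P1", to = "T")
  g <- tabu_search(d, whitelist = wl)
  expect_true(any(g$edges$from == "P1" & g$edges$to == "T"))
  expect_error(tabu_search(d, whitelist = wl, blacklist = wl), "conflicts")
  gb <- tabu_search(d, blacklist = data.frame(from = c("P1", "T"), to = c("T", "P1")))
  expect_false(any((gb$edges$from == "P1" & gb$edges$to == "T") |
                     (gb$edges$from == "T" & gb$edges$to == "P1")))
})

test_that("bootstrap strengths separate a planted arc from an independent pair", {
  d <- withr::with_seed(16, {
    x <- rbinom(500, 1, 0.5)
    y <- ifelse(rbinom(500, 1, 0.9) == 1, x, 1 - x)
    data.frame(x = factor(x), y = factor(y), z = factor(rbinom(500, 1, 0.5)))
  })
  st <- bootstrap_arc_strength(d, R = 100, seed = 5)
  tb <- tibble::as_tibble(st)
  sxy <- tb$strength[tb$from == "x" & tb$to == "y"]
  expect_gt(sxy, 0.9)
  sz <- tb$strength[tb$from == "x" & tb$to == "z"]
  expect_true(length(sz) == 0 || sz < 0.3)
  expect_error(bootstrap_arc_strength(d, R = 0), "R must be")
})

test_that("strength symmetry and direction normalization hold", {
  d <- sample_mb_net(400, seed = 17)
  st <- tibble::as_tibble(bootstrap_arc_strength(d, R = 30, seed = 2))
  key <- paste(st$from, st$to)
  rkey <- paste(st$to, st$from)
  expect_true(all(rkey %in% key))
  for (i in seq_len(nrow(st))) {
    j <- match(rkey[[i]], key)
    expect_equal(st$strength[[i]], st$strength[[j]])
    expect_equal(st$direction[[i]] + st$direction[[j]], 1)
  }
  # single replicate: strengths are exactly 0 or 1
  st1 <- bootstrap_arc_strength(d, R = 1, seed = 3)
  expect_true(all(st1$strength %in% c(0, 1)))
})

test_that("averaged_network thresholds monotonically and stays acyclic", {
  d <- sample_mb_net(600, seed = 18)
  st <- bootstrap_arc_strength(d, R = 50, seed = 4)
  arcs <- function(g) paste(g$edges$from, g$edges$to)
  prev <- NULL
  for (thr in c(0.3, 0.5, 0.8, 1.0)) {
    g <- averaged_network(st, thr)
    expect_true(is_acyclic(g))
    if (!is.null(prev)) expect_true(all(arcs(g) %in% prev))
    prev <- arcs(g)
  }
  expect_error(averaged_network(st, 0), "threshold")
})

test_that("cycle-breaking removes the weakest arc and warns", {
  st <- tibble::tibble(
    from = c("a", "b", "b", "c", "c", "a"),
    to = c("b", "a", "c", "b", "a", "c"),
    strength = c(0.9, 0.9, 0.8, 0.8, 0.6, 0.6),
    direction = c(1, 0, 1, 0, 1, 0)
  )
  st <- structure(st, class = c("ekbn_strength", class(st)),
                  R = 10L, nodes = c("a", "b", "c"))
  expect_warning(g <- averaged_network(st, 0.5), "cycle")
  expect_true(is_acyclic(g))
  expect_equal(nrow(g$edges), 2L)
  expect_false(any(g$edges$from == "c" & g$edges$to == "a"))
})

test_that("structure learning is deterministic given data, seed and config", {
  d <- sample_mb_net(300, seed = 19, n_noise = 2)
  s1 <- bootstrap_arc_strength(d, R = 25, seed = 9)
  s2 <- bootstrap_arc_strength(d, R = 25, seed = 9)
  expect_identical(s1, s2)
  expect_identical(serialize(averaged_network(s1, 0.5), NULL),
                   serialize(averaged_network(s2, 0.5), NULL))
})

test_that("the true 5-node skeleton is recovered from averaged bootstraps", {
  hits <- vapply(1:6, function(s) {
    d <- sample_mb_net(3000, seed = 200 + s)
    st <- bootstrap_arc_strength(d, R = 40, seed = s)
    g <- averaged_network(st, 0.5)
    und <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    truth <- und(data.frame(from = c("P1", "P2", "T", "S"),
                            to = c("T", "T", "C", "C")))
    setequal(und(g$edges), truth)
  }, logical(1))
  expect_gte(sum(hits), 5L)
})
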