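test_that("expert aggregation takes the plurality score, complementarily", {
  # seven experts with a plurality at 0
  p <- expert_panel("node", c("a", "b"),
                    data.frame(i = "a", j = "b", expert = 1:7,
                               score = c(0, 0, 0.5, 1, 0.5, 0, 1)))
  f <- aggregate_scores(p)
  expect_identical(f["a", "b"], 0)
  expect_identical(f["b", "a"], 1)
  # a single expert decides alone
  p1 <- expert_panel("node", c("a", "b"),
                     data.frame(i = "a", j = "b", expert = 1, score = 1))
  expect_identical(aggregate_scores(p1)["a", "b"], 1)
  expect_identical(aggregate_scores(p1)["b", "a"], 0)
  # tied extremes fall back to equal importance
  p2 <- expert_panel("node", c("a", "b"),
                     data.frame(i = "a", j = "b", expert = 1:2, score = c(0, 1)))
  expect_identical(aggregate_scores(p2)["a", "b"], 0.5)
})

test_that("aggregation is symmetric: complementary panels give complementary matrices", {
  # exhaustive over all multisets of three scores for one pair
  grid <- expand.grid(s1 = c(0, 0.5, 1), s2 = c(0, 0.5, 1), s3 = c(0, 0.5, 1))
  for (k in seq_len(nrow(grid))) {
    s <- as.numeric(grid[k, ])
    f <- aggregate_scores(expert_panel("n", c("a", "b"),
                                       data.frame(i = "a", j = "b", expert = 1:3, score = s)))
    g <- aggregate_scores(expert_panel("n", c("a", "b"),
                                       data.frame(i = "a", j = "b", expert = 1:3, score = 1 - s)))
    expect_identical(g, 1 - f)
  }
  # scores recorded in either pair orientation agree
  pa <- expert_panel("n", c("a", "b"),
                     data.frame(i = "b", j = "a", expert = 1:3, score = c(0, 0, 1)))
  expect_identical(aggregate_scores(pa)["a", "b"], 1)
})

test_that("panel validation rejects malformed score tables", {
  expect_error(expert_panel("n", c("a", "b"),
                            data.frame(i = "a", j = "b", expert = 1, score = 0.3)),
               class = "fahp_validation")
  expect_error(expert_panel("n", c("a", "b", "c"),
                            data.frame(i = "a", j = "b", expert = 1, score = 1)),
               class = "fahp_missing_value")
  expect_error(expert_panel("n", c("a", "b"),
                            data.frame(i = "a", j = "a", expert = 1, score = 1)),
               class = "fahp_validation")
  expect_error(expert_panel("n", c("a", "b", "c"),
                            rbind(data.frame(i = "a", j = c("b", "c"), expert = 1, score = 1),
                                  data.frame(i = "b", j = "c", expert = 1:2, score = 1))),
               class = "fahp_validation")
})

test_that("the consistent transform reproduces the worked 3 x 3 example", {
  r <- to_consistent(fjm3())
  expect_equal(round(unclass(r)[1, ], 3), c(0.5, 0.667, 0.833), tolerance = 1e-12)
  expect_equal(unclass(r)[, 1], c(0.5, 1/3, 1/6), tolerance = 1e-12)
  expect_equal(attr(r, "row_sums"), c(2.5, 1.5, 0.5))
  # total indifference stays indifferent
  f0 <- matrix(0.5, 4, 4)
  expect_equal(unclass(to_consistent(f0)), matrix(0.5, 4, 4), ignore_attr = TRUE)
  # 5 x 5 case-study node, hand arithmetic: r31 = (4 - 0.5)/10 + 0.5
  expect_equal(to_consistent(fjm5())[3, 1], 0.85)
})

test_that("normalizing-method weights match the worked examples", {
  w <- weights_normalizing(to_consistent(fjm3()))
  expect_equal(round(as.numeric(w), 4), c(0.4444, 0.3333, 0.2222), tolerance = 1e-12)
  expect_equal(as.numeric(weights_normalizing(matrix(0.5, 4, 4))), rep(0.25, 4))
  w5 <- weights_normalizing(to_consistent(fjm5()))
  expect_equal(as.numeric(w5), c(0.12, 0.20, 0.26, 0.26, 0.16), tolerance = 1e-12)
})

test_that("square-root-method weights match the worked examples", {
  w <- weights_sqrt(to_consistent(fjm3()))
  # reported vector carries 3-decimal intermediate rounding; full precision
  # agrees to 2e-4 per component
  expect_true(all(abs(as.numeric(w) - c(0.4543, 0.3347, 0.2110)) < 2e-4))
  expect_equal(as.numeric(weights_sqrt(matrix(0.5, 3, 3))), rep(1/3, 3))
  # closed form at n = 2: w1 = sqrt(0.5 * 0.75) / (sqrt(0.375) + sqrt(0.125))
  r2 <- matrix(c(0.5, 0.75, 0.25, 0.5), 2, byrow = TRUE)
  expect_equal(as.numeric(weights_sqrt(r2)), c(0.634, 0.366), tolerance = 1e-3)
  # a zero entry makes the geometric mean degenerate
  expect_error(weights_sqrt(matrix(c(0.5, 1, 0, 0.5), 2, byrow = TRUE)),
               class = "fahp_degenerate")
})

test_that("reciprocal conversion reproduces the printed matrix and flags degeneracy", {
  e <- to_reciprocal(rcm3_printed())
  expect_equal(round(unclass(e), 4),
                   matrix(c(1, 2.0030, 4.9880,
                            0.4993, 1, 2.0030,
                            0.2005, 0.4993, 1), 3, byrow = TRUE))
  expect_equal(unclass(to_reciprocal(matrix(0.5, 3, 3))),
               matrix(1, 3, 3), ignore_attr = TRUE)
  # case-study 5 x 5 node: e35 = 0.75 / 0.25
  expect_equal(to_reciprocal(to_consistent(fjm5()))[3, 5], 3)
  expect_error(to_reciprocal(matrix(c(0.5, 1, 0, 0.5), 2, byrow = TRUE)),
               class = "fahp_degenerate")
})

test_that("power iteration refines the 3 x 3 priorities as reported", {
  r <- to_consistent(fjm3())
  w <- power_iterate(to_reciprocal(r), seed = weights_normalizing(r))
  expect_equal(attr(w, "lambda_max"), 3.0061, tolerance = 2e-3)
  expect_equal(as.numeric(w), c(0.5954, 0.2763, 0.1283), tolerance = 2e-3)
  expect_lte(attr(w, "iterations"), 6L)
})

test_that("power iteration handles the consistent-indifference and error cases", {
  e1 <- matrix(1, 4, 4)
  w <- power_iterate(e1)
  expect_equal(as.numeric(w), rep(0.25, 4))
  expect_equal(attr(w, "lambda_max"), 4)
  expect_lte(attr(w, "iterations"), 2L)
  expect_error(power_iterate(e1, seed = c(1, -1, 1, 1)), class = "fahp_validation")
  expect_error(power_iterate(matrix(c(1, 2, 3, 1), 2)), class = "fahp_validation")
  expect_error(power_iterate(e1, tol = 0, max_iter = 5), class = "fahp_convergence")
})

test_that("the full per-node pipeline reproduces the case-study weights", {
  w3 <- node_weights(fjm3(), method = "iterative")
  expect_equal(as.numeric(w3), c(0.5954, 0.2763, 0.1283), tolerance = 2e-3)
  w5 <- node_weights(fjm5(), method = "iterative")
  expect_equal(as.numeric(w5), c(0.0647, 0.1665, 0.3310, 0.3310, 0.1068),
               tolerance = 2e-3)
  # eigen-decomposition oracle for the 5 x 5 node
  e5 <- to_reciprocal(to_consistent(fjm5()))
  v <- Re(eigen(e5)$vectors[, 1]); v <- v / sum(v)
  w5hi <- power_iterate(e5, tol = 1e-12, max_iter = 1000)
  expect_equal(as.numeric(w5hi), v, tolerance = 1e-6)
  # a panel route gives the same answer as its aggregated matrix
  p <- generate_panel(letters[1:4], n_experts = 5, seed = 11)
  expect_equal(as.numeric(node_weights(p)),
               as.numeric(node_weights(aggregate_scores(p))))
})

test_that("all weight methods preserve the row-sum importance ordering (exhaustive n = 3)", {
  for (f in all_fjm3()) {
    rs <- rowSums(f)
    for (m in c("normalizing", "sqrt", "iterative")) {
      w <- as.numeric(node_weights(f, method = m))
      expect_equal(sum(w), 1, tolerance = 1e-9)
      for (i in 1:2) for (j in (i + 1):3) {
        if (rs[i] > rs[j]) expect_gt(w[i], w[j])
        if (rs[i] == rs[j]) expect_equal(w[i], w[j], tolerance = 1e-6)
        if (rs[i] < rs[j]) expect_lt(w[i], w[j])
      }
    }
  }
})

test_that("calculus invariants hold on randomly generated panels", {
  set.seed(202)
  lambda_floor_ok <- TRUE; consistency_ok <- TRUE; reciprocity_ok <- TRUE
  oracle_ok <- TRUE; complement_ok <- TRUE
  for (trial in seq_len(1000)) {
    n <- sample(3:9, 1)
    p <- generate_panel(paste0("c", seq_len(n)), n_experts = sample(c(1, 3, 7), 1))
    f <- aggregate_scores(p)
    complement_ok <- complement_ok && all(f + t(f) == 1)
    r <- to_consistent(f)
    # additive consistency: r[i,j] = r[i,k] - r[j,k] + 0.5 for all triples
    for (k in seq_len(n)) {
      dev <- max(abs(outer(r[, k], r[, k], "-") + 0.5 - unclass(r)))
      consistency_ok <- consistency_ok && dev < 1e-12
    }
    e <- to_reciprocal(r)
    reciprocity_ok <- reciprocity_ok && max(abs(e * t(e) - 1)) < 1e-9
    w <- power_iterate(e, seed = weights_normalizing(r), tol = 1e-12, max_iter = 1000)
    lambda_floor_ok <- lambda_floor_ok && attr(w, "lambda_max") >= n - 1e-6
    if (trial %% 20 == 0) {  # dense-eigen oracle on a subsample
      v <- Re(eigen(e)$vectors[, 1]); v <- v / sum(v)
      oracle_ok <- oracle_ok && max(abs(as.numeric(w) - v)) < 1e-6
    }
  }
  expect_true(complement_ok)
  expect_true(consistency_ok)
  expect_true(reciprocity_ok)
  expect_true(lambda_floor_ok)
  expect_true(oracle_ok)
})
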