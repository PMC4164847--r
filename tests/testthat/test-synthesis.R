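# Weight synthesis down the hierarchy and the comprehensive score.

toy_fit <- function(w1 = 0.6, x = c(0.2, 0.9, 0.4, 0.1), c0 = 0) {
  h <- build_hierarchy(
    list(A  = list(children = c("B1", "B2")),
         B1 = list(direction = "positive", weight = w1),
         B2 = list(direction = "positive", weight = 1 - w1)),
    alternatives = c("p", "q"))
  v <- data.frame(leaf = c("B1", "B2", "B1", "B2"),
                  alternative = c("p", "p", "q", "q"), value = x)
  fahp(h, v, correction = c0)
}

test_that("composite weights follow the path-product rule and sum to one", {
  case <- skidding_case()
  lam <- composite_weights(case$hierarchy)
  expect_length(lam, 39)
  expect_equal(sum(lam), 1, tolerance = 1e-9)
  expect_equal(unname(lam["D1"]), 0.5954 * 0.2763 * 0.0647, tolerance = 1e-12)
  # consistency with the published per-leaf integrated value
  expect_equal(round(unname(lam["D1"]) * 0.66, 4), 0.0070)
  # two leaves weighted 0.6 / 0.4
  f <- toy_fit()
  expect_equal(unname(coef(f)), c(0.6, 0.4))
  # an unweighted node is reported by name
  h <- build_hierarchy(
    list(A = list(children = c("B1", "B2")),
         B1 = list(direction = "positive"), B2 = list(direction = "positive")),
    "x")
  err <- tryCatch(composite_weights(h), error = identity)
  expect_s3_class(err, "fahp_missing_weight")
  expect_match(conditionMessage(err), "B1")
})

test_that("the comprehensive score is the weighted sum of leaf values plus c", {
  f <- toy_fit(x = c(0.2, 0.9, 0.4, 0.1), c0 = 0.05)
  expect_equal(unname(f$scores["p"]), 0.6 * 0.2 + 0.4 * 0.9 + 0.05)
  # P decomposes exactly into the per-leaf integrated values plus c
  for (a in c("p", "q")) {
    expect_equal(sum(f$values$integrated[f$values$alternative == a]) + 0.05,
                 unname(f$scores[a]), tolerance = 1e-9)
  }
  # all-zero values score c
  f0 <- toy_fit(x = rep(0, 4))
  expect_equal(unname(f0$scores), c(0, 0))
  # values outside [0,1] are rejected unless standardization is requested
  expect_error(toy_fit(x = c(2, 0.9, 0.4, 0.1)), class = "fahp_validation")
})

test_that("P is monotone in any positive-leaf value and bounded on [0, 1]", {
  set.seed(99)
  h <- random_hierarchy(depth = 2, n_children = c(3, 5), seed = 31)
  panels <- generate_panels(h, seed = 32)
  v <- expand.grid(leaf = h$leaves, alternative = h$alternatives,
                   stringsAsFactors = FALSE)
  v$value <- runif(nrow(v))
  fit <- fahp(h, v, panels = panels)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  for (rep in 1:20) {
    k <- sample(which(v$leaf %in% h$leaves), 1)
    v2 <- v
    v2$value[k] <- min(1, v2$value[k] + runif(1, 0, 1 - v2$value[k]))
    bumped <- predict(fit, v2)
    expect_gte(bumped[[v$alternative[k]]] + 1e-12, fit$scores[[v$alternative[k]]])
  }
})

test_that("alternatives are ranked by decreasing P with adjacent gaps", {
  cmp <- compare_alternatives(c(road = 0.4473, cableway = 0.6727))
  expect_identical(cmp$alternative, c("cableway", "road"))
  expect_equal(cmp$delta_next, c(0.2254, NA))
  # identical scores: stable input order, zero gap
  tie <- compare_alternatives(c(a = 0.5, b = 0.5))
  expect_identical(tie$alternative, c("a", "b"))
  expect_equal(tie$delta_next, c(0, NA))
  # matches a brute-force sort for several alternatives
  s <- c(x = 0.31, y = 0.62, z = 0.47)
  expect_identical(compare_alternatives(s)$alternative,
                   names(sort(s, decreasing = TRUE)))
  expect_error(compare_alternatives(c(a = 1)), class = "fahp_validation")
})

test_that("fit methods expose the evaluation table and scores coherently", {
  case <- skidding_case()
  fit <- fahp(case$hierarchy, case$values)
  s <- summary(fit)
  expect_identical(nrow(s$table), 39L)
  expect_true(all(c("std.road", "int.road", "std.cableway", "int.cableway")
                  %in% names(s$table)))
  expect_equal(sum(s$table$int.cableway), unname(fit$scores["cableway"]),
               tolerance = 1e-12)
  expect_output(print(fit), "Comprehensive scores")
  # report round-trips through a delimited file
  tmp <- tempfile(fileext = ".tsv")
  fahp_report(fit, tmp)
  back <- read.delim(tmp)
  expect_identical(nrow(back), 39L)
  expect_equal(back$weight, round(unname(coef(fit)), 4))
  # predict with fitted weights on a fresh value table
  alt3 <- data.frame(leaf = rep(case$hierarchy$leaves, 3),
                     alternative = rep(c("m1", "m2", "m3"),
                                       each = length(case$hierarchy$leaves)),
                     value = rep(c(0.2, 0.5, 0.8), each = length(case$hierarchy$leaves)))
  pr <- predict(fit, alt3)
  expect_equal(unname(pr), c(0.2, 0.5, 0.8), tolerance = 1e-9)
})
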