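test_that("degenerate value vectors give degenerate bounds", {
  ws <- weight_space(standard_ranking, 1e-6)
  b1 <- solve_bounds(rep(1, 5), ws)
  expect_equal(unname(b1), c(1, 1), tolerance = 1e-9)
  b0 <- solve_bounds(rep(0, 5), ws)
  expect_equal(unname(b0), c(0, 0), tolerance = 1e-9)
})

test_that("LP bounds equal prefix-average vertex extremes (oracle)", {
  b <- solve_bounds(c(0.6, 0.2, 1.0), weight_space(c("a", "b", "c"), 0))
  expect_equal(unname(b), c(0.4, 0.6), tolerance = 1e-9)
  set.seed(123)
  for (n in 2:8) {
    ws <- weight_space(paste0("c", seq_len(n)), epsilon = 0)
    for (rep in 1:5) {
      v <- round(runif(n), 6)
      expect_equal(unname(solve_bounds(v, ws)),
                   unname(prefix_average_bounds(v)),
                   tolerance = 1e-9,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("solve_bounds validates input and flags infeasible spaces", {
  ws <- weight_space(c("a", "b"), 1e-6)
  expect_error(solve_bounds(c(0.5, 1.2), ws), "0, 1")
  expect_error(solve_bounds(c(a = 0.5, z = 0.5), ws), "names")
  bad <- add_constraint(
    add_constraint(ws, tradeoff_constraint(1, 2, 0.5, "prefer_upper")),
    tradeoff_constraint(1, 2, 0.5, "prefer_lower"))
  expect_error(solve_bounds(c(0.5, 0.5), bad),
               class = "fitsort_infeasible")
})

test_that("band assignment follows the lower-closed threshold convention", {
  prof <- class_profile()
  expect_identical(assign_classes(0.2099, 0.4586, prof), c("M", "B"))
  expect_identical(assign_classes(0.9050, 0.9372, prof), "W")
  expect_identical(assign_classes(0.35, 0.75, prof), c("M", "B", "W"))
  # bounds exactly on a threshold belong to the lower band
  expect_identical(assign_classes(0.4, 0.4, prof), "M")
  expect_identical(assign_classes(0.7, 0.7, prof), "B")
  expect_identical(assign_classes(0.4, 0.7, prof), c("M", "B"))
  expect_identical(assign_classes(0, 0, prof), "M")
  expect_identical(assign_classes(1, 1, prof), "W")
  # solver noise within tol does not push a bound across a threshold
  expect_identical(assign_classes(0.4 + 1e-10, 0.7 + 1e-10, prof),
                   c("M", "B"))
})

test_that("recommendation picks the most critical viable class", {
  prof <- class_profile()
  expect_identical(recommend_class(c("M", "B"), prof), "B")
  expect_identical(recommend_class(c("B", "W"), prof), "W")
  expect_identical(recommend_class("M", prof), "M")
  expect_error(recommend_class("X", prof), "unknown")
})

test_that("classification is deterministic and dominance-consistent", {
  criteria <- list(criterion("a", "maximize"), criterion("b", "maximize"),
                   criterion("c", "maximize"))
  set.seed(7)
  perf <- matrix(runif(18), 6, 3,
                 dimnames = list(paste0("alt", 1:6), c("a", "b", "c")))
  perf[2, ] <- perf[1, ]                      # identical pair
  cm <- consequence_matrix(perf, criteria)
  v <- compute_value_matrix(cm)
  ws <- weight_space(c("a", "b", "c"), 1e-6)
  res <- classify_all(v, ws, class_profile())
  expect_equal(res$s1[1], res$s1[2])
  expect_equal(res$s2[1], res$s2[2])
  expect_identical(res$viable[1], res$viable[2])
  # componentwise dominance of marginal values orders both bounds
  for (i in 1:6) for (j in 1:6) {
    if (all(v[i, ] >= v[j, ])) {
      expect_gte(res$s1[i], res$s1[j] - 1e-9)
      expect_gte(res$s2[i], res$s2[j] - 1e-9)
    }
  }
})

test_that("an all-best row lands in the top class", {
  criteria <- list(criterion("a", "maximize"), criterion("b", "maximize"))
  perf <- matrix(c(1, 0, 0.3, 1, 0, 0.6), 3, 2,
                 dimnames = list(c("best", "worst", "mid"), c("a", "b")))
  v <- compute_value_matrix(consequence_matrix(perf, criteria))
  res <- classify_all(v, weight_space(c("a", "b"), 1e-6),
                      class_profile())
  expect_identical(res$viable[1], "W")
  expect_identical(res$recommended[1], "W")
  expect_identical(res$viable[2], "M")
})

test_that("adding a constraint only narrows every bound interval", {
  fx <- huol_fixture()
  v <- compute_value_matrix(fx$matrix)
  ws <- weight_space(fx$ranking, 1e-6)
  before <- classify_all(v, ws, fx$profile)
  ws2 <- add_constraint(ws, tradeoff_constraint(1, 5, 0.5, "prefer_upper"))
  ws2 <- add_constraint(ws2, tradeoff_constraint(2, 4, 0.3, "prefer_lower"))
  after <- classify_all(v, ws2, fx$profile)
  expect_true(all(after$s1 >= before$s1 - 1e-9))
  expect_true(all(after$s2 <= before$s2 + 1e-9))
  # classified count can only grow
  expect_gte(attr(after, "n_single"), attr(before, "n_single"))
})

test_that("global value at any feasible weights lies within the bounds", {
  fx <- huol_fixture()
  v <- compute_value_matrix(fx$matrix)
  ws <- weight_space(fx$ranking, 0)
  res <- classify_all(v, ws, fx$profile)
  verts <- enumerate_vertices(ws)
  set.seed(11)
  for (rep in 1:5) {
    mix <- runif(nrow(verts)); mix <- mix / sum(mix)
    k <- as.numeric(mix %*% verts)           # random feasible weights
    g <- as.numeric(v[, colnames(verts)] %*% k)
    expect_true(all(g >= res$s1 - 1e-9 & g <= res$s2 + 1e-9))
  }
})

test_that("count_summary aggregates the reference classification", {
  fx <- huol_fixture()
  rb <- huol_reference_bounds()
  res <- data.frame(alternative = rb$alternative, s1 = rb$s1, s2 = rb$s2)
  sets <- mapply(function(a, b) assign_classes(a, b, fx$profile),
                 rb$s1, rb$s2, SIMPLIFY = FALSE)
  res$viable <- vapply(sets, function(s) paste(rev(s), collapse = "|"),
                       character(1))
  res$n_classes <- lengths(sets)
  res$recommended <- vapply(sets, recommend_class, character(1),
                            profile = fx$profile)
  cs <- count_summary(res, fx$profile)
  expect_equal(cs$n_single, 34)
  expect_equal(cs$n_multi, 14)
  expect_length(cs$top_class_items, 4)
  empty <- count_summary(res[0, ], fx$profile)
  expect_equal(empty$n, 0)
  expect_equal(unname(empty$by_recommended), c(0L, 0L, 0L))
})

test_that("classification reports round-trip through CSV", {
  fx <- huol_fixture()
  v <- compute_value_matrix(fx$matrix)
  res <- classify_all(v, weight_space(fx$ranking, 1e-6), fx$profile)
  tmp <- tempfile(fileext = ".csv")
  write_classification(res, tmp)
  back <- read_bounds(tmp)
  expect_equal(back$s1, res$s1)
  expect_equal(back$s2, res$s2)
  expect_identical(back$alternative, res$alternative)
})
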