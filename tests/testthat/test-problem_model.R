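test_that("criterion validates direction against declared levels", {
  expect_error(criterion("c", "maximize", worst_level = 3, best_level = 1),
               "contradict")
  expect_error(criterion("c", "minimize", worst_level = 1, best_level = 3),
               "contradict")
  expect_error(criterion("c", "maximize", worst_level = 2, best_level = 2),
               "differ")
  cr <- criterion("c", "minimize", worst_level = 60, best_level = 2)
  expect_s3_class(cr, "criterion")
})

test_that("consequence matrix rejects malformed input", {
  criteria <- hospital_criteria()
  perf <- matrix(1, 3, 5,
                 dimnames = list(c("a", "b", "a"),
                                 sapply(criteria, `[[`, "name")))
  expect_error(consequence_matrix(perf, criteria), "duplicated.*a")
  perf2 <- matrix(c(1, 2, 1, 2, 1, 2, 2, 4, 1, 2), 2, 5,
                  dimnames = list(c("a", "b"),
                                  sapply(criteria, `[[`, "name")))
  expect_error(consequence_matrix(perf2, criteria),
               "criticality.*4")
  perf3 <- matrix(1, 1, 5,
                  dimnames = list("a", sapply(criteria, `[[`, "name")))
  expect_error(consequence_matrix(perf3, criteria), "at least 2")
})

test_that("CSV loading reports missing columns, bad cells, duplicates", {
  criteria <- hospital_criteria()
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(alternative = c("a", "b"), cost = 1:2,
                       demand = 1:2, lead_time = 1:2),
            tmp, row.names = FALSE)
  expect_error(load_consequence_matrix(tmp, criteria),
               "missing criterion column.*criticality")
  write.csv(data.frame(alternative = c("a", "b"), cost = c("1", "oops"),
                       demand = 1:2, lead_time = 1:2,
                       criticality = c(1, 2), volume = c(1, 2)),
            tmp, row.names = FALSE)
  expect_error(load_consequence_matrix(tmp, criteria), "non-numeric")
  write.csv(data.frame(alternative = c("a", "a"), cost = 1:2,
                       demand = 1:2, lead_time = 1:2,
                       criticality = c(1, 2), volume = c(1, 2)),
            tmp, row.names = FALSE)
  expect_error(load_consequence_matrix(tmp, criteria), "duplicated")
  write.csv(data.frame(alternative = c("a", "b"), cost = 1:2,
                       demand = 1:2, lead_time = 1:2,
                       criticality = c(1, 4), volume = c(1, 2)),
            tmp, row.names = FALSE)
  expect_error(load_consequence_matrix(tmp, criteria),
               "'b'.*criticality")
})

test_that("column order follows the criteria config, not the file", {
  criteria <- list(criterion("gain", "maximize"),
                   criterion("loss", "minimize"))
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("x", "y"), loss = c(5, 1),
                       gain = c(1, 3)), tmp, row.names = FALSE)
  cm <- load_consequence_matrix(tmp, criteria)
  expect_identical(colnames(cm$performance), c("gain", "loss"))
  expect_equal(cm$performance["x", "loss"], 5)
})

test_that("marginal values map worst to 0, best to 1, midpoint to 1/2", {
  cm <- tiny_matrix()
  v <- compute_value_matrix(cm)
  # gain observed on [10, 30], maximized; loss on [2, 8], minimized
  expect_equal(unname(v[, "gain"]), c(0, 0.5, 1))
  expect_equal(unname(v[, "loss"]), c(0.5, 1, 0))
  # built 1-3 scale: (x - 1)/2
  fx <- huol_fixture()
  vx <- compute_value_matrix(fx$matrix)
  expect_equal(unname(vx[, "criticality"]),
               unname((fx$matrix$performance[, "criticality"] - 1) / 2))
})

test_that("every non-degenerate value column attains 0 and 1", {
  fx <- huol_fixture()
  v <- compute_value_matrix(fx$matrix)
  expect_true(all(v >= 0 & v <= 1))
  for (nm in colnames(v)) {
    expect_equal(min(v[, nm]), 0, info = nm)
    expect_equal(max(v[, nm]), 1, info = nm)
  }
})

test_that("value computation is equivariant to positive affine rescaling", {
  fx <- huol_fixture()
  v0 <- compute_value_matrix(fx$matrix)
  perf <- fx$matrix$performance
  perf[, "cost"] <- 3.7 * perf[, "cost"] + 12
  perf[, "demand"] <- 0.25 * perf[, "demand"] + 100
  cm2 <- consequence_matrix(perf, fx$matrix$criteria)
  v1 <- compute_value_matrix(cm2)
  expect_equal(v1[, "cost"], v0[, "cost"], tolerance = 1e-12)
  expect_equal(v1[, "demand"], v0[, "demand"], tolerance = 1e-12)
})

test_that("degenerate criteria are rejected; declared levels clip", {
  criteria <- list(criterion("a", "maximize"), criterion("b", "minimize"))
  perf <- matrix(c(1, 1, 2, 3), 2, 2,
                 dimnames = list(c("x", "y"), c("a", "b")))
  cm <- consequence_matrix(perf, criteria)
  expect_error(compute_value_matrix(cm), "'a' is degenerate")
  criteria2 <- list(criterion("a", "maximize", worst_level = 0,
                              best_level = 10),
                    criterion("b", "minimize"))
  perf2 <- matrix(c(5, 20, 2, 3), 2, 2,
                  dimnames = list(c("x", "y"), c("a", "b")))
  v <- compute_value_matrix(consequence_matrix(perf2, criteria2))
  expect_equal(unname(v[, "a"]), c(0.5, 1))  # 20 clipped to 1
})

test_that("a written matrix reloads with identical values", {
  fx <- huol_fixture()
  tmp <- tempfile(fileext = ".csv")
  write_consequence_matrix(fx$matrix, tmp)
  cm2 <- load_consequence_matrix(tmp, fx$matrix$criteria)
  expect_identical(cm2$alternatives, fx$matrix$alternatives)
  expect_equal(cm2$performance, fx$matrix$performance)
})

test_that("class profile validates thresholds", {
  expect_error(class_profile(c("M", "B", "W"), c(0.7, 0.4)),
               "increasing")
  expect_error(class_profile(c("M", "B", "W"), c(0.4, 1.0)), "inside")
  expect_error(class_profile(c("M", "B"), c(0.4, 0.7)), "exactly 1")
  prof <- class_profile()
  expect_identical(prof$labels, c("M", "B", "W"))
  expect_equal(prof$thresholds, c(0.4, 0.7))
})

test_that("criteria and profile configs round-trip from files", {
  crit_path <- system.file("extdata", "huol_criteria.csv",
                           package = "fitsort")
  criteria <- read_criteria_config(crit_path)
  expect_length(criteria, 5)
  expect_identical(criteria[[4]]$name, "criticality")
  expect_identical(criteria[[4]]$scale_kind, "built")
  prof <- read_class_profile(system.file("extdata", "huol_profile.yaml",
                                         package = "fitsort"))
  expect_equal(prof$thresholds, c(0.4, 0.7))
})
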