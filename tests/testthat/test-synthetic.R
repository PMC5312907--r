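test_that("random molecular graphs are connected, degree-capped and seed-stable", {
  g1 <- generate_random_graphs(30, c(2, 8), odd_ring_probability = 0.5, seed = 42)
  g2 <- generate_random_graphs(30, c(2, 8), odd_ring_probability = 0.5, seed = 42)
  expect_identical(lapply(g1, `[[`, "A"), lapply(g2, `[[`, "A"))
  for (g in g1) {
    expect_true(all(graph_degrees(g) <= 4))
    expect_true(all(is.finite(distance_matrix(g))))   # connected
    expect_true(all(g$elements == "C"))
  }
  expect_error(generate_random_graphs(3, c(1, 1)), "size_range")
})

test_that("ring-free graphs are bipartite so odd walk counts vanish", {
  trees <- generate_random_graphs(20, c(3, 8), odd_ring_probability = 0, seed = 6)
  for (g in trees) expect_equal(srw_count(g, 9), 0)
})

test_that("noise-free linear data recovers the true coefficients exactly", {
  ds <- generate_linear_dataset(30, 9, c("D01", "D05", "D06"),
                                c(0.005, 1.4, -0.8),
                                noise_sd = 0, intercept = -1.2, seed = 17)
  fit <- fit_ols(ds$X[ds$truth$subset], ds$y)
  expect_equal(unname(fit$coefficients[-1]),
               unname(ds$truth$coefficients), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[1]), ds$truth$intercept,
               tolerance = 1e-10)
  expect_equal(fit$stats$R2, 1, tolerance = 1e-12)
})

test_that("generator validates its preconditions", {
  expect_error(generate_linear_dataset(4, 6, c("D01", "D02"), c(1, 2),
                                       seed = 1), "exceed")
  expect_error(generate_linear_dataset(30, 6, c("D01", "D02"), c(1, 2),
                                       noise_sd = -1, seed = 1), "noise_sd")
  expect_error(generate_linear_dataset(30, 6, c("D99"), 1, seed = 1), "pool")
})

test_that("GA recovers a planted subset at moderate signal-to-noise", {
  hits <- 0L
  for (seed in 1:20) {
    ds <- generate_linear_dataset(60, 12, c("D01", "D02", "D03"),
                                  c(0.004, 1.2, 0.9),
                                  noise_sd = 0.26, seed = seed)
    ga <- ga_select(ds$X, ds$y,
                    ga_config(max_vars = 3, min_vars = 3, generations = 80,
                              population = 50, seed = seed))
    if (setequal(ga$size3$subset, ds$truth$subset)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("study-shaped synthetic data has the reference design and is seed-stable", {
  ds <- generate_study_dataset(seed = 4)
  expect_equal(nrow(ds$records), 29L)
  expect_equal(sum(ds$records$split == "test"), 7L)
  expect_equal(dim(as.data.frame(ds$matrix)), c(29L, 7L))  # id + 6 columns
  expect_setequal(setdiff(names(ds$matrix), "id"),
                  c("SRW09", "DipoleZ", "piPC05", "Ram", "X0Av", "ATS6m"))
  expect_identical(generate_study_dataset(seed = 4), ds)
  expect_false(identical(generate_study_dataset(seed = 5)$records$log_conc,
                         ds$records$log_conc))
  expect_true(all(ds$matrix$SRW09 %in% c(0, 504, 684, 702)))
  expect_true(all(ds$matrix$X0Av > 0.5 & ds$matrix$X0Av < 0.8))
})

test_that("the full pipeline recovers the generating subset at low noise", {
  ds <- generate_study_dataset(seed = 12, noise_sd = 0.05)
  sp <- split_dataset(ds$records)
  tr <- match(sp$train$id, ds$matrix$id)
  pool <- ds$matrix[tr, setdiff(names(ds$matrix), "id")]
  ex <- exhaustive_select(pool, sp$train$log_conc, max_vars = 3,
                          fitness = "Q2")
  expect_setequal(ex$size3$subset, ds$truth$subset)
})
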