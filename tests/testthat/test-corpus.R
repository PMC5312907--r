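test_that("packaged dataset has the documented layout and endpoint", {
  solv <- solvent_data()
  expect_s3_class(solv, "solvent_table")
  expect_equal(nrow(solv), 29L)
  expect_equal(solv$id, 1:29)
  expect_equal(sum(solv$split == "test"), 7L)
  expect_equal(solv$id[solv$split == "test"], c(2L, 5L, 12L, 19L, 20L, 21L, 25L))
  expect_equal(solv$name[1], "N-Cyclohexyl-pyrrolidinone")
  expect_equal(solv$conc[1], 3.5)
  expect_equal(solv$split[2], "test")

  # log endpoint agrees with the printed concentration for every compound;
  # one compound's concentration is printed rounded to a single significant
  # digit, so there the check is that the endpoint back-transforms to it
  agree <- abs(solv$log_conc - log10(solv$conc)) <= 0.001
  rounded <- abs(solv$conc - signif(10^solv$log_conc, 1)) < 1e-12
  expect_true(all(agree | rounded))
  expect_equal(sum(!agree), 1L)
})

test_that("log endpoint transform is log10 of mg/mL with domain checks", {
  expect_equal(to_log_endpoint(3.5), 0.544, tolerance = 0.002)
  expect_equal(to_log_endpoint(1), 0)
  expect_equal(to_log_endpoint(2.79e-4), -3.554, tolerance = 0.001)
  expect_error(to_log_endpoint(0), "positive")
  expect_error(to_log_endpoint(-1), "positive")
})

test_that("solvent table round-trips through CSV unchanged", {
  solv <- solvent_data()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_solvent_table(solv, tmp)
  back <- load_solvent_table(tmp, strict = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(solv))
})

test_that("loader rejects malformed tables with the row identified", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name,conc,split", tmp)
  expect_error(load_solvent_table(tmp), "no rows")

  df <- data.frame(id = c(1, 1), name = c("a", "b"), conc = c(1, 2),
                   split = c("train", "train"))
  write.csv(df, tmp, row.names = FALSE)
  expect_error(load_solvent_table(tmp), "duplicate id")

  df <- data.frame(id = 1:2, name = c("a", "b"), conc = c(1, -2),
                   split = c("train", "train"))
  write.csv(df, tmp, row.names = FALSE)
  expect_error(load_solvent_table(tmp), "row 2")

  df <- data.frame(id = 1:2, name = c("a", "b"), conc = c(1, 2),
                   split = c("train", "held-out"))
  write.csv(df, tmp, row.names = FALSE)
  expect_error(load_solvent_table(tmp), "split")

  df <- data.frame(id = 1:3, name = letters[1:3], conc = 1:3,
                   split = rep("train", 3))
  write.csv(df, tmp, row.names = FALSE)
  expect_error(load_solvent_table(tmp, strict = TRUE), "29")
})

test_that("split_dataset partitions by flag preserving order", {
  solv <- solvent_data()
  sp <- split_dataset(solv)
  expect_equal(nrow(sp$train), 22L)
  expect_equal(nrow(sp$test), 7L)
  expect_equal(sort(c(sp$train$id, sp$test$id)), 1:29)
  expect_true(!is.unsorted(sp$train$id))

  all_train <- transform(solv, split = "train")
  sp2 <- split_dataset(all_train)
  expect_equal(nrow(sp2$test), 0L)

  broken <- solv
  broken$split[3] <- "maybe"
  expect_error(split_dataset(broken), "id 3")
})

test_that("reference descriptor matrix is complete with supplied provenance", {
  ref <- reference_descriptors()
  expect_s3_class(ref, "descriptor_matrix")
  expect_equal(nrow(ref), 29L)
  expect_setequal(setdiff(names(ref), "id"),
                  c("SRW09", "DipoleZ", "piPC05", "Ram", "X0Av", "ATS6m"))
  expect_true(all(attr(ref, "provenance") == "supplied"))
  expect_false(anyNA(as.data.frame(ref)))
  expect_true(all(ref$SRW09 >= 0 & ref$piPC05 >= 0 & ref$Ram >= 0))
  expect_true(all(ref$SRW09 == round(ref$SRW09)))
  expect_true(all(ref$Ram == round(ref$Ram)))
})
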