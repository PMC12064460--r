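test_that("bundled banks match the published calibration tables", {
  expect_equal(n_items(anxiety_bank), 15L)
  expect_equal(n_items(depressive_bank), 14L)
  expect_false(anyDuplicated(item_ids(anxiety_bank)) > 0)

  row <- anxiety_bank$items[anxiety_bank$items$item_id == "2230R1r", ]
  expect_equal(row$a, 1.49)
  expect_equal(unlist(row[c("b1", "b2", "b3", "b4")], use.names = FALSE),
               c(0.36, 1.15, 1.83, 2.43))
  row <- depressive_bank$items[depressive_bank$items$item_id == "5047R1r", ]
  expect_equal(row$a, 1.74)
  expect_equal(unlist(row[c("b1", "b2", "b3", "b4")], use.names = FALSE),
               c(-1.24, -0.51, 0.49, 1.38))

  # published parameter ranges
  expect_equal(range(bank_a(anxiety_bank)), c(1.49, 3.57))
  expect_equal(range(bank_b(anxiety_bank)), c(-0.47, 3.18))
  expect_equal(range(bank_b(depressive_bank)), c(-1.24, 2.04))
  expect_equal(range(bank_a(depressive_bank)), c(1.74, 4.36))
})

test_that("item bank validation rejects malformed tables", {
  items <- data.frame(item_id = "x", a = 2, b1 = 0.5, b2 = 0.1, b3 = 1,
                      b4 = 2)
  expect_error(item_bank(items), "non-decreasing.*x")
  expect_error(item_bank(data.frame(item_id = "x", a = 2, b1 = 0)),
               "missing column")
  expect_error(item_bank(data.frame(item_id = "x", a = -1, b1 = 0, b2 = 1,
                                    b3 = 2, b4 = 3)),
               "non-positive discrimination")
  expect_error(item_bank(rbind(anxiety_bank$items, anxiety_bank$items[1, ])),
               "duplicated")
  # file with unordered thresholds is rejected at load
  path <- tempfile(fileext = ".csv")
  write.csv(items, path, row.names = FALSE)
  expect_error(load_item_bank(path), "non-decreasing")
  expect_error(load_item_bank("no_such_fixture"), "no such fixture")
})

test_that("bank serialization round-trips losslessly in CSV and JSON", {
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_item_bank(anxiety_bank, path)
    back <- load_item_bank(path)
    expect_equal(back$items$a, anxiety_bank$items$a, tolerance = 1e-9)
    expect_equal(bank_b(back), bank_b(anxiety_bank), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(item_ids(back), item_ids(anxiety_bank))
  }
})

test_that("response CSV round-trips and dialects shift coding", {
  set.seed(1)
  rm <- simulate_responses(toy_bank(3L), rnorm(20), seed = 1)
  rm$responses[c(2, 17)] <- NA_integer_
  rm <- response_matrix(rm$responses, rm$covariates)

  path <- tempfile(fileext = ".csv")
  write_responses(rm, path)
  back <- read_responses(path, bank = toy_bank(3L))
  expect_identical(unname(back$responses), unname(rm$responses))

  # one_based file holds the same data plus one
  path1 <- tempfile(fileext = ".csv")
  write_responses(rm, path1, dialect = "one_based")
  raw <- read.csv(path1, check.names = FALSE)
  expect_equal(max(raw[item_ids(toy_bank(3L))], na.rm = TRUE),
               max(rm$responses, na.rm = TRUE) + 1L)
  back1 <- read_responses(path1, dialect = "one_based")
  expect_identical(unname(back1$responses), unname(rm$responses))

  # out-of-range value names the position
  bad <- rm
  bad$responses[1, 1] <- 7L
  expect_error(response_matrix(bad$responses), "out of range")
  writeLines(c("i1,i2", "7,0"), path)
  expect_error(read_responses(path), "outside 0..4")
  # unknown item vs the bank
  writeLines(c("zzz,2220R2r", "1,0"), path)
  expect_error(read_responses(path, bank = toy_bank(2L)), "not in bank")
})

test_that("listwise deletion drops exactly the persons with missingness", {
  set.seed(2)
  rm <- simulate_responses(toy_bank(4L), rnorm(60), seed = 2)
  # no missing: identity
  cc <- listwise_complete(rm)
  expect_equal(nrow(cc$responses), 60L)
  expect_equal(attr(cc, "fraction_removed"), 0)

  miss <- rm
  miss$responses[cbind(c(3, 9, 9, 41), c(1, 2, 4, 3))] <- NA_integer_
  miss <- response_matrix(miss$responses, miss$covariates)
  cc <- listwise_complete(miss)
  expect_equal(nrow(cc$responses), 57L)
  expect_equal(attr(cc, "fraction_removed"), 3 / 60)
  expect_false(anyNA(cc$responses))
  # covariates stay aligned with retained persons
  expect_equal(nrow(cc$covariates), 57L)

  all_miss <- miss
  all_miss$responses[, 1] <- NA_integer_
  all_miss <- response_matrix(all_miss$responses)
  expect_error(listwise_complete(all_miss), "empty sample")
})
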