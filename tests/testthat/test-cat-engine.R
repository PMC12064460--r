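test_that("item selection is the exhaustive information argmax with bank-order ties", {
  # starting item: most informative at theta = 0
  info0 <- drop(bank_info(anxiety_bank, 0))
  expect_equal(select_starting_item(anxiety_bank),
               item_ids(anxiety_bank)[which.max(info0)])

  # two identical items: the first wins
  twin <- item_bank(data.frame(item_id = c("x1", "x2"), a = 2, b1 = -1,
                               b2 = 0, b3 = 1, b4 = 2), name = "twin")
  expect_equal(select_starting_item(twin), "x1")
  single <- item_bank(twin$items[1, ], name = "one")
  expect_equal(select_starting_item(single), "x1")

  # next item equals the exhaustive argmax at arbitrary interim thetas
  set.seed(20)
  for (rep in 1:20) {
    th <- runif(1, -3, 3)
    remaining <- sample(item_ids(anxiety_bank), sample(2:15, 1))
    pick <- select_next_item(th, anxiety_bank, remaining)
    info <- drop(bank_info(anxiety_bank, th))[match(remaining,
                                                    item_ids(anxiety_bank))]
    expect_equal(pick, remaining[which.max(info)])
  }
  # at an extreme positive theta, equal-a items are separated by thresholds
  hi_lo <- item_bank(data.frame(item_id = c("low_b", "high_b"), a = 2,
                                b1 = c(-2, 1), b2 = c(-1.5, 1.5),
                                b3 = c(-1, 2), b4 = c(-0.5, 2.5)))
  expect_equal(select_next_item(3, hi_lo, item_ids(hi_lo)), "high_b")
  expect_equal(select_next_item(2, hi_lo, "low_b"), "low_b")
})

test_that("the stop rule bounds and the exhaustion identity hold", {
  set.seed(21)
  rm <- simulate_responses(anxiety_bank, rnorm(40), seed = 21)

  # huge se_stop: stops right at min_items, by the SE rule
  r <- run_cat(rm$responses[1, ], anxiety_bank,
               cat_config(se_stop = 100, min_items = 3L))
  expect_equal(length(r$administered_items), 3L)
  expect_equal(r$stopped_by, "se_rule")

  # tiny se_stop: administers the whole bank; final theta equals the
  # full-bank EAP exactly
  full <- eap_score_matrix(rm, anxiety_bank)
  for (p in 1:5) {
    r <- run_cat(rm$responses[p, ], anxiety_bank,
                 cat_config(se_stop = 1e-6))
    expect_equal(length(r$administered_items), 15L)
    expect_equal(r$stopped_by, "exhausted")
    expect_equal(r$final$theta, full$theta[p], tolerance = 1e-12)
    expect_equal(r$final$se, full$se[p], tolerance = 1e-12)
    expect_false(anyDuplicated(r$administered_items) > 0)
  }

  # missing recorded response: the item is skipped with a warning
  x <- rm$responses[2, ]
  x[select_starting_item(anxiety_bank)] <- NA_integer_
  expect_warning(r2 <- run_cat(x, anxiety_bank, cat_config()), "skipped")
  expect_false(select_starting_item(anxiety_bank) %in% r2$administered_items)
})

test_that("stop-rule soundness implies the reliability target", {
  set.seed(22)
  rm <- simulate_responses(anxiety_bank, rnorm(150), seed = 22)
  sim <- posthoc_cat_simulation(rm, anxiety_bank, cat_config())
  stopped <- sim$per_person$stopped_by == "se_rule"
  expect_true(any(stopped))
  expect_true(all(sim$per_person$se_cat[stopped] <= 0.316))
  expect_true(all(se_to_reliability(sim$per_person$se_cat[stopped]) >= 0.90))
  # never more items than the bank holds
  expect_true(all(sim$per_person$test_length <= n_items(anxiety_bank)))
})

test_that("posterior SD shrinks across steps in nearly all administrations", {
  set.seed(23)
  rm <- simulate_responses(anxiety_bank, rnorm(1000), seed = 23)
  cfg <- cat_config(se_stop = 1e-6)   # run every item to see the whole trace
  drops <- 0L
  steps <- 0L
  parr <- grmcat:::bank_prob_array(anxiety_bank, cfg$grid$nodes)
  for (p in seq_len(1000)) {
    r <- grmcat:::run_cat_internal(rm$responses[p, ], anxiety_bank, cfg, parr)
    d <- diff(r$se_trace)
    drops <- drops + sum(d <= 1e-12)
    steps <- steps + length(d)
  }
  expect_gt(drops / steps, 0.95)
})

test_that("decile summaries show the low-trait long-test gradient", {
  prof <- decile_profile("anxiety")
  th <- thetas_from_decile_means(prof$mean_theta, prof$n_simulees,
                                 jitter_sd = 0.15, seed = 24)
  rm <- simulate_responses(anxiety_bank, th, seed = 25)
  sim <- posthoc_cat_simulation(rm, anxiety_bank, cat_config())
  bd <- sim$by_decile
  expect_equal(nrow(bd), 10L)
  expect_equal(sum(bd$n_simulees), 196L)
  # the lowest measured decile needs the most items and the top half few
  expect_equal(which.max(bd$mean_test_length), 1L)
  expect_true(all(diff(bd$mean_theta) > 0))
  expect_true(all(bd$rmse >= abs(bd$mean_bias) - 1e-12))
  expect_true(all(bd$proportion_stop_satisfied >= 0 &
                    bd$proportion_stop_satisfied <= 1))
  # reliability convention: 1 - mean(SE)^2
  expect_equal(bd$reliability, 1 - bd$mean_se^2)

  # small samples refuse decile summaries but keep the overall block
  small <- posthoc_cat_simulation(
    response_matrix(rm$responses[1:12, ]), anxiety_bank, cat_config())
  expect_null(small$by_decile)
  expect_true(is.finite(small$overall$rmse))
})

test_that("the true-theta reference is honored when requested", {
  prof <- decile_profile("depressive")
  th <- thetas_from_decile_means(prof$mean_theta, prof$n_simulees, seed = 26)
  rm <- simulate_responses(depressive_bank, th, seed = 27)
  sim <- posthoc_cat_simulation(rm, depressive_bank, cat_config(),
                                reference = "true_theta")
  expect_equal(sim$reference, "true_theta")
  expect_equal(sim$per_person$theta_ref, th)
  no_truth <- response_matrix(rm$responses)
  expect_error(posthoc_cat_simulation(no_truth, depressive_bank,
                                      cat_config(), reference = "true_theta"),
               "true_theta")
})
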