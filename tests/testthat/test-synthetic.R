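test_that("simulated response frequencies match the model probabilities", {
  item <- anxiety_bank$items[6, ]            # a = 1.49 item
  bank1 <- item_bank(item, name = "one")
  n <- 20000L
  rm <- simulate_responses(bank1, rep(0, n), seed = 30)
  freq <- tabulate(rm$responses[, 1] + 1L, nbins = 5L) / n
  p <- drop(grm_prob(item$a, unlist(item[paste0("b", 1:4)]), 0))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))

  # reproducibility under the seed
  again <- simulate_responses(bank1, rep(0, n), seed = 30)
  expect_identical(rm$responses, again$responses)

  # enormous discrimination: deterministic Guttman step pattern
  steep <- item_bank(transform(anxiety_bank$items[1, ], a = a * 100))
  th <- seq(-2, 3, by = 0.25)
  det <- simulate_responses(steep, th, seed = 31)$responses[, 1]
  b <- unlist(anxiety_bank$items[1, paste0("b", 1:4)])
  expect_equal(det, vapply(th, function(t) sum(t > b), numeric(1)),
               ignore_attr = TRUE)
})

test_that("the default cohort reproduces the known-group effect-size band", {
  # EAP scoring attenuates the latent separation (0.73 on the theta scale)
  # by roughly the root of the marginal reliability, so per-seed d values
  # scatter around 0.70; the across-seed mean is held to the 0.6-1.0 band.
  ds <- vapply(1:10, function(s) {
    cohort <- generate_cohort(anxiety_bank, cohort_config(seed = s))
    cc <- listwise_complete(cohort)
    tsc <- theta_to_tscore(eap_score_matrix(cc, anxiety_bank)$theta)
    kg <- known_group_analysis(tsc, cc$covariates$sample_type)
    expect_lt(kg$p, 0.001)
    abs(kg$cohens_d)
  }, numeric(1))
  expect_gt(mean(ds), 0.6)
  expect_lt(mean(ds), 1.0)
  expect_true(all(ds > 0.5 & ds < 1.1))
})

test_that("cohort covariates, group sizes and missingness follow the config", {
  cfg <- cohort_config(seed = 32)
  cohort <- generate_cohort(anxiety_bank, cfg)
  expect_equal(dim(cohort$responses), c(928L, 15L))
  expect_equal(table(cohort$covariates$sample_type),
               table(rep(c("cap", "school"), c(291L, 637L))),
               ignore_attr = TRUE)
  expect_lt(abs(missing_fraction(cohort) - 0.034), 0.01)
  expect_equal(length(cohort$covariates$true_theta), 928L)

  # single-group cohort
  solo <- generate_cohort(anxiety_bank, cohort_config(n_cap = 0L, seed = 33))
  expect_equal(unique(solo$covariates$sample_type), "school")

  expect_error(cohort_config(missing_rate = 0.5))
  expect_error(cohort_config(sd_theta = -1))
})

test_that("inject_dif shifts only the selected items and keeps order", {
  ident <- inject_dif(anxiety_bank, "7005", b_shift = 0, a_ratio = 1)
  expect_equal(ident$items[c("a", "b1", "b2", "b3", "b4")],
               anxiety_bank$items[c("a", "b1", "b2", "b3", "b4")])

  shifted <- inject_dif(anxiety_bank, c("7005", "953R1r"), b_shift = 0.5,
                        a_ratio = 2)
  touched <- shifted$items$item_id %in% c("7005", "953R1r")
  expect_equal(bank_b(shifted)[touched, ],
               bank_b(anxiety_bank)[touched, ] + 0.5, ignore_attr = TRUE)
  expect_equal(bank_a(shifted)[touched],
               bank_a(anxiety_bank)[touched] * 2, ignore_attr = TRUE)
  expect_equal(shifted$items[!touched, ], anxiety_bank$items[!touched, ],
               ignore_attr = TRUE)
  expect_error(inject_dif(anxiety_bank, "missing_item", 0.5), "unknown item")
})

test_that("decile-profile trait reconstruction matches counts and means", {
  prof <- decile_profile("anxiety")
  expect_equal(sum(prof$n_simulees), 196L)
  expect_equal(sum(decile_profile("depressive")$n_simulees), 199L)

  exact <- thetas_from_decile_means(prof$mean_theta, prof$n_simulees,
                                    jitter_sd = 0, seed = 1)
  expect_equal(exact, rep(prof$mean_theta, prof$n_simulees))

  jit <- thetas_from_decile_means(prof$mean_theta, prof$n_simulees,
                                  jitter_sd = 0.15, seed = 1)
  expect_equal(length(jit), 196L)
  expect_error(thetas_from_decile_means(c(0, 1), c(5, -1)), "negative")
  expect_error(thetas_from_decile_means(c(0, 1), c(5, 5, 5)))
})

test_that("generated cohorts satisfy the pipeline's structural assumptions", {
  for (s in 1:3) {
    cohort <- generate_cohort(anxiety_bank,
                              cohort_config(n_school = 600L, n_cap = 300L,
                                            seed = 40L + s))
    cc <- listwise_complete(cohort)
    pa <- parallel_analysis(cc, n_random = 10L, seed = s)
    expect_equal(pa$n_factors_retained, 1L)
  }
})
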