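test_that("bivariate normal CDF matches mvtnorm", {
  skip_if_not_installed("mvtnorm")
  for (rho in c(-0.95, -0.4, 0.3, 0.7, 0.95)) {
    for (h in c(-2, -0.5, 0.8)) {
      for (k in c(-1.2, 0, 1.5)) {
        ref <- mvtnorm::pmvnorm(upper = c(h, k),
                                corr = matrix(c(1, rho, rho, 1), 2))[1]
        expect_lt(abs(pbvnorm(h, k, rho) - ref), 1e-10)
      }
    }
  }
  expect_equal(pbvnorm(Inf, 0.3, 0.5), pnorm(0.3))
  expect_equal(pbvnorm(-Inf, 0.3, 0.5), 0)
})

test_that("polychoric estimate recovers the latent correlation", {
  skip_if_not_installed("mvtnorm")
  set.seed(1)
  n <- 5000L
  z <- mvtnorm::rmvnorm(n, sigma = matrix(c(1, 0.5, 0.5, 1), 2))
  cuts <- c(-Inf, 0.36, 1.15, 1.83, 2.43, Inf)
  x <- cbind(i1 = cut(z[, 1], cuts, labels = FALSE) - 1L,
             i2 = cut(z[, 2], cuts, labels = FALSE) - 1L)
  R <- polychoric_matrix(x)
  expect_equal(diag(R), c(i1 = 1, i2 = 1))
  expect_equal(R[1, 2], R[2, 1])
  expect_lt(abs(R[1, 2] - 0.5), 0.05)

  # independent items: off-diagonals within Monte-Carlo noise of zero
  set.seed(2)
  ind <- sapply(1:4, function(j) sample(0:4, 2000, replace = TRUE))
  colnames(ind) <- paste0("i", 1:4)
  Ri <- polychoric_matrix(ind)
  expect_lt(max(abs(Ri[upper.tri(Ri)])), 0.08)

  expect_error(polychoric_matrix(cbind(flat = rep(2L, 50), ok = rep(0:4, 10))),
               "single observed category.*flat")
})

test_that("KMO matches a closed-form oracle and orders structures sensibly", {
  # 3-variable equicorrelated rho = 0.5: partial correlations are 1/3
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  k <- kmo(R)
  r2 <- 6 * 0.5^2
  q2 <- 6 * (1 / 3)^2
  expect_equal(k$overall, r2 / (r2 + q2), tolerance = 1e-10)
  expect_equal(unname(k$per_item), rep(r2 / (r2 + q2), 3), tolerance = 1e-10)

  # one strong common factor (loadings 0.8, 15 items): excellent band
  R1 <- matrix(0.64, 15, 15)
  diag(R1) <- 1
  expect_gt(kmo(R1)$overall, 0.90)

  # block-diagonal two-factor structure scores lower
  R2 <- matrix(0, 14, 14)
  R2[1:7, 1:7] <- 0.64
  R2[8:14, 8:14] <- 0.64
  diag(R2) <- 1
  expect_lt(kmo(R2)$overall, kmo(R1)$overall)
})

test_that("parallel analysis retains one factor for bank-generated data", {
  set.seed(4)
  rm <- simulate_responses(anxiety_bank, rnorm(450), seed = 4)
  pa <- parallel_analysis(rm, n_random = 20L, seed = 5)
  expect_equal(pa$n_factors_retained, 1L)
  expect_gt(pa$first_factor_proportion, 0.20)
  expect_gt(pa$eigen_ratio_1_2, 4)
  expect_true(all(diff(pa$eigenvalues) <= 1e-8))

  # independent items fail every unidimensionality criterion
  set.seed(6)
  ind <- sapply(1:10, function(j) sample(0:4, 400, replace = TRUE))
  colnames(ind) <- paste0("i", 1:10)
  pai <- parallel_analysis(ind, n_random = 20L, seed = 7)
  expect_lt(pai$first_factor_proportion, 0.20)
  expect_lt(pai$eigen_ratio_1_2, 4)
  expect_lte(pai$n_factors_retained, 1L)
})

test_that("least-squares EFA recovers planted loading structures", {
  # rank-1 plus diagonal: exact recovery up to sign
  L <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  R <- tcrossprod(L)
  diag(R) <- 1
  fit <- efa_wls(R, 1L)
  expect_equal(drop(fit$loadings), L, tolerance = 1e-6, ignore_attr = TRUE)

  # agreement with an iterative principal-factor oracle on a 4-item matrix
  R4 <- matrix(c(1, .6, .5, .4,
                 .6, 1, .45, .35,
                 .5, .45, 1, .3,
                 .4, .35, .3, 1), 4, 4)
  pf <- function(R, iters = 200L) {
    h <- 1 - 1 / diag(solve(R))          # SMC start
    for (it in seq_len(iters)) {
      Rh <- R
      diag(Rh) <- h
      e <- eigen(Rh, symmetric = TRUE)
      l <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
      h <- l^2
    }
    abs(l)
  }
  fit4 <- efa_wls(R4, 1L)
  expect_equal(abs(drop(fit4$loadings)), pf(R4), tolerance = 0.02,
               ignore_attr = TRUE)

  # bank-like simulated data carry a dominant first factor
  set.seed(8)
  rm <- simulate_responses(anxiety_bank, rnorm(450), seed = 8)
  fit_anx <- efa_wls(polychoric_matrix(rm$responses), 1L)
  expect_gt(fit_anx$proportion_variance[1], 0.20)
})

test_that("one-factor CFA residuals isolate planted local dependence", {
  L <- seq(0.85, 0.55, length.out = 8)
  R <- tcrossprod(L)
  diag(R) <- 1
  colnames(R) <- rownames(R) <- paste0("i", 1:8)
  fit <- cfa_one_factor(R, n = 500L)
  expect_lt(fit$residual_corr_max, 0.05)
  expect_lt(fit$fit_indices["srmr"], 0.08)
  expect_gt(fit$fit_indices["cfi"], 0.95)
  expect_true(fit$locally_independent)

  # plant an extra correlated pair beyond the common factor
  R2 <- R
  R2["i3", "i6"] <- R2["i6", "i3"] <- R["i3", "i6"] + 0.3
  fit2 <- cfa_one_factor(smooth_psd(R2), n = 500L)
  expect_false(fit2$locally_independent)
  expect_true(any(fit2$locally_dependent_pairs$item_1 == "i3" &
                    fit2$locally_dependent_pairs$item_2 == "i6"))
})

test_that("Mokken scalability is 1 for Guttman data, near 0 for noise, high for the bank", {
  # deterministic Guttman ordering
  th <- seq(-3, 3, length.out = 60)
  guttman <- sapply(1:5, function(i) {
    cuts <- c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf) + 0.15 * i
    as.integer(cut(th, cuts)) - 1L
  })
  colnames(guttman) <- paste0("i", 1:5)
  h <- mokken_h(guttman)
  expect_equal(unname(h$h_per_item), rep(1, 5), tolerance = 1e-12)
  expect_equal(h$h_scale, 1, tolerance = 1e-12)

  # independent items
  set.seed(10)
  ind <- sapply(1:6, function(j) sample(0:4, 1500, replace = TRUE))
  colnames(ind) <- paste0("i", 1:6)
  expect_lt(abs(mokken_h(ind)$h_scale), 0.05)

  # anxiety-bank cohort scales above the 0.50 bank cut-off
  set.seed(5)
  rm <- simulate_responses(anxiety_bank, rnorm(900), seed = 5)
  hb <- mokken_h(rm, n_boot = 20L, seed = 6)
  expect_gt(hb$h_scale, 0.50)
  expect_true(is.finite(hb$standard_error) && hb$standard_error < 0.1)

  expect_error(mokken_h(cbind(flat = rep(1L, 30), ok = rep(0:4, 6))),
               "zero-variance")
})

test_that("the combined assumption report applies the printed cut-off logic", {
  cohort <- generate_cohort(anxiety_bank, cohort_config(n_school = 300L,
                                                        n_cap = 150L,
                                                        seed = 21L))
  rep <- check_irt_assumptions(cohort, seed = 2, n_random = 20L)
  expect_true(rep$unidimensional)
  expect_true(rep$locally_independent)
  expect_true(rep$monotone)
  expect_true(all(rep$kmo_per_item >= 0 & rep$kmo_per_item <= 1))
  expect_gt(rep$h_scale, 0.5)
  expect_output(print(rep), "IRT assumptions")
})
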