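# --- Synthetic response generation --------------------------------------

#' Simulate GRM responses for given trait values
#'
#' Each response is drawn from the item's category probabilities at the
#' person's trait value. The generating trait is stored as the
#' `true_theta` covariate.
#'
#' @param bank an `item_bank`.
#' @param thetas numeric vector of latent trait values.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return `response_matrix` of dimension `length(thetas)` x `n_items(bank)`.
#' @export
simulate_responses <- function(bank, thetas, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- length(thetas)
  m <- n_items(bank)
  a <- bank_a(bank)
  b <- bank_b(bank)
  resp <- matrix(NA_integer_, n, m, dimnames = list(NULL, item_ids(bank)))
  u <- matrix(stats::runif(n * m), n, m)
  for (i in seq_len(m)) {
    # P(X >= k) at each person's theta; response = number of boundaries passed
    pstar <- logistic(a[i] * outer(thetas, b[i, ], "-"))
    resp[, i] <- as.integer(rowSums(u[, i] < pstar))
  }
  response_matrix(resp, covariates = data.frame(true_theta = thetas))
}

#' Cohort configuration for the synthetic two-group design
#'
#' Defaults emulate the validation cohort the package's simulations target:
#' a school sample (n = 637) and a child-and-adolescent-psychiatry (CAP)
#' sample (n = 291) with latent-trait group means obtained by inverting the
#' T-score map from the known-group means (school T 47.7 -> theta -0.23;
#' CAP T 55.0 -> theta 0.50), unit trait SD within group, and 3.4% missing
#' responses completely at random. Female proportions (61.1% school, 71.4%
#' CAP) are used only as grouping labels for DIF checks.
#'
#' @param n_school,n_cap group sizes.
#' @param mean_theta_school,mean_theta_cap latent group means.
#' @param sd_theta within-group trait SD.
#' @param missing_rate MCAR missingness probability (at most 0.2).
#' @param prop_female_school,prop_female_cap proportion labelled female.
#' @param seed RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_school = 637L, n_cap = 291L,
                          mean_theta_school = -0.23, mean_theta_cap = 0.50,
                          sd_theta = 1.0, missing_rate = 0.034,
                          prop_female_school = 0.611,
                          prop_female_cap = 0.714, seed = 1L) {
  stopifnot(n_school >= 0L, n_cap >= 0L, sd_theta > 0,
            missing_rate >= 0, missing_rate <= 0.2)
  structure(list(n_school = n_school, n_cap = n_cap,
                 mean_theta_school = mean_theta_school,
                 mean_theta_cap = mean_theta_cap, sd_theta = sd_theta,
                 missing_rate = missing_rate,
                 prop_female_school = prop_female_school,
                 prop_female_cap = prop_female_cap, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic two-group cohort
#'
#' Latent traits are drawn Normal(group mean, sd) per group, responses are
#' simulated from the bank, missingness is injected completely at random,
#' and covariates (`sample_type`, `sex`, `age_group`, `true_theta`) are
#' attached.
#'
#' @param bank an `item_bank`.
#' @param config a [cohort_config()].
#' @return `response_matrix` with covariates.
#' @export
generate_cohort <- function(bank, config = cohort_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_school + config$n_cap
  sample_type <- rep(c("school", "cap"), c(config$n_school, config$n_cap))
  thetas <- stats::rnorm(n,
                         mean = ifelse(sample_type == "school",
                                       config$mean_theta_school,
                                       config$mean_theta_cap),
                         sd = config$sd_theta)
  prop_f <- ifelse(sample_type == "school", config$prop_female_school,
                   config$prop_female_cap)
  sex <- ifelse(stats::runif(n) < prop_f, "female", "male")
  age_group <- sample(c("12-15", "16-20"), n, replace = TRUE)
  rm <- simulate_responses(bank, thetas)
  resp <- rm$responses
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(resp)) < config$missing_rate,
                   nrow(resp), ncol(resp))
    resp[miss] <- NA_integer_
  }
  response_matrix(resp,
                  covariates = data.frame(sample_type = sample_type,
                                          sex = sex, age_group = age_group,
                                          true_theta = thetas))
}

#' Inject planted DIF into a bank
#'
#' Returns a focal-group version of the bank with the named items' thresholds
#' shifted by `b_shift` (uniform DIF) and/or discriminations multiplied by
#' `a_ratio` (non-uniform DIF). Threshold ordering is preserved.
#'
#' @param bank an `item_bank`.
#' @param ids item ids to alter.
#' @param b_shift additive threshold shift.
#' @param a_ratio multiplicative discrimination change.
#' @return altered `item_bank`.
#' @export
inject_dif <- function(bank, ids, b_shift = 0, a_ratio = 1) {
  unknown <- setdiff(ids, item_ids(bank))
  if (length(unknown) > 0L) {
    stop("unknown item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  items <- bank$items
  rows <- match(ids, items$item_id)
  bcols <- grep("^b[0-9]+$", names(items))
  items[rows, bcols] <- items[rows, bcols] + b_shift
  items[rows, "a"] <- items[rows, "a"] * a_ratio
  item_bank(items, name = paste0(bank$name, "_focal"),
            n_categories = bank$n_categories)
}

#' Rebuild a trait distribution from decile summaries
#'
#' Places `counts[i]` trait values at `decile_means[i]` plus
#' Normal(0, `jitter_sd`) noise — used to reconstruct a validation sample
#' whose trait distribution matches a published decile profile.
#'
#' @param decile_means decile mean trait values.
#' @param counts simulees per decile (same length).
#' @param jitter_sd SD of the within-decile jitter (default 0.15, small
#'   relative to decile spacing).
#' @param seed RNG seed (`NULL` = current RNG state).
#' @return numeric vector of length `sum(counts)`.
#' @export
thetas_from_decile_means <- function(decile_means, counts, jitter_sd = 0.15,
                                     seed = NULL) {
  stopifnot(length(decile_means) == length(counts))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  mu <- rep(decile_means, counts)
  mu + stats::rnorm(length(mu), 0, jitter_sd)
}

#' Bundled decile trait profiles
#'
#' Decile-level mean trait values and simulee counts of the post-hoc CAT
#' validation samples (n = 196 anxiety, n = 199 depressive; the lowest
#' reported decile pools the floor), used with
#' [thetas_from_decile_means()] to rebuild matching validation samples.
#'
#' @param name `"anxiety"` or `"depressive"`.
#' @return data frame with columns `decile`, `mean_theta`, `n_simulees`.
#' @export
decile_profile <- function(name = c("anxiety", "depressive")) {
  name <- match.arg(name)
  utils::read.csv(system.file("extdata",
                              paste0("decile_profile_", name, ".csv"),
                              package = "grmcat", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
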