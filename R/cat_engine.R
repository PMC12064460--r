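# --- Post-hoc computerized adaptive testing -----------------------------

#' CAT configuration
#'
#' @param se_stop standard-error stopping rule: the test ends once the EAP
#'   posterior SD falls to or below this value (default 0.316, i.e.
#'   reliability 0.90).
#' @param max_items largest number of items to administer (`NULL` = bank
#'   size).
#' @param min_items smallest number of items before the stop rule applies.
#' @param selection_rule item selection criterion; only maximum Fisher
#'   information (`"MFI"`) is implemented.
#' @param estimator interim/final trait estimator; only `"EAP"`.
#' @param grid a `quadrature_grid`.
#' @return object of class `cat_config`.
#' @export
cat_config <- function(se_stop = 0.316, max_items = NULL, min_items = 1L,
                       selection_rule = "MFI", estimator = "EAP",
                       grid = default_grid()) {
  stopifnot(se_stop > 0, min_items >= 1L)
  selection_rule <- match.arg(selection_rule, "MFI")
  estimator <- match.arg(estimator, "EAP")
  structure(list(se_stop = se_stop, max_items = max_items,
                 min_items = as.integer(min_items),
                 selection_rule = selection_rule, estimator = estimator,
                 grid = grid),
            class = "cat_config")
}

#' Starting item: most informative at the population mean
#'
#' The item with the highest Fisher information at theta = 0, the average
#' trait level in the reference population; ties break by bank order.
#'
#' @param bank an `item_bank`.
#' @return item id.
#' @export
select_starting_item <- function(bank) {
  stopifnot(n_items(bank) > 0L)
  info <- drop(bank_info(bank, 0))
  item_ids(bank)[which.max(info)]
}

#' Next item by maximum Fisher information
#'
#' @param theta current interim trait estimate.
#' @param bank an `item_bank`.
#' @param remaining ids of the not-yet-administered items.
#' @return item id maximizing information at `theta` (ties break by bank
#'   order).
#' @export
select_next_item <- function(theta, bank, remaining) {
  stopifnot(length(remaining) > 0L)
  idx <- match(remaining, item_ids(bank))
  info <- drop(bank_info(bank, theta))[idx]
  remaining[which.max(info)]
}

#' Run a post-hoc CAT for one person
#'
#' Replays the adaptive algorithm against a fully recorded response vector:
#' starting with the most informative item at theta = 0, responses are
#' looked up (never generated), the EAP estimate is updated after each
#' administration, and the next item is the most informative at the current
#' estimate. The test stops when the posterior SD reaches `config$se_stop`
#' (after at least `min_items` items), or when items are exhausted. Items
#' with a missing recorded response are skipped with a warning.
#'
#' @param responses_row integer vector of recorded responses (0..4, `NA`
#'   allowed), in bank item order.
#' @param bank an `item_bank`.
#' @param config a [cat_config()].
#' @return object of class `cat_result`: list with `administered_items`,
#'   `theta_trace`, `se_trace`, `final` (a `theta_estimate`), `stopped_by`
#'   (`"se_rule"` or `"exhausted"`).
#' @export
run_cat <- function(responses_row, bank, config = cat_config()) {
  grid <- config$grid
  parr <- bank_prob_array(bank, grid$nodes)
  run_cat_internal(responses_row, bank, config, parr)
}

# Inner loop with the probability array precomputed (shared across persons
# by posthoc_cat_simulation).
run_cat_internal <- function(responses_row, bank, config, parr) {
  ids <- item_ids(bank)
  max_items <- if (is.null(config$max_items)) n_items(bank) else
    min(config$max_items, n_items(bank))
  grid <- config$grid
  a <- bank_a(bank)
  b <- bank_b(bank)

  post <- grid$weights
  theta <- 0
  administered <- character(0L)
  theta_trace <- numeric(0L)
  se_trace <- numeric(0L)
  remaining <- seq_len(n_items(bank))
  stopped_by <- "exhausted"
  se <- 1

  while (length(administered) < max_items && length(remaining) > 0L) {
    info <- vapply(remaining, function(i) grm_item_info(a[i], b[i, ], theta),
                   numeric(1L))
    pick <- remaining[which.max(info)]
    if (is.na(responses_row[pick])) {
      warning("no recorded response for item ", ids[pick], "; skipped")
      remaining <- setdiff(remaining, pick)
      next
    }
    post <- post * parr[, pick, responses_row[pick] + 1L]
    post <- post / sum(post)
    theta <- sum(post * grid$nodes)
    se <- sqrt(sum(post * (grid$nodes - theta)^2))
    administered <- c(administered, ids[pick])
    theta_trace <- c(theta_trace, theta)
    se_trace <- c(se_trace, se)
    remaining <- setdiff(remaining, pick)
    if (length(administered) >= config$min_items && se <= config$se_stop) {
      stopped_by <- "se_rule"
      break
    }
  }
  structure(list(administered_items = administered,
                 theta_trace = theta_trace,
                 se_trace = se_trace,
                 final = structure(list(theta = theta, se = se,
                                        n_items_used = length(administered)),
                                   class = "theta_estimate"),
                 stopped_by = stopped_by),
            class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("CAT: %d items, theta = %.3f (SE %.3f), stopped by %s\n",
              length(x$administered_items), x$final$theta, x$final$se,
              x$stopped_by))
  cat(" order:", paste(x$administered_items, collapse = " -> "), "\n")
  invisible(x)
}

#' Post-hoc CAT simulation over a response matrix
#'
#' Runs [run_cat()] for every person, then summarizes performance against a
#' reference trait value: by default the full-bank EAP estimate from all
#' recorded responses, optionally the simulees' true generating trait when
#' present in the covariates. Persons are ranked by the reference value and
#' cut into ten equal deciles (ties broken by person order); per-decile and
#' overall bias, RMSE, test length, SE, stop-rule satisfaction and marginal
#' reliability (1 - mean SE^2) are reported.
#'
#' @param matrix `response_matrix` with complete recorded responses.
#' @param bank `item_bank` used for both the CAT and full-bank scoring.
#' @param config a [cat_config()].
#' @param reference `"full_bank"` (default) or `"true_theta"`.
#' @return object of class `cat_simulation`: list with `per_person`
#'   (data frame), `by_decile` (data frame, `NULL` when n < 20), `overall`
#'   (named list), and `reference` (which reference trait was used).
#' @export
posthoc_cat_simulation <- function(matrix, bank, config = cat_config(),
                                   reference = c("full_bank", "true_theta")) {
  reference <- match.arg(reference)
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  n <- nrow(resp)
  grid <- config$grid
  parr <- bank_prob_array(bank, grid$nodes)

  full <- eap_score_matrix(resp, bank, grid)
  runs <- lapply(seq_len(n), function(p) {
    run_cat_internal(resp[p, ], bank, config, parr)
  })
  per_person <- data.frame(
    person = rownames(resp) %||% seq_len(n),
    theta_cat = vapply(runs, function(r) r$final$theta, numeric(1L)),
    se_cat = vapply(runs, function(r) r$final$se, numeric(1L)),
    test_length = vapply(runs, function(r) length(r$administered_items),
                         numeric(1L)),
    stopped_by = vapply(runs, function(r) r$stopped_by, character(1L)),
    theta_full = full$theta,
    se_full = full$se)
  if (reference == "true_theta") {
    tt <- matrix$covariates$true_theta
    if (is.null(tt)) {
      stop("reference = 'true_theta' but no true_theta covariate present",
           call. = FALSE)
    }
    per_person$theta_ref <- tt
  } else {
    per_person$theta_ref <- per_person$theta_full
  }

  summarize <- function(d) {
    err <- d$theta_cat - d$theta_ref
    list(mean_theta = mean(d$theta_ref),
         rmse = sqrt(mean(err^2)),
         mean_bias = mean(err),
         mean_test_length = mean(d$test_length),
         mean_se = mean(d$se_cat),
         proportion_stop_satisfied = mean(d$stopped_by == "se_rule"),
         reliability = 1 - mean(d$se_cat)^2)
  }

  by_decile <- NULL
  if (n >= 20L) {
    ord <- order(per_person$theta_ref)
    dec <- integer(n)
    dec[ord] <- ceiling(seq_len(n) / (n / 10))
    per_person$decile <- dec
    by_decile <- do.call(rbind, lapply(1:10, function(d) {
      s <- summarize(per_person[per_person$decile == d, ])
      data.frame(decile = paste0("D", d), n_simulees = sum(dec == d),
                 as.data.frame(s))
    }))
  }
  overall <- summarize(per_person)
  overall$correlation_cat_vs_full <- stats::cor(per_person$theta_cat,
                                                per_person$theta_full)
  structure(list(per_person = per_person, by_decile = by_decile,
                 overall = overall, reference = reference),
            class = "cat_simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cat_simulation <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Post-hoc CAT simulation (n = %d, reference = %s)\n",
              nrow(x$per_person), x$reference))
  cat(sprintf(" mean test length %.2f | RMSE %.2f | bias %.2f | r(CAT, full) %.3f | stop rule met %.2f\n",
              o$mean_test_length, o$rmse, o$mean_bias,
              o$correlation_cat_vs_full, o$proportion_stop_satisfied))
  if (!is.null(x$by_decile)) {
    print(format(x$by_decile, digits = 3L), row.names = FALSE)
  }
  invisible(x)
}
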