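# --- Sample splitting, known-group validity, floor/ceiling --------------

#' Random evaluation/validation split
#'
#' Disjoint, exhaustive, reproducible split of `1..n`;
#' `|evaluation| = round(fraction * n)`.
#'
#' @param n number of persons.
#' @param fraction evaluation fraction (in (0.5, 0.95); the calibrate-then-
#'   simulate design uses slightly under 80%).
#' @param seed RNG seed.
#' @return list with integer vectors `evaluation` and `validation`.
#' @export
split_sample <- function(n, fraction = 0.78, seed = 1L) {
  stopifnot(n >= 2L)
  if (fraction <= 0.5 || fraction >= 0.95) {
    stop("fraction must lie in (0.5, 0.95)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  n_eval <- round(fraction * n)
  list(evaluation = sort(idx[seq_len(n_eval)]),
       validation = sort(idx[-seq_len(n_eval)]))
}

#' Known-group analysis of T-scores
#'
#' Welch two-sample t-test (unequal variances) between the two groups plus
#' pooled-SD Cohen's d with a normal-approximation 95% confidence interval.
#' Effect-size band labels follow the usual convention: |d| of 0.2 is small,
#' 0.5 medium, 0.8 large.
#'
#' @param tscores numeric vector of T-scores.
#' @param groups two-level grouping vector, same length.
#' @return object of class `known_group_result`: list with the group means,
#'   `t_statistic`, `df`, `p`, `cohens_d`, `d_ci`, `band`.
#' @export
known_group_analysis <- function(tscores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  x <- tscores[groups == levels(groups)[1L]]
  y <- tscores[groups == levels(groups)[2L]]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  band <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "medium" else
    if (abs(d) >= 0.2) "small" else "negligible"
  structure(list(groups = levels(groups),
                 mean_t = c(mean(x), mean(y)),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 cohens_d = d,
                 d_ci = c(d - 1.96 * se_d, d + 1.96 * se_d),
                 band = band),
            class = "known_group_result")
}

#' @export
print.known_group_result <- function(x, ...) {
  cat(sprintf("Known-group analysis: %s %.2f vs %s %.2f\n",
              x$groups[1L], x$mean_t[1L], x$groups[2L], x$mean_t[2L]))
  cat(sprintf(" Welch t = %.3f, df = %.2f, p = %.3g\n",
              x$t_statistic, x$df, x$p))
  cat(sprintf(" Cohen's d = %.2f, 95%% CI [%.2f, %.2f] (%s)\n",
              x$cohens_d, x$d_ci[1L], x$d_ci[2L], x$band))
  invisible(x)
}

#' Floor and ceiling effects
#'
#' Percentage of complete-case persons at the minimum and maximum possible
#' raw summed score; a percentage above `cutoff` (15% by convention) flags
#' an important floor/ceiling effect.
#'
#' @param matrix `response_matrix` (complete rows are used).
#' @param cutoff flag threshold in percent.
#' @return list with `floor_pct`, `ceiling_pct`, `floor_flag`,
#'   `ceiling_flag`, `n`.
#' @export
floor_ceiling <- function(matrix, cutoff = 15) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  resp <- resp[stats::complete.cases(resp), , drop = FALSE]
  total <- rowSums(resp)
  fl <- 100 * mean(total == 0)
  ce <- 100 * mean(total == 4 * ncol(resp))
  list(floor_pct = fl, ceiling_pct = ce,
       floor_flag = fl > cutoff, ceiling_flag = ce > cutoff,
       n = nrow(resp))
}

# --- Full pipeline ------------------------------------------------------

#' Run the full validation pipeline
#'
#' Orchestrates the analysis end to end on one item bank's data: listwise
#' deletion; IRT assumption checks on a random half split; random
#' evaluation/validation split; GRM calibration on the evaluation sample
#' with S-X2 item fit; DIF scans for the requested group comparisons;
#' known-group and floor/ceiling statistics; and the post-hoc CAT simulation
#' on the validation sample — with the calibrated bank and, optionally, with
#' a hybrid bank built from user-supplied reference parameters and a DIF
#' item list via Stocking-Lord linking.
#'
#' @param matrix `response_matrix` with covariates.
#' @param bank `item_bank` naming the columns (used for item ids; the CAT
#'   runs on freshly calibrated parameters).
#' @param dif_comparisons covariate column names to scan for DIF.
#' @param evaluation_fraction evaluation share of the split.
#' @param seed master seed; stage seeds are derived from it.
#' @param cat_se_stop stopping rule for the CAT simulation.
#' @param reference_bank optional `item_bank` on a reference metric for the
#'   hybrid CAT run.
#' @param reference_dif_items item ids to take (Stocking-Lord transformed)
#'   from the local calibration when building the hybrid bank.
#' @param n_random parallel-analysis replicates for the assumption checks.
#' @param fit_tol,fit_max_cycles EM settings passed to [fit_grm()].
#' @param output_dir optional directory; when given, stage outputs are
#'   written there as CSV/JSON.
#' @return object of class `pipeline_result`: list with `assumptions`,
#'   `calibration` (fitted bank), `item_fit`, `dif` (per comparison),
#'   `known_group`, `floor_ceiling`, `cat_swedish` (calibrated-parameter
#'   run), `cat_hybrid` (or `NULL`), `split`, `seeds`.
#' @export
run_full_pipeline <- function(matrix, bank,
                              dif_comparisons = c("sex", "age_group",
                                                  "sample_type"),
                              evaluation_fraction = 0.78, seed = 1L,
                              cat_se_stop = 0.316,
                              reference_bank = NULL,
                              reference_dif_items = character(0L),
                              n_random = 100L,
                              fit_tol = 1e-4, fit_max_cycles = 500L,
                              output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- list(assumptions = seed + 101L, split = seed + 202L)

  cc <- stage("listwise_deletion", listwise_complete(matrix))
  assumptions <- stage("assumptions",
                       check_irt_assumptions(cc, seed = seeds$assumptions,
                                             n_random = n_random))
  n <- nrow(cc$responses)
  split <- stage("split", split_sample(n, evaluation_fraction, seeds$split))
  eval_rm <- response_matrix(cc$responses[split$evaluation, , drop = FALSE],
                             cc$covariates[split$evaluation, , drop = FALSE])
  valid_rm <- response_matrix(cc$responses[split$validation, , drop = FALSE],
                              cc$covariates[split$validation, , drop = FALSE])

  calibration <- stage("grm_calibration",
                       fit_grm(eval_rm, tol = fit_tol,
                               max_cycles = fit_max_cycles,
                               name = paste0(bank$name, "_calibrated")))
  item_fit <- stage("s_x2", sx2_item_fit(eval_rm, calibration))

  dif <- lapply(dif_comparisons, function(cmp) {
    stage(paste0("dif_", cmp), dif_scan(cc, cmp, calibration))
  })
  names(dif) <- dif_comparisons

  scores <- stage("scoring", eap_score_matrix(cc, calibration))
  tsc <- theta_to_tscore(scores$theta)
  known_group <- if (!is.null(cc$covariates$sample_type) &&
                     length(unique(cc$covariates$sample_type)) == 2L) {
    stage("known_group", known_group_analysis(tsc, cc$covariates$sample_type))
  } else NULL
  fc <- stage("floor_ceiling", floor_ceiling(cc))

  cat_cfg <- cat_config(se_stop = cat_se_stop)
  cat_swedish <- stage("cat_calibrated",
                       posthoc_cat_simulation(valid_rm, calibration, cat_cfg))
  cat_hybrid <- NULL
  if (!is.null(reference_bank)) {
    hybrid <- stage("linking",
                    build_hybrid_bank(reference_bank, calibration,
                                      reference_dif_items))
    cat_hybrid <- stage("cat_hybrid",
                        posthoc_cat_simulation(valid_rm, hybrid, cat_cfg))
  }

  out <- structure(list(assumptions = assumptions,
                        calibration = calibration,
                        item_fit = item_fit, dif = dif,
                        known_group = known_group, floor_ceiling = fc,
                        cat_swedish = cat_swedish, cat_hybrid = cat_hybrid,
                        split = split, seeds = seeds),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

#' Write pipeline outputs to disk
#'
#' One file per stage: the calibrated parameter/item-fit table (CSV,
#' mirroring the bank-table schema `item_id, a, b1..b4, s_x2, df, p`), DIF
#' tables (CSV), the decile-level CAT table (CSV), and a JSON summary.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grm_table <- merge(result$calibration$items, result$item_fit,
                     by = "item_id", sort = FALSE)
  utils::write.csv(grm_table, file.path(dir, "grm_parameters.csv"),
                   row.names = FALSE)
  for (cmp in names(result$dif)) {
    utils::write.csv(result$dif[[cmp]],
                     file.path(dir, paste0("dif_", cmp, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$cat_swedish$by_decile,
                   file.path(dir, "cat_deciles.csv"), row.names = FALSE)
  summary_json <- list(
    assumptions = list(kmo = result$assumptions$kmo_overall,
                       unidimensional = result$assumptions$unidimensional,
                       locally_independent = result$assumptions$locally_independent,
                       monotone = result$assumptions$monotone,
                       h_scale = result$assumptions$h_scale),
    known_group = if (!is.null(result$known_group)) {
      list(mean_t = result$known_group$mean_t,
           t = result$known_group$t_statistic, df = result$known_group$df,
           cohens_d = result$known_group$cohens_d)
    },
    floor_ceiling = result$floor_ceiling,
    cat_overall = result$cat_swedish$overall,
    seeds = result$seeds)
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("=== Validation pipeline ===\n")
  print(x$assumptions)
  cat(sprintf("\nGRM calibration: %d items, %s (%d EM cycles)\n",
              n_items(x$calibration),
              if (attr(x$calibration, "converged")) "converged"
              else "NOT converged", attr(x$calibration, "n_cycles")))
  cat(sprintf("Item fit: %d/%d items adequate (p > 0.001)\n",
              sum(x$item_fit$fit_ok, na.rm = TRUE), nrow(x$item_fit)))
  for (cmp in names(x$dif)) {
    flagged <- x$dif[[cmp]]$item_id[which(x$dif[[cmp]]$flagged)]
    cat(sprintf("DIF (%s): %s\n", cmp,
                if (length(flagged)) paste(flagged, collapse = ", ")
                else "none"))
  }
  if (!is.null(x$known_group)) print(x$known_group)
  cat(sprintf("Floor %.2f%%, ceiling %.2f%%\n",
              x$floor_ceiling$floor_pct, x$floor_ceiling$ceiling_pct))
  cat("\nPost-hoc CAT (calibrated parameters):\n")
  print(x$cat_swedish)
  if (!is.null(x$cat_hybrid)) {
    cat("\nPost-hoc CAT (hybrid reference parameters):\n")
    print(x$cat_hybrid)
  }
  invisible(x)
}
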