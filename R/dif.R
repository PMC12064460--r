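# --- Proportional-odds fitting ------------------------------------------

# Direct optimizer for the cumulative-logit likelihood, used as a
# ridge-stabilized fallback when the main fitter fails (e.g. complete
# separation). Cutpoints are parameterized as first value plus log-gaps.
.polr_optim <- function(y, X, ridge = 0) {
  K <- length(unique(y))
  lev <- sort(unique(y))
  yy <- match(y, lev)
  X <- as.matrix(X)
  p <- ncol(X)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    z <- par[p + 1L] + c(0, cumsum(exp(par[(p + 2L):(p + K - 1L)])))
    eta <- drop(X %*% beta)
    cum <- cbind(0, stats::plogis(outer(-eta, z, "+")), 1)
    pr <- cum[cbind(seq_along(yy), yy + 1L)] - cum[cbind(seq_along(yy), yy)]
    -sum(log(pmax(pr, 1e-300))) + ridge * sum(beta^2)
  }
  marg <- cumsum(tabulate(yy, K))[-K] / length(yy)
  start <- c(rep(0, p), stats::qlogis(marg)[1L],
             log(pmax(diff(stats::qlogis(marg)), 1e-3)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  beta <- opt$par[seq_len(p)]
  z <- opt$par[p + 1L] + c(0, cumsum(exp(opt$par[(p + 2L):(p + K - 1L)])))
  list(coefficients = stats::setNames(beta, colnames(X)),
       cutpoints = z,
       log_likelihood = -(opt$value - ridge * sum(beta^2)))
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Cumulative-logit model \eqn{logit P(Y \le k) = \zeta_k - x'\beta} fit by
#' maximum likelihood via [MASS::polr()]. On failure (typically complete
#' separation) a ridge-stabilized direct optimization is used instead, with
#' a warning. With no covariates the closed-form intercept-only
#' log-likelihood \eqn{\sum_k n_k \log(n_k/n)} is returned.
#'
#' @param y ordinal responses (integers 0..4; unobserved categories are
#'   merged upward before fitting).
#' @param X covariate matrix / data frame (or `NULL` for the null model).
#' @return list with `coefficients`, `cutpoints`, `log_likelihood`.
#' @export
ordinal_logistic_fit <- function(y, X = NULL) {
  y <- as.integer(y)
  if (is.null(X) || NCOL(X) == 0L) {
    nk <- table(y)
    return(list(coefficients = numeric(0L), cutpoints = numeric(0L),
                log_likelihood = sum(nk * log(nk / length(y)))))
  }
  X <- as.matrix(X)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  fit <- tryCatch({
    df <- data.frame(.y = factor(y, levels = sort(unique(y)), ordered = TRUE),
                     X)
    pf <- MASS::polr(.y ~ ., data = df, Hess = FALSE)
    list(coefficients = pf$coefficients, cutpoints = pf$zeta,
         log_likelihood = as.numeric(stats::logLik(pf)))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("proportional-odds fit unstable; ridge-stabilized refit used")
    fit <- .polr_optim(y, X, ridge = 1e-4)
  }
  fit
}

#' McFadden pseudo-R-squared change between nested fits
#'
#' \eqn{R^2_m = 1 - \ell_m / \ell_0}; the change between a smaller and a
#' larger nested model is the DIF flagging statistic.
#'
#' @param loglik_small,loglik_large log-likelihoods of the nested fits
#'   (larger model must not fit worse beyond numerical tolerance).
#' @param loglik_null intercept-only log-likelihood on the same rows.
#' @return the (non-negative up to 1e-8) R-squared change.
#' @export
mcfadden_delta_r2 <- function(loglik_small, loglik_large, loglik_null) {
  if (loglik_large < loglik_small - 1e-6) {
    stop("models are not nested: larger model has lower log-likelihood",
         call. = FALSE)
  }
  (1 - loglik_large / loglik_null) - (1 - loglik_small / loglik_null)
}

# Merge unobserved categories upward so the ordinal fitter sees consecutive
# observed levels; the H-ordering of the remaining categories is preserved.
.merge_categories <- function(y) {
  match(y, sort(unique(y))) - 1L
}

#' Scan an item bank for differential item functioning
#'
#' Per item, three nested proportional-odds models are fit with the EAP
#' latent-trait estimate (from all bank items) as the matching variable:
#' trait only; trait + group; trait + group + trait-by-group interaction.
#' Uniform DIF is flagged when the McFadden pseudo-R-squared change from the
#' first to the second model reaches `threshold` (default 2%), non-uniform
#' DIF when the second-to-third change does. One purification round
#' (re-estimating the matching trait without flagged items, then rescanning)
#' is run by default.
#'
#' @param matrix `response_matrix` with complete responses for the bank's
#'   items (listwise deletion applied otherwise).
#' @param group two-level grouping vector (length = persons), or the name of
#'   a covariate column.
#' @param bank `item_bank` the columns of `matrix` correspond to.
#' @param threshold pseudo-R-squared change cut-off.
#' @param purify run one purification round after the initial scan.
#' @param min_group_n smallest group size accepted.
#' @param grid quadrature grid for the matching-trait EAP estimates.
#' @return data frame (class `dif_result`) with one row per item:
#'   `item_id`, `r2_null_to_uniform`, `r2_uniform_to_nonuniform`,
#'   `r2_total`, `flagged`, `dif_type`.
#' @export
dif_scan <- function(matrix, group, bank, threshold = 0.02, purify = TRUE,
                     min_group_n = 25L, grid = default_grid()) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  if (is.character(group) && length(group) == 1L) {
    group <- matrix$covariates[[group]]
  }
  keep <- stats::complete.cases(resp) & !is.na(group)
  resp <- resp[keep, , drop = FALSE]
  group <- factor(group[keep])
  if (nlevels(group) != 2L) {
    stop("group must have exactly two levels", call. = FALSE)
  }
  if (any(table(group) < min_group_n)) {
    warning(sprintf("a group level has fewer than %d complete rows; all items skipped",
                    min_group_n))
    return(structure(data.frame(item_id = item_ids(bank),
                                r2_null_to_uniform = NA_real_,
                                r2_uniform_to_nonuniform = NA_real_,
                                r2_total = NA_real_, flagged = NA,
                                dif_type = NA_character_),
                     class = c("dif_result", "data.frame")))
  }
  g <- as.numeric(group) - 1

  scan_once <- function(theta) {
    res <- lapply(seq_len(n_items(bank)), function(i) {
      y <- .merge_categories(resp[, i])
      ll0 <- ordinal_logistic_fit(y)$log_likelihood
      ll1 <- ordinal_logistic_fit(y, cbind(theta = theta))$log_likelihood
      ll2 <- ordinal_logistic_fit(y, cbind(theta = theta, group = g))$log_likelihood
      ll3 <- ordinal_logistic_fit(
        y, cbind(theta = theta, group = g, tg = theta * g))$log_likelihood
      d_unif <- mcfadden_delta_r2(ll1, ll2, ll0)
      d_nonu <- mcfadden_delta_r2(ll2, ll3, ll0)
      dif_type <- if (d_nonu >= threshold) "nonuniform" else
        if (d_unif >= threshold) "uniform" else "none"
      data.frame(item_id = item_ids(bank)[i],
                 r2_null_to_uniform = d_unif,
                 r2_uniform_to_nonuniform = d_nonu,
                 r2_total = mcfadden_delta_r2(ll1, ll3, ll0),
                 flagged = dif_type != "none",
                 dif_type = dif_type)
    })
    do.call(rbind, res)
  }

  theta <- eap_score_matrix(resp, bank, grid)$theta
  result <- scan_once(theta)
  if (purify && any(result$flagged)) {
    anchor <- item_ids(bank)[!result$flagged]
    if (length(anchor) > 0L) {
      resp_anchor <- resp
      resp_anchor[, result$flagged] <- NA_integer_
      theta2 <- eap_score_matrix(resp_anchor, bank, grid)$theta
      result <- scan_once(theta2)
    }
  }
  structure(result, class = c("dif_result", "data.frame"))
}
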