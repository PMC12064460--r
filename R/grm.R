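#' Quadrature grid for latent-trait integration
#'
#' Equally spaced nodes with standard-normal weights, renormalized to sum to
#' one. The same grid is used by the EM calibration, EAP scoring and
#' information summaries; the latent trait is taken to range over roughly
#' \eqn{[-4, 4]}.
#'
#' @param n_nodes number of nodes (default 61).
#' @param range lower/upper bound of the grid.
#' @return object of class `quadrature_grid`: list with `nodes` (increasing)
#'   and `weights` (positive, summing to 1).
#' @export
make_quadrature <- function(n_nodes = 61L, range = c(-4, 4)) {
  nodes <- seq(range[1L], range[2L], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

default_grid <- function() make_quadrature()

logistic <- function(x) 1 / (1 + exp(-x))

#' Graded-response-model category probabilities
#'
#' Samejima's model for an item with discrimination `a` and ordered
#' thresholds `b`: the cumulative (boundary) curves are
#' \eqn{P^*_k(\theta) = 1 / (1 + e^{-a(\theta - b_k)})} for k = 1..4 (logistic
#' metric, D = 1), and category probabilities are adjacent differences with
#' \eqn{P^*_0 = 1}, \eqn{P^*_5 = 0}.
#'
#' @param a discrimination (> 0).
#' @param b numeric vector of 4 non-decreasing thresholds.
#' @param theta latent trait value(s).
#' @return matrix `length(theta)` x 5 of category probabilities (rows sum
#'   to 1).
#' @examples
#' p <- grm_prob(1.49, c(0.36, 1.15, 1.83, 2.43), 0)
#' rowSums(p)  # 1
#' @export
grm_prob <- function(a, b, theta) {
  pstar <- cbind(1, logistic(a * outer(theta, b, "-")), 0)
  p <- pstar[, 1:5, drop = FALSE] - pstar[, 2:6, drop = FALSE]
  # guard against tiny negative values from floating-point cancellation
  p[p < 0] <- 0
  dimnames(p) <- list(NULL, paste0("cat", 0:4))
  p
}

#' GRM item Fisher information
#'
#' \eqn{I(\theta) = \sum_k (P^{*\prime}_k - P^{*\prime}_{k+1})^2 / P_k} where
#' the boundary-curve derivative is \eqn{a P^*_k (1 - P^*_k)}.
#'
#' @inheritParams grm_prob
#' @return numeric vector of information values (>= 0), one per `theta`.
#' @export
grm_item_info <- function(a, b, theta) {
  pstar <- cbind(1, logistic(a * outer(theta, b, "-")), 0)
  dstar <- a * pstar * (1 - pstar)      # zero in the two padding columns
  p <- pstar[, 1:5, drop = FALSE] - pstar[, 2:6, drop = FALSE]
  dp <- dstar[, 1:5, drop = FALSE] - dstar[, 2:6, drop = FALSE]
  rowSums(ifelse(p > 0, dp^2 / pmax(p, .Machine$double.xmin), 0))
}

#' Per-item information across a bank
#'
#' @param bank an `item_bank`.
#' @param theta latent trait value(s).
#' @return matrix `length(theta)` x `n_items(bank)`, columns named by item.
#' @export
bank_info <- function(bank, theta) {
  a <- bank_a(bank)
  b <- bank_b(bank)
  out <- vapply(seq_len(n_items(bank)),
                function(i) grm_item_info(a[i], b[i, ], theta),
                numeric(length(theta)))
  out <- matrix(out, nrow = length(theta),
                dimnames = list(NULL, item_ids(bank)))
  out
}

#' Test information and its standard-error curve
#'
#' Test information is the sum of item informations; the corresponding
#' standard error is \eqn{SE(\theta) = 1 / \sqrt{I(\theta)}}.
#'
#' @inheritParams bank_info
#' @param items optional subset of item ids.
#' @return for `test_info()`, a numeric vector; for `test_se()`, the
#'   reciprocal square root.
#' @export
test_info <- function(bank, theta, items = NULL) {
  info <- bank_info(bank, theta)
  if (!is.null(items)) info <- info[, items, drop = FALSE]
  rowSums(info)
}

#' @rdname test_info
#' @export
test_se <- function(bank, theta, items = NULL) {
  1 / sqrt(test_info(bank, theta, items))
}

#' Expected item score under the GRM
#'
#' @inheritParams grm_prob
#' @return expected response (0..4), non-decreasing in `theta`.
#' @export
grm_expected_score <- function(a, b, theta) {
  drop(grm_prob(a, b, theta) %*% (0:4))
}

#' Test characteristic curve
#'
#' Sum of expected item scores over (a subset of) the bank.
#'
#' @inheritParams test_info
#' @return numeric vector of expected summed scores.
#' @export
tcc <- function(bank, theta, items = NULL) {
  a <- bank_a(bank)
  b <- bank_b(bank)
  idx <- if (is.null(items)) seq_len(n_items(bank)) else
    match(items, item_ids(bank))
  out <- numeric(length(theta))
  for (i in idx) out <- out + grm_expected_score(a[i], b[i, ], theta)
  out
}

# Category-probability array over a grid: nodes x items x 5. Shared by the
# EM calibration, EAP scoring and the CAT engine.
bank_prob_array <- function(bank, nodes) {
  a <- bank_a(bank)
  b <- bank_b(bank)
  arr <- array(NA_real_, c(length(nodes), n_items(bank), 5L),
               dimnames = list(NULL, item_ids(bank), NULL))
  for (i in seq_len(n_items(bank))) {
    arr[, i, ] <- grm_prob(a[i], b[i, ], nodes)
  }
  arr
}

#' Expected-a-posteriori trait estimate
#'
#' Posterior mean and standard deviation of the latent trait under a
#' standard-normal prior (carried by the quadrature weights), given one
#' person's responses. Missing responses are skipped in the likelihood; with
#' no answered items the prior mean/SD is returned.
#'
#' @param responses_row integer vector of responses 0..4 (`NA` = missing), in
#'   bank item order.
#' @param bank an `item_bank`.
#' @param grid a `quadrature_grid` (default: 61 nodes on \[-4, 4\]).
#' @return object of class `theta_estimate`: list with `theta`, `se`
#'   (posterior SD) and `n_items_used`.
#' @export
eap_score <- function(responses_row, bank, grid = default_grid()) {
  parr <- bank_prob_array(bank, grid$nodes)
  est <- eap_from_array(responses_row, parr, grid)
  structure(est, class = "theta_estimate")
}

# Core EAP computation given the precomputed probability array.
eap_from_array <- function(responses_row, parr, grid) {
  post <- grid$weights
  used <- which(!is.na(responses_row))
  for (i in used) {
    post <- post * parr[, i, responses_row[i] + 1L]
  }
  z <- sum(post)
  post <- post / z
  theta <- sum(post * grid$nodes)
  se <- sqrt(sum(post * (grid$nodes - theta)^2))
  list(theta = theta, se = se, n_items_used = length(used))
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta = %.3f (SE %.3f, %d items)\n",
              x$theta, x$se, x$n_items_used))
  invisible(x)
}

#' EAP scores for a whole response matrix
#'
#' @param matrix a `response_matrix` (or bare integer matrix) with columns in
#'   bank order.
#' @inheritParams eap_score
#' @return data frame with columns `theta`, `se`, `n_items_used`, one row per
#'   person.
#' @export
eap_score_matrix <- function(matrix, bank, grid = default_grid()) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  parr <- bank_prob_array(bank, grid$nodes)
  out <- t(vapply(seq_len(nrow(resp)), function(p) {
    est <- eap_from_array(resp[p, ], parr, grid)
    c(est$theta, est$se, est$n_items_used)
  }, numeric(3L)))
  data.frame(theta = out[, 1L], se = out[, 2L],
             n_items_used = as.integer(out[, 3L]),
             row.names = rownames(resp))
}

#' Theta / T-score conversions
#'
#' The PROMIS T-score metric is the affine map \eqn{T = 10\theta + 50}
#' (mean 50, SD 10 in the reference population).
#'
#' @param theta latent trait value(s).
#' @param tscore T-score value(s).
#' @return the converted score(s).
#' @examples
#' theta_to_tscore(0)      # 50
#' tscore_to_theta(55.0)   # 0.5
#' @export
theta_to_tscore <- function(theta) 10 * theta + 50

#' @rdname theta_to_tscore
#' @export
tscore_to_theta <- function(tscore) (tscore - 50) / 10

#' Standard error to marginal reliability
#'
#' reliability = 1 - SE^2 on the standard-normal trait metric; an SE of
#' 0.316 corresponds to reliability 0.90 and 0.548 to 0.70.
#'
#' @param se positive standard error(s).
#' @return reliability value(s) (can be negative for SE > 1).
#' @export
se_to_reliability <- function(se) {
  stopifnot(all(se > 0))
  1 - se^2
}
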