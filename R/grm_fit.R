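# --- Marginal maximum likelihood calibration of the GRM -----------------

# Parameter transform used by the per-item M-step optimizer: a is optimized
# on the log scale and thresholds as b1 plus log-gaps, which enforces a > 0
# and non-decreasing b without constraints.
.par_pack <- function(a, b) {
  d <- diff(b)
  c(log(a), b[1L], log(pmax(d, 1e-6)))
}

.par_unpack <- function(p) {
  list(a = exp(p[1L]), b = p[2L] + c(0, cumsum(exp(p[3:5]))))
}

# Expected complete-data log-likelihood for one item given expected counts
# r (nodes x 5) at the quadrature nodes.
.item_ecll <- function(p, r, nodes) {
  pars <- .par_unpack(p)
  prob <- grm_prob(pars$a, pars$b, nodes)
  sum(r * log(pmax(prob, 1e-300)))
}

.start_values <- function(x, n_categories = 5L) {
  n <- length(x)
  ge <- vapply(seq_len(n_categories - 1L),
               function(k) mean(x >= k), numeric(1L))
  ge <- pmin(pmax(ge, 1 / (2 * n)), 1 - 1 / (2 * n))
  b <- -stats::qlogis(ge) / 1.5
  b <- pmin(pmax(b, -4), 4)
  # enforce a strictly increasing start
  for (k in seq_along(b)[-1L]) b[k] <- max(b[k], b[k - 1L] + 0.05)
  list(a = 1.5, b = b)
}

#' Calibrate a graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM with a fixed quadrature grid and a standard-normal latent
#' density. The E-step computes posterior node weights per person and
#' expected category counts per node; the M-step maximizes each item's
#' expected complete-data log-likelihood by quasi-Newton iterations on an
#' unconstrained reparameterization (log discrimination, first threshold,
#' log threshold gaps). The marginal log-likelihood is non-decreasing across
#' cycles; convergence is declared when the largest absolute parameter change
#' falls below `tol`.
#'
#' @param matrix a listwise-complete `response_matrix` (or integer matrix,
#'   persons x items, values 0..4).
#' @param grid a `quadrature_grid`.
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_cycles maximum number of EM cycles.
#' @param name label for the returned bank.
#' @return an `item_bank` of estimated parameters with attributes
#'   `loglik_trace` (marginal log-likelihood per cycle), `converged`, and
#'   `n_cycles`.
#' @export
fit_grm <- function(matrix, grid = default_grid(), tol = 1e-4,
                    max_cycles = 500L, name = "fitted") {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  if (anyNA(resp)) {
    stop("calibration requires listwise-complete data; see listwise_complete()",
         call. = FALSE)
  }
  m <- ncol(resp)
  ids <- colnames(resp)
  if (is.null(ids)) ids <- paste0("item", seq_len(m))
  n_obs_cat <- apply(resp, 2L, function(x) length(unique(x)))
  if (any(n_obs_cat < 2L)) {
    stop("item(s) with a single observed category: ",
         paste(ids[n_obs_cat < 2L], collapse = ", "), call. = FALSE)
  }

  # collapse identical response patterns for speed
  pat_key <- apply(resp, 1L, paste, collapse = ",")
  first <- !duplicated(pat_key)
  patterns <- resp[first, , drop = FALSE]
  counts <- as.vector(table(pat_key)[pat_key[first]])

  pars <- lapply(seq_len(m), function(i) .start_values(resp[, i]))
  nodes <- grid$nodes
  nq <- length(nodes)
  trace <- numeric(0L)
  converged <- FALSE

  for (cycle in seq_len(max_cycles)) {
    # E-step: posterior over nodes for each response pattern
    logp <- array(NA_real_, c(nq, m, 5L))
    for (i in seq_len(m)) {
      logp[, i, ] <- log(pmax(grm_prob(pars[[i]]$a, pars[[i]]$b, nodes),
                              1e-300))
    }
    ll_mat <- matrix(0, nrow(patterns), nq)
    for (i in seq_len(m)) {
      ll_mat <- ll_mat + t(logp[, i, ])[patterns[, i] + 1L, , drop = FALSE]
    }
    lw <- sweep(ll_mat, 2L, log(grid$weights), "+")
    mx <- apply(lw, 1L, max)
    post <- exp(lw - mx)
    marg <- rowSums(post)
    trace <- c(trace, sum(counts * (log(marg) + mx)))
    post <- counts * post / marg            # pattern-weighted posteriors

    # M-step: per-item quasi-Newton on the expected complete-data loglik
    max_change <- 0
    for (i in seq_len(m)) {
      r <- vapply(0:4, function(k) {
        rows <- patterns[, i] == k
        if (any(rows)) colSums(post[rows, , drop = FALSE]) else numeric(nq)
      }, numeric(nq))
      p0 <- .par_pack(pars[[i]]$a, pars[[i]]$b)
      opt <- stats::optim(p0, .item_ecll, r = r, nodes = nodes,
                          method = "L-BFGS-B",
                          lower = c(-4.6, -6, rep(-13, 3L)),
                          upper = c(3, 6, rep(2.5, 3L)),
                          control = list(fnscale = -1))
      new <- .par_unpack(opt$par)
      max_change <- max(max_change, abs(new$a - pars[[i]]$a),
                        abs(new$b - pars[[i]]$b))
      pars[[i]] <- new
    }
    if (max_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d cycles (last change %.2g)",
                    max_cycles, max_change))
  }
  items <- data.frame(item_id = ids,
                      a = vapply(pars, `[[`, numeric(1L), "a"),
                      b1 = vapply(pars, function(p) p$b[1L], numeric(1L)),
                      b2 = vapply(pars, function(p) p$b[2L], numeric(1L)),
                      b3 = vapply(pars, function(p) p$b[3L], numeric(1L)),
                      b4 = vapply(pars, function(p) p$b[4L], numeric(1L)))
  out <- item_bank(items, name = name)
  attr(out, "loglik_trace") <- trace
  attr(out, "converged") <- converged
  attr(out, "n_cycles") <- length(trace)
  out
}

# --- Lord-Wingersky summed-score recursion ------------------------------

#' Summed-score distribution by the Lord-Wingersky recursion
#'
#' Probability of each summed score (0..4m) over a set of GRM items,
#' conditional on each quadrature node.
#'
#' @param parr category-probability array (nodes x items x 5) as produced by
#'   the internal grid machinery, or an `item_bank` (with `nodes` supplied).
#' @param nodes quadrature nodes (used when `parr` is an `item_bank`).
#' @return matrix nodes x (4m + 1); each row sums to 1.
#' @export
lord_wingersky <- function(parr, nodes = NULL) {
  if (inherits(parr, "item_bank")) {
    if (is.null(nodes)) nodes <- default_grid()$nodes
    parr <- bank_prob_array(parr, nodes)
  }
  nq <- dim(parr)[1L]
  m <- dim(parr)[2L]
  f <- matrix(1, nq, 1L)
  for (i in seq_len(m)) {
    s_max <- ncol(f) - 1L
    new <- matrix(0, nq, s_max + 5L)
    for (k in 0:4) {
      cols <- seq_len(s_max + 1L) + k
      new[, cols] <- new[, cols] + f * parr[, i, k + 1L]
    }
    f <- new
  }
  colnames(f) <- paste0("s", 0:(ncol(f) - 1L))
  f
}

# --- Orlando-Thissen S-X2 item fit --------------------------------------

# Merge adjacent category cells within one summed-score row until every
# expected count reaches `floor_`; a row that collapses to a single cell
# carries no information and is dropped by the caller.
.collapse_cells_in_row <- function(o, e, floor_ = 1) {
  while (length(e) > 1L && min(e) < floor_) {
    j <- which.min(e)
    nb <- if (j == 1L) 2L else if (j == length(e)) j - 1L else
      if (e[j - 1L] < e[j + 1L]) j - 1L else j + 1L
    e[nb] <- e[nb] + e[j]
    o[nb] <- o[nb] + o[j]
    o <- o[-j]
    e <- e[-j]
  }
  list(o = o, e = e)
}

#' Orlando-Thissen S-X2 item-fit statistics
#'
#' For each item, observed category frequencies conditional on the total
#' summed score are compared with model-expected frequencies obtained by
#' integrating the Lord-Wingersky rest-score distribution against the
#' standard-normal latent density. Within each summed-score group, adjacent
#' category cells are merged until every expected count reaches 1; groups
#' left with a single cell are dropped. The Pearson statistic is referred to
#' a chi-square with df = (cells after collapsing) - (score groups) -
#' (item parameters, when estimated from the same data). Items are flagged
#' as adequately fitting when p > 0.001.
#'
#' @param matrix listwise-complete `response_matrix` (or integer matrix) the
#'   bank was calibrated on.
#' @param bank calibrated `item_bank`.
#' @param grid a `quadrature_grid`.
#' @param alpha significance level for the adequacy flag.
#' @param params_estimated were the bank's parameters estimated from this
#'   same data? If `TRUE` (the calibration-then-fit workflow) the degrees of
#'   freedom are reduced by the 5 item parameters; set `FALSE` when the
#'   parameters are known a priori (e.g. simulation studies with generating
#'   values).
#' @return data frame with columns `item_id`, `s_x2`, `df`, `p`, `fit_ok`.
#' @export
sx2_item_fit <- function(matrix, bank, grid = default_grid(), alpha = 0.001,
                         params_estimated = TRUE) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  stopifnot(!anyNA(resp))
  m <- n_items(bank)
  stopifnot(ncol(resp) == m)
  parr <- bank_prob_array(bank, grid$nodes)
  full <- lord_wingersky(parr)                       # nodes x (4m+1)
  marg_s <- colSums(grid$weights * full)             # P(S = s)
  total <- rowSums(resp)
  n_s <- tabulate(total + 1L, nbins = 4L * m + 1L)

  out <- lapply(seq_len(m), function(i) {
    rest <- lord_wingersky(parr[, -i, , drop = FALSE])  # nodes x (4(m-1)+1)
    smax_rest <- ncol(rest) - 1L
    obs <- NULL
    exp_ <- NULL
    for (s in 0:(4L * m)) {
      ks <- (0:4)[s - (0:4) >= 0 & s - (0:4) <= smax_rest]
      if (length(ks) < 2L || n_s[s + 1L] == 0L || marg_s[s + 1L] <= 0) next
      o_row <- rep(NA_real_, 5L)
      e_row <- rep(NA_real_, 5L)
      e_prop <- vapply(ks, function(k) {
        sum(grid$weights * parr[, i, k + 1L] * rest[, s - k + 1L])
      }, numeric(1L)) / marg_s[s + 1L]
      o_row[ks + 1L] <- vapply(ks, function(k) {
        sum(total == s & resp[, i] == k)
      }, numeric(1L))
      e_row[ks + 1L] <- n_s[s + 1L] * e_prop
      obs <- rbind(obs, o_row)
      exp_ <- rbind(exp_, e_row)
    }
    if (is.null(obs)) {
      warning("item ", item_ids(bank)[i], " skipped: no scorable cells")
      return(data.frame(item_id = item_ids(bank)[i], s_x2 = NA_real_,
                        df = NA_integer_, p = NA_real_, fit_ok = NA))
    }
    x2 <- 0
    n_cells <- 0L
    n_rows <- 0L
    for (r in seq_len(nrow(obs))) {
      nz <- which(!is.na(exp_[r, ]))
      cc <- .collapse_cells_in_row(obs[r, nz], exp_[r, nz])
      if (length(cc$e) < 2L) next
      x2 <- x2 + sum((cc$o - cc$e)^2 / pmax(cc$e, 1e-12))
      n_cells <- n_cells + length(cc$e)
      n_rows <- n_rows + 1L
    }
    df <- n_cells - n_rows - if (params_estimated) 5L else 0L
    if (df < 1L) {
      warning("item ", item_ids(bank)[i],
              " skipped: not enough cells after collapsing")
      return(data.frame(item_id = item_ids(bank)[i], s_x2 = x2,
                        df = NA_integer_, p = NA_real_, fit_ok = NA))
    }
    p <- stats::pchisq(x2, df, lower.tail = FALSE)
    data.frame(item_id = item_ids(bank)[i], s_x2 = x2, df = as.integer(df),
               p = p, fit_ok = p > alpha)
  })
  do.call(rbind, out)
}
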