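# --- Bivariate normal CDF ----------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1L, ]^2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  .gl_cache[[key]] <- out
  out
}

#' Standard bivariate normal CDF
#'
#' \eqn{\Phi_2(h, k; \rho) = P(X \le h, Y \le k)} for standard normal X, Y
#' with correlation `rho`, computed from the single-integral representation
#' \eqn{\Phi(h)\Phi(k) + \frac{1}{2\pi}\int_0^{\rho} (1-r^2)^{-1/2}
#' \exp\{-(h^2 - 2hkr + k^2)/(2(1-r^2))\}\,dr}
#' by Gauss-Legendre quadrature, vectorized over `(h, k)` pairs. Infinite
#' bounds are handled exactly.
#'
#' @param h,k upper integration limits (recycled to common length).
#' @param rho correlation in (-1, 1).
#' @param n_nodes quadrature order.
#' @return vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho, n_nodes = 48L) {
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn)
  k <- rep_len(k, nn)
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(out)
  finite <- is.finite(h) & is.finite(k)
  # when one bound is infinite the joint CDF collapses to a marginal
  out[h == -Inf | k == -Inf] <- 0
  idx <- which(finite)
  if (length(idx)) {
    gl <- gauss_legendre(n_nodes)
    r <- rho / 2 * (gl$nodes + 1)            # map [-1,1] -> [0, rho]
    wr <- abs(rho) / 2 * gl$weights
    hh <- h[idx]
    kk <- k[idx]
    om <- 1 - r^2
    # matrix: pairs x nodes
    expo <- exp(-(outer(hh^2 + kk^2, rep(1, length(r))) -
                    2 * outer(hh * kk, r)) /
                  (2 * matrix(om, length(idx), length(r), byrow = TRUE)))
    corr_term <- (expo / matrix(sqrt(om), length(idx), length(r),
                                byrow = TRUE)) %*% wr
    out[idx] <- out[idx] + sign(rho) * drop(corr_term) / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# --- Polychoric correlation --------------------------------------------

# Thresholds from marginal category proportions (qnorm of the cumulative
# distribution); empty categories produce duplicated thresholds which give
# zero-probability cells and drop out of the likelihood.
.poly_thresholds <- function(counts) {
  n <- sum(counts)
  cum <- cumsum(counts)[-length(counts)] / n
  stats::qnorm(pmin(pmax(cum, 1e-12), 1 - 1e-12))
}

# Two-step ML estimate of the latent correlation for one pair from the
# cross-tabulation `tab`.
.polychoric_pair <- function(tab, bound = 0.999) {
  tx <- c(-Inf, .poly_thresholds(rowSums(tab)), Inf)
  ty <- c(-Inf, .poly_thresholds(colSums(tab)), Inf)
  nr <- nrow(tab)
  nc <- ncol(tab)
  hi <- rep(tx[-1L], nc)
  hj <- rep(ty[-1L], each = nr)
  li <- rep(tx[-(nr + 1L)], nc)
  lj <- rep(ty[-(nc + 1L)], each = nr)
  nvec <- as.vector(tab)
  obs <- nvec > 0
  negll <- function(rho) {
    p <- pbvnorm(hi, hj, rho) - pbvnorm(li, hj, rho) -
      pbvnorm(hi, lj, rho) + pbvnorm(li, lj, rho)
    -sum(nvec[obs] * log(pmax(p[obs], 1e-300)))
  }
  stats::optimize(negll, c(-bound, bound), tol = 1e-5)$minimum
}

#' Polychoric correlation matrix
#'
#' Two-step maximum-likelihood polychoric estimates for every item pair:
#' thresholds from the marginal category proportions via normal quantiles,
#' then a one-dimensional likelihood maximization over the latent
#' correlation. The result is smoothed to the nearest positive semi-definite
#' matrix by eigenvalue clipping if needed (attribute `"smoothed"`).
#'
#' @param matrix listwise-complete `response_matrix` or integer matrix
#'   (values 0..4).
#' @param bound search bound for the correlation.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(matrix, bound = 0.999) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  stopifnot(!anyNA(resp))
  m <- ncol(resp)
  ids <- colnames(resp)
  single <- apply(resp, 2L, function(x) length(unique(x)) < 2L)
  if (any(single)) {
    stop("item(s) with a single observed category: ",
         paste(if (is.null(ids)) which(single) else ids[single],
               collapse = ", "), call. = FALSE)
  }
  R <- diag(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      tab <- table(factor(resp[, i], levels = 0:4),
                   factor(resp[, j], levels = 0:4))
      R[i, j] <- R[j, i] <- .polychoric_pair(tab, bound)
    }
  }
  dimnames(R) <- list(ids, ids)
  smooth_psd(R)
}

#' Smooth a correlation matrix to positive semi-definiteness
#'
#' Eigenvalue clipping at a small floor followed by rescaling to a unit
#' diagonal; sets attribute `"smoothed"` when clipping was applied.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor_ smallest allowed eigenvalue.
#' @return correlation matrix.
#' @export
smooth_psd <- function(R, floor_ = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor_) {
    attr(R, "smoothed") <- FALSE
    return(R)
  }
  vals <- pmax(e$values, floor_)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(R)
  attr(out, "smoothed") <- TRUE
  out
}

# --- Kaiser-Meyer-Olkin -------------------------------------------------

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' \eqn{KMO = \sum r^2 / (\sum r^2 + \sum q^2)} over off-diagonal entries,
#' where q are the anti-image partial correlations derived from the inverse
#' correlation matrix; the per-item analog restricts the sums to one row.
#' Values above 0.90 are conventionally "excellent", above 0.70 "moderate",
#' below 0.50 "unacceptable".
#'
#' @param corr correlation matrix (invertible, smooth first if needed).
#' @return list with `overall` and `per_item`.
#' @export
kmo <- function(corr) {
  inv <- tryCatch(solve(corr),
                  error = function(e) stop("correlation matrix is singular",
                                           call. = FALSE))
  s <- diag(inv)
  q <- -inv / sqrt(tcrossprod(s))
  diag(q) <- 0
  r <- corr
  diag(r) <- 0
  overall <- sum(r^2) / (sum(r^2) + sum(q^2))
  per_item <- rowSums(r^2) / (rowSums(r^2) + rowSums(q^2))
  names(per_item) <- colnames(corr)
  list(overall = overall, per_item = per_item)
}

# --- Parallel analysis --------------------------------------------------

#' Parallel analysis on polychoric eigenvalues
#'
#' Compares the eigenvalues of the observed polychoric correlation matrix
#' with the mean eigenvalues of `n_random` datasets of independent ordinal
#' variables whose marginal category proportions match the data. Factors
#' whose observed eigenvalue exceeds the random mean are retained.
#'
#' @param matrix listwise-complete `response_matrix` or integer matrix.
#' @param n_random number of random comparison datasets.
#' @param seed RNG seed.
#' @return list with `eigenvalues`, `random_means`, `n_factors_retained`,
#'   `first_factor_proportion` (first eigenvalue / number of items) and
#'   `eigen_ratio_1_2`.
#' @export
parallel_analysis <- function(matrix, n_random = 100L, seed = 1L) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  ev <- eigen(polychoric_matrix(resp), symmetric = TRUE,
              only.values = TRUE)$values
  m <- ncol(resp)
  n <- nrow(resp)
  rand <- matrix(NA_real_, n_random, m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(n_random)) {
    sim <- vapply(seq_len(m), function(j) sample(resp[, j], n, replace = TRUE),
                  integer(n))
    colnames(sim) <- colnames(resp)
    rand[r, ] <- eigen(polychoric_matrix(sim), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  rmeans <- colMeans(rand)
  below <- which(ev <= rmeans)
  list(eigenvalues = ev, random_means = rmeans,
       n_factors_retained = if (length(below)) below[1L] - 1L else m,
       first_factor_proportion = ev[1L] / m,
       eigen_ratio_1_2 = ev[1L] / ev[2L])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- Factor analysis ----------------------------------------------------

#' Least-squares exploratory factor analysis of a correlation matrix
#'
#' Extracts `n_factors` factors by minimizing the (optionally weighted)
#' least-squares discrepancy between off-diagonal observed and model-implied
#' correlations, \eqn{\sum_{i<j} w_{ij}(r_{ij} - (\Lambda\Lambda')_{ij})^2},
#' by quasi-Newton iterations from a principal-component start.
#'
#' @param corr correlation matrix.
#' @param n_factors number of factors.
#' @param weights optional weight matrix (default: all 1, i.e. unweighted
#'   least squares).
#' @return list with `loadings` (p x q), `proportion_variance` (per factor,
#'   sum of squared loadings / p), `eigenvalues` of `corr`, and
#'   `communalities`.
#' @export
efa_wls <- function(corr, n_factors = 1L, weights = NULL) {
  p <- ncol(corr)
  if (is.null(weights)) weights <- matrix(1, p, p)
  off <- upper.tri(corr)
  e <- eigen(corr, symmetric = TRUE)
  L0 <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(n_factors)], 1e-8)), n_factors)
  objective <- function(v) {
    L <- matrix(v, p, n_factors)
    imp <- tcrossprod(L)
    sum(weights[off] * (corr[off] - imp[off])^2)
  }
  opt <- stats::optim(as.vector(L0), objective, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  L <- matrix(opt$par, p, n_factors)
  comm <- rowSums(L^2)
  if (any(comm > 1)) {
    warning("Heywood case: communalities > 1 clipped")
    scale <- pmin(1, 1 / sqrt(comm))
    L <- L * scale
    comm <- rowSums(L^2)
  }
  # orient each factor so its loading sum is positive
  for (q in seq_len(n_factors)) if (sum(L[, q]) < 0) L[, q] <- -L[, q]
  rownames(L) <- colnames(corr)
  list(loadings = L, proportion_variance = colSums(L^2) / p,
       eigenvalues = e$values, communalities = comm)
}

#' One-factor confirmatory model with residual-correlation diagnostics
#'
#' Fits a single-factor model to a (polychoric) correlation matrix by
#' unweighted least squares and reports the residual correlations
#' (observed minus model-implied), flagging pairs with absolute residual
#' above `ld_cutoff` as locally dependent. Fit indices (CFI, TLI, RMSEA,
#' SRMR) are computed from the maximum-likelihood discrepancy at the
#' least-squares solution with the standard formulas; they approximate, but
#' do not reproduce, scaled robust DWLS values.
#'
#' @param corr correlation matrix.
#' @param n sample size behind `corr`.
#' @param ld_cutoff local-dependence residual threshold.
#' @return list with `loadings`, `fit_indices` (cfi, tli, rmsea, srmr),
#'   `residual_corr`, `residual_corr_max`, `locally_dependent_pairs`
#'   (data frame), `locally_independent` (logical).
#' @export
cfa_one_factor <- function(corr, n, ld_cutoff = 0.20) {
  p <- ncol(corr)
  stopifnot(n > p)
  fit <- efa_wls(corr, 1L)
  lambda <- drop(fit$loadings)
  implied <- tcrossprod(lambda)
  diag(implied) <- 1
  resid <- corr - implied
  diag(resid) <- 0

  # ML discrepancy at the LS solution, for approximate fit indices
  f_ml <- function(S, Sigma) {
    inv <- solve(Sigma)
    as.numeric(determinant(Sigma)$modulus -
                 determinant(S)$modulus + sum(inv * S) - p)
  }
  Tm <- (n - 1) * f_ml(corr, implied)
  df <- p * (p + 1) / 2 - 2 * p
  Tb <- (n - 1) * f_ml(corr, diag(p))
  dfb <- p * (p - 1) / 2
  cfi <- 1 - max(Tm - df, 0) / max(Tb - dfb, Tm - df, .Machine$double.eps)
  tli <- ((Tb / dfb) - (Tm / df)) / ((Tb / dfb) - 1)
  rmsea <- sqrt(max(Tm - df, 0) / (df * (n - 1)))
  off <- upper.tri(corr)
  srmr <- sqrt(mean(resid[off]^2))

  flag <- which(abs(resid) > ld_cutoff & upper.tri(resid), arr.ind = TRUE)
  ids <- colnames(corr)
  if (is.null(ids)) ids <- paste0("item", seq_len(p))
  pairs <- data.frame(item_1 = ids[flag[, 1L]], item_2 = ids[flag[, 2L]],
                      residual = resid[flag])
  list(loadings = lambda,
       fit_indices = c(cfi = cfi, tli = min(tli, 1), rmsea = rmsea,
                       srmr = srmr),
       residual_corr = resid,
       residual_corr_max = max(abs(resid)),
       locally_dependent_pairs = pairs,
       locally_independent = nrow(pairs) == 0L)
}

# --- Mokken scalability -------------------------------------------------

# Maximal covariance between two ordinal items given their marginals: the
# comonotonic (north-west corner) coupling maximizes E[XY].
.covmax_pair <- function(counts_i, counts_j, n) {
  mi <- sum((0:4) * counts_i) / n
  mj <- sum((0:4) * counts_j) / n
  ci <- counts_i
  cj <- counts_j
  ki <- 1L
  kj <- 1L
  exy <- 0
  while (ki <= 5L && kj <= 5L) {
    if (ci[ki] == 0L) { ki <- ki + 1L; next }
    if (cj[kj] == 0L) { kj <- kj + 1L; next }
    mass <- min(ci[ki], cj[kj])
    exy <- exy + mass * (ki - 1L) * (kj - 1L)
    ci[ki] <- ci[ki] - mass
    cj[kj] <- cj[kj] - mass
  }
  exy / n - mi * mj
}

#' Mokken scalability coefficients
#'
#' Loevinger-type scalability: for each pair,
#' \eqn{H_{ij} = cov(X_i, X_j) / cov_{max}(X_i, X_j)} with the maximal
#' covariance given by the marginal-preserving comonotonic (Guttman-ordered)
#' coupling. Item and scale coefficients are covariance-weighted aggregates.
#' Conventional cut-offs: items scalable at H >= 0.30, the scale at
#' H >= 0.50. The scale standard error is available by bootstrap.
#'
#' @param matrix listwise-complete `response_matrix` or integer matrix.
#' @param n_boot bootstrap replicates for the scale-H standard error
#'   (0 = skip, returns `NA`).
#' @param seed bootstrap seed.
#' @return list with `h_per_item` (named), `h_scale`, `standard_error`.
#' @export
mokken_h <- function(matrix, n_boot = 0L, seed = 1L) {
  resp <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  stopifnot(!anyNA(resp))
  if (any(apply(resp, 2L, stats::var) == 0)) {
    bad <- which(apply(resp, 2L, stats::var) == 0)
    stop("zero-variance item(s): ",
         paste(if (is.null(colnames(resp))) bad else colnames(resp)[bad],
               collapse = ", "), call. = FALSE)
  }
  h_stats <- function(resp) {
    m <- ncol(resp)
    n <- nrow(resp)
    counts <- apply(resp, 2L, function(x) tabulate(x + 1L, nbins = 5L))
    cv <- stats::cov(resp) * (n - 1) / n
    cvmax <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        cvmax[i, j] <- cvmax[j, i] <- .covmax_pair(counts[, i], counts[, j], n)
      }
    }
    diag(cv) <- 0
    h_item <- rowSums(cv) / rowSums(cvmax)
    names(h_item) <- colnames(resp)
    list(h_per_item = h_item,
         h_scale = sum(cv[upper.tri(cv)]) / sum(cvmax[upper.tri(cvmax)]))
  }
  est <- h_stats(resp)
  se <- NA_real_
  if (n_boot > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    hs <- replicate(n_boot, {
      h_stats(resp[sample(nrow(resp), replace = TRUE), , drop = FALSE])$h_scale
    })
    se <- stats::sd(hs)
  }
  c(est, list(standard_error = se))
}

# --- Combined assumption report -----------------------------------------

#' Check the IRT assumptions for an item bank's response data
#'
#' Runs the unidimensionality, local-independence, and monotonicity checks
#' on listwise-complete data. To avoid exploring and confirming on the same
#' respondents, the sample is randomly split in half: KMO, parallel analysis
#' and EFA run on the first half, the one-factor model and residual
#' correlations on the second; Mokken scalability uses the full sample.
#' Verdicts apply the conventional cut-offs: first factor explaining at
#' least 20% of the variance with a first/second eigenvalue ratio above 4
#' and one factor retained by parallel analysis (unidimensional); no
#' residual correlation above 0.20 (locally independent); item H >= 0.30 and
#' scale H >= 0.50 (monotone).
#'
#' @param matrix `response_matrix` (listwise deletion is applied).
#' @param seed seed for the half split and parallel analysis.
#' @param n_random parallel-analysis replicates.
#' @param n_boot bootstrap replicates for the Mokken scale-H standard error.
#' @return object of class `assumption_report`.
#' @export
check_irt_assumptions <- function(matrix, seed = 1L, n_random = 100L,
                                  n_boot = 0L) {
  cc <- listwise_complete(matrix)
  n <- nrow(cc$responses)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- sample(n, floor(n / 2))
  r1 <- cc$responses[half, , drop = FALSE]
  r2 <- cc$responses[-half, , drop = FALSE]

  R1 <- polychoric_matrix(r1)
  kmo_res <- kmo(R1)
  pa <- parallel_analysis(r1, n_random = n_random, seed = seed + 1L)
  efa <- efa_wls(R1, 1L)
  R2 <- polychoric_matrix(r2)
  cfa <- cfa_one_factor(R2, n = nrow(r2))
  mok <- mokken_h(cc, n_boot = n_boot, seed = seed + 2L)

  structure(list(
    kmo_overall = kmo_res$overall,
    kmo_per_item = kmo_res$per_item,
    eigenvalues = pa$eigenvalues,
    first_factor_proportion = pa$first_factor_proportion,
    eigen_ratio_1_2 = pa$eigen_ratio_1_2,
    n_factors_retained = pa$n_factors_retained,
    efa_loadings = efa$loadings,
    fit_indices = cfa$fit_indices,
    residual_corr_max = cfa$residual_corr_max,
    locally_dependent_pairs = cfa$locally_dependent_pairs,
    h_per_item = mok$h_per_item,
    h_scale = mok$h_scale,
    h_scale_se = mok$standard_error,
    unidimensional = pa$first_factor_proportion >= 0.20 &&
      pa$eigen_ratio_1_2 > 4 && pa$n_factors_retained == 1L,
    locally_independent = nrow(cfa$locally_dependent_pairs) == 0L,
    monotone = all(mok$h_per_item >= 0.30) && mok$h_scale >= 0.50,
    n_complete = n
  ), class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("IRT assumptions analysis\n")
  cat(sprintf(" Unidimensionality          %s\n",
              if (x$unidimensional) "supported" else "NOT supported"))
  cat(sprintf("  KMO item range            %.2f-%.2f\n",
              min(x$kmo_per_item), max(x$kmo_per_item)))
  cat(sprintf("  KMO item bank             %.2f\n", x$kmo_overall))
  cat(sprintf("  Parallel analysis eigen   [1] %.2f [2] %.2f (ratio %.1f), %d factor(s) retained\n",
              x$eigenvalues[1L], x$eigenvalues[2L], x$eigen_ratio_1_2,
              x$n_factors_retained))
  cat(sprintf("  EFA proportion variance   %.2f\n", x$first_factor_proportion))
  cat(sprintf("  CFA (approx.)             CFI = %.2f, TLI = %.2f, RMSEA = %.2f, SRMR = %.2f\n",
              x$fit_indices["cfi"], x$fit_indices["tli"],
              x$fit_indices["rmsea"], x$fit_indices["srmr"]))
  cat(sprintf(" Local independence         %s (max |residual| %.2f)\n",
              if (x$locally_independent) "no item pairs > 0.2"
              else sprintf("%d pair(s) > 0.2", nrow(x$locally_dependent_pairs)),
              x$residual_corr_max))
  cat(sprintf(" Monotonicity               %s\n",
              if (x$monotone) "supported" else "NOT supported"))
  cat(sprintf("  Coefficient h, items      %.2f-%.2f\n",
              min(x$h_per_item), max(x$h_per_item)))
  if (is.na(x$h_scale_se)) {
    cat(sprintf("  Coefficient h, item bank  %.2f\n", x$h_scale))
  } else {
    cat(sprintf("  Coefficient h, item bank  %.2f (%.2f)\n",
                x$h_scale, x$h_scale_se))
  }
  invisible(x)
}
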