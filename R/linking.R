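# Convention: the linking constants (A, B) describe the affine trait map
# theta_ref = A * theta_focal + B. An item calibrated on the focal metric is
# expressed on the reference metric as a -> a / A, b_k -> A * b_k + B.

#' Stocking-Lord linking constants
#'
#' Finds the slope/intercept (A, B) of the affine trait transformation
#' placing the focal calibration onto the reference metric, by minimizing
#' the weighted squared distance between the reference test characteristic
#' curve and the transformed focal one over a quadrature grid with
#' standard-normal weights:
#' \eqn{\sum_q w_q \left[TCC_{ref}(\theta_q) - TCC_{focal \to ref}(\theta_q)\right]^2}.
#' Minimization is by Nelder-Mead from (1, 0), refined from the best point
#' of a coarse grid search when that improves the loss.
#'
#' @param reference,focal `item_bank`s (or item data frames) holding the
#'   same items in the same order.
#' @param grid a `quadrature_grid`.
#' @return object of class `linking_constants`: list with `A`, `B`,
#'   `loss_at_optimum`.
#' @export
stocking_lord <- function(reference, focal, grid = default_grid()) {
  stopifnot(n_items(reference) == n_items(focal))
  if (!identical(item_ids(reference), item_ids(focal))) {
    stop("reference and focal banks must hold the same items in the same order",
         call. = FALSE)
  }
  if (any(bank_a(focal) < 0.1)) {
    warning("focal item(s) with near-zero discrimination; linking may be ill-conditioned")
  }
  ref_tcc <- tcc(reference, grid$nodes)
  loss <- function(par) {
    if (par[1L] <= 0) return(Inf)
    trans <- apply_transform(focal, linking_constants(par[1L], par[2L]))
    sum(grid$weights * (ref_tcc - tcc(trans, grid$nodes))^2)
  }
  opt <- stats::optim(c(1, 0), loss, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-14))
  # coarse grid fallback in case Nelder-Mead stalled in a poor basin
  grid_pts <- expand.grid(A = seq(0.4, 2.5, by = 0.3),
                          B = seq(-1.5, 1.5, by = 0.3))
  g_loss <- apply(grid_pts, 1L, loss)
  if (min(g_loss) < opt$value) {
    best <- as.numeric(grid_pts[which.min(g_loss), ])
    opt2 <- stats::optim(best, loss, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-14))
    if (opt2$value < opt$value) opt <- opt2
  }
  linking_constants(opt$par[1L], opt$par[2L], opt$value)
}

#' Construct linking constants
#'
#' @param A positive slope of the trait map `theta_ref = A * theta_focal + B`.
#' @param B intercept.
#' @param loss_at_optimum optional Stocking-Lord loss.
#' @return `linking_constants` object.
#' @export
linking_constants <- function(A, B, loss_at_optimum = NA_real_) {
  stopifnot(A > 0)
  structure(list(A = A, B = B, loss_at_optimum = loss_at_optimum),
            class = "linking_constants")
}

#' @export
print.linking_constants <- function(x, ...) {
  cat(sprintf("Stocking-Lord constants: A = %.4f, B = %.4f (loss %.3g)\n",
              x$A, x$B, x$loss_at_optimum))
  invisible(x)
}

#' Apply an affine metric transformation to item parameters
#'
#' Maps focal-metric parameters onto the reference metric:
#' a -> a / A, b_k -> A * b_k + B. Threshold ordering is preserved.
#' `invert_transform()` gives the constants of the inverse map, so that
#' transforming and then inverse-transforming returns the original bank.
#'
#' @param bank an `item_bank` on the focal metric.
#' @param constants `linking_constants`.
#' @return transformed `item_bank`.
#' @export
apply_transform <- function(bank, constants) {
  items <- bank$items
  items$a <- items$a / constants$A
  bcols <- grep("^b[0-9]+$", names(items))
  items[bcols] <- constants$A * items[bcols] + constants$B
  item_bank(items, name = bank$name, n_categories = bank$n_categories)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(constants) {
  linking_constants(1 / constants$A, -constants$B / constants$A)
}

#' Assemble a hybrid item bank
#'
#' Takes the reference bank's parameters for every item except those named
#' in `dif_item_ids`, which instead receive the focal bank's parameters
#' transformed onto the reference metric by Stocking-Lord constants
#' estimated on the anchor (non-DIF) items.
#'
#' @param reference,focal `item_bank`s sharing item ids.
#' @param dif_item_ids item ids exhibiting DIF between the calibrations.
#' @param grid a `quadrature_grid`.
#' @return hybrid `item_bank` with attribute `"linking"` holding the
#'   estimated constants.
#' @export
build_hybrid_bank <- function(reference, focal, dif_item_ids,
                              grid = default_grid()) {
  stopifnot(setequal(item_ids(reference), item_ids(focal)))
  anchor <- setdiff(item_ids(reference), dif_item_ids)
  if (length(anchor) == 0L) {
    stop("no anchor items: every item is listed as DIF", call. = FALSE)
  }
  unknown <- setdiff(dif_item_ids, item_ids(reference))
  if (length(unknown) > 0L) {
    stop("unknown DIF item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  subset_bank <- function(bank, ids) {
    item_bank(bank$items[match(ids, item_ids(bank)), , drop = FALSE],
              name = bank$name, n_categories = bank$n_categories)
  }
  constants <- stocking_lord(subset_bank(reference, anchor),
                             subset_bank(focal, anchor), grid)
  items <- reference$items
  if (length(dif_item_ids) > 0L) {
    focal_tr <- apply_transform(focal, constants)
    rows <- match(dif_item_ids, item_ids(reference))
    items[rows, ] <- focal_tr$items[match(dif_item_ids, item_ids(focal_tr)), ]
  }
  out <- item_bank(items, name = paste0(reference$name, "_hybrid"),
                   n_categories = reference$n_categories)
  attr(out, "linking") <- constants
  out
}
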