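#' Split a table into two age bins
#'
#' @param table a [response_table()] (or data.frame with `age_months`).
#' @param cut bin boundary in months (default 17); rows with
#'   `age <= cut` go to the younger bin.
#' @return list with `younger` and `older`; both must be non-empty.
#' @export
split_age_bins <- function(table, cut = 17) {
  lo <- table$age_months <= cut
  if (!any(lo) || all(lo)) stop("empty age bin at cut = ", cut)
  list(younger = table[lo, , drop = FALSE],
       older = table[!lo, , drop = FALSE])
}

# Keep one (seeded random) row per participant.
one_row_per_participant <- function(table, seed = 1) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(table)), table$participant_id),
                       function(r) if (length(r) == 1L) r else sample(r, 1L)))
  table[sort(idx), , drop = FALSE]
}

#' Estimate the latent correlation of a two-factor binary model
#'
#' Items in `items_A` load on the first factor and `items_B` on the
#' second; both factors are standard normal with correlation `phi`.
#' Marginal ML with a 2-D tensor-product Gauss-Hermite rule;
#' the correlation is optimized on the `atanh` scale with the SE mapped
#' back by the delta method.
#'
#' @param table a binary [response_table()], data.frame or matrix
#'   containing the item columns.
#' @param items_A,items_B disjoint character vectors of item names, each
#'   of length >= 3.
#' @param quad_points 1-D nodes per dimension (default 15).
#' @param max_iter BFGS iteration cap.
#' @return list: `phi`, `se`, `loglik`, `converged`, `boundary`
#'   (TRUE when `|phi| >= 0.999`), `nu0`, `lambda0`.
#' @export
fit_two_factor <- function(table, items_A, items_B, quad_points = 15,
                           max_iter = 400) {
  if (length(intersect(items_A, items_B))) stop("item sets must be disjoint")
  if (length(items_A) < 3 || length(items_B) < 3) {
    stop("each factor needs at least 3 items")
  }
  df <- as.data.frame(table)
  y <- as.matrix(df[, c(items_A, items_B), drop = FALSE])
  fac <- c(rep(0L, length(items_A)), rep(1L, length(items_B)))
  j <- ncol(y)
  g2 <- gh_rule_2d(quad_points)

  rate <- colMeans(y, na.rm = TRUE)
  theta0 <- c(qlogis(pmin(pmax(rate, 0.02), 0.98)), rep(1, j), atanh(0.3))

  eval2 <- function(theta, want_grad) {
    phi <- tanh(theta[2 * j + 1])
    twofactor_ll_cpp(y, fac, theta[seq_len(j)], theta[j + seq_len(j)],
                     phi, g2$za, g2$zb, g2$w, want_grad)
  }
  fn <- function(theta) {
    v <- eval2(theta, FALSE)$loglik
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- function(theta) {
    r <- eval2(theta, TRUE)
    phi <- tanh(theta[2 * j + 1])
    -c(r$g_nu0, r$g_lambda0, r$g_phi * (1 - phi^2))
  }
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-10))
  theta <- opt$par
  phi <- tanh(theta[2 * j + 1])

  H <- grad_jacobian(gr, theta, rep(1, length(theta)))
  v <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  se <- if (!is.null(v) && all(is.finite(diag(v))) && diag(v)[2 * j + 1] > 0) {
    sqrt(diag(v)[2 * j + 1]) * (1 - phi^2)
  } else {
    NA_real_
  }
  list(phi = phi, se = se, loglik = -opt$value,
       converged = opt$convergence == 0, boundary = abs(phi) >= 0.999,
       nu0 = setNames(theta[seq_len(j)], c(items_A, items_B)),
       lambda0 = setNames(theta[j + seq_len(j)], c(items_A, items_B)))
}

#' Decide whether to merge two subscales into one factor
#'
#' The two subscales are collapsed when the estimated inter-factor
#' correlation exceeds `threshold` in both age bins.
#'
#' @param phi_younger,phi_older estimated correlations per age bin.
#' @param threshold merge threshold (default 0.75).
#' @param map optional [item_map()]; when supplied and the decision is
#'   to merge, the returned map relabels `ritual_routine` and
#'   `restricted` items is unchanged (the merged `higher_order` view is
#'   always available via [subscale_items()]), and the merged item list
#'   is attached.
#' @return list: `merge` (logical), `phi` (the two estimates),
#'   `threshold`, and (with `map`) `higher_order_items`.
#' @export
collapse_decision <- function(phi_younger, phi_older, threshold = 0.75,
                              map = NULL) {
  stopifnot(is.finite(phi_younger), is.finite(phi_older))
  merge <- min(phi_younger, phi_older) > threshold
  out <- list(merge = merge,
              phi = c(younger = phi_younger, older = phi_older),
              threshold = threshold)
  if (!is.null(map) && merge) {
    out$higher_order_items <- subscale_items(map, "higher_order")
  }
  out
}

#' Configural structure check on age-binned data
#'
#' Splits the table at `cut` months, keeps one row per participant per
#' bin, fits the ritual-routine vs restricted two-factor model in each
#' bin, and applies [collapse_decision()].
#'
#' @param table a binary [response_table()] containing both subscales'
#'   items.
#' @param cut age split in months (default 17).
#' @param threshold merge threshold.
#' @param seed seed for the per-bin row selection.
#' @param quad_points 1-D quadrature nodes per dimension.
#' @return list: `decision` (from [collapse_decision()]), `fits` (per
#'   bin), `cut`.
#' @export
configural_check <- function(table, cut = 17, threshold = 0.75, seed = 1,
                             quad_points = 15) {
  map <- rt_map(table)
  bins <- split_age_bins(table, cut)
  items_a <- subscale_items(map, "ritual_routine")
  items_b <- subscale_items(map, "restricted")
  fits <- lapply(bins, function(b) {
    fit_two_factor(one_row_per_participant(b, seed), items_a, items_b,
                   quad_points = quad_points)
  })
  decision <- collapse_decision(fits$younger$phi, fits$older$phi,
                                threshold, map)
  list(decision = decision, fits = fits, cut = cut)
}
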