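#' Item response probability under the moderated measurement model
#'
#' Probability that item `j` is endorsed given latent value `eta` and
#' covariates `x`:
#' `plogis(nu0_j + kappa_j'x + (lambda0_j + delta_j'x) * eta)`.
#'
#' @param params an [mnlfa_params()].
#' @param j item index or name.
#' @param eta latent factor value(s).
#' @param x named numeric vector of covariate values (covariates absent
#'   from `x` are taken as 0).
#' @return probability in (0, 1), vectorized over `eta`.
#' @export
item_prob <- function(params, j, eta, x = NULL) {
  xv <- setNames(numeric(length(params$covariates)), params$covariates)
  if (!is.null(x)) xv[names(x)] <- x
  if (is.character(j)) j <- match(j, params$items)
  nu <- params$nu0[j] + sum(params$kappa[j, ] * xv)
  lam <- params$lambda0[j] + sum(params$delta[j, ] * xv)
  pr <- plogis(nu + lam * eta)
  # keep strictly inside (0, 1) even where plogis saturates in floating point
  unname(pmin(pmax(pr, 1e-12), 1 - 1e-12))
}

#' Moderated factor mean and variance
#'
#' `alpha(x) = gamma'x` and `psi(x) = exp(omega'x)`; at the covariate
#' reference (`x = 0`) these are exactly 0 and 1, the identification
#' constraint of the model.
#'
#' @inheritParams item_prob
#' @return named numeric `c(alpha = , psi = )`.
#' @export
structural_moments <- function(params, x = NULL) {
  xv <- setNames(numeric(length(params$covariates)), params$covariates)
  if (!is.null(x)) xv[names(x)] <- x
  c(alpha = sum(params$gamma * xv), psi = exp(sum(params$omega * xv)))
}

# Shared input preparation: binary item matrix + covariate matrix.
mnlfa_inputs <- function(params, table, design) {
  stopifnot(inherits(table, "response_table"))
  if (rt_scale(table) != "binary") {
    stop("a binary-scale table is required; run binarize_items first")
  }
  y <- item_matrix(table)
  if (!identical(colnames(y), params$items)) {
    y <- y[, params$items, drop = FALSE]
  }
  x <- covariate_matrix(table, design)
  stopifnot(identical(colnames(x), params$covariates))
  list(y = y, x = x)
}

#' Marginal log-likelihood of a moderated one-factor binary model
#'
#' For each row, the Bernoulli likelihood of the observed items (missing
#' items skipped) is integrated over the latent factor
#' `eta ~ N(alpha(x), psi(x))` by Gauss-Hermite quadrature, and the log
#' integrals are summed over rows.
#'
#' @param params an [mnlfa_params()].
#' @param table a binary [response_table()] whose items match `params`.
#' @param design a [moderator_design()].
#' @param quad_points number of quadrature nodes (default 21).
#' @param per_row return the per-row log-likelihood vector instead of
#'   the sum.
#' @return scalar log-likelihood (or a vector if `per_row`).
#' @export
marginal_loglik <- function(params, table, design, quad_points = 21,
                            per_row = FALSE) {
  inp <- mnlfa_inputs(params, table, design)
  gh <- gh_rule(quad_points)
  r <- mnlfa_ll_cpp(inp$y, inp$x, params$nu0, params$lambda0, params$kappa,
                    params$delta, params$gamma, params$omega, gh$z, gh$w,
                    FALSE)
  if (!all(is.finite(r$row_loglik))) {
    stop("non-finite log-likelihood at row(s): ",
         paste(which(!is.finite(r$row_loglik)), collapse = ", "))
  }
  if (per_row) r$row_loglik else r$loglik
}

#' Fit the moderated nonlinear factor model by marginal ML
#'
#' Maximizes [marginal_loglik()] over the free parameters declared in
#' `mask` using BFGS with the analytic score.  Initial values default to
#' `nu0 = logit(endorsement rate)`, `lambda0 = 1`, all moderation 0.
#' Items endorsed by everyone or no one (quasi-separation) are reported
#' and their parameters frozen at the initial values.  Standard errors
#' come from the inverse observed information (central-difference
#' Jacobian of the analytic gradient).
#'
#' @param table a binary [response_table()].
#' @param design a [moderator_design()].
#' @param mask an `mnlfa_mask` ([param_mask()]); default frees baselines
#'   only.
#' @param init optional [mnlfa_params()] of starting (and frozen) values.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param quad_points quadrature nodes (default 21).
#' @param max_iter BFGS iteration cap.
#' @param se compute standard errors (default TRUE).
#' @return an object of class `mnlfa_fit`: elements `params`, `se`
#'   (same shape, NA where fixed), `loglik`, `converged`, `vcov`,
#'   `free` (packed parameter names), `mask`, `design`, `quad_points`,
#'   `n`, `frozen_items`.  Non-convergence is flagged, not an error.
#' @export
fit_mnlfa <- function(table, design, mask = NULL, init = NULL, tol = 1e-8,
                      quad_points = 21, max_iter = 500, se = TRUE) {
  map <- rt_map(table)
  items <- names(map)
  if (is.null(init)) {
    init <- mnlfa_params(items, design$covariates)
    rate <- colMeans(item_matrix(table), na.rm = TRUE)
    init$nu0 <- qlogis(pmin(pmax(rate, 0.02), 0.98))
    init$lambda0[] <- 1
  }
  if (is.null(mask)) mask <- param_mask(init)
  inp <- mnlfa_inputs(init, table, design)

  rate <- colMeans(inp$y, na.rm = TRUE)
  frozen <- items[rate %in% c(0, 1)]
  if (length(frozen)) {
    warning("quasi-separated item(s) frozen: ", paste(frozen, collapse = ", "))
    fi <- match(frozen, items)
    mask$nu0[fi] <- FALSE; mask$lambda0[fi] <- FALSE
    mask$kappa[fi, ] <- FALSE; mask$delta[fi, ] <- FALSE
  }

  theta0 <- pack_params(init, mask)
  p <- length(theta0)
  if (p == 0L) stop("no free parameters")
  if (nrow(inp$y) < p) stop("fewer rows than free parameters")
  free_loadings <- sum(mask$lambda0)
  if (free_loadings > 0 && free_loadings < 2) {
    if (length(items) < 2) stop("at least 2 items are required to estimate a loading")
  }

  gh <- gh_rule(quad_points)
  eval_ll <- function(theta, want_grad) {
    pr <- unpack_params(theta, init, mask)
    mnlfa_ll_cpp(inp$y, inp$x, pr$nu0, pr$lambda0, pr$kappa, pr$delta,
                 pr$gamma, pr$omega, gh$z, gh$w, want_grad)
  }
  fn <- function(theta) {
    v <- eval_ll(theta, FALSE)$loglik
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- function(theta) -pack_grad(eval_ll(theta, TRUE), mask)

  parscale <- pack_parscale(init, mask, design)
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol,
                              parscale = parscale))
  theta <- opt$par
  g <- gr(theta)
  converged <- opt$convergence == 0 &&
    max(abs(g * parscale)) < 1e-3 * (1 + abs(opt$value))
  params <- unpack_params(theta, init, mask)

  vcov <- NULL
  se_params <- NULL
  if (se) {
    H <- grad_jacobian(gr, theta, parscale)
    vcov <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
      vcov <- NULL
    } else {
      dimnames(vcov) <- list(names(theta0), names(theta0))
      se_vec <- sqrt(diag(vcov))
      blank <- mnlfa_params(params$items, params$covariates, nu0 = NA,
                            lambda0 = NA, kappa = NA, delta = NA,
                            gamma = NA, omega = NA)
      se_params <- unpack_params(se_vec, blank, mask)
    }
  }

  structure(list(params = params, se = se_params, loglik = -opt$value,
                 converged = converged, vcov = vcov,
                 free = names(theta0), mask = mask, design = design,
                 quad_points = quad_points, n = nrow(inp$y),
                 frozen_items = frozen, counts = opt$counts),
            class = "mnlfa_fit")
}

# Central-difference Jacobian of the (negative) gradient = observed
# information; step scaled per parameter.
grad_jacobian <- function(gr, theta, parscale) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    h <- 1e-5 * max(1, abs(theta[i]) / parscale[i]) * parscale[i]
    tp <- theta; tp[i] <- theta[i] + h
    tm <- theta; tm[i] <- theta[i] - h
    H[, i] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  H
}

#' @export
print.mnlfa_fit <- function(x, ...) {
  cat("MNLFA fit:", length(x$params$items), "items,", x$n, "rows,",
      length(x$free), "free parameters\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (length(x$frozen_items)) {
    cat("  frozen (quasi-separated) items:",
        paste(x$frozen_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
logLik.mnlfa_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free), class = "logLik")
}

#' Wald z tests for all free parameters of a fitted MNLFA model
#'
#' Standard errors from the inverse observed information;
#' `p = 2 * (1 - pnorm(|z|))`.  If the information matrix was singular
#' the SEs are unavailable and p is reported as 1 with a warning.
#'
#' @param fitted an `mnlfa_fit` from [fit_mnlfa()].
#' @return data.frame with columns `parameter`, `block`, `item`,
#'   `covariate`, `estimate`, `se`, `z`, `p`.
#' @export
wald_tests <- function(fitted) {
  stopifnot(inherits(fitted, "mnlfa_fit"))
  est <- pack_params(fitted$params, fitted$mask)
  parts <- strsplit(names(est), ":", fixed = TRUE)
  block_of <- c(nu0 = "baseline_intercept", lambda0 = "baseline_loading",
                kappa = "intercept", delta = "loading",
                gamma = "mean", omega = "variance")
  block <- block_of[vapply(parts, `[`, "", 1L)]
  item <- vapply(parts, function(p) {
    if (p[1] %in% c("nu0", "lambda0", "kappa", "delta")) p[2] else ""
  }, "")
  covariate <- vapply(parts, function(p) {
    switch(p[1], kappa = , delta = p[3], gamma = , omega = p[2], "")
  }, "")
  if (is.null(fitted$vcov)) {
    warning("singular observed information: SEs unavailable, p set to 1")
    se <- rep(NA_real_, length(est))
    z <- rep(NA_real_, length(est))
    p <- rep(1, length(est))
  } else {
    se <- sqrt(diag(fitted$vcov))
    z <- ifelse(est == 0, 0, est / se)
    p <- ifelse(est == 0, 1, 2 * pnorm(-abs(z)))
  }
  data.frame(parameter = names(est), block = unname(block), item = item,
             covariate = covariate, estimate = unname(est), se = se,
             z = z, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected-a-posteriori factor scores
#'
#' Posterior mean and SD of the latent factor for every row of `table`,
#' given fixed measurement/structural parameters (typically from a
#' calibration fit).  Rows with no observed items score at the prior
#' mean `alpha(x)` with prior SD `sqrt(psi(x))`.
#'
#' @inheritParams marginal_loglik
#' @return data.frame of class `factor_scores`: `participant_id`,
#'   `age_months`, `eta` (EAP estimate), `eta_sd` (posterior SD > 0).
#' @export
eap_scores <- function(params, table, design, quad_points = 21) {
  inp <- mnlfa_inputs(params, table, design)
  y <- inp$y; x <- inp$x
  n <- nrow(y); q <- quad_points
  gh <- gh_rule(q)
  alpha <- drop(x %*% params$gamma)
  sigma <- exp(0.5 * drop(x %*% params$omega))
  nux <- matrix(params$nu0, n, ncol(y), byrow = TRUE) + x %*% t(params$kappa)
  lam <- matrix(params$lambda0, n, ncol(y), byrow = TRUE) + x %*% t(params$delta)
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)

  logf <- matrix(0, n, q)
  eta_q <- matrix(0, n, q)
  for (k in seq_len(q)) {
    eta <- alpha + sigma * gh$z[k]
    eta_q[, k] <- eta
    a <- nux + lam * eta
    lp <- ifelse(a > 0, -log1p(exp(-a)), a - log1p(exp(a)))
    lq <- ifelse(-a > 0, -log1p(exp(a)), -a - log1p(exp(-a)))
    logf[, k] <- rowSums((y0 * lp + (1 - y0) * lq) * obs)
  }
  m <- apply(logf, 1, max)
  u <- exp(logf - m) * matrix(gh$w, n, q, byrow = TRUE)
  u <- u / rowSums(u)
  eap <- rowSums(u * eta_q)
  eap_sd <- sqrt(pmax(rowSums(u * eta_q^2) - eap^2, 0))
  eap_sd <- pmax(eap_sd, 1e-8)
  structure(data.frame(participant_id = table$participant_id,
                       age_months = table$age_months,
                       eta = eap, eta_sd = eap_sd,
                       stringsAsFactors = FALSE),
            class = c("factor_scores", "data.frame"))
}
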