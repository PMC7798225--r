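# Brute-force integration oracles, independent of the quadrature code
# under test: dense trapezoid rules over a wide latent grid.

# Marginal log-likelihood of the moderated one-factor model by trapezoid
# integration over eta in [lo, hi].
oracle_ll_1d <- function(params, table, design, lo = -12, hi = 12, m = 6001,
                         per_row = FALSE) {
  x <- covariate_matrix(table, design)
  y <- as.matrix(as.data.frame(table)[, params$items, drop = FALSE])
  grid <- seq(lo, hi, length.out = m)
  h <- grid[2] - grid[1]
  wts <- rep(h, m); wts[c(1, m)] <- h / 2
  out <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    alpha <- sum(params$gamma * x[i, ])
    psi <- exp(sum(params$omega * x[i, ]))
    nux <- params$nu0 + drop(params$kappa %*% x[i, ])
    lam <- params$lambda0 + drop(params$delta %*% x[i, ])
    a <- outer(grid, lam) + matrix(nux, m, length(nux), byrow = TRUE)
    yy <- y[i, ]; obs <- !is.na(yy)
    lp <- plogis(a[, obs, drop = FALSE], log.p = TRUE)
    lq <- plogis(-a[, obs, drop = FALSE], log.p = TRUE)
    lf <- drop(lp %*% yy[obs] + lq %*% (1 - yy[obs]))
    dens <- stats::dnorm(grid, alpha, sqrt(psi))
    out[i] <- log(sum(wts * exp(lf) * dens))
  }
  if (per_row) out else sum(out)
}

# Posterior mean/SD of eta for each row by the same dense grid.
oracle_eap_1d <- function(params, table, design, lo = -12, hi = 12, m = 6001) {
  x <- covariate_matrix(table, design)
  y <- as.matrix(as.data.frame(table)[, params$items, drop = FALSE])
  grid <- seq(lo, hi, length.out = m)
  res <- matrix(NA_real_, nrow(y), 2, dimnames = list(NULL, c("eta", "sd")))
  for (i in seq_len(nrow(y))) {
    alpha <- sum(params$gamma * x[i, ])
    psi <- exp(sum(params$omega * x[i, ]))
    nux <- params$nu0 + drop(params$kappa %*% x[i, ])
    lam <- params$lambda0 + drop(params$delta %*% x[i, ])
    a <- outer(grid, lam) + matrix(nux, m, length(nux), byrow = TRUE)
    yy <- y[i, ]; obs <- !is.na(yy)
    lp <- plogis(a[, obs, drop = FALSE], log.p = TRUE)
    lq <- plogis(-a[, obs, drop = FALSE], log.p = TRUE)
    lf <- drop(lp %*% yy[obs] + lq %*% (1 - yy[obs]))
    post <- exp(lf) * stats::dnorm(grid, alpha, sqrt(psi))
    post <- post / sum(post)
    mu <- sum(post * grid)
    res[i, ] <- c(mu, sqrt(sum(post * grid^2) - mu^2))
  }
  res
}

# Two-factor marginal log-likelihood by a dense 2-D trapezoid rule.
oracle_ll_2d <- function(y, items_A, items_B, nu0, lambda0, phi,
                         lo = -6, hi = 6, m = 201) {
  grid <- seq(lo, hi, length.out = m)
  h <- grid[2] - grid[1]
  w1 <- rep(h, m); w1[c(1, m)] <- h / 2
  g <- expand.grid(e1 = grid, e2 = grid)
  wts <- as.vector(outer(w1, w1))
  S <- rbind(c(1, phi), c(phi, 1))
  Sinv <- solve(S)
  q <- Sinv[1, 1] * g$e1^2 + 2 * Sinv[1, 2] * g$e1 * g$e2 +
    Sinv[2, 2] * g$e2^2
  dens <- exp(-q / 2) / (2 * pi * sqrt(det(S)))
  cols <- c(items_A, items_B)
  eta <- cbind(matrix(g$e1, nrow(g), length(items_A)),
               matrix(g$e2, nrow(g), length(items_B)))
  out <- 0
  for (i in seq_len(nrow(y))) {
    yy <- y[i, cols]
    a <- matrix(nu0[cols], nrow(g), length(cols), byrow = TRUE) +
      eta * matrix(lambda0[cols], nrow(g), length(cols), byrow = TRUE)
    lp <- plogis(a, log.p = TRUE); lq <- plogis(-a, log.p = TRUE)
    obs <- !is.na(yy)
    lf <- drop(lp[, obs, drop = FALSE] %*% yy[obs] +
                 lq[, obs, drop = FALSE] %*% (1 - yy[obs]))
    out <- out + log(sum(wts * exp(lf) * dens))
  }
  out
}

# Small well-formed toy response data.frame for IO tests.
toy_response_df <- function(n = 3, map = default_item_map(), seed = 99) {
  set.seed(seed)
  df <- data.frame(participant_id = sprintf("T%02d", seq_len(n)),
                   age_months = seq(10, 30, length.out = n),
                   sex = rep_len(c(0, 1), n), cohort = rep_len(c(0, 1), n))
  for (it in names(map)) df[[it]] <- sample(0:4, n, replace = TRUE)
  df
}
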