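#' Assemble growth-model data from factor scores and covariates
#'
#' @param scores a `factor_scores` table (same rows as `table`).
#' @param table the [response_table()] the scores were computed from.
#' @param age_center months (default 18).
#' @return data.frame with `participant_id`, `age_months`, `age_c`,
#'   `sex`, `cohort`, `outcome`.
#' @export
growth_data <- function(scores, table, age_center = 18) {
  if (nrow(scores) != nrow(table)) stop("mismatched rows")
  data.frame(participant_id = table$participant_id,
             age_months = table$age_months,
             age_c = table$age_months - age_center,
             sex = as.numeric(table$sex),
             cohort = as.numeric(table$cohort),
             outcome = scores$eta, stringsAsFactors = FALSE)
}

#' Fit a linear mixed-effects growth model by maximum likelihood
#'
#' Thin wrapper around [lme4::lmer()] with `REML = FALSE` (so fits can
#' be compared by LRT and AICc), returning the pieces the taxonomy
#' machinery needs.  Fixed-effect p-values are Wald-normal; model
#' selection uses [lrt()] instead.
#'
#' @param data a [growth_data()]-style data.frame with `outcome`,
#'   `age_c` and `participant_id`.
#' @param fixed character vector of fixed-effect terms beyond the
#'   intercept, e.g. `c("age_c", "I(age_c^2)", "sex", "age_c:sex")`.
#' @param random character vector of random-effect terms; `"1"` for a
#'   random intercept only, `c("1", "age_c")` to add a random slope.
#' @return object of class `growth_fit`: `model` (the `lmerMod`),
#'   `fixed` (coefficient table), `ranef_vcov`, `sigma2` (residual
#'   variance), `loglik`, `k`, `n`, `aicc`, `singular` flag, and the
#'   term lists.
#' @export
fit_growth <- function(data, fixed = "age_c", random = "1") {
  stopifnot(all(c("outcome", "participant_id") %in% names(data)))
  rhs <- paste(c("1", fixed), collapse = " + ")
  rterm <- paste0("(", paste(random, collapse = " + "), " | participant_id)")
  form <- as.formula(paste("outcome ~", rhs, "+", rterm))
  model <- lme4::lmer(form, data = data, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                        check.conv.singular = "ignore"))
  ll <- logLik(model)
  k <- attr(ll, "df")
  n <- nrow(data)
  b <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- b / se
  vc <- lme4::VarCorr(model)
  structure(list(model = model,
                 fixed = data.frame(term = names(b), estimate = unname(b),
                                    se = unname(se), z = unname(z),
                                    p = 2 * pnorm(-abs(unname(z))),
                                    stringsAsFactors = FALSE),
                 ranef_vcov = as.matrix(vc$participant_id),
                 sigma2 = stats::sigma(model)^2,
                 loglik = as.numeric(ll), k = k, n = n,
                 aicc = aicc(as.numeric(ll), k, n),
                 singular = lme4::isSingular(model),
                 fixed_terms = fixed, random_terms = random,
                 data = data),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth model (ML): outcome ~", paste(c("1", x$fixed_terms),
      collapse = " + "), "+ (", paste(x$random_terms, collapse = " + "),
      "| participant_id)\n")
  cat("  logLik", format(x$loglik, digits = 7), " k =", x$k, " n =", x$n,
      " AICc =", format(x$aicc, digits = 7),
      if (x$singular) " [singular random effects]" else "", "\n")
  print(x$fixed, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of nested ML fits
#'
#' @param nested,full `growth_fit` objects fit to the same data by ML,
#'   with `nested` a restriction of `full`.
#' @return list of class `lrt_result`: `delta_m2ll` (`2 * (ll_full -
#'   ll_nested)`), `delta_df`, `p` (chi-squared upper tail).
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "growth_fit"), inherits(full, "growth_fit"))
  if (nested$n != full$n) stop("fits use different data")
  ddf <- full$k - nested$k
  d <- 2 * (full$loglik - nested$loglik)
  if (d < -1e-6) {
    stop("full model has lower likelihood than nested model: ",
         "models are not nested or did not converge")
  }
  d <- max(d, 0)
  if (ddf < 1) {
    if (d <= 1e-8) return(structure(list(delta_m2ll = 0, delta_df = 0, p = 1),
                                    class = "lrt_result"))
    stop("full model has no additional parameters")
  }
  structure(list(delta_m2ll = d, delta_df = ddf,
                 p = pchisq(d, ddf, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Second-order (small-sample) Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik log-likelihood (numeric or `logLik`).
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  loglik <- as.numeric(loglik)
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Growth-model taxonomy search
#'
#' Fits, in order: (1) random-intercept-only; (2) + fixed linear age;
#' (3) + random linear slope; (4) + fixed quadratic age; then candidate
#' covariates (sex and cohort main effects, then their age
#' interactions).  Each addition is kept when the LRT against the
#' current model has `p < alpha` and the AICc decreases; covariate terms
#' that do not survive a final drop-one LRT prune (respecting
#' marginality) are removed.
#'
#' @param data a [growth_data()]-style data.frame.
#' @param alpha LRT level (default 0.05).
#' @param covariates candidate covariate columns (default sex, cohort).
#' @return list: `best` (`growth_fit`), `table` (one row per model
#'   tried: description, loglik, k, n, AICc, LRT p, kept), and `form`
#'   (`"intercept"`, `"linear"` or `"quadratic"`).
#' @export
taxonomy_search <- function(data, alpha = 0.05,
                            covariates = c("sex", "cohort")) {
  rows <- list()
  log_row <- function(desc, fit, p, kept) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = desc, loglik = fit$loglik, k = fit$k, n = fit$n,
      aicc = fit$aicc, lrt_p = p, kept = kept, stringsAsFactors = FALSE)
  }
  try_add <- function(cur, fixed, random, desc) {
    cand <- fit_growth(data, fixed, random)
    p <- lrt(cur, cand)$p
    kept <- is.finite(p) && p < alpha && cand$aicc < cur$aicc
    log_row(desc, cand, p, kept)
    if (kept) cand else cur
  }

  f1 <- fit_growth(data, character(0), "1")
  log_row("random intercept", f1, NA, TRUE)

  # time polynomial ladder: the quadratic is always examined on top of
  # the linear model (a flat linear trend can hide real curvature, so a
  # non-significant slope does not halt the ladder; marginality keeps
  # the linear term under a retained quadratic)
  f2 <- fit_growth(data, "age_c", "1")
  p12 <- lrt(f1, f2)$p
  keep_lin <- is.finite(p12) && p12 < alpha && f2$aicc < f1$aicc
  log_row("+ fixed linear age", f2, p12, keep_lin)

  f3 <- fit_growth(data, "age_c", c("1", "age_c"))
  p23 <- lrt(f2, f3)$p
  keep_rs <- is.finite(p23) && p23 < alpha && f3$aicc < f2$aicc
  log_row("+ random linear slope", f3, p23, keep_rs)

  base_rand <- if (keep_rs) c("1", "age_c") else "1"
  base_lin <- if (keep_rs) f3 else f2
  f4 <- fit_growth(data, c("age_c", "I(age_c^2)"), base_rand)
  p34 <- lrt(base_lin, f4)$p
  keep_quad <- is.finite(p34) && p34 < alpha && f4$aicc < base_lin$aicc
  log_row("+ fixed quadratic age", f4, p34, keep_quad)

  cur <- if (keep_quad) f4 else if (keep_lin) base_lin else f1
  has_linear <- "age_c" %in% cur$fixed_terms

  for (cv in covariates) {
    cur <- try_add(cur, c(cur$fixed_terms, cv), cur$random_terms,
                   paste("+", cv))
    if (has_linear) {
      inter <- paste0("age_c:", cv)
      fixed_cand <- unique(c(cur$fixed_terms, cv, inter))
      cand <- fit_growth(data, fixed_cand, cur$random_terms)
      p <- lrt(cur, cand)$p
      kept <- is.finite(p) && p < alpha && cand$aicc < cur$aicc
      log_row(paste("+", inter), cand, p, kept)
      if (kept) cur <- cand
    }
  }

  # backward prune of covariate terms (mains stay while their
  # interaction is present)
  repeat {
    dropped <- FALSE
    cov_terms <- setdiff(cur$fixed_terms, c("age_c", "I(age_c^2)"))
    for (tm in cov_terms) {
      if (tm %in% covariates &&
          any(grepl(paste0(":", tm, "$"), cur$fixed_terms))) next
      reduced <- fit_growth(data, setdiff(cur$fixed_terms, tm),
                            cur$random_terms)
      p <- lrt(reduced, cur)$p
      if (!is.finite(p) || p >= alpha) {
        log_row(paste("-", tm, "(pruned)"), reduced, p, TRUE)
        cur <- reduced
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  form <- if ("I(age_c^2)" %in% cur$fixed_terms) "quadratic"
          else if ("age_c" %in% cur$fixed_terms) "linear"
          else "intercept"
  list(best = cur, table = do.call(rbind, rows), form = form)
}

#' Fixed-effect change over an age span in within-person SD units
#'
#' The absolute change of the fixed age polynomial over the span,
#' divided by the residual (within-person) SD.  By default the span is
#' symmetric about the centering age; pass `age_range` (relative to the
#' centering age) for an asymmetric window.
#'
#' @param fit a `growth_fit` with positive residual variance.
#' @param age_span span in months (used as `[-span/2, span/2]`).
#' @param age_range optional length-2 centered-age interval overriding
#'   `age_span`.
#' @return change in SD units (non-negative).
#' @export
effect_in_within_person_sd <- function(fit, age_span = NULL,
                                       age_range = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$sigma2 <= 0) stop("zero residual variance: scaling undefined")
  if (is.null(age_range)) {
    stopifnot(!is.null(age_span))
    age_range <- c(-age_span / 2, age_span / 2)
  }
  b <- setNames(fit$fixed$estimate, fit$fixed$term)
  f <- function(a) {
    sum(b["age_c"] * a, na.rm = TRUE) + sum(b["I(age_c^2)"] * a^2, na.rm = TRUE)
  }
  abs(f(age_range[2]) - f(age_range[1])) / sqrt(fit$sigma2)
}

#' Variance explained by the conditional model predictions
#'
#' Squared Pearson correlation between conditional predictions (fixed
#' effects plus predicted random effects) and the observed outcomes.
#'
#' @param fit a `growth_fit`.
#' @param data optional data.frame (defaults to the fitting data).
#' @return R-squared in `[0, 1]`.
#' @export
variance_explained <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(data)) data <- fit$data
  pred <- predict(fit$model, newdata = data)
  if (sd(pred) == 0) stop("constant predictions: R^2 undefined")
  cor(pred, data$outcome)^2
}

#' Fixed-effect trajectory grid for plotting
#'
#' Evaluates the fitted fixed-effect age polynomial (at reference
#' covariate values 0) over a grid of ages, for export as delimited
#' text or direct plotting.
#'
#' @param fit a `growth_fit`.
#' @param ages vector of ages in months (default 8 to 36 by 0.5).
#' @param age_center centering age used in the fit (default 18).
#' @return data.frame with `age_months`, `age_c`, `predicted`.
#' @export
fitted_curve_grid <- function(fit, ages = seq(8, 36, by = 0.5),
                              age_center = 18) {
  stopifnot(inherits(fit, "growth_fit"))
  b <- setNames(fit$fixed$estimate, fit$fixed$term)
  a <- ages - age_center
  pred <- unname(b["(Intercept)"]) +
    sum(b["age_c"], na.rm = TRUE) * a +
    sum(b["I(age_c^2)"], na.rm = TRUE) * a^2
  data.frame(age_months = ages, age_c = a, predicted = pred)
}
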