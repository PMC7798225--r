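#' Draw a one-row-per-participant calibration sample
#'
#' Selects exactly one visit per participant while matching the age
#' distribution of the full longitudinal sample: participants are
#' visited in seeded random order and each contributes the visit whose
#' age falls in the currently most under-filled decile of the
#' full-sample age distribution.  Deterministic given the seed.
#'
#' @param table a longitudinal [response_table()].
#' @param rng_seed integer seed.
#' @return a [response_table()] with one row per participant.
#' @export
draw_calibration_sample <- function(table, rng_seed = 1) {
  stopifnot(inherits(table, "response_table"))
  ages <- table$age_months
  breaks <- unique(quantile(ages, probs = seq(0, 1, 0.1), names = FALSE))
  nbin <- length(breaks) - 1L
  bin_of <- function(a) {
    pmin(pmax(findInterval(a, breaks, rightmost.closed = TRUE), 1L), nbin)
  }
  ids <- unique(table$participant_id)
  target <- length(ids) / nbin
  set.seed(rng_seed)
  ord <- sample(ids)
  fill <- numeric(nbin)
  keep <- integer(length(ids))
  for (i in seq_along(ord)) {
    rows <- which(table$participant_id == ord[i])
    if (length(rows) == 1L) {
      pick <- rows
    } else {
      b <- bin_of(ages[rows])
      best <- b[which.min(fill[b] + runif(length(b)) * 1e-9)]
      cand <- rows[b == best]
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    keep[i] <- pick
    fill[bin_of(ages[pick])] <- fill[bin_of(ages[pick])] + 1
  }
  out <- table[sort(keep), , drop = FALSE]
  attr(out, "item_map") <- rt_map(table)
  attr(out, "response_scale") <- rt_scale(table)
  class(out) <- c("response_table", "data.frame")
  out
}

new_trace <- function(stage, block, item, covariate, estimate, se, p,
                      retained, threshold) {
  if (length(block) == 0L) {
    return(data.frame(stage = character(0), block = character(0),
                      item = character(0), covariate = character(0),
                      estimate = numeric(0), se = numeric(0),
                      p = numeric(0), retained = logical(0),
                      threshold = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(stage = stage, block = block, item = item,
             covariate = covariate, estimate = estimate, se = se, p = p,
             retained = retained, threshold = threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

moderation_rows <- function(wt) {
  wt[wt$block %in% c("mean", "variance", "intercept", "loading"), ,
     drop = FALSE]
}

#' Stage 1: impact model
#'
#' Fits the MNLFA with every candidate mean moderator plus the variance
#' moderators (age only, by default) and no DIF, then marks each
#' structural effect with Wald `p < alpha` as retained.
#'
#' @param calibration a binary one-row-per-participant
#'   [response_table()].
#' @param design a [moderator_design()].
#' @param alpha retention threshold (default 0.1).
#' @param quad_points quadrature nodes.
#' @return list with `fit` (an `mnlfa_fit`) and `trace` (stage
#'   `"impact"` rows of the workflow trace).
#' @export
fit_impact_model <- function(calibration, design, alpha = 0.1,
                             quad_points = 21) {
  items <- names(rt_map(calibration))
  p0 <- mnlfa_params(items, design$covariates)
  mask <- param_mask(p0)
  mask$gamma[design$mean_covariates] <- TRUE
  mask$omega[design$var_covariates] <- TRUE
  fit <- fit_mnlfa(calibration, design, mask, quad_points = quad_points)
  wt <- moderation_rows(wald_tests(fit))
  trace <- new_trace("impact", wt$block, wt$item, wt$covariate, wt$estimate,
                     wt$se, wt$p, wt$p < alpha, alpha)
  list(fit = fit, trace = trace)
}

#' Stage 2: item-wise DIF scan
#'
#' For each item in turn, frees that item's intercept- and loading-DIF
#' coefficients for all candidate covariates (all other items' DIF fixed
#' at 0) in the presence of the retained impact effects, and records
#' each DIF effect's estimate and Wald p.  Items whose scan fit fails to
#' converge are skipped with a warning and their effects marked
#' untested (`retained = NA`).
#'
#' @inheritParams fit_impact_model
#' @param impact_trace the `trace` from [fit_impact_model()].
#' @param alpha flagging threshold recorded in the trace (default 0.05,
#'   the trim threshold).
#' @param init optional [mnlfa_params()] used as warm start (typically
#'   the impact-model estimates); DIF entries start at 0 either way.
#' @return workflow-trace data.frame, stage `"dif_scan"`.
#' @export
scan_item_dif <- function(calibration, design, impact_trace, alpha = 0.05,
                          quad_points = 21, init = NULL) {
  items <- names(rt_map(calibration))
  if (length(items) < 3) stop("DIF scan undefined with < 3 items")
  p0 <- mnlfa_params(items, design$covariates)
  retained_impact <- impact_trace[impact_trace$retained %in% TRUE, ,
                                  drop = FALSE]
  out <- list()
  for (j in items) {
    mask <- mask_from_effects(p0, retained_impact)
    mask$kappa[j, design$dif_covariates] <- TRUE
    mask$delta[j, design$dif_covariates] <- TRUE
    fit <- tryCatch(fit_mnlfa(calibration, design, mask, init = init,
                              quad_points = quad_points),
                    error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    if (!ok) {
      warning("DIF scan did not converge for item ", j, "; effects untested")
      out[[j]] <- new_trace("dif_scan",
                            rep(c("intercept", "loading"),
                                each = length(design$dif_covariates)),
                            j, rep(design$dif_covariates, 2), NA_real_,
                            NA_real_, NA_real_, NA, alpha)
      next
    }
    wt <- moderation_rows(wald_tests(fit))
    wt <- wt[wt$item == j, , drop = FALSE]
    out[[j]] <- new_trace("dif_scan", wt$block, wt$item, wt$covariate,
                          wt$estimate, wt$se, wt$p, wt$p < alpha, alpha)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Stage 3: trim and simultaneous refit
#'
#' Retains every impact and DIF effect with stage p below `alpha` and
#' refits them simultaneously in one model, producing fresh Wald p per
#' effect.  If no candidate survives, the plain unmoderated model is
#' returned.
#'
#' @inheritParams fit_impact_model
#' @param candidates combined trace (impact + DIF scan stages).
#' @param alpha trim threshold (default 0.05).
#' @param init optional [mnlfa_params()] warm start.
#' @return list with `fit` and `trace` (stage `"trim"`).
#' @export
trim_and_refit <- function(calibration, design, candidates, alpha = 0.05,
                           quad_points = 21, init = NULL) {
  items <- names(rt_map(calibration))
  p0 <- mnlfa_params(items, design$covariates)
  surv <- candidates[!is.na(candidates$p) & candidates$p < alpha, ,
                     drop = FALSE]
  mask <- mask_from_effects(p0, surv)
  fit <- fit_mnlfa(calibration, design, mask, init = init,
                   quad_points = quad_points)
  wt <- moderation_rows(wald_tests(fit))
  trace <- new_trace("trim", wt$block, wt$item, wt$covariate, wt$estimate,
                     wt$se, wt$p, NA, alpha)
  list(fit = fit, trace = trace)
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending, finds the largest `k` with
#' `p[(k)] <= k * alpha / m`, and retains those `k` hypotheses.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return integer indices (into `p_values`) of the retained set; empty
#'   for empty input.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(integer(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  ord <- order(p_values)
  ok <- which(p_values[ord] <= seq_len(m) * alpha / m)
  if (!length(ok)) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

#' Run the full invariance cascade and score the longitudinal sample
#'
#' Impact model (p < 0.1 retention), item-wise DIF scan, trim at
#' p < 0.05, simultaneous refit, Benjamini-Hochberg correction over all
#' moderation effects of the trim model, final-model fit on the
#' calibration rows, and EAP scoring of every row of the full
#' longitudinal table with the final parameters fixed.
#'
#' @param full_table the full longitudinal binary [response_table()].
#' @param calibration_table one-row-per-participant calibration subtable
#'   (see [draw_calibration_sample()]).
#' @param design a [moderator_design()].
#' @param alpha_impact,alpha_trim,alpha_bh stage thresholds.
#' @param quad_points quadrature nodes.
#' @return list with `fit` (final `mnlfa_fit`), `scores`
#'   (a `factor_scores` table, one row per row of `full_table`), and
#'   `trace` (all stages bound together; stage `"final"` marks the
#'   BH-surviving effects).
#' @export
finalize_and_score <- function(full_table, calibration_table, design,
                               alpha_impact = 0.1, alpha_trim = 0.05,
                               alpha_bh = 0.05, quad_points = 21) {
  imp <- fit_impact_model(calibration_table, design, alpha = alpha_impact,
                          quad_points = quad_points)
  scan <- scan_item_dif(calibration_table, design, imp$trace,
                        alpha = alpha_trim, quad_points = quad_points,
                        init = imp$fit$params)
  trim <- trim_and_refit(calibration_table, design,
                         rbind(imp$trace, scan), alpha = alpha_trim,
                         quad_points = quad_points,
                         init = imp$fit$params)
  tt <- trim$trace
  keep_idx <- bh_correct(tt$p, alpha_bh)
  final_effects <- tt[keep_idx, , drop = FALSE]
  items <- names(rt_map(calibration_table))
  p0 <- mnlfa_params(items, design$covariates)
  final_mask <- mask_from_effects(p0, final_effects)
  fit <- fit_mnlfa(calibration_table, design, final_mask,
                   quad_points = quad_points)
  wt <- moderation_rows(wald_tests(fit))
  final_trace <- new_trace("final", wt$block, wt$item, wt$covariate,
                           wt$estimate, wt$se, wt$p, TRUE, alpha_bh)
  tt$retained <- seq_len(nrow(tt)) %in% keep_idx
  scores <- eap_scores(fit$params, full_table, design,
                       quad_points = quad_points)
  list(fit = fit, scores = scores,
       trace = rbind(imp$trace, scan, tt, final_trace))
}

#' Two-seed calibration stability check
#'
#' Runs the whole pipeline twice with different calibration samples and
#' returns the Pearson correlation of the two EAP score sets over all
#' rows of the full table.
#'
#' @inheritParams finalize_and_score
#' @param seed1,seed2 calibration-sampling seeds.
#' @return the correlation `r`, with the two pipeline results attached
#'   as attributes `run1` and `run2`, and the calibration overlap
#'   fraction as `overlap`.
#' @export
stability_check <- function(full_table, seed1, seed2, design,
                            quad_points = 21, ...) {
  c1 <- draw_calibration_sample(full_table, seed1)
  c2 <- draw_calibration_sample(full_table, seed2)
  r1 <- finalize_and_score(full_table, c1, design,
                           quad_points = quad_points, ...)
  r2 <- finalize_and_score(full_table, c2, design,
                           quad_points = quad_points, ...)
  k1 <- paste(c1$participant_id, c1$age_months)
  k2 <- paste(c2$participant_id, c2$age_months)
  r <- cor(r1$scores$eta, r2$scores$eta)
  structure(r, run1 = r1, run2 = r2,
            overlap = mean(k1 %in% k2))
}

#' Correlation between EAP scores and raw subscale means
#'
#' @param scores a `factor_scores` table from the pipeline.
#' @param table the binary [response_table()] (same rows, same subscale)
#'   the scores were computed from.
#' @return Pearson r.
#' @export
score_vs_raw_mean <- function(scores, table) {
  stopifnot(inherits(table, "response_table"))
  if (nrow(scores) != nrow(table)) stop("mismatched rows")
  raw <- rowMeans(item_matrix(table), na.rm = TRUE)
  if (sd(raw, na.rm = TRUE) == 0) {
    stop("zero-variance raw means: correlation undefined")
  }
  cor(scores$eta, raw, use = "complete.obs")
}

#' Write a workflow trace as JSON
#'
#' @param trace a workflow-trace data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  jsonlite::write_json(trace, path, dataframe = "rows", pretty = TRUE,
                       na = "null")
  invisible(path)
}
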