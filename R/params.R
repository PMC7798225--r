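#' Moderator design for an MNLFA model
#'
#' Declares the observed covariates that may moderate the model and
#' which parameter blocks each may enter.  Age enters in months centered
#' at `age_center`; the age-by-cohort product is formed after centering.
#' By default all four covariates are candidates for the factor mean and
#' for item-level DIF, while only centered age may moderate the (log)
#' factor variance.
#'
#' @param covariates ordered covariate names; the defaults are
#'   `age_c` (months - `age_center`), `sex`, `cohort`, and
#'   `age_x_cohort` (their product).
#' @param mean_covariates covariates allowed on the factor mean.
#' @param var_covariates covariates allowed on the log factor variance.
#' @param dif_covariates covariates allowed on item intercepts/loadings.
#' @param age_center months; default 18.
#' @return an object of class `moderator_design`.
#' @export
moderator_design <- function(covariates = c("age_c", "sex", "cohort",
                                            "age_x_cohort"),
                             mean_covariates = covariates,
                             var_covariates = intersect("age_c", covariates),
                             dif_covariates = covariates,
                             age_center = 18) {
  stopifnot(all(mean_covariates %in% covariates),
            all(var_covariates %in% covariates),
            all(dif_covariates %in% covariates))
  structure(list(covariates = covariates,
                 mean_covariates = mean_covariates,
                 var_covariates = var_covariates,
                 dif_covariates = dif_covariates,
                 age_center = age_center),
            class = "moderator_design")
}

#' Covariate matrix implied by a design
#'
#' @param table a [response_table()] (or any data.frame with
#'   `age_months`, `sex`, `cohort`).
#' @param design a [moderator_design()].
#' @return numeric matrix, one column per design covariate.
#' @export
covariate_matrix <- function(table, design) {
  age_c <- table$age_months - design$age_center
  pool <- list(age_c = age_c, sex = as.numeric(table$sex),
               cohort = as.numeric(table$cohort),
               age_x_cohort = age_c * as.numeric(table$cohort))
  unknown <- setdiff(design$covariates, names(pool))
  for (u in unknown) {
    if (is.null(table[[u]])) stop("covariate not found in table: ", u)
    pool[[u]] <- as.numeric(table[[u]])
  }
  x <- do.call(cbind, pool[design$covariates])
  colnames(x) <- design$covariates
  if (!all(is.finite(x))) stop("non-finite covariate values")
  x
}

# Per-covariate optimizer scale: coefficients on (centered) age are of
# order 0.1 per month, others of order 1.
covariate_parscale <- function(design) {
  ifelse(design$covariates %in% c("age_c", "age_x_cohort"), 0.1, 1)
}

#' Parameter set of a moderated one-factor binary model
#'
#' Holds, for each item `j`, the baseline intercept `nu0[j]` and loading
#' `lambda0[j]` (logit units), the intercept-DIF row `kappa[j, ]` and
#' loading-DIF row `delta[j, ]` (one column per covariate), and the
#' structural coefficients: `gamma` on the factor mean and `omega` on
#' the log factor variance.  The factor mean and variance at the
#' covariate reference (all covariates 0) are fixed at 0 and 1.
#'
#' @param items character vector of item names.
#' @param covariates character vector of covariate names.
#' @param nu0,lambda0 length-`J` numerics (recycled).
#' @param kappa,delta `J x K` matrices (or scalars, recycled).
#' @param gamma,omega length-`K` numerics (recycled).
#' @return object of class `mnlfa_params`.
#' @export
mnlfa_params <- function(items, covariates, nu0 = 0, lambda0 = 1,
                         kappa = 0, delta = 0, gamma = 0, omega = 0) {
  j <- length(items); k <- length(covariates)
  expand_vec <- function(v, n, nm) {
    v <- rep_len(as.numeric(v), n); names(v) <- nm; v
  }
  expand_mat <- function(m, nm_r, nm_c) {
    if (is.matrix(m)) {
      stopifnot(nrow(m) == j, ncol(m) == k)
    } else {
      m <- matrix(as.numeric(m), j, k)
    }
    dimnames(m) <- list(nm_r, nm_c); m
  }
  structure(list(items = items, covariates = covariates,
                 nu0 = expand_vec(nu0, j, items),
                 lambda0 = expand_vec(lambda0, j, items),
                 kappa = expand_mat(kappa, items, covariates),
                 delta = expand_mat(delta, items, covariates),
                 gamma = expand_vec(gamma, k, covariates),
                 omega = expand_vec(omega, k, covariates)),
            class = "mnlfa_params")
}

#' @export
print.mnlfa_params <- function(x, ...) {
  cat("MNLFA parameter set:", length(x$items), "items,",
      length(x$covariates), "covariates\n")
  cat("  free-form moderation:",
      sum(x$kappa != 0), "intercept-DIF,", sum(x$delta != 0),
      "loading-DIF,", sum(x$gamma != 0), "mean,", sum(x$omega != 0),
      "variance coefficients nonzero\n")
  invisible(x)
}

#' Free-parameter mask for [fit_mnlfa()]
#'
#' Logical structure mirroring [mnlfa_params()]: `TRUE` entries are
#' estimated, `FALSE` entries stay at their initial value.  The default
#' frees every baseline intercept and loading and no moderation effect
#' (a plain 2PL).
#'
#' @param params an [mnlfa_params()] giving the items and covariates.
#' @param nu0,lambda0 logical, recycled over items.
#' @param kappa,delta logical `J x K` (or scalar, recycled).
#' @param gamma,omega logical, recycled over covariates.
#' @return object of class `mnlfa_mask`.
#' @export
param_mask <- function(params, nu0 = TRUE, lambda0 = TRUE, kappa = FALSE,
                       delta = FALSE, gamma = FALSE, omega = FALSE) {
  j <- length(params$items); k <- length(params$covariates)
  as_mat <- function(m) {
    if (is.matrix(m)) stopifnot(nrow(m) == j, ncol(m) == k)
    else m <- matrix(m, j, k)
    dimnames(m) <- list(params$items, params$covariates)
    m
  }
  structure(list(nu0 = setNames(rep_len(nu0, j), params$items),
                 lambda0 = setNames(rep_len(lambda0, j), params$items),
                 kappa = as_mat(kappa), delta = as_mat(delta),
                 gamma = setNames(rep_len(gamma, k), params$covariates),
                 omega = setNames(rep_len(omega, k), params$covariates)),
            class = "mnlfa_mask")
}

# Build a mask from a data.frame of moderation effects with columns
# block ("mean", "variance", "intercept", "loading"), item, covariate.
mask_from_effects <- function(params, effects, nu0 = TRUE, lambda0 = TRUE) {
  m <- param_mask(params, nu0 = nu0, lambda0 = lambda0)
  if (is.null(effects) || !nrow(effects)) return(m)
  key <- paste(effects$block, effects$item, effects$covariate)
  if (anyDuplicated(key)) stop("duplicate effect specification")
  for (i in seq_len(nrow(effects))) {
    b <- effects$block[i]; it <- effects$item[i]; cv <- effects$covariate[i]
    if (!cv %in% params$covariates) stop("unknown covariate: ", cv)
    if (b == "mean") m$gamma[cv] <- TRUE
    else if (b == "variance") m$omega[cv] <- TRUE
    else if (b == "intercept") m$kappa[it, cv] <- TRUE
    else if (b == "loading") m$delta[it, cv] <- TRUE
    else stop("unknown effect block: ", b)
  }
  m
}

# Pack the free entries of params into a named vector, and back.
pack_params <- function(params, mask) {
  p0 <- function(...) paste0(..., recycle0 = TRUE)
  out <- c(
    setNames(params$nu0[mask$nu0], p0("nu0:", names(params$nu0)[mask$nu0])),
    setNames(params$lambda0[mask$lambda0],
             p0("lambda0:", names(params$lambda0)[mask$lambda0])))
  idx <- which(mask$kappa, arr.ind = TRUE)
  if (nrow(idx)) {
    out <- c(out, setNames(params$kappa[idx],
      p0("kappa:", params$items[idx[, 1]], ":",
             params$covariates[idx[, 2]])))
  }
  idx <- which(mask$delta, arr.ind = TRUE)
  if (nrow(idx)) {
    out <- c(out, setNames(params$delta[idx],
      p0("delta:", params$items[idx[, 1]], ":",
             params$covariates[idx[, 2]])))
  }
  out <- c(out,
    setNames(params$gamma[mask$gamma],
             p0("gamma:", names(params$gamma)[mask$gamma])),
    setNames(params$omega[mask$omega],
             p0("omega:", names(params$omega)[mask$omega])))
  out
}

unpack_params <- function(theta, params, mask) {
  i <- 0L
  take <- function(n) {
    if (n == 0L) return(numeric(0))
    v <- theta[(i + 1L):(i + n)]; i <<- i + n; v
  }
  params$nu0[mask$nu0] <- take(sum(mask$nu0))
  params$lambda0[mask$lambda0] <- take(sum(mask$lambda0))
  params$kappa[mask$kappa] <- take(sum(mask$kappa))
  params$delta[mask$delta] <- take(sum(mask$delta))
  params$gamma[mask$gamma] <- take(sum(mask$gamma))
  params$omega[mask$omega] <- take(sum(mask$omega))
  params
}

# Gradient of the log-likelihood packed in the same order as pack_params.
pack_grad <- function(gl, mask) {
  c(gl$g_nu0[mask$nu0], gl$g_lambda0[mask$lambda0],
    gl$g_kappa[mask$kappa], gl$g_delta[mask$delta],
    gl$g_gamma[mask$gamma], gl$g_omega[mask$omega])
}

# Optimizer parscale for packed parameters: baseline parameters get 1,
# moderation coefficients inherit the covariate scale (0.1 for age).
pack_parscale <- function(params, mask, design) {
  cs <- setNames(covariate_parscale(design), design$covariates)
  sel <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) return(numeric(0))
    cs[params$covariates[idx[, 2]]]
  }
  unname(c(rep(1, sum(mask$nu0)), rep(1, sum(mask$lambda0)),
           sel(mask$kappa), sel(mask$delta),
           cs[names(params$gamma)[mask$gamma]],
           cs[names(params$omega)[mask$omega]]))
}
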