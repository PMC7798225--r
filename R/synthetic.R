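#' Default generating parameters for the three subscales
#'
#' The moderation coefficients are published final-model estimates for
#' this instrument, used as generating truth: repetitive motor -- factor-mean
#' age effect -0.107 and log-variance age effect 0.068, with loading DIF
#' of age -0.147 on the mouthing-objects item; self-directed --
#' factor-mean age effect -0.054; higher-order -- log-variance age
#' effect 0.043 and six age loading-DIF effects (arranging 0.214,
#' placement 0.152, restricted media 0.109, preoccupation with parts
#' -0.303, visual inspection -0.145, fascination with movement -0.261).
#' Baseline intercepts are evenly spread over `[-1.4, -0.1]` logits per
#' subscale (endorsement roughly 0.20-0.48 at the reference) and all
#' baseline loadings are 1; these baselines are package defaults, not
#' published values.
#'
#' @param map an [item_map()]; defaults to [default_item_map()].
#' @param design a [moderator_design()].
#' @return named list of [mnlfa_params()] for `repetitive_motor`,
#'   `self_directed` and `higher_order`.
#' @export
default_true_params <- function(map = default_item_map(),
                                design = moderator_design()) {
  k <- design$covariates
  spread <- function(j) seq(-1.4, -0.1, length.out = j)
  make <- function(items, gamma_age = 0, omega_age = 0, dif = NULL) {
    p <- mnlfa_params(items, k, nu0 = spread(length(items)), lambda0 = 1)
    p$gamma["age_c"] <- gamma_age
    p$omega["age_c"] <- omega_age
    for (nm in intersect(names(dif), items)) p$delta[nm, "age_c"] <- dif[[nm]]
    p
  }
  list(
    repetitive_motor = make(subscale_items(map, "repetitive_motor"),
                            gamma_age = -0.107, omega_age = 0.068,
                            dif = list(rm_mouthing = -0.147)),
    self_directed = make(subscale_items(map, "self_directed"),
                         gamma_age = -0.054),
    higher_order = make(subscale_items(map, "higher_order"),
                        omega_age = 0.043,
                        dif = list(rr_arranging = 0.214,
                                   rr_placement = 0.152,
                                   rr_media = 0.109,
                                   rs_parts = -0.303,
                                   rs_visual = -0.145,
                                   rs_movement = -0.261)))
}

#' Configuration of the synthetic accelerated-longitudinal design
#'
#' Defaults emulate the motivating two-cohort accelerated design: cohort A with
#' 110 participants (mean 3.85 sessions, SD 1.5, range 1-7; entry age
#' 11.0 months, SD 3.8), cohort B with 70 participants (mean 2.6
#' sessions, SD 0.8, range 1-3; entry 13.8 months, SD 3.2), inter-visit
#' gaps around 3.2 months, visits capped at `age_max` months, and about
#' half female per cohort.  Latent trajectories are linear (optionally
#' quadratic) in age centered at 18 months with person-level random
#' intercepts and slopes and a visit-level residual.
#'
#' @param n_participants named vector `c(A = , B = )`.
#' @param sessions_mean,sessions_sd,sessions_range per-cohort visit-count
#'   distribution (rounded normal, clamped to the range).
#' @param entry_age_mean,entry_age_sd,entry_age_range per-cohort entry
#'   age distribution (normal, clamped), months.
#' @param visit_gap_mean,visit_gap_sd,visit_gap_min inter-visit gap
#'   distribution, months.
#' @param female_prop per-cohort probability of sex = 1 (female).
#' @param age_max visits beyond this age are dropped (months).
#' @param map an [item_map()].
#' @param design a [moderator_design()].
#' @param true_params list of [mnlfa_params()] per subscale (defaults to
#'   [default_true_params()]); names must cover `repetitive_motor`,
#'   `self_directed`, `higher_order`.
#' @param trajectory per-subscale list of `intercept`, `slope`, `quad`
#'   (fixed effects on the centered-age scale), `ri_sd`, `rs_sd`
#'   (random intercept/slope SDs) and `resid_sd` (visit-level SD).
#' @param ordinal_levels list describing the ordinal emission used by
#'   [emit_ordinal()]: `median_level` (0-3), `low_probs` (within-level
#'   probabilities for levels `0:median_level`), `high_probs` (for
#'   levels above it).
#' @param item_missingness probability that an emitted item cell is set
#'   missing (default 0).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_participants = c(A = 110, B = 70),
                             sessions_mean = c(A = 3.85, B = 2.6),
                             sessions_sd = c(A = 1.5, B = 0.8),
                             sessions_range = list(A = c(1, 7), B = c(1, 3)),
                             entry_age_mean = c(A = 11.0, B = 13.8),
                             entry_age_sd = c(A = 3.8, B = 3.2),
                             entry_age_range = list(A = c(7.4, 30),
                                                    B = c(8.8, 19.3)),
                             visit_gap_mean = 3.2, visit_gap_sd = 1.0,
                             visit_gap_min = 1.5,
                             female_prop = c(A = 52 / 110, B = 40 / 70),
                             age_max = 36.5,
                             map = default_item_map(),
                             design = moderator_design(),
                             true_params = default_true_params(map, design),
                             trajectory = list(
                               repetitive_motor = list(intercept = 0,
                                 slope = -0.11, quad = 0, ri_sd = 1,
                                 rs_sd = 0.03, resid_sd = 1),
                               self_directed = list(intercept = 0,
                                 slope = -0.06, quad = 0, ri_sd = 1,
                                 rs_sd = 0.03, resid_sd = 1),
                               higher_order = list(intercept = 0,
                                 slope = -0.002, quad = -0.002, ri_sd = 1,
                                 rs_sd = 0.03, resid_sd = 1)),
                             ordinal_levels = list(median_level = 1,
                               low_probs = c(0.45, 0.55),
                               high_probs = c(0.5, 0.3, 0.2)),
                             item_missingness = 0) {
  for (s in names(trajectory)) {
    t <- trajectory[[s]]
    if (any(c(t$ri_sd, t$rs_sd, t$resid_sd) < 0)) {
      stop("trajectory SDs must be non-negative")
    }
  }
  if (any(unlist(lapply(sessions_range, min)) < 1)) {
    stop("visit counts must be >= 1")
  }
  for (s in c("repetitive_motor", "self_directed", "higher_order")) {
    p <- true_params[[s]]
    if (is.null(p)) stop("true_params lacks subscale: ", s)
    if (!setequal(p$items, subscale_items(map, s))) {
      stop("item_map and true_params disagree for subscale: ", s)
    }
  }
  structure(as.list(environment()), class = "generator_config")
}

# Draw the participant/visit structure (ids, cohort, sex, ages).
sample_design <- function(config, seed) {
  set.seed(seed)
  rows <- list()
  pid <- 0L
  for (co in names(config$n_participants)) {
    np <- config$n_participants[[co]]
    rng <- config$sessions_range[[co]]
    arng <- config$entry_age_range[[co]]
    for (i in seq_len(np)) {
      pid <- pid + 1L
      nv <- round(rnorm(1, config$sessions_mean[[co]], config$sessions_sd[[co]]))
      nv <- min(max(nv, rng[1]), rng[2])
      entry <- min(max(rnorm(1, config$entry_age_mean[[co]],
                             config$entry_age_sd[[co]]), arng[1]), arng[2])
      gaps <- pmax(rnorm(nv - 1, config$visit_gap_mean, config$visit_gap_sd),
                   config$visit_gap_min)
      ages <- entry + c(0, cumsum(gaps))
      ages <- ages[ages <= config$age_max]
      sex <- rbinom(1, 1, config$female_prop[[co]])
      rows[[pid]] <- data.frame(
        participant_id = sprintf("P%03d", pid),
        cohort = as.numeric(co == names(config$n_participants)[2]),
        sex = sex, age_months = round(ages, 1))
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic accelerated-longitudinal binary dataset
#'
#' Draws the participant/visit design, person-level latent trajectories
#' for each subscale (`eta = intercept + slope * age_c + quad * age_c^2 +
#' b0_i + b1_i * age_c + e_visit`, plus structural shifts for sex,
#' cohort and age-by-cohort from the generating parameters), and emits
#' each binary item with probability
#' `plogis(nu_j(x) + lambda_j(x) * eta)`.  The age-related decline of
#' the construct is carried by the trajectory's fixed slope, so the
#' generating `gamma` age coefficient is not applied again here.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed; output is reproducible given the seed.
#' @return list with `table` (a binary [response_table()]) and `truth`
#'   (participant random effects, per-row latent values per subscale,
#'   the generating parameters and the config).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  dsn <- sample_design(config, seed)
  n <- nrow(dsn)
  age_c <- dsn$age_months - config$design$age_center
  x <- covariate_matrix(dsn, config$design)

  subscales <- names(config$trajectory)
  eta_tab <- dsn[c("participant_id", "age_months")]
  ranef <- list()
  items_all <- list()
  ids <- unique(dsn$participant_id)
  idx <- match(dsn$participant_id, ids)

  for (s in subscales) {
    tr <- config$trajectory[[s]]
    p <- config$true_params[[s]]
    b0 <- rnorm(length(ids), 0, tr$ri_sd)
    b1 <- rnorm(length(ids), 0, tr$rs_sd)
    shift <- numeric(n)
    for (cv in setdiff(p$covariates, "age_c")) {
      shift <- shift + p$gamma[cv] * x[, cv]
    }
    eta <- tr$intercept + tr$slope * age_c + tr$quad * age_c^2 +
      b0[idx] + b1[idx] * age_c + rnorm(n, 0, tr$resid_sd) + shift
    eta_tab[[paste0("eta_", s)]] <- eta
    ranef[[s]] <- data.frame(participant_id = ids, b0 = b0, b1 = b1)

    nux <- matrix(p$nu0, n, length(p$items), byrow = TRUE) + x %*% t(p$kappa)
    lam <- matrix(p$lambda0, n, length(p$items), byrow = TRUE) +
      x %*% t(p$delta)
    pr <- plogis(nux + lam * eta)
    yj <- matrix(rbinom(length(pr), 1, pr), n)
    colnames(yj) <- p$items
    items_all[[s]] <- yj
  }

  y <- do.call(cbind, items_all)[, names(config$map), drop = FALSE]
  if (config$item_missingness > 0) {
    y[matrix(runif(length(y)) < config$item_missingness, nrow(y))] <- NA
  }
  df <- cbind(dsn[c("participant_id", "age_months", "sex", "cohort")],
              as.data.frame(y))
  table <- response_table(df, config$map, "binary")
  list(table = table,
       truth = list(eta = eta_tab, ranef = ranef,
                    params = config$true_params, config = config,
                    seed = seed))
}

#' Generating latent value for a participant-visit
#'
#' Looks up the stored ground-truth latent value for one participant,
#' subscale and (optionally) visit age in a [generate_cohort()] truth
#' record.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param participant_id participant identifier.
#' @param subscale subscale name.
#' @param visit_age optional age; if omitted, all of the participant's
#'   visits are returned.
#' @return numeric vector of latent values.
#' @export
calibration_truth <- function(truth, participant_id, subscale,
                              visit_age = NULL) {
  col <- paste0("eta_", subscale)
  if (!col %in% names(truth$eta)) stop("unknown subscale: ", subscale)
  rows <- truth$eta$participant_id == participant_id
  if (!any(rows)) stop("unknown participant: ", participant_id)
  if (!is.null(visit_age)) {
    rows <- rows & truth$eta$age_months == visit_age
    if (!any(rows)) stop("no visit at age ", visit_age, " for ", participant_id)
  }
  truth$eta[[col]][rows]
}

#' Emit an ordinal (0-4) dataset whose median split recovers the binary data
#'
#' Generates a binary cohort with [generate_cohort()] and maps each cell
#' to the 0-4 frequency scale: cells coded 0 draw a level in
#' `0:median_level` and cells coded 1 a level above it, with the
#' configured within-side probabilities.  Provided the binary
#' endorsement rate of every item is below 1/2 (true under the default
#' parameters), the empirical median of each emitted column equals
#' `median_level`, so [binarize_items()] returns the original binary
#' table.
#'
#' @inheritParams generate_cohort
#' @return an `ordinal04` [response_table()], with the source binary
#'   table in attribute `binary` and the truth record in `truth`.
#' @export
emit_ordinal <- function(config = generator_config(), seed = 1) {
  lv <- config$ordinal_levels
  m <- lv$median_level
  if (!is.numeric(m) || m < 0 || m > 3) stop("median_level must be in 0..3")
  lo <- lv$low_probs; hi <- lv$high_probs
  if (length(lo) != m + 1 || length(hi) != 4 - m) {
    stop("ordinal level probabilities do not match median_level")
  }
  if (any(lo <= 0) || any(hi <= 0)) {
    stop("non-monotone ordinal thresholds: level probabilities must be positive")
  }
  gen <- generate_cohort(config, seed)
  y <- item_matrix(gen$table)
  out <- y
  is0 <- !is.na(y) & y == 0
  is1 <- !is.na(y) & y == 1
  out[is0] <- sample(0:m, sum(is0), replace = TRUE, prob = lo)
  out[is1] <- sample((m + 1):4, sum(is1), replace = TRUE, prob = hi)
  df <- as.data.frame(gen$table)
  df[colnames(out)] <- as.data.frame(out)
  tab <- response_table(df, config$map, "ordinal04")
  attr(tab, "binary") <- gen$table
  attr(tab, "truth") <- gen$truth
  tab
}

#' Simulate independent calibration respondents from the structural model
#'
#' Cross-sectional draws: covariates are sampled (age from a truncated
#' normal emulating the study's calibration-sample age distribution),
#' the latent factor from `N(alpha(x), psi(x))`, and items from the
#' moderated measurement model.  This is the generator used for
#' parameter-recovery simulations.
#'
#' @param params an [mnlfa_params()] used as generating truth.
#' @param design a [moderator_design()].
#' @param n number of respondents.
#' @param seed RNG seed.
#' @param age_mean,age_sd,age_range age distribution in months.
#' @param female_prop,cohort_prop covariate probabilities.
#' @return list with `table` (binary [response_table()]) and `eta`
#'   (generating latent values).
#' @export
simulate_calibration <- function(params, design, n, seed = 1,
                                 age_mean = 17.9, age_sd = 6.2,
                                 age_range = c(8, 36),
                                 female_prop = 92 / 180,
                                 cohort_prop = 70 / 180) {
  set.seed(seed)
  age <- pmin(pmax(rnorm(n, age_mean, age_sd), age_range[1]), age_range[2])
  df <- data.frame(participant_id = sprintf("S%04d", seq_len(n)),
                   age_months = age,
                   sex = rbinom(n, 1, female_prop),
                   cohort = rbinom(n, 1, cohort_prop))
  x <- covariate_matrix(df, design)
  alpha <- drop(x %*% params$gamma)
  sigma <- exp(0.5 * drop(x %*% params$omega))
  eta <- rnorm(n, alpha, sigma)
  nux <- matrix(params$nu0, n, length(params$items), byrow = TRUE) +
    x %*% t(params$kappa)
  lam <- matrix(params$lambda0, n, length(params$items), byrow = TRUE) +
    x %*% t(params$delta)
  pr <- plogis(nux + lam * eta)
  y <- matrix(rbinom(length(pr), 1, pr), n)
  colnames(y) <- params$items
  sub <- unclass(default_item_map())[params$items]
  map <- if (all(params$items %in% names(default_item_map())) && !anyNA(sub)) {
    item_map(params$items, unname(sub))
  } else {
    item_map(params$items, rep("repetitive_motor", length(params$items)))
  }
  tab <- response_table(cbind(df, as.data.frame(y)), map, "binary")
  list(table = tab, eta = eta)
}

#' Simulate two correlated latent factors with binary indicators
#'
#' Latent pair from a standard bivariate normal with correlation `phi`;
#' items in set A load on the first factor, set B on the second.  Used
#' to exercise the configural structure check.
#'
#' @param n respondents.
#' @param nu0_A,lambda0_A,nu0_B,lambda0_B item parameters per set.
#' @param phi latent correlation in (-1, 1).
#' @param seed RNG seed.
#' @return list with `y` (binary matrix, columns `A1.. B1..`),
#'   `items_A`, `items_B`, and the latent draws `eta1`, `eta2`.
#' @export
simulate_two_factor <- function(n, nu0_A, lambda0_A = 1, nu0_B,
                                lambda0_B = 1, phi = 0.8, seed = 1) {
  stopifnot(abs(phi) < 1)
  set.seed(seed)
  e1 <- rnorm(n)
  e2 <- phi * e1 + sqrt(1 - phi^2) * rnorm(n)
  ja <- length(nu0_A); jb <- length(nu0_B)
  lambda0_A <- rep_len(lambda0_A, ja); lambda0_B <- rep_len(lambda0_B, jb)
  pa <- plogis(matrix(nu0_A, n, ja, byrow = TRUE) + outer(e1, lambda0_A))
  pb <- plogis(matrix(nu0_B, n, jb, byrow = TRUE) + outer(e2, lambda0_B))
  y <- cbind(matrix(rbinom(n * ja, 1, pa), n),
             matrix(rbinom(n * jb, 1, pb), n))
  colnames(y) <- c(paste0("A", seq_len(ja)), paste0("B", seq_len(jb)))
  list(y = y, items_A = paste0("A", seq_len(ja)),
       items_B = paste0("B", seq_len(jb)), eta1 = e1, eta2 = e2)
}

#' Simulate factor-score trajectories under the two-cohort visit design
#'
#' Person-visit outcomes follow a linear (optionally quadratic)
#' random-intercept/random-slope model on age centered at 18 months.
#' Used for growth-model recovery simulations.
#'
#' @param config a [generator_config()] supplying the visit design.
#' @param seed RNG seed.
#' @param intercept,slope,quad fixed effects.
#' @param ri_sd,rs_sd,resid_sd random-intercept, random-slope and
#'   residual SDs.
#' @param beta_sex,beta_sex_age sex effects on intercept and slope.
#' @return a data.frame with `participant_id`, `age_months`, `age_c`,
#'   `sex`, `cohort`, `outcome`.
#' @export
simulate_growth_data <- function(config = generator_config(), seed = 1,
                                 intercept = 0, slope = -0.11, quad = 0,
                                 ri_sd = 1, rs_sd = 0.03, resid_sd = 1,
                                 beta_sex = 0, beta_sex_age = 0) {
  dsn <- sample_design(config, seed)
  age_c <- dsn$age_months - config$design$age_center
  ids <- unique(dsn$participant_id)
  idx <- match(dsn$participant_id, ids)
  b0 <- rnorm(length(ids), 0, ri_sd)
  b1 <- rnorm(length(ids), 0, rs_sd)
  dsn$age_c <- age_c
  dsn$outcome <- intercept + slope * age_c + quad * age_c^2 +
    beta_sex * dsn$sex + beta_sex_age * dsn$sex * age_c +
    b0[idx] + b1[idx] * age_c + rnorm(nrow(dsn), 0, resid_sd)
  dsn[c("participant_id", "age_months", "age_c", "sex", "cohort", "outcome")]
}

#' Write a generator truth record as JSON
#'
#' Serializes the latent draws, random effects and generating
#' parameters of a [generate_cohort()] truth record.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(seed = truth$seed, eta = truth$eta, ranef = truth$ranef,
              params = lapply(truth$params, function(p) {
                list(items = p$items, covariates = p$covariates,
                     nu0 = p$nu0, lambda0 = p$lambda0,
                     kappa = p$kappa, delta = p$delta,
                     gamma = p$gamma, omega = p$omega)
              }))
  jsonlite::write_json(out, path, dataframe = "columns", matrix = "rowmajor",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
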