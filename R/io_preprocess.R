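#' Construct a long-format item-response table
#'
#' One row per participant-visit: identifier, age in months, sex
#' (0 = male, 1 = female), cohort (0 = first cohort, 1 = second) and one
#' column per item of `map`.  Item responses are integers 0-4 on the
#' `ordinal04` scale or 0/1 on the `binary` (post-median-split) scale;
#' missing responses are `NA`.
#'
#' @param df data.frame with columns `participant_id`, `age_months`,
#'   `sex`, `cohort` and every item named in `map`.
#' @param map an [item_map()] registering the item columns.
#' @param response_scale `"ordinal04"` or `"binary"`.
#' @return `df` (covariates first, items in map order) with class
#'   `response_table` and attributes `item_map` and `response_scale`.
#' @export
response_table <- function(df, map, response_scale = c("ordinal04", "binary")) {
  response_scale <- match.arg(response_scale)
  stopifnot(is.data.frame(df), inherits(map, "item_map"))
  req <- c("participant_id", "age_months", "sex", "cohort")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  miss_items <- setdiff(names(map), names(df))
  if (length(miss_items)) {
    stop("item column(s) absent from data: ",
         paste(miss_items, collapse = ", "))
  }
  for (v in req) {
    if (anyNA(df[[v]])) stop("missing values in required column '", v, "'")
  }
  if (any(df$age_months <= 0)) stop("age_months must be positive")
  df <- df[, c(req, names(map))]
  vals <- unlist(df[names(map)], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  rng <- if (response_scale == "binary") c(0, 1) else 0:4
  if (length(vals) && !all(vals %in% rng)) {
    stop("item responses outside the ", response_scale, " range")
  }
  structure(df, item_map = map, response_scale = response_scale,
            class = c("response_table", "data.frame"))
}

rt_map <- function(table) attr(table, "item_map")
rt_scale <- function(table) attr(table, "response_scale")

# Item responses as a numeric matrix in item-map order.
item_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, names(rt_map(table)), drop = FALSE])
}

#' Load item responses from a delimited text file
#'
#' Reads a comma-separated file with a header row naming
#' `participant_id`, `age_months`, `sex`, `cohort` and every item in
#' `map`.  Unparseable item cells (e.g. `"NA"`, `"."`, free text) become
#' missing; duplicated (participant, age) rows are kept with a warning.
#'
#' @inheritParams response_table
#' @param path path to the file.
#' @return a [response_table()] on the `ordinal04` scale.
#' @export
load_responses <- function(path, map = default_item_map()) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("participant_id", "age_months", "sex", "cohort")
  miss <- setdiff(c(req, names(map)), names(raw))
  if (length(miss)) {
    stop("schema error: file lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (it in names(map)) {
    v <- suppressWarnings(as.numeric(raw[[it]]))
    v[!is.na(v) & !(v %in% 0:4)] <- NA
    raw[[it]] <- v
  }
  key <- paste(raw$participant_id, raw$age_months)
  if (anyDuplicated(key)) {
    warning("duplicate (participant, age) rows present; keeping all")
  }
  response_table(raw, map, "ordinal04")
}

#' Exclude questionnaires by missingness and age range
#'
#' Removes rows whose fraction of missing item responses is at least
#' `max_missing_frac` and rows whose visit age falls outside
#' `age_bounds` (a half-open interval `[lo, hi)`).  Counts per exclusion
#' reason are recorded in the `exclusion_log` attribute of the result.
#' Missingness is evaluated before the age filter; a row failing both is
#' counted once, under missingness.
#'
#' @param table a [response_table()].
#' @param max_missing_frac fraction in (0, 1]; default 0.5.
#' @param age_bounds numeric length-2, months; default `c(8, 37)`.
#' @return the filtered table, with attribute `exclusion_log`.
#' @export
apply_exclusions <- function(table, max_missing_frac = 0.5,
                             age_bounds = c(8, 37)) {
  stopifnot(inherits(table, "response_table"),
            length(age_bounds) == 2, age_bounds[1] < age_bounds[2])
  y <- item_matrix(table)
  frac_missing <- rowMeans(is.na(y))
  drop_miss <- frac_missing >= max_missing_frac
  in_age <- table$age_months >= age_bounds[1] & table$age_months < age_bounds[2]
  drop_age <- !drop_miss & !in_age
  keep <- !drop_miss & !drop_age
  if (!any(keep)) stop("no rows survive exclusion")
  out <- table[keep, , drop = FALSE]
  attr(out, "exclusion_log") <- data.frame(
    reason = c("missingness", "age_range"),
    n_excluded = c(sum(drop_miss), sum(drop_age)),
    threshold = c(max_missing_frac,
                  paste0("[", age_bounds[1], ", ", age_bounds[2], ")")),
    stringsAsFactors = FALSE)
  out
}

#' Binarize ordinal items by per-item median split
#'
#' Each item's median is computed over all retained rows (missing cells
#' ignored); responses at or below the median are coded 0, responses
#' above it 1.  Missing cells are preserved.  The per-item medians are
#' stored in the `medians` attribute.
#'
#' @param table a [response_table()]; usually on the `ordinal04` scale.
#'   Already-binary tables are accepted (the same rule applies).
#' @return a binary-scale [response_table()].
#' @export
binarize_items <- function(table) {
  stopifnot(inherits(table, "response_table"))
  y <- item_matrix(table)
  all_missing <- colSums(!is.na(y)) == 0
  if (any(all_missing)) {
    stop("item(s) entirely missing: ",
         paste(colnames(y)[all_missing], collapse = ", "))
  }
  med <- apply(y, 2, median, na.rm = TRUE)
  yb <- 1 * sweep(y, 2, med, `>`)
  df <- as.data.frame(table)
  df[colnames(yb)] <- as.data.frame(yb)
  out <- response_table(df, rt_map(table), "binary")
  attr(out, "medians") <- med
  attr(out, "exclusion_log") <- attr(table, "exclusion_log")
  out
}

#' Restrict a table to one subscale's items
#'
#' Covariate columns are preserved; item columns are subset to the
#' requested subscale (including the merged `higher_order` view).
#' Taking the same view twice is the identity.
#'
#' @param table a [response_table()].
#' @param label subscale label registered in the table's item map, or
#'   `"higher_order"`.
#' @return a [response_table()] with the subset item map.
#' @export
subscale_view <- function(table, label) {
  stopifnot(inherits(table, "response_table"))
  map <- rt_map(table)
  items <- subscale_items(map, label)
  if (!length(items)) stop("no items registered for subscale: ", label)
  sub_map <- item_map(items, unname(unclass(map)[items]))
  df <- as.data.frame(table)[, c("participant_id", "age_months", "sex",
                                 "cohort", items)]
  out <- response_table(df, sub_map, rt_scale(table))
  attr(out, "subscale") <- label
  attr(out, "medians") <- attr(table, "medians")[items]
  out
}

#' Per-row composite and subscale scores
#'
#' For a binary table, counts items endorsed overall (`composite`) and
#' per subscale; missing items are ignored, with the number of items
#' contributing reported in `n_items_observed`.
#'
#' @param table a binary-scale [response_table()].
#' @return data.frame with one row per input row: `participant_id`,
#'   `age_months`, `n_items_observed`, `composite`, one sum per base
#'   subscale, and `higher_order`.
#' @export
composite_scores <- function(table) {
  stopifnot(inherits(table, "response_table"))
  if (rt_scale(table) != "binary") {
    stop("composite_scores requires a binary table; run binarize_items first")
  }
  y <- item_matrix(table)
  map <- rt_map(table)
  out <- data.frame(participant_id = table$participant_id,
                    age_months = table$age_months,
                    n_items_observed = rowSums(!is.na(y)),
                    composite = rowSums(y, na.rm = TRUE))
  for (s in intersect(base_subscales(), unique(unclass(map)))) {
    cols <- subscale_items(map, s)
    out[[s]] <- rowSums(y[, cols, drop = FALSE], na.rm = TRUE)
  }
  ho <- subscale_items(map, "higher_order")
  if (length(ho)) out$higher_order <- rowSums(y[, ho, drop = FALSE], na.rm = TRUE)
  out
}

#' Write a response table (and its exclusion log) as delimited text
#'
#' @param table a [response_table()].
#' @param path output CSV path.
#' @param log_path optional path for the exclusion log.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path, log_path = NULL) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  log <- attr(table, "exclusion_log")
  if (!is.null(log_path) && !is.null(log)) {
    write.csv(log, log_path, row.names = FALSE)
  }
  invisible(path)
}
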