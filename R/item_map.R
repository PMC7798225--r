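#' Item-to-subscale map
#'
#' An item map assigns each questionnaire item to one of the four base
#' subscales of the 34-item early-childhood repetitive-behavior
#' questionnaire: `repetitive_motor` (9 items), `ritual_routine` (10),
#' `restricted` (8) and `self_directed` (7).  The merged view
#' `higher_order` is the union of `ritual_routine` and `restricted`
#' (18 items) and is always available for lookup.
#'
#' @param items character vector of item (column) names.
#' @param subscales character vector of the same length with values in
#'   `repetitive_motor`, `ritual_routine`, `restricted`, `self_directed`.
#' @return named character vector (item -> subscale) of class `item_map`.
#' @seealso [default_item_map()], [subscale_items()]
#' @export
item_map <- function(items, subscales) {
  stopifnot(is.character(items), length(items) == length(subscales))
  if (anyDuplicated(items)) stop("duplicate item names in item map")
  bad <- setdiff(unique(subscales), base_subscales())
  if (length(bad)) {
    stop("unknown subscale label(s): ", paste(bad, collapse = ", "))
  }
  structure(setNames(as.character(subscales), items), class = "item_map")
}

base_subscales <- function() {
  c("repetitive_motor", "ritual_routine", "restricted", "self_directed")
}

#' Default item map for the 34-item instrument
#'
#' Items carrying known age-related loading DIF in the default generating
#' parameters are given descriptive names (e.g. `rm_mouthing`,
#' `rr_arranging`, `rs_parts`); the remainder use positional names.
#'
#' @return an [item_map()] with 9 + 10 + 8 + 7 = 34 items.
#' @export
default_item_map <- function() {
  rm_items <- c("rm_mouthing", paste0("rm_", sprintf("%02d", 2:9)))
  rr_items <- c("rr_arranging", "rr_placement", "rr_media",
                paste0("rr_", sprintf("%02d", 4:10)))
  rs_items <- c("rs_parts", "rs_visual", "rs_movement",
                paste0("rs_", sprintf("%02d", 4:8)))
  sd_items <- paste0("sd_", sprintf("%02d", 1:7))
  item_map(c(rm_items, rr_items, rs_items, sd_items),
           c(rep("repetitive_motor", 9), rep("ritual_routine", 10),
             rep("restricted", 8), rep("self_directed", 7)))
}

#' Items belonging to a subscale
#'
#' @param map an [item_map()].
#' @param label a base subscale label or `"higher_order"` (the merged
#'   ritual-routine + restricted set).
#' @return character vector of item names.
#' @export
subscale_items <- function(map, label) {
  stopifnot(inherits(map, "item_map"))
  if (identical(label, "higher_order")) {
    return(names(map)[map %in% c("ritual_routine", "restricted")])
  }
  if (!label %in% base_subscales()) {
    stop("unknown subscale label: ", label)
  }
  names(map)[map == label]
}

#' Write / read an item map as flat JSON
#'
#' @param map an [item_map()].
#' @param path file path.
#' @return `read_item_map` returns an [item_map()]; `write_item_map`
#'   returns `path` invisibly.
#' @export
write_item_map <- function(map, path) {
  stopifnot(inherits(map, "item_map"))
  jsonlite::write_json(as.list(unclass(map)), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_item_map
#' @export
read_item_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  item_map(names(x), unlist(x, use.names = FALSE))
}
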