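#' Construct a two-mode store--supplier network
#'
#' A `bipartite_network` holds the mode label (`"HSN"` for the healthy
#' supplier network, `"UHSN"` for the unhealthy one), the full store roster
#' (stores keep degree 0 rather than dropping out), the suppliers with at
#' least one edge, and the deduplicated edge set.
#'
#' @param mode `"HSN"` or `"UHSN"`.
#' @param stores Character vector of all store ids in the dataset.
#' @param edges Tibble with columns `store_id`, `supplier_id`.
#' @return A `bipartite_network`.
#' @export
new_bipartite_network <- function(mode, stores, edges) {
  if (!mode %in% c("HSN", "UHSN")) {
    cn_usage_error("network mode must be 'HSN' or 'UHSN'")
  }
  edges <- tibble::as_tibble(edges) |>
    dplyr::distinct(.data$store_id, .data$supplier_id) |>
    dplyr::arrange(.data$store_id, .data$supplier_id)
  if (!all(edges$store_id %in% stores)) {
    cn_integrity_error("edge references a store not in the store roster")
  }
  structure(list(mode = mode,
                 stores = sort(unique(stores)),
                 suppliers = sort(unique(edges$supplier_id)),
                 edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("<bipartite_network ", x$mode, "> ", length(x$stores), " stores, ",
      length(x$suppliers), " suppliers, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Classify items against the promoted-food catalog
#'
#' Items are canonicalized (trim/collapse/lowercase) and looked up in the
#' catalog; items absent from the catalog are `"unknown"` — they are
#' reported, never silently dropped.
#'
#' @param item_name Character vector of item names.
#' @param catalog A validated catalog tibble.
#' @return Character vector in `{"healthy", "unhealthy", "unknown"}`.
#' @export
#' @examples
#' cat <- validate_catalog(data.frame(
#'   item = c("bottled water", "chips"), class = c("healthy", "unhealthy")))
#' classify_item(c("  Bottled  WATER ", "chips", "motor oil"), cat)
classify_item <- function(item_name, catalog) {
  if (nrow(catalog) == 0) cn_config_error("promoted-food catalog is empty")
  cls <- catalog$class[match(canonicalize_item(item_name), catalog$item)]
  ifelse(is.na(cls), "unknown", cls)
}

#' Build the healthy and unhealthy supplier networks
#'
#' A store--supplier edge enters the HSN when the store reports at least one
#' healthy-classified purchase from that supplier, and enters the UHSN when
#' at least one purchase is unhealthy-classified. The two networks are not
#' mutually exclusive: a supplier selling both soda and bananas to the same
#' store appears in both. Purchases whose item is not in the catalog
#' contribute to neither network and are returned for reporting.
#'
#' @param purchases,catalog,stores,suppliers Validated dataset tables (see
#'   [load_dataset()]).
#' @return List with elements `hsn`, `uhsn` (both `bipartite_network`) and
#'   `unknown_items` (tibble `store_id`, `supplier_id`, `item_name`).
#' @export
build_networks <- function(purchases, catalog, stores, suppliers) {
  cls <- classify_item(purchases$item_name, catalog)
  edge_set <- function(keep) {
    purchases[keep, c("store_id", "supplier_id")] |>
      dplyr::distinct()
  }
  list(
    hsn = new_bipartite_network("HSN", stores$store_id,
                                edge_set(cls == "healthy")),
    uhsn = new_bipartite_network("UHSN", stores$store_id,
                                 edge_set(cls == "unhealthy")),
    unknown_items = purchases[cls == "unknown",
                              c("store_id", "supplier_id", "item_name")]
  )
}

#' Extract the supplier roster of a built network
#'
#' Converts a `bipartite_network` into roster form (one row per supplier
#' present in the network, with its name, category, and roster-entry
#' multiplicity) so that [roster_summary()] can be applied to built networks
#' and to packaged roster fixtures alike.
#'
#' @param network A `bipartite_network`.
#' @param suppliers The supplier table the network was built from.
#' @return Tibble with columns `network`, `category`, `name`, `multiplicity`.
#' @export
network_roster <- function(network, suppliers) {
  idx <- match(network$suppliers, suppliers$supplier_id)
  if (anyNA(idx)) cn_integrity_error("network supplier missing from supplier table")
  tibble::tibble(network = network$mode,
                 category = suppliers$category[idx],
                 name = suppliers$name[idx],
                 multiplicity = suppliers$multiplicity[idx])
}

#' Summarize a supplier roster under both counting conventions
#'
#' Supplier rosters can be counted two ways: *entries*, expanding a
#' multiplicity annotation such as a chain listed once with multiplicity 2
#' into 2 entries; and *distinct*, collapsing by supplier name. Both are
#' reported, together with per-category counts and the distinct-name overlap
#' with the other mode's roster.
#'
#' @param roster Tibble with columns `network`, `category`, `name`,
#'   `multiplicity` (from [network_roster()] or [supplier_roster_fixture()],
#'   filtered to one mode).
#' @param other_roster Roster of the other mode, for the overlap count
#'   (`NULL` to skip).
#' @return A list of class `roster_summary`: `mode`, `n_entries`,
#'   `n_distinct`, `per_category` (tibble `category`, `n_entries`,
#'   `n_distinct`), `overlap_with_other_mode`.
#' @export
roster_summary <- function(roster, other_roster = NULL) {
  mode <- unique(roster$network)
  if (length(mode) > 1) {
    cn_usage_error("roster_summary expects a single-mode roster; filter by network first")
  }
  if (nrow(roster) == 0) mode <- NA_character_
  per_cat <- roster |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_entries = sum(.data$multiplicity),
                     n_distinct = dplyr::n_distinct(.data$name),
                     .groups = "drop")
  overlap <- if (is.null(other_roster)) NA_integer_ else {
    length(intersect(unique(roster$name), unique(other_roster$name)))
  }
  structure(list(mode = mode,
                 n_entries = sum(roster$multiplicity),
                 n_distinct = dplyr::n_distinct(roster$name),
                 per_category = per_cat,
                 overlap_with_other_mode = overlap),
            class = "roster_summary")
}

#' @export
print.roster_summary <- function(x, ...) {
  cat("<roster_summary ", x$mode, "> entries ", x$n_entries,
      ", distinct ", x$n_distinct, ", overlap ", x$overlap_with_other_mode,
      "\n", sep = "")
  invisible(x)
}

#' Drop purchases from delivering suppliers
#'
#' Sensitivity-analysis filter: keeps only purchases whose supplier does not
#' deliver, i.e. the self-supply trips where travel distance plausibly
#' matters.
#'
#' @param purchases,suppliers Validated dataset tables.
#' @return The filtered purchase tibble.
#' @export
filter_delivering <- function(purchases, suppliers) {
  delivering <- suppliers$supplier_id[suppliers$delivers]
  purchases[!purchases$supplier_id %in% delivering, , drop = FALSE]
}
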