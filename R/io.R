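read_csv_strict <- function(path, col_types) {
  if (!file.exists(path)) cn_data_error(paste0("file not found: ", path))
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' Load a store/supplier/purchase/catalog dataset from CSV
#'
#' Reads the four tables, validates every type invariant, and enforces
#' referential integrity (purchases must reference known stores and
#' suppliers; supplier names must be unique). Catalog item names are
#' canonicalized on load.
#'
#' @param store_path,supplier_path,purchase_path,catalog_path CSV paths. See
#'   the package vignette for the column schemas.
#' @return A list with class `cornernet_dataset` and elements `stores`,
#'   `suppliers`, `purchases`, `catalog`.
#' @export
load_dataset <- function(store_path, supplier_path, purchase_path, catalog_path) {
  stores <- validate_stores(read_csv_strict(store_path, readr::cols(
    store_id = readr::col_character(),
    accepts_wic = readr::col_logical(),
    accepts_snap = readr::col_logical(),
    owner_ethnicity = readr::col_character(),
    .default = readr::col_double()
  )))
  suppliers <- validate_suppliers(read_csv_strict(supplier_path, readr::cols(
    supplier_id = readr::col_character(),
    name = readr::col_character(),
    category = readr::col_character(),
    delivers = readr::col_logical(),
    sites = readr::col_character(),
    .default = readr::col_integer()
  )))
  purchases <- validate_purchases(read_csv_strict(purchase_path, readr::cols(
    store_id = readr::col_character(),
    supplier_id = readr::col_character(),
    item_name = readr::col_character(),
    .default = readr::col_guess()
  )), stores = stores, suppliers = suppliers)
  catalog <- validate_catalog(read_csv_strict(catalog_path, readr::cols(
    .default = readr::col_character()
  )))
  new_dataset(stores, suppliers, purchases, catalog)
}

#' Assemble a validated dataset from in-memory tables
#'
#' @param stores,suppliers,purchases,catalog Tables matching the CSV schemas.
#' @return A `cornernet_dataset` list.
#' @export
new_dataset <- function(stores, suppliers, purchases, catalog) {
  stores <- validate_stores(stores)
  suppliers <- validate_suppliers(suppliers)
  purchases <- validate_purchases(purchases, stores, suppliers)
  catalog <- validate_catalog(catalog)
  structure(list(stores = stores, suppliers = suppliers,
                 purchases = purchases, catalog = catalog),
            class = "cornernet_dataset")
}

#' Write a dataset to four CSV files
#'
#' Inverse of [load_dataset()]: writing then re-reading reproduces the
#' collections field-by-field.
#'
#' @param dataset A `cornernet_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("stores.csv", "suppliers.csv",
                            "purchases.csv", "catalog.csv"))
  readr::write_csv(dataset$stores, paths[1], progress = FALSE)
  readr::write_csv(dataset$suppliers, paths[2], progress = FALSE)
  readr::write_csv(dataset$purchases, paths[3], progress = FALSE)
  readr::write_csv(dataset$catalog, paths[4], progress = FALSE)
  invisible(paths)
}

#' @export
print.cornernet_dataset <- function(x, ...) {
  cat("<cornernet_dataset> ", nrow(x$stores), " stores, ",
      nrow(x$suppliers), " suppliers, ", nrow(x$purchases), " purchases, ",
      nrow(x$catalog), " catalog items\n", sep = "")
  invisible(x)
}

as_igraph <- function(network, core_suppliers = NULL) {
  if (inherits(network, "bipartite_network")) {
    nodes <- tibble::tibble(
      name = c(network$stores, network$suppliers),
      role = c(rep("store", length(network$stores)),
               rep("supplier", length(network$suppliers))),
      type = c(rep(FALSE, length(network$stores)),
               rep(TRUE, length(network$suppliers)))
    )
    if (!is.null(core_suppliers)) {
      nodes$core <- nodes$name %in% core_suppliers
    }
    g <- igraph::graph_from_data_frame(
      network$edges[, c("store_id", "supplier_id")],
      directed = FALSE, vertices = nodes)
    g <- igraph::set_graph_attr(g, "mode", network$mode)
    g
  } else if (inherits(network, "one_mode_network")) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("store_a", "store_b", "weight")],
      directed = FALSE,
      vertices = tibble::tibble(name = network$stores, role = "store"))
    g
  } else {
    cn_usage_error("export_graph expects a bipartite_network or one_mode_network")
  }
}

#' Export a network to GraphML or a weighted edge-list CSV
#'
#' Bipartite exports tag each node's role (store/supplier) and, when a core
#' result is supplied, core membership; one-mode exports carry the
#' shared-supplier edge weights. [import_graph()] reproduces the node and
#' edge sets exactly.
#'
#' @param network A `bipartite_network` or `one_mode_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @param core_suppliers Optional character vector of core supplier ids to
#'   tag in a bipartite export.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(network, path, format = c("graphml", "edgelist_csv"),
                         core_suppliers = NULL) {
  if (!is.character(format) || !format[1] %in% c("graphml", "edgelist_csv")) {
    cn_usage_error(paste0("unknown graph format: ", format[1]))
  }
  format <- format[1]
  if (format == "graphml") {
    g <- as_igraph(network, core_suppliers)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    if (inherits(network, "bipartite_network")) {
      edges <- network$edges[, c("store_id", "supplier_id")]
    } else if (inherits(network, "one_mode_network")) {
      edges <- network$edges[, c("store_a", "store_b", "weight")]
    } else {
      cn_usage_error("export_graph expects a bipartite_network or one_mode_network")
    }
    readr::write_csv(edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path A GraphML file written by [export_graph()].
#' @return For bipartite exports, a `bipartite_network`; for one-mode
#'   exports, a `one_mode_network`.
#' @export
import_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  roles <- igraph::vertex_attr(g, "role")
  names <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  if (all(roles == "store")) {
    w <- igraph::edge_attr(g, "weight")
    if (is.null(w)) w <- rep(1L, nrow(el))
    edges <- tibble::tibble(store_a = pmin(el[, 1], el[, 2]),
                            store_b = pmax(el[, 1], el[, 2]),
                            weight = as.integer(w)) |>
      dplyr::arrange(.data$store_a, .data$store_b)
    new_one_mode_network(stores = sort(names), edges = edges)
  } else {
    is_store <- el[, 1] %in% names[roles == "store"]
    edges <- tibble::tibble(
      store_id = ifelse(is_store, el[, 1], el[, 2]),
      supplier_id = ifelse(is_store, el[, 2], el[, 1])
    ) |> dplyr::arrange(.data$store_id, .data$supplier_id)
    mode <- igraph::graph_attr(g, "mode")
    new_bipartite_network(mode = if (is.null(mode)) "HSN" else mode,
                          stores = sort(names[roles == "store"]),
                          edges = edges)
  }
}
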