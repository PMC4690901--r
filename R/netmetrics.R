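#' Construct a one-mode (store--store) network
#'
#' @param stores Character vector of all store ids (isolates included).
#' @param edges Tibble `store_a`, `store_b`, `weight` with `store_a <
#'   store_b`; weight is the shared-supplier count (>= 1).
#' @return A `one_mode_network`.
#' @export
new_one_mode_network <- function(stores, edges) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    if (any(edges$store_a == edges$store_b)) {
      cn_integrity_error("one-mode network may not contain self-loops")
    }
    if (any(edges$weight < 1)) {
      cn_integrity_error("one-mode edge weights must be >= 1")
    }
  }
  structure(list(stores = sort(unique(stores)),
                 edges = dplyr::arrange(edges, .data$store_a, .data$store_b)),
            class = "one_mode_network")
}

#' @export
print.one_mode_network <- function(x, ...) {
  cat("<one_mode_network> ", length(x$stores), " stores, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Two-mode degree centrality of every store
#'
#' A store's raw degree is its number of distinct supplier connections in
#' the network; normalized degree centrality divides by the number of
#' suppliers in that same network (HSN and UHSN denominators differ) and is
#' expressed as a percentage. All stores appear, including degree-0 stores.
#'
#' @param network A `bipartite_network`.
#' @return Tibble `store_id`, `mode`, `raw_degree`, `normalized_pct`. When
#'   the network has no suppliers the normalized column is `NA` and the
#'   result carries attribute `flagged = TRUE`.
#' @export
degree_centrality <- function(network) {
  deg <- table(factor(network$edges$store_id, levels = network$stores))
  n_sup <- length(network$suppliers)
  out <- tibble::tibble(
    store_id = network$stores,
    mode = network$mode,
    raw_degree = as.integer(deg),
    normalized_pct = if (n_sup == 0) NA_real_ else 100 * as.integer(deg) / n_sup
  )
  if (n_sup == 0) attr(out, "flagged") <- TRUE
  out
}

#' Extract the network core of suppliers by cumulative edge coverage
#'
#' Suppliers are ranked by degree (number of connected stores) in descending
#' order, ties broken by id ascending for reproducibility. The core is the
#' shortest prefix of that ranking whose summed degrees cover at least
#' `threshold` of the network's edges; core suppliers are the
#' highest-connectivity, most influential suppliers in the network.
#'
#' @param network A `bipartite_network` with at least one edge.
#' @param threshold Coverage proportion in (0, 1]; default 0.80.
#' @return A list of class `core_result`: `mode`, `ranked_suppliers` (tibble
#'   `supplier_id`, `degree`, `cum_coverage`), `core_suppliers`,
#'   `covered_edge_fraction`, `threshold`.
#' @export
extract_core <- function(network, threshold = 0.80) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    cn_usage_error("core threshold must lie in (0, 1]")
  }
  n_edges <- nrow(network$edges)
  if (n_edges == 0) cn_usage_error("cannot extract a core from an edgeless network")
  ranked <- network$edges |>
    dplyr::count(.data$supplier_id, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$supplier_id) |>
    dplyr::mutate(cum_coverage = cumsum(.data$degree) / n_edges)
  k <- which(ranked$cum_coverage >= threshold)[1]
  structure(list(mode = network$mode,
                 ranked_suppliers = ranked,
                 core_suppliers = ranked$supplier_id[seq_len(k)],
                 covered_edge_fraction = ranked$cum_coverage[k],
                 threshold = threshold),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat("<core_result ", x$mode, "> ", length(x$core_suppliers),
      " core suppliers covering ",
      sprintf("%.1f%%", 100 * x$covered_edge_fraction), " of edges\n", sep = "")
  invisible(x)
}

#' Supplier-category diversity of a store
#'
#' Number of distinct supplier categories among the store's network
#' neighbors; ranges from 0 (isolated store) to 7 (all categories).
#'
#' @param network A `bipartite_network`.
#' @param store_id A store id present in the network (vectorized).
#' @param suppliers The supplier table carrying categories.
#' @return Integer vector of category counts.
#' @export
diversity <- function(network, store_id, suppliers) {
  unknown <- setdiff(store_id, network$stores)
  if (length(unknown) > 0) {
    cn_usage_error(paste0("unknown store id: ", paste(unknown, collapse = ", ")))
  }
  cat_of <- setNames(suppliers$category, suppliers$supplier_id)
  vapply(store_id, function(s) {
    nb <- network$edges$supplier_id[network$edges$store_id == s]
    length(unique(cat_of[nb]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Project a two-mode network onto stores
#'
#' Two stores are adjacent in the one-mode projection when they share at
#' least one supplier; the edge weight is the number of shared suppliers.
#' Every store stays in the node set, so isolates remain visible.
#'
#' @param network A `bipartite_network`.
#' @return A `one_mode_network`.
#' @export
project_one_mode <- function(network) {
  if (nrow(network$edges) == 0) {
    return(new_one_mode_network(network$stores,
                                tibble::tibble(store_a = character(),
                                               store_b = character(),
                                               weight = integer())))
  }
  edges <- dplyr::inner_join(
    network$edges, network$edges, by = "supplier_id",
    relationship = "many-to-many", suffix = c("_a", "_b")) |>
    dplyr::filter(.data$store_id_a < .data$store_id_b) |>
    dplyr::count(store_a = .data$store_id_a, store_b = .data$store_id_b,
                 name = "weight") |>
    dplyr::mutate(weight = as.integer(.data$weight))
  new_one_mode_network(network$stores, edges)
}

#' One-mode network density
#'
#' Percentage of store pairs connected by at least one shared supplier:
#' `100 * |edges| / (n(n-1)/2)`. Weights are dichotomized and isolated
#' stores stay in the denominator, so density reads as overall cohesion of
#' the store set.
#'
#' @param one_mode A `one_mode_network` with at least 2 store nodes.
#' @return Density as a percentage in [0, 100].
#' @export
one_mode_density <- function(one_mode) {
  n <- length(one_mode$stores)
  if (n < 2) cn_usage_error("density is undefined for fewer than 2 stores")
  100 * nrow(one_mode$edges) / (n * (n - 1) / 2)
}

#' Shared-supplier statistics of a one-mode network
#'
#' Mean/min/max of the positive shared-supplier counts over connected store
#' pairs, and the number of isolated stores (degree 0 in the projection).
#'
#' @param one_mode A `one_mode_network`.
#' @return A list of class `shared_stats`: `mean_shared`, `min_shared`,
#'   `max_shared`, `n_isolates`. With zero edges the mean is `NA` and
#'   min/max are absent (`NA`); every store is then an isolate.
#' @export
shared_stats <- function(one_mode) {
  connected <- unique(c(one_mode$edges$store_a, one_mode$edges$store_b))
  w <- one_mode$edges$weight
  structure(list(
    mean_shared = if (length(w) == 0) NA_real_ else mean(w),
    min_shared = if (length(w) == 0) NA_integer_ else min(w),
    max_shared = if (length(w) == 0) NA_integer_ else max(w),
    n_isolates = length(setdiff(one_mode$stores, connected))
  ), class = "shared_stats")
}

#' @export
print.shared_stats <- function(x, ...) {
  cat("<shared_stats> mean ", format(x$mean_shared), ", range ",
      x$min_shared, "-", x$max_shared, ", isolates ", x$n_isolates,
      "\n", sep = "")
  invisible(x)
}
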