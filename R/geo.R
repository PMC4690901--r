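EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#' Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(39.2904, -76.6122, 38.9072, -77.0369) # Baltimore -> DC
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    cn_data_error("coordinates out of range: |lat| <= 90, |lon| <= 180")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Store-to-supplier distances with nearest-site resolution
#'
#' For every edge of the given network, computes the great-circle distance
#' from the store to the nearest of the supplier's distribution sites
#' (suppliers with several sites are assumed to be visited at the site
#' closest to the store), then averages per store over that store's
#' connected suppliers.
#'
#' @param stores,suppliers Validated dataset tables.
#' @param network A `bipartite_network` naming the edges to measure.
#' @return A list of class `distance_table`: `distances` (tibble `store_id`,
#'   `supplier_id`, `km`, `site_index`) and `store_means` (tibble
#'   `store_id`, `mean_km`; `NA` for stores with no connected supplier).
#' @export
store_supplier_distances <- function(stores, suppliers, network) {
  sites <- parse_sites(suppliers)
  edges <- network$edges
  no_site <- setdiff(unique(edges$supplier_id), unique(sites$supplier_id))
  if (length(no_site) > 0) {
    cn_data_error(paste0("connected supplier(s) with no distribution site: ",
                         paste(no_site, collapse = ", ")))
  }
  st <- stores[match(edges$store_id, stores$store_id), c("latitude", "longitude")]
  per_edge <- dplyr::bind_cols(edges, st) |>
    dplyr::inner_join(sites, by = "supplier_id", suffix = c("_store", "_site"),
                      relationship = "many-to-many") |>
    dplyr::mutate(km = haversine_km(.data$latitude_store, .data$longitude_store,
                                    .data$latitude_site, .data$longitude_site)) |>
    dplyr::arrange(.data$store_id, .data$supplier_id, .data$km,
                   .data$site_index) |>
    dplyr::distinct(.data$store_id, .data$supplier_id, .keep_all = TRUE) |>
    dplyr::select("store_id", "supplier_id", "km", "site_index")
  means <- per_edge |>
    dplyr::group_by(.data$store_id) |>
    dplyr::summarise(mean_km = mean(.data$km), .groups = "drop")
  store_means <- tibble::tibble(store_id = network$stores) |>
    dplyr::left_join(means, by = "store_id")
  structure(list(distances = per_edge, store_means = store_means),
            class = "distance_table")
}
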