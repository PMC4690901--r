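#' Built-in promoted-food catalog
#'
#' A compact catalog in the promoted-food style used for classification:
#' healthy items split into lower-calorie beverages, healthier essentials,
#' and healthier snacks; unhealthy items are the snack-food staples higher
#' in salt, fat, and sugar.
#'
#' @return A validated catalog tibble.
#' @export
default_catalog <- function() {
  validate_catalog(tibble::tibble(
    item = c("bottled water", "diet soda", "low-fat milk",
             "whole wheat bread", "canned tuna in water", "frozen vegetables",
             "fresh fruit", "baked chips", "bananas",
             "chips", "candy", "baked goods", "soda",
             "sugar sweetened beverage", "ice cream", "cookies", "pastries",
             "deli meats"),
    class = c(rep("healthy", 9), rep("unhealthy", 9)),
    subclass = c(rep("lower_calorie_beverage", 3),
                 rep("healthier_essential", 3),
                 rep("healthier_snack", 3), rep(NA_character_, 9))
  ))
}

healthy_menu_for <- function(category, index_in_category, config) {
  switch(category,
    wholesale_club = ,
    supermarket_grocery = ,
    discount_department = c("bottled water", "diet soda", "low-fat milk",
                            "whole wheat bread", "canned tuna in water",
                            "frozen vegetables", "fresh fruit", "baked chips",
                            "bananas"),
    snacks = if (index_in_category <= config$n_healthy_snack_suppliers)
      c("baked chips") else character(),
    beverages = c("bottled water", "diet soda"),
    specialty_foods = if (index_in_category <= config$n_healthy_specialty_suppliers)
      c("whole wheat bread") else character(),
    meat_market = character())
}

unhealthy_menu_for <- function(category) {
  switch(category,
    wholesale_club = ,
    supermarket_grocery = ,
    discount_department = c("chips", "candy", "baked goods", "soda", "cookies"),
    snacks = c("chips", "candy", "cookies", "pastries", "ice cream"),
    beverages = c("soda", "sugar sweetened beverage"),
    specialty_foods = c("baked goods", "pastries"),
    meat_market = c("deli meats"))
}

#' Configuration for the synthetic procurement-data generator
#'
#' Defaults emulate the study conditions the analysis targets: 24 corner
#' stores; 42 suppliers across the seven categories (11 wholesale clubs, 10
#' snacks, 4 specialty foods, 5 beverages, 9 supermarkets/groceries, 2
#' discount department stores, 1 meat market); a dense unhealthy network
#' (tie probability 0.215, i.e. a mean normalized UHSN centrality near
#' 21.5%) and a sparse healthy one (baseline tie probability 0.117 for the
#' reference-ethnicity stores); store attributes matching the observed
#' covariate distribution (WIC acceptance 45.8%, SNAP 91.7%, 79%
#' Asian/Hispanic owners, tenure/customer/employee moments); and additive
#' covariate effects on expected healthy raw degree (ethnicity -1.5
#' connections, SNAP -1.9), applied to the healthy network only.
#'
#' Effects are spread uniformly over the healthy-capable suppliers
#' (wholesale clubs, supermarkets, discount stores, the beverage companies'
#' lower-calorie lines, plus a few snack/specialty suppliers), so the
#' expected raw-degree shift equals the configured effect exactly as long as
#' no per-supplier probability is driven below 0; probabilities are clamped
#' to [0, 1] with a warning otherwise.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_stores = 24L,
    suppliers_per_category = c(wholesale_club = 11L, snacks = 10L,
                               specialty_foods = 4L, beverages = 5L,
                               supermarket_grocery = 9L,
                               discount_department = 2L, meat_market = 1L),
    p_unhealthy_tie = 0.215,
    p_healthy_tie_base = 0.117,
    ethnicity_effect = -1.5,
    snap_effect = -1.9,
    wic_effect = 0,
    wic_rate = 0.458,
    snap_rate = 0.917,
    p_asian_hispanic = 0.79,
    years_current_mean = 9.5, years_current_sd = 7.7,
    years_any_mean = 15.6, years_any_sd = 9.1,
    customers_mean = 165.0, customers_sd = 145.2,
    nonfamily_mean = 0.75, family_mean = 1.96,
    delivery_rate = 0.5,
    store_bbox = c(lat_min = 39.20, lat_max = 39.37,
                   lon_min = -76.71, lon_max = -76.53),
    site_bbox = c(lat_min = 39.00, lat_max = 39.60,
                  lon_min = -77.10, lon_max = -76.20),
    n_sites_range = c(1L, 3L),
    n_healthy_snack_suppliers = 2L,
    n_healthy_specialty_suppliers = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    cn_config_error(paste0("unknown synthetic_config field(s): ",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, overrides)
  probs <- c(cfg$p_unhealthy_tie, cfg$p_healthy_tie_base, cfg$wic_rate,
             cfg$snap_rate, cfg$p_asian_hispanic, cfg$delivery_rate)
  if (any(probs < 0 | probs > 1)) {
    cn_config_error("all probabilities must lie in [0, 1]")
  }
  if (any(cfg$suppliers_per_category < 0) || cfg$n_stores < 1) {
    cn_config_error("counts must be nonnegative (and n_stores >= 1)")
  }
  structure(cfg, class = "synthetic_config")
}

runif_box <- function(n, bbox) {
  tibble::tibble(
    latitude = round(runif(n, bbox[["lat_min"]], bbox[["lat_max"]]), 6),
    longitude = round(runif(n, bbox[["lon_min"]], bbox[["lon_max"]]), 6)
  )
}

#' Generate a synthetic store/supplier/purchase dataset
#'
#' Draws a reproducible dataset with the statistical structure the analysis
#' assumes: store attributes from the configured covariate distributions;
#' suppliers with category-specific healthy/unhealthy product menus
#' (beverage and snack suppliers carry mostly unhealthy items, wholesalers
#' and supermarkets carry both); and store--supplier ties drawn
#' independently per (store, supplier, class) as Bernoulli variables, with
#' the configured covariate effects shifting the healthy tie rate. Every
#' realized tie yields at least one purchase row with a catalogued item, so
#' [build_networks()] on the output recovers exactly the simulated tie sets.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; identical seeds yield byte-identical tables.
#' @return A `cornernet_dataset`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed) {
  if (missing(seed)) cn_usage_error("a seed is required")
  set.seed(seed)
  cfg <- config

  n <- cfg$n_stores
  stores <- tibble::tibble(
    store_id = sprintf("store_%02d", seq_len(n)),
    accepts_wic = runif(n) < cfg$wic_rate,
    accepts_snap = runif(n) < cfg$snap_rate,
    owner_ethnicity = ifelse(runif(n) < cfg$p_asian_hispanic,
                             "asian_hispanic", "african_american"),
    years_current_store = round(pmax(0, rnorm(n, cfg$years_current_mean,
                                              cfg$years_current_sd)), 1),
    years_any_store = NA_real_,
    customers_per_day = round(pmax(0, rnorm(n, cfg$customers_mean,
                                            cfg$customers_sd))),
    n_nonfamily_employees = rpois(n, cfg$nonfamily_mean),
    n_family_employees = rpois(n, cfg$family_mean)
  )
  # total tenure can't be shorter than tenure at the current store
  stores$years_any_store <- round(pmax(
    stores$years_current_store,
    pmax(0, rnorm(n, cfg$years_any_mean, cfg$years_any_sd))), 1)
  stores <- dplyr::bind_cols(stores, runif_box(n, cfg$store_bbox))

  counts <- cfg$suppliers_per_category
  m <- sum(counts)
  category <- rep(names(counts), counts)
  index_in_category <- unlist(lapply(counts, seq_len), use.names = FALSE)
  n_sites <- sample(seq(cfg$n_sites_range[1], cfg$n_sites_range[2]),
                    m, replace = TRUE)
  site_strings <- vapply(n_sites, function(k) {
    xy <- runif_box(k, cfg$site_bbox)
    paste(sprintf("%.6f,%.6f", xy$latitude, xy$longitude), collapse = ";")
  }, character(1))
  suppliers <- tibble::tibble(
    supplier_id = sprintf("sup_%02d", seq_len(m)),
    name = paste0(gsub("_", " ", category), " supplier ",
                  sprintf("%02d", seq_len(m))),
    category = category,
    delivers = runif(m) < cfg$delivery_rate,
    sites = site_strings,
    multiplicity = 1L
  )

  healthy_menus <- lapply(seq_len(m), function(j)
    healthy_menu_for(category[j], index_in_category[j], cfg))
  unhealthy_menus <- lapply(seq_len(m), function(j)
    unhealthy_menu_for(category[j]))
  healthy_capable <- which(lengths(healthy_menus) > 0)
  H <- length(healthy_capable)
  if (H == 0 && cfg$p_healthy_tie_base > 0) {
    cn_config_error(
      "infeasible config: nonzero healthy tie rate but no supplier carries healthy items")
  }

  # healthy-tie probability per store: additive raw-degree effects spread
  # over the healthy-capable suppliers
  shift <- cfg$ethnicity_effect * (stores$owner_ethnicity == "asian_hispanic") +
    cfg$snap_effect * stores$accepts_snap +
    cfg$wic_effect * stores$accepts_wic
  p_healthy <- cfg$p_healthy_tie_base + if (H > 0) shift / H else 0
  if (any(p_healthy < 0 | p_healthy > 1)) {
    warning("covariate effects drove healthy tie probabilities outside [0, 1]; clamped")
    p_healthy <- pmin(1, pmax(0, p_healthy))
  }

  unhealthy_ties <- matrix(runif(n * m) < cfg$p_unhealthy_tie, n, m)
  healthy_ties <- matrix(FALSE, n, m)
  if (H > 0) {
    healthy_ties[, healthy_capable] <-
      matrix(runif(n * H), n, H) < p_healthy
  }

  tie_rows <- function(ties, menus) {
    idx <- which(ties, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(tibble::tibble(store_id = character(), supplier_id = character(),
                            item_name = character(),
                            monthly_frequency = integer(),
                            via_delivery = logical()))
    }
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    items <- vapply(idx[, 2], function(j) {
      menu <- menus[[j]]
      if (length(menu) == 1) menu else sample(menu, 1)
    }, character(1))
    tibble::tibble(
      store_id = stores$store_id[idx[, 1]],
      supplier_id = suppliers$supplier_id[idx[, 2]],
      item_name = items,
      monthly_frequency = 1L + rpois(nrow(idx), 1),
      via_delivery = suppliers$delivers[idx[, 2]]
    )
  }
  purchases <- dplyr::bind_rows(
    tie_rows(unhealthy_ties, unhealthy_menus),
    tie_rows(healthy_ties, healthy_menus)
  ) |> dplyr::arrange(.data$store_id, .data$supplier_id, .data$item_name)

  new_dataset(stores, suppliers, purchases, default_catalog())
}
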