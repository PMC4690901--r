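#' Supplier category taxonomy
#'
#' The seven supplier categories used throughout the package, following the
#' Standard Industrial Classification food-store groupings: wholesale clubs,
#' snack manufacturers/distributors, other specialty foods (breads, coffee,
#' eggs), beverage companies, supermarkets/groceries, discount department
#' stores, and meat markets.
#'
#' @return Character vector of the seven category codes.
#' @export
supplier_categories <- function() {
  c("wholesale_club", "snacks", "specialty_foods", "beverages",
    "supermarket_grocery", "discount_department", "meat_market")
}

#' Storeowner ethnicity levels
#'
#' Two analysis groups: African American storeowners (the regression
#' reference level) and Asian or Hispanic storeowners, grouped together.
#'
#' @return Character vector of the two ethnicity codes.
#' @export
ethnicity_levels <- function() c("african_american", "asian_hispanic")

#' Canonicalize free-text item names
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and lowercases, so survey free-text entries ("  Bottled
#' WATER ") match catalog keys ("bottled water").
#'
#' @param x Character vector of item names.
#' @return Canonicalized character vector.
#' @export
#' @examples
#' canonicalize_item("  Bottled  WATER ")
canonicalize_item <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

store_columns <- c(
  "store_id", "accepts_wic", "accepts_snap", "owner_ethnicity",
  "years_current_store", "years_any_store", "customers_per_day",
  "n_nonfamily_employees", "n_family_employees", "latitude", "longitude"
)
supplier_columns <- c("supplier_id", "name", "category", "delivers", "sites")
purchase_columns <- c("store_id", "supplier_id", "item_name")
catalog_columns  <- c("item", "class")

row_label <- function(i) paste0("row ", i)

#' Validate a store table
#'
#' Checks the schema and the per-row invariants: ethnicity is one of the two
#' analysis groups, coordinates lie in valid ranges, and all counts/tenures
#' are nonnegative.
#'
#' @param stores A data frame with columns `store_id`, `accepts_wic`,
#'   `accepts_snap`, `owner_ethnicity`, `years_current_store`,
#'   `years_any_store`, `customers_per_day`, `n_nonfamily_employees`,
#'   `n_family_employees`, `latitude`, `longitude`.
#' @return The validated table as a tibble.
#' @export
validate_stores <- function(stores) {
  missing <- setdiff(store_columns, names(stores))
  if (length(missing) > 0) {
    cn_schema_error(paste0("store table is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  stores <- tibble::as_tibble(stores)
  if (anyDuplicated(stores$store_id)) {
    dup <- unique(stores$store_id[duplicated(stores$store_id)])
    cn_integrity_error(paste0("duplicate store_id: ", paste(dup, collapse = ", ")))
  }
  bad_eth <- which(!stores$owner_ethnicity %in% ethnicity_levels())
  if (length(bad_eth) > 0) {
    cn_integrity_error(paste0(
      "owner_ethnicity must be one of {",
      paste(ethnicity_levels(), collapse = ", "), "}; offending ",
      paste(row_label(bad_eth), collapse = ", ")))
  }
  bad_geo <- which(abs(stores$latitude) > 90 | abs(stores$longitude) > 180 |
                     is.na(stores$latitude) | is.na(stores$longitude))
  if (length(bad_geo) > 0) {
    cn_integrity_error(paste0("store coordinates out of range at ",
                              paste(row_label(bad_geo), collapse = ", ")))
  }
  counts <- c("years_current_store", "years_any_store", "customers_per_day",
              "n_nonfamily_employees", "n_family_employees")
  for (col in counts) {
    bad <- which(is.na(stores[[col]]) | stores[[col]] < 0)
    if (length(bad) > 0) {
      cn_integrity_error(paste0(col, " must be nonnegative; offending ",
                                paste(row_label(bad), collapse = ", ")))
    }
  }
  stores
}

#' Validate a supplier table
#'
#' Checks the schema and invariants: category is one of the seven-level
#' taxonomy and names are unique within the dataset. The `sites` column holds
#' zero or more semicolon-separated `"lat,lon"` pairs; an optional
#' `multiplicity` column (roster-entry multiplicity, default 1) is preserved.
#'
#' @param suppliers A data frame with columns `supplier_id`, `name`,
#'   `category`, `delivers`, `sites`.
#' @return The validated table as a tibble (with a `multiplicity` column).
#' @export
validate_suppliers <- function(suppliers) {
  missing <- setdiff(supplier_columns, names(suppliers))
  if (length(missing) > 0) {
    cn_schema_error(paste0("supplier table is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  suppliers <- tibble::as_tibble(suppliers)
  if (!"multiplicity" %in% names(suppliers)) suppliers$multiplicity <- 1L
  suppliers$multiplicity <- as.integer(suppliers$multiplicity)
  if (anyDuplicated(suppliers$supplier_id)) {
    dup <- unique(suppliers$supplier_id[duplicated(suppliers$supplier_id)])
    cn_integrity_error(paste0("duplicate supplier_id: ",
                              paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(suppliers$name)) {
    dup <- unique(suppliers$name[duplicated(suppliers$name)])
    cn_integrity_error(paste0("duplicate supplier name: ",
                              paste(dup, collapse = ", ")))
  }
  bad_cat <- which(!suppliers$category %in% supplier_categories())
  if (length(bad_cat) > 0) {
    cn_integrity_error(paste0(
      "supplier category must be one of the 7 taxonomy values; offending ",
      paste(row_label(bad_cat), collapse = ", ")))
  }
  # parse sites now so malformed coordinates fail at load, not at use
  parse_sites(suppliers)
  suppliers
}

#' Parse supplier sites into a long table
#'
#' Expands the semicolon-separated `"lat,lon"` site strings into one row per
#' distribution site.
#'
#' @param suppliers A validated supplier table.
#' @return Tibble with columns `supplier_id`, `site_index`, `latitude`,
#'   `longitude`. Suppliers with no sites contribute no rows.
#' @export
parse_sites <- function(suppliers) {
  out <- lapply(seq_len(nrow(suppliers)), function(i) {
    s <- suppliers$sites[i]
    if (is.na(s) || !nzchar(trimws(s))) return(NULL)
    pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    coords <- do.call(rbind, lapply(pairs, function(p) {
      xy <- suppressWarnings(as.numeric(strsplit(trimws(p), ",", fixed = TRUE)[[1]]))
      if (length(xy) != 2 || anyNA(xy)) {
        cn_schema_error(paste0("malformed site '", p, "' for supplier ",
                               suppliers$supplier_id[i]))
      }
      xy
    }))
    if (any(abs(coords[, 1]) > 90) || any(abs(coords[, 2]) > 180)) {
      cn_integrity_error(paste0("site coordinates out of range for supplier ",
                                suppliers$supplier_id[i]))
    }
    tibble::tibble(supplier_id = suppliers$supplier_id[i],
                   site_index = seq_len(nrow(coords)),
                   latitude = coords[, 1], longitude = coords[, 2])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(supplier_id = character(), site_index = integer(),
                          latitude = double(), longitude = double()))
  }
  dplyr::bind_rows(out)
}

#' Validate a purchase table
#'
#' Each row records one store acquiring one item from one supplier — the raw
#' evidence for a network edge. Optional columns `monthly_frequency`
#' (default 1) and `via_delivery` (default `NA`) are filled in.
#'
#' @param purchases A data frame with columns `store_id`, `supplier_id`,
#'   `item_name`.
#' @param stores,suppliers Validated tables used for referential-integrity
#'   checks (skipped when `NULL`).
#' @return The validated table as a tibble.
#' @export
validate_purchases <- function(purchases, stores = NULL, suppliers = NULL) {
  missing <- setdiff(purchase_columns, names(purchases))
  if (length(missing) > 0) {
    cn_schema_error(paste0("purchase table is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  purchases <- tibble::as_tibble(purchases)
  if (!"monthly_frequency" %in% names(purchases)) purchases$monthly_frequency <- 1L
  purchases$monthly_frequency <- as.integer(purchases$monthly_frequency)
  if (!"via_delivery" %in% names(purchases)) purchases$via_delivery <- NA
  purchases$via_delivery <- as.logical(purchases$via_delivery)
  bad_item <- which(is.na(purchases$item_name) | !nzchar(trimws(purchases$item_name)))
  if (length(bad_item) > 0) {
    cn_integrity_error(paste0("empty item_name at ",
                              paste(row_label(bad_item), collapse = ", ")))
  }
  bad_freq <- which(is.na(purchases$monthly_frequency) | purchases$monthly_frequency < 0)
  if (length(bad_freq) > 0) {
    cn_integrity_error(paste0("monthly_frequency must be nonnegative; offending ",
                              paste(row_label(bad_freq), collapse = ", ")))
  }
  if (!is.null(stores)) {
    bad <- which(!purchases$store_id %in% stores$store_id)
    if (length(bad) > 0) {
      cn_integrity_error(paste0(
        "purchase references unknown store_id: ",
        paste(unique(purchases$store_id[bad]), collapse = ", "),
        " (", paste(row_label(bad), collapse = ", "), ")"))
    }
  }
  if (!is.null(suppliers)) {
    bad <- which(!purchases$supplier_id %in% suppliers$supplier_id)
    if (length(bad) > 0) {
      cn_integrity_error(paste0(
        "purchase references unknown supplier_id: ",
        paste(unique(purchases$supplier_id[bad]), collapse = ", "),
        " (", paste(row_label(bad), collapse = ", "), ")"))
    }
  }
  purchases
}

#' Validate a promoted-food catalog
#'
#' The catalog maps canonical item names to a class (`healthy` or
#' `unhealthy`); healthy items carry a subclass tag (`lower_calorie_beverage`,
#' `healthier_essential`, `healthier_snack`). Item names are canonicalized
#' (trim/collapse/lowercase) and no item may map to both classes.
#'
#' @param catalog A data frame with columns `item`, `class` and optionally
#'   `subclass`.
#' @return The validated catalog as a tibble with canonical item keys.
#' @export
validate_catalog <- function(catalog) {
  missing <- setdiff(catalog_columns, names(catalog))
  if (length(missing) > 0) {
    cn_schema_error(paste0("catalog is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  catalog <- tibble::as_tibble(catalog)
  if (!"subclass" %in% names(catalog)) catalog$subclass <- NA_character_
  catalog$item <- canonicalize_item(catalog$item)
  bad_class <- which(!catalog$class %in% c("healthy", "unhealthy"))
  if (length(bad_class) > 0) {
    cn_integrity_error(paste0("catalog class must be healthy/unhealthy at ",
                              paste(row_label(bad_class), collapse = ", ")))
  }
  both <- catalog |>
    dplyr::distinct(.data$item, .data$class) |>
    dplyr::count(.data$item) |>
    dplyr::filter(.data$n > 1)
  if (nrow(both) > 0) {
    cn_integrity_error(paste0("item(s) mapped to both classes: ",
                              paste(both$item, collapse = ", ")))
  }
  dplyr::distinct(catalog, .data$item, .keep_all = TRUE)
}
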