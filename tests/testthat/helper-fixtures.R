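# Small in-code fixtures and independent brute-force oracles.

toy_stores <- function(n = 3, ids = sprintf("st%02d", seq_len(n))) {
  tibble::tibble(
    store_id = ids,
    accepts_wic = rep(c(TRUE, FALSE), length.out = n),
    accepts_snap = TRUE,
    owner_ethnicity = rep(c("african_american", "asian_hispanic"),
                          length.out = n),
    years_current_store = 5, years_any_store = 10,
    customers_per_day = 100, n_nonfamily_employees = 1,
    n_family_employees = 2,
    latitude = 39.29 + 0.01 * seq_len(n), longitude = -76.61
  )
}

toy_suppliers <- function(n = 3, ids = sprintf("sup%02d", seq_len(n)),
                          categories = rep(supplier_categories(),
                                           length.out = n),
                          delivers = rep(FALSE, n),
                          sites = rep("39.30,-76.60", n)) {
  tibble::tibble(supplier_id = ids, name = paste("Supplier", ids),
                 category = categories, delivers = delivers, sites = sites)
}

toy_catalog <- function() {
  tibble::tibble(
    item = c("bottled water", "bananas", "chips", "soda", "candy"),
    class = c("healthy", "healthy", "unhealthy", "unhealthy", "unhealthy")
  )
}

toy_purchases <- function(...) {
  rows <- list(...)
  tibble::tibble(
    store_id = vapply(rows, `[[`, "", 1),
    supplier_id = vapply(rows, `[[`, "", 2),
    item_name = vapply(rows, `[[`, "", 3)
  )
}

# Random bipartite graph as a bipartite_network plus its raw edge matrix.
random_bipartite <- function(n_stores, n_suppliers, p = 0.4,
                             mode = "UHSN") {
  stores <- sprintf("st%02d", seq_len(n_stores))
  sups <- sprintf("sup%02d", seq_len(n_suppliers))
  adj <- matrix(runif(n_stores * n_suppliers) < p, n_stores, n_suppliers,
                dimnames = list(stores, sups))
  idx <- which(adj, arr.ind = TRUE)
  edges <- tibble::tibble(store_id = stores[idx[, 1]],
                          supplier_id = sups[idx[, 2]])
  list(network = new_bipartite_network(mode, stores, edges), adj = adj)
}

# --- brute-force oracles (plain loops, independent of package internals) ---

bf_degree <- function(adj) rowSums(adj)

bf_projection_weights <- function(adj) {
  stores <- rownames(adj)
  out <- list()
  for (i in seq_along(stores)) {
    for (j in seq_along(stores)) {
      if (i < j) {
        w <- 0
        for (k in seq_len(ncol(adj))) if (adj[i, k] && adj[j, k]) w <- w + 1
        if (w > 0) {
          out[[length(out) + 1]] <- data.frame(
            store_a = stores[i], store_b = stores[j], weight = w)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(store_a = character(), store_b = character(),
                      weight = integer()))
  }
  do.call(rbind, out)
}

bf_density_pct <- function(adj) {
  w <- bf_projection_weights(adj)
  n <- nrow(adj)
  100 * nrow(w) / (n * (n - 1) / 2)
}

# Minimal core by exhaustive prefix search over the ranked supplier order.
bf_core <- function(adj, threshold = 0.8) {
  deg <- colSums(adj)
  ord <- order(-deg, colnames(adj))
  total <- sum(adj)
  cum <- cumsum(deg[ord])
  k <- 1
  while (cum[k] < threshold * total) k <- k + 1
  colnames(adj)[ord[seq_len(k)]]
}

make_er_one_mode <- function(n, p) {
  ids <- sprintf("s%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  new_one_mode_network(ids, tibble::tibble(store_a = pairs[keep, 1],
                                           store_b = pairs[keep, 2],
                                           weight = 1L))
}
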