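test_that("degree centrality handles saturation, isolation, and rounding", {
  net <- new_bipartite_network(
    "HSN", c("a", "b", "c"),
    tibble::tibble(
      store_id = c("a", "a", "a", "b", "b"),
      supplier_id = c("s1", "s2", "s3", "s1", "s2")))
  ct <- degree_centrality(net)
  expect_equal(ct$normalized_pct[ct$store_id == "a"], 100)
  expect_equal(ct$normalized_pct[ct$store_id == "c"], 0)
  expect_equal(round(ct$normalized_pct[ct$store_id == "b"], 1), 66.7)
  # two-mode handshake: store degrees sum to |edges|
  expect_equal(sum(ct$raw_degree), nrow(net$edges))
})

test_that("an edgeless network yields flagged centrality with NA normalization", {
  net <- new_bipartite_network("HSN", c("a", "b"),
                               tibble::tibble(store_id = character(),
                                              supplier_id = character()))
  ct <- degree_centrality(net)
  expect_true(all(is.na(ct$normalized_pct)))
  expect_equal(ct$raw_degree, c(0L, 0L))
  expect_true(isTRUE(attr(ct, "flagged")))
})

test_that("core extraction follows the ranked-prefix coverage definition", {
  # degrees {S1:5, S2:3, S3:2}, 10 edges, threshold 0.8 -> {S1, S2} at 0.8
  edges <- tibble::tibble(
    store_id = sprintf("t%02d", c(1:5, 1:3, 1:2)),
    supplier_id = rep(c("S1", "S2", "S3"), c(5, 3, 2)))
  net <- new_bipartite_network("UHSN", sprintf("t%02d", 1:5), edges)
  core <- extract_core(net, 0.8)
  expect_equal(core$core_suppliers, c("S1", "S2"))
  expect_equal(core$covered_edge_fraction, 0.8)

  # single dominant supplier
  solo <- new_bipartite_network(
    "UHSN", c("a", "b"),
    tibble::tibble(store_id = c("a", "b"), supplier_id = "only"))
  expect_equal(extract_core(solo)$core_suppliers, "only")
  expect_equal(extract_core(solo)$covered_edge_fraction, 1)

  # uniform degrees 1 across 10 suppliers -> prefix of 8 at threshold 0.8
  unif <- new_bipartite_network(
    "UHSN", "a",
    tibble::tibble(store_id = "a", supplier_id = sprintf("u%02d", 1:10)))
  expect_length(extract_core(unif, 0.8)$core_suppliers, 8)

  expect_error(extract_core(net, 0), class = "cornernet_usage_error")
  expect_error(extract_core(net, 1.2), class = "cornernet_usage_error")
})

test_that("core is minimal and non-decreasing in the threshold", {
  set.seed(23)
  for (rep in 1:20) {
    g <- random_bipartite(sample(3:10, 1), sample(3:10, 1), p = 0.5)
    if (nrow(g$network$edges) == 0) next
    core <- extract_core(g$network, 0.8)
    expect_setequal(core$core_suppliers, bf_core(g$adj, 0.8))
    # minimality: dropping the last-ranked member loses coverage
    deg <- table(g$network$edges$supplier_id)
    kept <- sum(deg[core$core_suppliers]) - deg[[core$core_suppliers[length(core$core_suppliers)]]]
    expect_lt(kept / nrow(g$network$edges), 0.8)
    # monotone in threshold
    sizes <- vapply(c(0.3, 0.5, 0.8, 1), function(th)
      length(extract_core(g$network, th)$core_suppliers), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("diversity counts distinct supplier categories of a store", {
  suppliers <- toy_suppliers(3, categories = c("wholesale_club", "snacks",
                                               "snacks"))
  net <- new_bipartite_network(
    "UHSN", c("a", "b"),
    tibble::tibble(store_id = c("a", "a", "a"),
                   supplier_id = c("sup01", "sup02", "sup03")))
  expect_equal(diversity(net, "a", suppliers), 2L)
  expect_equal(diversity(net, "b", suppliers), 0L)
  expect_error(diversity(net, "zz", suppliers),
               class = "cornernet_usage_error")

  seven <- toy_suppliers(7, categories = supplier_categories())
  full <- new_bipartite_network(
    "UHSN", "a", tibble::tibble(store_id = "a",
                                supplier_id = sprintf("sup%02d", 1:7)))
  expect_equal(diversity(full, "a", seven), 7L)
})

test_that("one-mode projection weights equal pairwise neighbor intersections", {
  set.seed(41)
  for (rep in 1:20) {
    g <- random_bipartite(sample(2:10, 1), sample(2:10, 1), p = 0.4)
    om <- project_one_mode(g$network)
    bf <- bf_projection_weights(g$adj)
    got <- as.data.frame(om$edges)
    bf <- bf[order(bf$store_a, bf$store_b), ]
    rownames(bf) <- NULL
    expect_equal(got, transform(bf, weight = as.integer(weight)))
    expect_setequal(om$stores, rownames(g$adj))  # isolates kept
  }
})

test_that("projection basics: shared supplier links, disjoint sets do not", {
  net <- new_bipartite_network(
    "HSN", c("A", "B", "C"),
    tibble::tibble(store_id = c("A", "B", "C"),
                   supplier_id = c("S", "S", "T")))
  om <- project_one_mode(net)
  expect_equal(nrow(om$edges), 1)
  expect_equal(om$edges$store_a, "A")
  expect_equal(om$edges$store_b, "B")
  expect_equal(om$edges$weight, 1L)
})

test_that("density matches the dichotomized pair fraction", {
  # 4 stores, edges {AB, AC} -> 2/6
  om <- new_one_mode_network(
    c("A", "B", "C", "D"),
    tibble::tibble(store_a = c("A", "A"), store_b = c("B", "C"),
                   weight = c(2L, 1L)))
  expect_equal(round(one_mode_density(om), 1), 33.3)

  # complete graph -> 100; single global supplier -> complete projection
  star <- new_bipartite_network(
    "UHSN", sprintf("s%d", 1:5),
    tibble::tibble(store_id = sprintf("s%d", 1:5), supplier_id = "hub"))
  expect_equal(one_mode_density(project_one_mode(star)), 100)

  expect_error(one_mode_density(new_one_mode_network("a", om$edges[0, ])),
               class = "cornernet_usage_error")
})

test_that("density is relabel-invariant and monotone under edge addition", {
  set.seed(53)
  g <- random_bipartite(6, 5, p = 0.4)
  om <- project_one_mode(g$network)
  d0 <- one_mode_density(om)
  expect_equal(d0, bf_density_pct(g$adj))
  # relabel stores
  perm <- setNames(sprintf("z%02d", seq_along(om$stores)), om$stores)
  om2 <- new_one_mode_network(
    unname(perm[om$stores]),
    tibble::tibble(store_a = pmin(perm[om$edges$store_a], perm[om$edges$store_b]),
                   store_b = pmax(perm[om$edges$store_a], perm[om$edges$store_b]),
                   weight = om$edges$weight))
  expect_equal(one_mode_density(om2), d0)
  # adding an edge never decreases density
  all_pairs <- t(utils::combn(om$stores, 2))
  present <- paste(om$edges$store_a, om$edges$store_b)
  missing <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% present, ,
                       drop = FALSE]
  if (nrow(missing) > 0) {
    om3 <- new_one_mode_network(om$stores, dplyr::bind_rows(
      om$edges, tibble::tibble(store_a = missing[1, 1],
                               store_b = missing[1, 2], weight = 1L)))
    expect_gt(one_mode_density(om3), d0)
  }
})

test_that("shared-supplier statistics summarize weights and isolates", {
  om <- new_one_mode_network(
    c("a", "b", "c", "d"),
    tibble::tibble(store_a = c("a", "a", "b"), store_b = c("b", "c", "c"),
                   weight = c(3L, 9L, 15L)))
  st <- shared_stats(om)
  expect_equal(st$mean_shared, 9)
  expect_equal(st$min_shared, 3L)
  expect_equal(st$max_shared, 15L)
  expect_equal(st$n_isolates, 1L)

  empty <- new_one_mode_network(sprintf("s%d", 1:5),
                                tibble::tibble(store_a = character(),
                                               store_b = character(),
                                               weight = integer()))
  est <- shared_stats(empty)
  expect_true(is.na(est$mean_shared))
  expect_equal(est$n_isolates, 5L)
})

test_that("a universally connected supplier saturates the projection", {
  set.seed(67)
  g <- random_bipartite(6, 4, p = 0.3)
  base_ct <- degree_centrality(g$network)
  plus <- new_bipartite_network(
    g$network$mode, g$network$stores,
    dplyr::bind_rows(g$network$edges,
                     tibble::tibble(store_id = g$network$stores,
                                    supplier_id = "global")))
  expect_equal(one_mode_density(project_one_mode(plus)), 100)
  plus_ct <- degree_centrality(plus)
  expect_true(all(plus_ct$raw_degree > base_ct$raw_degree |
                    plus_ct$raw_degree == base_ct$raw_degree + 1))
})
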