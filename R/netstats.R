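new_ttest_result <- function(statistic, df, p, group_means, ci_95, method,
                             degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p = p,
                 group_means = group_means, ci_95 = ci_95,
                 method = method, degenerate = degenerate),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<ttest_result ", x$method, "> degenerate (zero variance)\n", sep = "")
  } else {
    cat(sprintf("<ttest_result %s> t = %.3f, df = %.1f, p = %.4g\n",
                x$method, x$statistic, x$df, x$p))
  }
  invisible(x)
}

#' Compare degree centrality between the two networks
#'
#' Tests whether stores' degree centrality differs between the unhealthy and
#' healthy supplier networks. The difference is taken as UHSN minus HSN, so
#' a positive t means stores are better connected to unhealthy suppliers.
#' The default is a paired test: the same 24 stores appear in both networks.
#'
#' @param table_hsn,table_uhsn Centrality tables from [degree_centrality()]
#'   for the two modes.
#' @param method `"paired"` (default), `"independent_pooled"`, or `"welch"`.
#' @param scale Which centrality column to compare, `"normalized_pct"`
#'   (default) or `"raw_degree"`.
#' @return A `ttest_result` with the UHSN and HSN means and the 95% CI of
#'   the UHSN−HSN difference. A paired test with zero variance of the
#'   differences is flagged degenerate (no t is returned).
#' @export
compare_centrality <- function(table_hsn, table_uhsn,
                               method = c("paired", "independent_pooled", "welch"),
                               scale = c("normalized_pct", "raw_degree")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (method == "paired") {
    merged <- dplyr::inner_join(table_uhsn, table_hsn, by = "store_id",
                                suffix = c("_uhsn", "_hsn"))
    x <- merged[[paste0(scale, "_uhsn")]]
    y <- merged[[paste0(scale, "_hsn")]]
  } else {
    x <- table_uhsn[[scale]]
    y <- table_hsn[[scale]]
  }
  if (length(x) < 2 || length(y) < 2) {
    cn_data_error("need at least 2 observations per group for a t-test")
  }
  means <- c(uhsn = mean(x), hsn = mean(y))
  if (method == "paired" && sd(x - y) == 0) {
    d <- mean(x - y)
    if (d == 0) {
      # identical tables: no difference and no evidence of one
      return(new_ttest_result(0, length(x) - 1, 1, means, c(0, 0), "paired"))
    }
    return(new_ttest_result(NA_real_, NA_real_, NA_real_, means,
                            c(d, d), "paired", degenerate = TRUE))
  }
  ht <- switch(method,
    paired = stats::t.test(x, y, paired = TRUE),
    independent_pooled = stats::t.test(x, y, var.equal = TRUE),
    welch = stats::t.test(x, y))
  new_ttest_result(unname(ht$statistic), unname(ht$parameter),
                   ht$p.value, means, unname(ht$conf.int), method)
}

# Node resampling duplicates each dyad (u,v) with clustered multiplicity
# c_u * c_v (c_u = times node u is drawn), so the raw spread of bootstrap
# densities overstates the sampling error of density by the factor
# sqrt(Var(c_u c_v)); for multinomial resampling of n nodes that variance is
# exact and tends to 3 as n grows. Dividing by it makes the estimator exact
# for dyad-independent graphs.
node_boot_inflation <- function(n) {
  (n - 1) * (n - 2) * (n - 3) / n^3 + 2 * (n - 1) * (n - 2) / n^2 +
    (n - 1) / n - ((n - 1) / n)^2
}

boot_density_se <- function(A, n_boot) {
  n <- nrow(A)
  ut <- upper.tri(A)
  dhat <- mean(A[ut])
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    M <- A[idx, idx]
    vals <- M[ut]
    # a pair made of two copies of the same store carries no tie
    # information; impute the observed density so duplicates neither
    # deflate the density nor inflate its spread
    same <- outer(idx, idx, "==")[ut]
    vals[same] <- dhat
    reps[b] <- mean(vals)
  }
  list(dhat = dhat, se = sd(reps) / sqrt(node_boot_inflation(n)))
}

one_mode_adjacency <- function(one_mode) {
  n <- length(one_mode$stores)
  A <- matrix(0, n, n, dimnames = list(one_mode$stores, one_mode$stores))
  if (nrow(one_mode$edges) > 0) {
    ia <- match(one_mode$edges$store_a, one_mode$stores)
    ib <- match(one_mode$edges$store_b, one_mode$stores)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

#' Bootstrap test for a one-mode density difference
#'
#' Densities of two store networks are compared with a node-resampling
#' bootstrap: each network's stores are resampled with replacement `n_boot`
#' times, the density of the induced dyads is recomputed each time, and the
#' bootstrap spread — deflated by the exact node-multiplicity inflation
#' factor, so that the estimator is calibrated for dyad-independent graphs —
#' gives each density's standard error. The statistic is
#' `t = (d_A - d_B) / sqrt(se_A^2 + se_B^2)` referred to a t distribution
#' with `n_A + n_B - 2` degrees of freedom.
#'
#' @param one_mode_a,one_mode_b `one_mode_network` objects (>= 2 nodes each).
#' @param n_boot Number of bootstrap resamples (>= 100; default 5000).
#' @param seed Integer seed; required for reproducibility.
#' @return A `ttest_result` (method `"bootstrap_density"`) with densities in
#'   percent as the group means. Degenerate (zero bootstrap spread on both
#'   sides, e.g. two complete graphs) results carry no t.
#' @export
bootstrap_density_compare <- function(one_mode_a, one_mode_b, n_boot = 5000,
                                      seed) {
  if (n_boot < 100) cn_usage_error("n_boot must be at least 100")
  if (length(one_mode_a$stores) < 2 || length(one_mode_b$stores) < 2) {
    cn_usage_error("both networks need at least 2 store nodes")
  }
  if (missing(seed)) cn_usage_error("a seed is required")
  set.seed(seed)
  ba <- boot_density_se(one_mode_adjacency(one_mode_a), n_boot)
  bb <- boot_density_se(one_mode_adjacency(one_mode_b), n_boot)
  means <- 100 * c(a = ba$dhat, b = bb$dhat)
  se <- sqrt(ba$se^2 + bb$se^2)
  df <- length(one_mode_a$stores) + length(one_mode_b$stores) - 2
  diff <- ba$dhat - bb$dhat
  if (se == 0) {
    return(new_ttest_result(if (diff == 0) 0 else NA_real_, df,
                            if (diff == 0) 1 else NA_real_, means,
                            100 * c(diff, diff), "bootstrap_density",
                            degenerate = diff != 0))
  }
  t_stat <- diff / se
  ci <- 100 * (diff + c(-1, 1) * qt(0.975, df) * se)
  new_ttest_result(t_stat, df, 2 * pt(-abs(t_stat), df), means, ci,
                   "bootstrap_density")
}

# HC2 sandwich variance for the slope of y ~ x with Satterthwaite degrees
# of freedom (the Bell-McCaffrey small-sample adjustment). For a binary
# covariate this reduces to the Welch two-group variance.
bm_slope_inference <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  XtXi <- solve(crossprod(X))
  Hm <- X %*% XtXi %*% t(X)
  h <- pmin(diag(Hm), 1)
  if (any(1 - h < 1e-10)) return(NULL)  # leverage-1 point (singleton group)
  e <- y - Hm %*% y
  w <- (XtXi %*% t(X))[2, ]
  a2 <- w^2 / (1 - h)
  v <- sum(a2 * e^2)
  M <- (diag(n) - Hm) %*% diag(a2) %*% (diag(n) - Hm)
  df <- sum(diag(M))^2 / sum(M * M)
  list(se = sqrt(v), df = df)
}

#' Bivariate regression of a store characteristic on degree centrality
#'
#' Ordinary least squares of one covariate at a time on a store's degree
#' centrality, mirroring a small-sample (n = 24) design where multivariate
#' adjustment is not supportable. Binary covariates are coded 0/1; ethnicity
#' uses African American as the reference level, so the slope reads as the
#' Asian/Hispanic difference.
#'
#' Degree counts are sums of tie indicators, so their spread differs
#' systematically between covariate groups; the default interval therefore
#' uses the heteroskedasticity-consistent HC2 variance with Satterthwaite
#' degrees of freedom (the Bell-McCaffrey small-sample adjustment, which for
#' a binary covariate reduces to a Welch interval). `se = "classical"` gives
#' the textbook homoskedastic interval instead. The slope itself is
#' identical under both.
#'
#' @param stores Store table, optionally carrying a `mean_distance_km`
#'   column (see [store_supplier_distances()]).
#' @param centrality A centrality table from [degree_centrality()].
#' @param covariate Column name in `stores` (or `"mean_distance_km"`).
#' @param outcome_scale `"raw_degree"` (default; slopes read as connection
#'   counts) or `"normalized_pct"`.
#' @param se `"bell_mccaffrey"` (default) or `"classical"`.
#' @return A list of class `regression_result`: `covariate`, `b`, `ci_95`,
#'   `p`, `n`, `outcome_scale`, `se_method`, `degenerate` (TRUE for a
#'   perfect fit, where the CI collapses to the point estimate).
#' @export
bivariate_ols <- function(stores, centrality, covariate,
                          outcome_scale = c("raw_degree", "normalized_pct"),
                          se = c("bell_mccaffrey", "classical")) {
  outcome_scale <- match.arg(outcome_scale)
  se <- match.arg(se)
  if (!covariate %in% names(stores)) {
    cn_usage_error(paste0("unknown covariate: ", covariate))
  }
  df <- dplyr::inner_join(centrality, stores, by = "store_id")
  x <- df[[covariate]]
  if (covariate == "owner_ethnicity") {
    x <- as.integer(x == "asian_hispanic")
  } else if (is.logical(x)) {
    x <- as.integer(x)
  }
  y <- df[[outcome_scale]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) cn_data_error("fewer than 3 complete cases for regression")
  if (sd(x) == 0) {
    cn_data_error(paste0("degenerate design: covariate ", covariate,
                         " has zero variance"))
  }
  fit <- lm(y ~ x)
  b <- unname(coef(fit)[2])
  res_var <- sum(fit$residuals^2) / fit$df.residual
  result <- function(ci, p, se_method, degenerate = FALSE) {
    structure(list(covariate = covariate, b = b, ci_95 = ci, p = p, n = n,
                   outcome_scale = outcome_scale, se_method = se_method,
                   degenerate = degenerate),
              class = "regression_result")
  }
  if (res_var < 1e-10 * max(stats::var(y), .Machine$double.eps)) {
    # perfect fit: no residual scale to build an interval from
    return(result(c(b, b), NA_real_, se, degenerate = TRUE))
  }
  bm <- if (se == "bell_mccaffrey") bm_slope_inference(x, y) else NULL
  if (!is.null(bm)) {
    t_stat <- b / bm$se
    return(result(b + c(-1, 1) * qt(0.975, bm$df) * bm$se,
                  2 * pt(-abs(t_stat), bm$df), "bell_mccaffrey"))
  }
  # classical normal-theory interval (also the fallback when a
  # leverage-one observation makes the HC2 variance undefined)
  ci <- unname(confint(fit)[2, ])
  p <- summary(fit)$coefficients[2, 4]
  result(ci, p, "classical")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s: b = %.3f (95%% CI %.3f, %.3f), p = %.4g, n = %d\n",
              x$covariate, x$b, x$ci_95[1], x$ci_95[2],
              if (is.na(x$p)) NaN else x$p, x$n))
  invisible(x)
}

#' Store covariates examined against degree centrality
#'
#' @return Character vector of the nine covariate names used by
#'   [run_full_analysis()].
#' @export
analysis_covariates <- function() {
  c("mean_distance_km", "accepts_wic", "accepts_snap", "owner_ethnicity",
    "years_current_store", "years_any_store", "customers_per_day",
    "n_nonfamily_employees", "n_family_employees")
}

regression_row <- function(mode, res, note = NA_character_) {
  tibble::tibble(mode = mode, covariate = res$covariate,
                 outcome_scale = res$outcome_scale, se_method = res$se_method,
                 b = res$b, ci_lo = res$ci_95[1], ci_hi = res$ci_95[2],
                 p = res$p, n = res$n, note = note)
}

run_regressions <- function(stores, cent_by_mode, dist_by_mode, outcome_scale) {
  rows <- list()
  for (mode in names(cent_by_mode)) {
    st <- dplyr::left_join(stores, dist_by_mode[[mode]], by = "store_id")
    for (cov in analysis_covariates()) {
      res <- tryCatch(
        bivariate_ols(st, cent_by_mode[[mode]], cov, outcome_scale),
        cornernet_error = function(e) e)
      rows[[length(rows) + 1]] <- if (inherits(res, "regression_result")) {
        regression_row(mode, res,
                       note = if (res$degenerate) "perfect fit" else NA_character_)
      } else {
        tibble::tibble(mode = mode, covariate = cov,
                       outcome_scale = outcome_scale,
                       se_method = NA_character_, b = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                       n = NA_integer_, note = conditionMessage(res))
      }
    }
  }
  dplyr::bind_rows(rows)
}

default_config <- function(config = list()) {
  defaults <- list(core_threshold = 0.80, ttest_method = "paired",
                   comparison_scale = "normalized_pct",
                   outcome_scale = "raw_degree", n_boot = 5000, seed = 1L,
                   adjust_p = FALSE)
  utils::modifyList(defaults, config)
}

summarise_table1 <- function(stores, mean_dist_overall) {
  tibble::tibble(
    characteristic = c(
      "Average distance to suppliers, km (mean)",
      "Average distance to suppliers, km (sd)",
      "Accept WIC, yes (%)", "Accept SNAP, yes (%)",
      "Storeowner ethnicity: African American (%)",
      "Storeowner ethnicity: Asian or Hispanic (%)",
      "Years operating current store (mean)", "Years operating current store (sd)",
      "Years operating any food store (mean)", "Years operating any food store (sd)",
      "Customers on an average day (mean)", "Customers on an average day (sd)",
      "Non-family paid employees (mean)", "Non-family paid employees (sd)",
      "Family member employees (mean)", "Family member employees (sd)"),
    value = c(
      mean(mean_dist_overall, na.rm = TRUE), sd(mean_dist_overall, na.rm = TRUE),
      100 * mean(stores$accepts_wic), 100 * mean(stores$accepts_snap),
      100 * mean(stores$owner_ethnicity == "african_american"),
      100 * mean(stores$owner_ethnicity == "asian_hispanic"),
      mean(stores$years_current_store), sd(stores$years_current_store),
      mean(stores$years_any_store), sd(stores$years_any_store),
      mean(stores$customers_per_day), sd(stores$customers_per_day),
      mean(stores$n_nonfamily_employees), sd(stores$n_nonfamily_employees),
      mean(stores$n_family_employees), sd(stores$n_family_employees))
  )
}

#' Run the full supplier-network analysis
#'
#' End-to-end pipeline: classifies purchases, builds the HSN and UHSN,
#' computes every network measure (degree centrality, 80%-coverage core,
#' category diversity, one-mode projection, density, shared-supplier
#' statistics), measures nearest-site distances, compares the two networks
#' (paired t-test on centrality, bootstrap test on density), runs the nine
#' bivariate store-characteristic regressions against both modes, and
#' re-runs the regressions after excluding delivering suppliers (the
#' self-supply sensitivity analysis).
#'
#' @param dataset A `cornernet_dataset` from [load_dataset()],
#'   [new_dataset()] or [generate_dataset()].
#' @param config Optional list overriding defaults: `core_threshold` (0.80),
#'   `ttest_method` ("paired"), `comparison_scale` ("normalized_pct"),
#'   `outcome_scale` ("raw_degree"), `n_boot` (5000), `seed` (1),
#'   `adjust_p` (FALSE, Benjamini-Hochberg across regression rows per mode).
#' @return A list of class `cornernet_report`; see [write_report()].
#' @export
run_full_analysis <- function(dataset, config = list()) {
  cfg <- default_config(config)
  nets <- build_networks(dataset$purchases, dataset$catalog,
                         dataset$stores, dataset$suppliers)
  modes <- list(UHSN = nets$uhsn, HSN = nets$hsn)

  cent <- lapply(modes, degree_centrality)
  core <- lapply(modes, function(nw) {
    if (nrow(nw$edges) == 0) NULL else extract_core(nw, cfg$core_threshold)
  })
  proj <- lapply(modes, project_one_mode)
  dens <- lapply(proj, function(p) {
    if (length(p$stores) < 2) NA_real_ else one_mode_density(p)
  })
  shared <- lapply(proj, shared_stats)
  divers <- lapply(modes, function(nw) {
    tibble::tibble(store_id = nw$stores, mode = nw$mode,
                   diversity = diversity(nw, nw$stores, dataset$suppliers))
  })
  dist <- lapply(modes, function(nw) {
    store_supplier_distances(dataset$stores, dataset$suppliers, nw)
  })
  dist_cov <- lapply(dist, function(d) {
    dplyr::rename(d$store_means, mean_distance_km = "mean_km")
  })

  comp_centrality <- tryCatch(
    compare_centrality(cent$HSN, cent$UHSN, method = cfg$ttest_method,
                       scale = cfg$comparison_scale),
    cornernet_error = function(e) e)
  comp_density <- bootstrap_density_compare(proj$UHSN, proj$HSN,
                                            n_boot = cfg$n_boot,
                                            seed = cfg$seed + 1L)

  regressions <- run_regressions(dataset$stores, cent, dist_cov,
                                 cfg$outcome_scale)

  sens_purchases <- filter_delivering(dataset$purchases, dataset$suppliers)
  sens_nets <- build_networks(sens_purchases, dataset$catalog,
                              dataset$stores, dataset$suppliers)
  sens_modes <- list(UHSN = sens_nets$uhsn, HSN = sens_nets$hsn)
  sens_cent <- lapply(sens_modes, degree_centrality)
  sens_dist_cov <- lapply(sens_modes, function(nw) {
    d <- store_supplier_distances(dataset$stores, dataset$suppliers, nw)
    dplyr::rename(d$store_means, mean_distance_km = "mean_km")
  })
  sensitivity <- run_regressions(dataset$stores, sens_cent, sens_dist_cov,
                                 cfg$outcome_scale)

  if (isTRUE(cfg$adjust_p)) {
    regressions <- regressions |>
      dplyr::group_by(.data$mode) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
    sensitivity <- sensitivity |>
      dplyr::group_by(.data$mode) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }

  # Table 1-style covariate summary; the distance column averages over
  # suppliers connected in either network
  union_edges <- dplyr::distinct(dplyr::bind_rows(nets$hsn$edges, nets$uhsn$edges))
  union_net <- new_bipartite_network("UHSN", dataset$stores$store_id, union_edges)
  union_dist <- store_supplier_distances(dataset$stores, dataset$suppliers,
                                         union_net)

  structure(list(
    networks = modes, unknown_items = nets$unknown_items,
    centrality = cent, core = core, projection = proj, density = dens,
    shared = shared, diversity = divers, distance = dist,
    comparisons = list(centrality = comp_centrality, density = comp_density),
    table1 = summarise_table1(dataset$stores, union_dist$store_means$mean_km),
    regressions = regressions, sensitivity_regressions = sensitivity,
    config = cfg
  ), class = "cornernet_report")
}

#' @export
print.cornernet_report <- function(x, ...) {
  cat("<cornernet_report>\n")
  for (m in names(x$networks)) {
    cat(sprintf("  %s: %d suppliers, %d edges, density %.1f%%, core size %s\n",
                m, length(x$networks[[m]]$suppliers),
                nrow(x$networks[[m]]$edges), x$density[[m]],
                if (is.null(x$core[[m]])) "-" else length(x$core[[m]]$core_suppliers)))
  }
  invisible(x)
}

format_ttest_line <- function(label, tt) {
  if (inherits(tt, "condition")) {
    return(paste0(label, ": not computed (", conditionMessage(tt), ")"))
  }
  if (tt$degenerate) return(paste0(label, ": degenerate (zero variance)"))
  sprintf("%s: t = %.4f, df = %.1f, p = %.6g, means = %.4f / %.4f, 95%% CI of diff (%.4f, %.4f) [%s]",
          label, tt$statistic, tt$df, tt$p, tt$group_means[1], tt$group_means[2],
          tt$ci_95[1], tt$ci_95[2], tt$method)
}

#' Write a report bundle to disk
#'
#' Emits tidy CSV tables (`table1_summary.csv`, `network_summary.csv`,
#' `centrality.csv`, `table3_regressions.csv`,
#' `sensitivity_regressions.csv`, `unknown_items.csv`), GraphML exports of
#' the four graphs (two-mode and one-mode per network, with core suppliers
#' tagged), a plain-text log of the comparison statistics, and an echo of
#' the configuration. Outputs are deterministic given the same dataset and
#' config.
#'
#' @param report A `cornernet_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table1, file.path(dir, "table1_summary.csv"),
                   progress = FALSE)
  net_sum <- dplyr::bind_rows(lapply(names(report$networks), function(m) {
    tibble::tibble(
      mode = m,
      n_suppliers = length(report$networks[[m]]$suppliers),
      n_edges = nrow(report$networks[[m]]$edges),
      mean_raw_degree = mean(report$centrality[[m]]$raw_degree),
      mean_normalized_pct = mean(report$centrality[[m]]$normalized_pct),
      density_pct = report$density[[m]],
      core_size = if (is.null(report$core[[m]])) NA_integer_ else
        length(report$core[[m]]$core_suppliers),
      core_coverage = if (is.null(report$core[[m]])) NA_real_ else
        report$core[[m]]$covered_edge_fraction,
      mean_shared = report$shared[[m]]$mean_shared,
      min_shared = report$shared[[m]]$min_shared,
      max_shared = report$shared[[m]]$max_shared,
      n_isolates = report$shared[[m]]$n_isolates,
      mean_diversity = mean(report$diversity[[m]]$diversity)
    )
  }))
  readr::write_csv(net_sum, file.path(dir, "network_summary.csv"),
                   progress = FALSE)
  cent <- dplyr::bind_rows(report$centrality) |>
    dplyr::left_join(dplyr::bind_rows(report$diversity),
                     by = c("store_id", "mode"))
  readr::write_csv(cent, file.path(dir, "centrality.csv"), progress = FALSE)
  readr::write_csv(report$regressions,
                   file.path(dir, "table3_regressions.csv"), progress = FALSE)
  readr::write_csv(report$sensitivity_regressions,
                   file.path(dir, "sensitivity_regressions.csv"),
                   progress = FALSE)
  readr::write_csv(report$unknown_items, file.path(dir, "unknown_items.csv"),
                   progress = FALSE)
  for (m in names(report$networks)) {
    core_ids <- if (is.null(report$core[[m]])) NULL else
      report$core[[m]]$core_suppliers
    export_graph(report$networks[[m]],
                 file.path(dir, paste0(tolower(m), "_two_mode.graphml")),
                 "graphml", core_suppliers = core_ids)
    export_graph(report$projection[[m]],
                 file.path(dir, paste0(tolower(m), "_one_mode.graphml")),
                 "graphml")
  }
  writeLines(c(
    format_ttest_line("degree centrality (UHSN - HSN)",
                      report$comparisons$centrality),
    format_ttest_line("one-mode density (UHSN - HSN)",
                      report$comparisons$density)
  ), file.path(dir, "stats_log.txt"))
  cfg <- report$config
  writeLines(paste0(names(cfg), ": ", vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1))),
    file.path(dir, "config_echo.txt"))
  invisible(dir)
}
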