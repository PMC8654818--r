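# shared fixture builders; everything is generated in code at test time

two_group_corr <- function(r) {
  m <- matrix(c(1, r, r, 1), 2)
  dimnames(m) <- list(c("A", "B"), c("A", "B"))
  m
}

# a small world sized for quick MCMC smoke tests
small_world <- function(seed = 7, truth = truth_params(), ...) {
  args <- utils::modifyList(
    list(n_grid_sites = 6, reefs_per_site = 3, years = 1998:2003,
         tows_per_reef_year = 8, n_reef_pairs = 4, seed = seed),
    list(...))
  simulate_world(do.call(world_config, args), truth)
}

# random reef-year tables for the duplicate-resolution / join oracles
random_reef_year_table <- function(n_sites = 4, years = 2000:2004,
                                   max_reefs = 3) {
  rows <- list()
  for (s in paste0("S", seq_len(n_sites))) {
    for (y in years) {
      k <- sample(0:max_reefs, 1)
      if (k == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        grid_site = s, year = y, reef_id = paste0(s, "_", seq_len(k)),
        zoning = sample(c("open", "closed"), k, replace = TRUE),
        cots_density = round(runif(k, 0, 3), 3),
        coral_cover = round(runif(k), 3))
    }
  }
  dplyr::bind_rows(rows)
}

random_catch_table <- function(n_sites = 3, years = 2000:2004, groups = "G") {
  g <- expand.grid(grid_site = paste0("S", seq_len(n_sites)), year = years,
                   group = groups, fishery = catch_fisheries(),
                   stringsAsFactors = FALSE)
  g <- g[runif(nrow(g)) < 0.7, ]
  g$retained_kg <- round(runif(nrow(g), 0, 500), 1)
  tibble::as_tibble(g)
}

# independent brute-force oracle for duplicate resolution (re-coded rules)
oracle_resolve <- function(df, fisheries_stream = FALSE) {
  out <- list()
  for (key in unique(paste(df$grid_site, df$year))) {
    g <- df[paste(df$grid_site, df$year) == key, ]
    if (any(g$zoning == "open") && any(g$zoning == "closed")) {
      g <- g[g$zoning == "open", ]
    }
    if (fisheries_stream && all(g$zoning == "closed")) next
    out[[key]] <- data.frame(grid_site = g$grid_site[1], year = g$year[1],
                             zoning = g$zoning[1],
                             cots_density = mean(g$cots_density),
                             coral_cover = mean(g$coral_cover))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$grid_site, res$year), ]
}
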