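# Deterministic transformations from raw survey/catch tables to
# model-ready datasets. Every drop or averaging decision is recorded in a
# machine-readable audit trail attached to the returned table (see
# audit_log(), write_audit()).

audit_entry <- function(action, grid_site = NA, year = NA, detail = "") {
  tibble::tibble(action = action, grid_site = as.character(grid_site),
                 year = as.integer(year), detail = detail)
}

set_audit <- function(x, audit) {
  attr(x, "audit") <- audit
  x
}

#' Retrieve the audit trail attached to a prepared table
#'
#' @param x A table returned by [resolve_duplicates()], [aggregate_catch()]
#'   or [site_mean_length()].
#' @return A tibble with columns `action`, `grid_site`, `year`, `detail`
#'   (empty if nothing was dropped or averaged).
#' @export
audit_log <- function(x) {
  a <- attr(x, "audit")
  if (is.null(a)) a <- audit_entry(character(0))[0, ]
  a
}

#' Write an audit trail as JSON lines
#'
#' @param x A prepared table carrying an audit attribute.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(x, path) {
  a <- audit_log(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    writeLines(jsonlite::toJSON(as.list(a[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' CoTS density per minute for one site-year
#'
#' Manta tows last two minutes; density is standardised to individuals per
#' minute and averaged across tows.
#'
#' @param counts Non-negative integer vector, one CoTS count per 2-min tow.
#' @return Mean individuals per minute.
#' @export
#' @examples
#' cots_density_per_minute(c(1, 2, 3, 0, 4))  # 1.0
cots_density_per_minute <- function(counts) {
  if (length(counts) == 0) stop("no tows supplied for site-year", call. = FALSE)
  if (any(counts < 0)) stop("tow counts must be non-negative", call. = FALSE)
  mean(counts / 2)
}

#' Collapse manta tows to reef-year records
#'
#' Computes, per reef x grid-site x year, the CoTS density (individuals per
#' minute) and mean coral-cover proportion across tows.
#'
#' @param manta Manta-tow table with columns `reef_id`, `grid_site`, `year`,
#'   `zoning`, `cots_count`, `cover_code`.
#' @return Tibble with one row per reef-year.
#' @export
summarise_tows <- function(manta) {
  validate_manta(manta)
  manta |>
    dplyr::mutate(cover = convert_cover_category(.data$cover_code)) |>
    dplyr::group_by(.data$reef_id, .data$grid_site, .data$year, .data$zoning) |>
    dplyr::summarise(
      cots_density = cots_density_per_minute(.data$cots_count),
      coral_cover = mean(.data$cover),
      n_tows = dplyr::n(),
      .groups = "drop")
}

#' Resolve multiple reef observations within a grid-site-year
#'
#' When one grid-site-year holds reefs from both zoning classes, the
#' closed-zone (unfished) reefs are removed, because the catch reported for
#' that site can only have come from reefs open to fishing. Remaining
#' same-zoning reefs are averaged (unweighted) on density and cover. For
#' the fisheries-lag dataset (`fisheries_stream = TRUE`), site-years whose
#' records come from closed zones only are dropped altogether.
#'
#' @param reef_year Reef-year table from [summarise_tows()].
#' @param fisheries_stream If `TRUE`, keep only open-zone site-years.
#' @return Tibble with one row per grid-site-year (and zoning stream),
#'   carrying an audit attribute recording every drop/average.
#' @export
resolve_duplicates <- function(reef_year, fisheries_stream = FALSE) {
  stopifnot(all(c("grid_site", "year", "zoning", "cots_density", "coral_cover")
                %in% names(reef_year)))
  audit <- list()
  grp <- dplyr::group_by(reef_year, .data$grid_site, .data$year)
  keys <- dplyr::group_keys(grp)
  parts <- dplyr::group_split(grp)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    g <- parts[[i]]
    if (length(unique(g$zoning)) > 1) {
      audit[[length(audit) + 1]] <- audit_entry(
        "drop_closed", keys$grid_site[i], keys$year[i],
        sprintf("dropped %d closed-zone reef record(s); open-zone present",
                sum(g$zoning == "closed")))
      g <- g[g$zoning == "open", , drop = FALSE]
    }
    if (nrow(g) > 1) {
      audit[[length(audit) + 1]] <- audit_entry(
        "average", keys$grid_site[i], keys$year[i],
        sprintf("averaged %d same-zoning reef records (unweighted)", nrow(g)))
      g <- tibble::tibble(
        grid_site = g$grid_site[1], year = g$year[1], zoning = g$zoning[1],
        cots_density = mean(g$cots_density), coral_cover = mean(g$coral_cover))
    } else {
      g <- g[, c("grid_site", "year", "zoning", "cots_density", "coral_cover")]
    }
    out[[i]] <- g
  }
  res <- dplyr::bind_rows(out)
  if (fisheries_stream) {
    drop <- res$zoning != "open"
    if (any(drop)) {
      for (j in which(drop)) {
        audit[[length(audit) + 1]] <- audit_entry(
          "drop_closed_only", res$grid_site[j], res$year[j],
          "site-year had closed-zone records only; removed from fisheries-lag stream")
      }
      res <- res[!drop, , drop = FALSE]
    }
  }
  set_audit(res, dplyr::bind_rows(audit))
}

#' Aggregate retained catch across fisheries
#'
#' Sums retained kilograms over the commercial line, net and trawl and the
#' recreational charter fisheries for every grid-site x year x fish group.
#' Fisheries absent from a cell contribute zero. Duplicate rows for the
#' same fishery within a cell are summed with a logged warning.
#'
#' @param catch Catch table with columns `grid_site`, `year`, `fishery`,
#'   `group`, `retained_kg`.
#' @return Tibble with one row per grid-site-year-group and column
#'   `biomass_kg`, carrying an audit attribute.
#' @export
aggregate_catch <- function(catch) {
  validate_catch(catch)
  dup <- catch |>
    dplyr::count(.data$grid_site, .data$year, .data$group, .data$fishery) |>
    dplyr::filter(.data$n > 1)
  audit <- list()
  if (nrow(dup) > 0) {
    warning(sprintf("%d duplicate fishery rows summed during catch aggregation",
                    sum(dup$n) - nrow(dup)), call. = FALSE)
    for (i in seq_len(nrow(dup))) {
      audit[[length(audit) + 1]] <- audit_entry(
        "sum_duplicate_fishery", dup$grid_site[i], dup$year[i],
        sprintf("group %s fishery %s appeared %d times; summed",
                dup$group[i], dup$fishery[i], dup$n[i]))
    }
  }
  res <- catch |>
    dplyr::group_by(.data$grid_site, .data$year, .data$group) |>
    dplyr::summarise(biomass_kg = sum(.data$retained_kg), .groups = "drop")
  set_audit(res, dplyr::bind_rows(audit))
}

#' Pair site-year CoTS densities with lagged catch
#'
#' Inner join of the site-year CoTS table and the site-year catch table for
#' one fish group such that catch in reporting year `t` is paired with CoTS
#' density (and same-year coral cover) in year `t + lag`.
#'
#' @param cots_sy Site-year CoTS table (open-zone stream) with columns
#'   `grid_site`, `year`, `cots_density`, `coral_cover`.
#' @param catch_sy Site-year catch table for one group with columns
#'   `grid_site`, `year`, `biomass_kg`.
#' @param lag Integer lag in years, 1-6.
#' @return Tibble of paired observations with columns `grid_site`,
#'   `catch_year`, `lag`, `cots_year`, `cots_density`, `coral_cover`,
#'   `biomass_kg`.
#' @export
build_lagged_pairs <- function(cots_sy, catch_sy, lag) {
  stopifnot(length(lag) == 1, lag %in% 1:6)
  if (anyDuplicated(cots_sy[c("grid_site", "year")]) > 0) {
    stop("cots_sy has duplicate site-years; run resolve_duplicates() first",
         call. = FALSE)
  }
  if (anyDuplicated(catch_sy[c("grid_site", "year")]) > 0) {
    stop("catch_sy has duplicate site-years; run aggregate_catch() first",
         call. = FALSE)
  }
  catch <- dplyr::transmute(catch_sy,
                            grid_site = .data$grid_site,
                            catch_year = .data$year,
                            cots_year = .data$year + lag,
                            biomass_kg = .data$biomass_kg)
  cots <- dplyr::rename(cots_sy, cots_year = "year")
  dplyr::inner_join(catch, cots, by = c("grid_site", "cots_year")) |>
    dplyr::transmute(grid_site = .data$grid_site,
                     catch_year = .data$catch_year,
                     lag = as.integer(lag),
                     cots_year = .data$cots_year,
                     cots_density = .data$cots_density,
                     coral_cover = .data$coral_cover,
                     biomass_kg = .data$biomass_kg)
}

#' Fish density per 1000 square metres
#'
#' Belt transects are 50 m x 5 m = 250 m2, so counts scale by 4.
#'
#' @param count Non-negative count per 250 m2 belt transect.
#' @return Density per 1000 m2.
#' @export
fish_density_per_1000m2 <- function(count) {
  stopifnot(all(count >= 0))
  count * 4
}

#' Fish mass from total length
#'
#' Standard allometric length-weight relationship `a * L^b`, in grams.
#'
#' @param length_cm Total length in cm, > 0.
#' @param a Coefficient, > 0.
#' @param b Exponent.
#' @return Mass in grams.
#' @export
#' @examples
#' biomass_from_length(50, a = 0.01, b = 3)  # 1250 g
biomass_from_length <- function(length_cm, a, b) {
  if (any(length_cm <= 0)) stop("fish length must be positive", call. = FALSE)
  stopifnot(all(a > 0))
  a * length_cm^b
}

#' Site-level mean total length
#'
#' Pools individual total lengths across transects within a site-year and
#' group and returns the flat (per-fish) arithmetic mean, not the mean of
#' transect means.
#'
#' @param lengths List of numeric length vectors (one per transect).
#' @return Mean total length in cm, or `NA` if no fish were measured.
#' @export
site_mean_length <- function(lengths) {
  all_len <- unlist(lengths, use.names = FALSE)
  if (length(all_len) == 0) return(NA_real_)
  mean(all_len)
}

#' Pairwise Pearson correlations between fish-group catches at each lag
#'
#' For each lag, the catch series of every pair of fish groups is
#' restricted to the grid-site-years that enter that lag's paired
#' CoTS-catch dataset, and the Pearson correlation of log(kg + 1) is
#' computed.
#'
#' @param catch_sy Site-year catch table with columns `grid_site`, `year`,
#'   `group`, `biomass_kg`.
#' @param cots_sy Site-year CoTS table (open-zone stream); used to define
#'   which catch site-years enter each lag. If `NULL`, all site-years are
#'   used at every lag.
#' @param lags Integer vector of lags.
#' @return Tibble with columns `lag`, `group_a`, `group_b`, `r`, `n`.
#'   Zero-variance series yield `NA` with a warning.
#' @export
pairwise_lag_correlations <- function(catch_sy, cots_sy = NULL, lags = 1:6) {
  groups <- sort(unique(catch_sy$group))
  out <- list()
  for (x in lags) {
    cs <- catch_sy
    if (!is.null(cots_sy)) {
      keys <- dplyr::transmute(cots_sy, grid_site = .data$grid_site,
                               year = .data$year - x)
      cs <- dplyr::semi_join(cs, keys, by = c("grid_site", "year"))
    }
    wide <- cs |>
      dplyr::mutate(logkg = log1p(.data$biomass_kg)) |>
      tidyr::pivot_wider(id_cols = c("grid_site", "year"),
                         names_from = "group", values_from = "logkg")
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        a <- wide[[groups[i]]]; b <- wide[[groups[j]]]
        ok <- !is.na(a) & !is.na(b)
        r <- NA_real_
        if (sum(ok) >= 3) {
          if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
            warning(sprintf("zero-variance catch series (%s vs %s, lag %d); correlation undefined",
                            groups[i], groups[j], x), call. = FALSE)
          } else {
            r <- cor(a[ok], b[ok])
          }
        }
        out[[length(out) + 1]] <- tibble::tibble(
          lag = as.integer(x), group_a = groups[i], group_b = groups[j],
          r = r, n = sum(ok))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Site-level reserve-comparison responses from belt transects
#'
#' Converts raw transect records into the three site-year responses used in
#' the paired-reef reserve models: density per 1000 m2 (mean across
#' transects), standing biomass in kg per 1000 m2 computed from individual
#' lengths via the supplied length-weight coefficients (mean across
#' transects), and mean population total length pooled across transects.
#'
#' @param transects Transect table with columns `reef_pair_id`, `reef_id`,
#'   `zoning`, `site`, `year`, `transect`, `group`, `count` and a
#'   list-column `lengths` (cm).
#' @param lw Length-weight coefficient table with columns `group`, `a`, `b`
#'   (mass in grams = `a * TL^b`).
#' @return Tibble with one row per reef x site x year x group and columns
#'   `density`, `biomass_kg`, `mean_length` (NA when no fish measured),
#'   carrying an audit attribute for excluded length records.
#' @export
prepare_reserve_sites <- function(transects, lw) {
  validate_transects(transects)
  stopifnot(all(c("group", "a", "b") %in% names(lw)))
  missing_lw <- setdiff(unique(transects$group), lw$group)
  if (length(missing_lw) > 0) {
    stop("no length-weight coefficients for group(s): ",
         paste(missing_lw, collapse = ", "), call. = FALSE)
  }
  lw_a <- setNames(lw$a, lw$group)
  lw_b <- setNames(lw$b, lw$group)
  transects$biomass_g <- mapply(function(len, g) {
    if (length(len) == 0) 0 else sum(biomass_from_length(len, lw_a[[g]], lw_b[[g]]))
  }, transects$lengths, transects$group)
  res <- transects |>
    dplyr::group_by(.data$reef_pair_id, .data$reef_id, .data$zoning,
                    .data$site, .data$year, .data$group) |>
    dplyr::summarise(
      density = mean(fish_density_per_1000m2(.data$count)),
      biomass_kg = mean(.data$biomass_g / 1000 * 4),
      mean_length = site_mean_length(.data$lengths),
      .groups = "drop")
  audit <- res |>
    dplyr::filter(is.na(.data$mean_length)) |>
    dplyr::rowwise() |>
    dplyr::group_split()
  entries <- lapply(audit, function(g) {
    audit_entry("no_lengths", g$reef_id, g$year,
                sprintf("group %s site %s: no measured lengths; excluded from length model",
                        g$group, g$site))
  })
  set_audit(res, dplyr::bind_rows(entries))
}
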