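# Schema validation for the three input tables. Each validator either
# returns the table invisibly or throws an error naming the offending
# column / rows; check_* variants return a tibble of row-level violations
# for use by the command-line `validate` entry point.

#' The six study fish groups
#'
#' Four families of documented or likely CoTS consumers plus two targeted
#' species aggregates: wrasses (Labridae), emperors (Lethrinidae),
#' redthroat and spangled emperors (Lethrinus miniatus and L. nebulosus),
#' tropical snappers (Lutjanidae), rockcods (Serranidae) and coral trout
#' (Plectropomus spp. and Variola spp.).
#'
#' @return Character vector of the six group labels.
#' @export
cots_fish_groups <- function() {
  c("Labridae", "Lethrinidae", "Lethrinus_miniatus_nebulosus",
    "Lutjanidae", "Serranidae", "Plectropomus_Variola")
}

#' The four fisheries whose retained catch is aggregated
#' @return Character vector of fishery labels.
#' @export
catch_fisheries <- function() {
  c("commercial_line", "commercial_net", "commercial_trawl", "charter")
}

req_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Row-level schema check for a manta-tow table
#'
#' @param manta Manta-tow table.
#' @return Tibble of violations with columns `row`, `column`, `problem`.
#' @export
check_manta <- function(manta) {
  req_cols(manta, c("reef_id", "grid_site", "year", "tow_index",
                    "cots_count", "cover_code", "zoning"), "manta-tow")
  v <- list()
  bad <- which(!(as.character(manta$cover_code) %in% names(cover_category_map())))
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "cover_code",
    problem = sprintf("unknown cover code '%s'", manta$cover_code[i]))
  bad <- which(manta$cots_count < 0 | manta$cots_count != round(manta$cots_count))
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "cots_count",
    problem = sprintf("count '%s' is not a non-negative integer", manta$cots_count[i]))
  bad <- which(!manta$zoning %in% c("open", "closed"))
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "zoning",
    problem = sprintf("zoning '%s' is not open/closed", manta$zoning[i]))
  dplyr::bind_rows(v, tibble::tibble(row = integer(0), column = character(0),
                                     problem = character(0)))
}

#' @rdname check_manta
#' @export
validate_manta <- function(manta) {
  v <- check_manta(manta)
  if (nrow(v) > 0) {
    stop("manta-tow table failed validation (", nrow(v), " violation(s)), e.g. row ",
         v$row[1], ": ", v$problem[1], call. = FALSE)
  }
  invisible(manta)
}

#' Row-level schema check for a retained-catch table
#'
#' @param catch Catch table.
#' @return Tibble of violations.
#' @export
check_catch <- function(catch) {
  req_cols(catch, c("grid_site", "year", "fishery", "group", "retained_kg"),
           "catch")
  v <- list()
  bad <- which(catch$retained_kg < 0)
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "retained_kg",
    problem = sprintf("negative retained mass %s", catch$retained_kg[i]))
  bad <- which(!catch$fishery %in% catch_fisheries())
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "fishery",
    problem = sprintf("unknown fishery '%s'", catch$fishery[i]))
  dplyr::bind_rows(v, tibble::tibble(row = integer(0), column = character(0),
                                     problem = character(0)))
}

#' @rdname check_catch
#' @export
validate_catch <- function(catch) {
  v <- check_catch(catch)
  if (nrow(v) > 0) {
    stop("catch table failed validation (", nrow(v), " violation(s)), e.g. row ",
         v$row[1], ": ", v$problem[1], call. = FALSE)
  }
  invisible(catch)
}

#' Row-level schema check for a belt-transect table
#'
#' @param transects Transect table (with list-column `lengths`).
#' @return Tibble of violations.
#' @export
check_transects <- function(transects) {
  req_cols(transects, c("reef_pair_id", "reef_id", "zoning", "site", "year",
                        "transect", "group", "count", "lengths"), "transect")
  v <- list()
  bad <- which(transects$count < 0)
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "count",
    problem = sprintf("negative count %s", transects$count[i]))
  nlen <- vapply(transects$lengths, length, integer(1))
  bad <- which(nlen > 0 & nlen != transects$count)
  for (i in bad) v[[length(v) + 1]] <- tibble::tibble(
    row = i, column = "lengths",
    problem = sprintf("count %d but %d lengths recorded", transects$count[i], nlen[i]))
  dplyr::bind_rows(v, tibble::tibble(row = integer(0), column = character(0),
                                     problem = character(0)))
}

#' @rdname check_transects
#' @export
validate_transects <- function(transects) {
  v <- check_transects(transects)
  if (nrow(v) > 0) {
    stop("transect table failed validation (", nrow(v), " violation(s)), e.g. row ",
         v$row[1], ": ", v$problem[1], call. = FALSE)
  }
  invisible(transects)
}
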