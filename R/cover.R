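#' Manta-tow coral-cover category conversion
#'
#' Long-term monitoring manta tows record hard coral cover as one of 16
#' ordered categories (`0`, `1L`, `1`, `1U`, ..., `5U`). Each category is
#' converted to a proportion using the mid-point of the cover interval it
#' represents, which is the scale all models in this package use.
#'
#' @return A named numeric vector mapping category code to cover proportion.
#' @export
#' @examples
#' cover_category_map()[["3"]]
cover_category_map <- function() {
  c("0" = 0,
    "1" = 0.05,   "1L" = 0.025,  "1U" = 0.075,
    "2" = 0.2,    "2L" = 0.15,   "2U" = 0.25,
    "3" = 0.4,    "3L" = 0.35,   "3U" = 0.45,
    "4" = 0.625,  "4L" = 0.5625, "4U" = 0.6875,
    "5" = 0.875,  "5L" = 0.8125, "5U" = 0.9375)
}

#' Category codes in increasing cover order
#'
#' @return Character vector of the 16 codes ordered by the proportion they
#'   map to.
#' @export
cover_category_levels <- function() {
  m <- cover_category_map()
  names(m)[order(m)]
}

#' Convert coral-cover category codes to proportions
#'
#' @param code Character vector of category codes.
#' @return Numeric vector of cover proportions in `[0, 1]`.
#' @export
#' @examples
#' convert_cover_category(c("0", "3", "5U"))
convert_cover_category <- function(code) {
  code <- as.character(code)
  m <- cover_category_map()
  bad <- setdiff(unique(code), names(m))
  if (length(bad) > 0) {
    stop("unknown coral-cover category code(s): ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(m[code])
}

#' Snap a latent cover proportion to the nearest category code
#'
#' Used by the synthetic-data generator: a latent Beta-distributed cover
#' proportion is recorded the way an observer would, as the category whose
#' mid-point is closest.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Character vector of category codes.
#' @export
snap_cover_to_category <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  m <- cover_category_map()
  names(m)[vapply(p, function(x) which.min(abs(m - x)), integer(1))]
}
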