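#' Construct a regional CPI series for medical services
#'
#' @param region_id Region identifier.
#' @param values Numeric vector of CPI values named by year. Default
#'   convention is "previous year = 100" (the statistical-yearbook form);
#'   fixed-base series are accepted via `convention`.
#' @param convention `"prev_year"` (default) or `"fixed_base"`.
#' @return Object of class `cpi_series`.
#' @export
cpi_series <- function(region_id, values, convention = c("prev_year",
                                                         "fixed_base")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(values), !is.null(names(values)))
  years <- as.integer(names(values))
  if (anyNA(years)) stop("CPI values must be named by year", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("CPI values must be positive", call. = FALSE)
  }
  if (length(years) > 1L && !identical(sort(years), seq(min(years),
                                                        max(years)))) {
    stop("CPI years for ", region_id, " must be contiguous", call. = FALSE)
  }
  values <- values[order(years)]
  structure(list(region_id = as.character(region_id), values = values,
                 convention = convention),
            class = "cpi_series")
}

cpi_link <- function(series, year) {
  # deflation factor for moving a level from `year` back to `year - 1`
  v <- series$values[as.character(year)]
  if (is.na(v)) {
    stop("missing CPI for region ", series$region_id, " year ", year,
         call. = FALSE)
  }
  if (series$convention == "prev_year") {
    v / 100
  } else {
    prev <- series$values[as.character(year - 1L)]
    if (is.na(prev)) {
      stop("missing CPI for region ", series$region_id, " year ", year - 1L,
           call. = FALSE)
    }
    v / prev
  }
}

#' Back-cast multilateral price levels with regional CPI series
#'
#' Moves a reference-year spatial comparison to earlier years by pure
#' deflation: level(r, t) = level(r, ref_year) divided by the region's
#' cumulative CPI growth from t to ref_year. The whole panel is then
#' presented relative to the reference region at the reference year = 100.
#' Cross-region comparability in earlier years is inherited from the
#' reference year -- a preliminary estimate, not a year-specific rematching.
#'
#' @param base_levels A `multilateral_result` at the reference year, or a
#'   named vector of reference-year levels.
#' @param cpi Named list of [cpi_series()], one per region.
#' @param ref_region Region fixed at 100 in the reference year.
#' @param ref_year Reference year (integer).
#' @param span Year range to cover, e.g. `2015:2020`; must end at or before
#'   `ref_year` and CPI must cover `min(span) + 1` through `ref_year`.
#' @return Long data frame (`region`, `year`, `level`) with the reference
#'   region at `ref_year` equal to 100 exactly.
#' @export
backcast_levels <- function(base_levels, cpi, ref_region, ref_year, span) {
  if (inherits(base_levels, "multilateral_result")) {
    base_levels <- rebase(base_levels, ref_region)
  }
  regions <- names(base_levels)
  stopifnot(!is.null(regions), ref_region %in% regions)
  span <- sort(as.integer(span))
  ref_year <- as.integer(ref_year)
  if (max(span) > ref_year) {
    stop("span cannot extend past the reference year", call. = FALSE)
  }
  missing_cpi <- setdiff(regions, names(cpi))
  if (length(missing_cpi) && min(span) < ref_year) {
    stop("missing CPI series for region(s): ",
         paste(missing_cpi, collapse = ", "), call. = FALSE)
  }
  years <- seq(min(span), ref_year)
  lv <- matrix(NA_real_, length(regions), length(years),
               dimnames = list(regions, years))
  lv[, as.character(ref_year)] <- base_levels
  if (length(years) > 1L) {
    for (y in rev(years[-length(years)])) {
      for (r in regions) {
        lv[r, as.character(y)] <-
          lv[r, as.character(y + 1L)] / cpi_link(cpi[[r]], y + 1L)
      }
    }
  }
  # present relative to ref_region at ref_year = 100
  lv <- lv / lv[ref_region, as.character(ref_year)] * 100
  keep <- as.character(span)
  out <- data.frame(region = rep(regions, times = length(keep)),
                    year = rep(as.integer(keep), each = length(regions)),
                    level = as.vector(lv[, keep]),
                    stringsAsFactors = FALSE)
  out[order(out$region, out$year), c("region", "year", "level")]
}
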