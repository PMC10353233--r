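#' Default basic headings of the national medical-service specification
#'
#' The four service categories that act as basic headings for parity
#' estimation: general medical services, medical diagnosis services,
#' clinical treatment services, and traditional medicine services.
#'
#' @return Character vector of the four heading labels, in canonical order.
#' @export
medical_headings <- function() {
  c("general medical services",
    "medical diagnosis services",
    "clinical treatment services",
    "traditional medicine services")
}

#' Column and format mapping for schedule files
#'
#' Describes how a delimited schedule file maps onto the fields a
#' [price_schedule()] needs, so files from different administrations can be
#' read without renaming columns.
#'
#' @param code,name,heading,price Column names in the file holding the
#'   service code, service name, basic-heading label and price.
#' @param sep Field separator (`","` or `"\t"`).
#' @param dec Decimal separator.
#' @param encoding File encoding.
#' @return A list of class `schedule_dialect`.
#' @export
schedule_dialect <- function(code = "code", name = "name",
                             heading = "heading", price = "price",
                             sep = ",", dec = ".", encoding = "UTF-8") {
  structure(list(code = code, name = name, heading = heading, price = price,
                 sep = sep, dec = dec, encoding = encoding),
            class = "schedule_dialect")
}

#' Construct a regional price schedule
#'
#' A price schedule is one region's list of priced service items. Each item
#' carries a service code (the national-specification key), a name, a
#' basic-heading label and a non-negative price in CNY.
#'
#' @param region_id Region identifier.
#' @param items Data frame with columns `code`, `name`, `heading`, `price`.
#' @param heading_set Ordered character vector of admissible headings;
#'   defaults to [medical_headings()].
#' @return An object of class `price_schedule`: a list with elements
#'   `region_id`, `items` and `heading_set`.
#' @export
price_schedule <- function(region_id, items,
                           heading_set = medical_headings()) {
  stopifnot(is.character(region_id) || is.factor(region_id),
            length(region_id) == 1L, is.data.frame(items))
  need <- c("code", "name", "heading", "price")
  miss <- setdiff(need, names(items))
  if (length(miss)) {
    stop("schedule for ", region_id, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  items <- items[need]
  items$code <- as.character(items$code)
  items$name <- as.character(items$name)
  items$heading <- as.character(items$heading)
  items$price <- as.numeric(items$price)

  if (any(!nzchar(items$code))) {
    stop("schedule for ", region_id, " has empty service codes", call. = FALSE)
  }
  bad_head <- setdiff(unique(items$heading), heading_set)
  if (length(bad_head)) {
    stop("schedule for ", region_id, " has unknown heading(s): ",
         paste(bad_head, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(items$price)) || any(items$price < 0)) {
    stop("schedule for ", region_id,
         " has missing or negative prices", call. = FALSE)
  }
  dup <- unique(items$code[duplicated(items$code)])
  if (length(dup)) {
    stop("schedule for ", region_id, " has duplicated code(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  structure(list(region_id = as.character(region_id),
                 items = items, heading_set = heading_set),
            class = "price_schedule")
}

#' @export
print.price_schedule <- function(x, ...) {
  cat("<price_schedule> region:", x$region_id,
      "| items:", nrow(x$items),
      "| headings:", length(x$heading_set), "\n")
  invisible(x)
}

#' Read a regional price schedule from a delimited file
#'
#' Rows whose price cannot be parsed as a number are rejected and reported in
#' the `rejected` attribute of the result rather than silently dropped.
#'
#' @param path Path to a delimited text file (one region per file).
#' @param region_id Region identifier to stamp on the schedule.
#' @param dialect A [schedule_dialect()] mapping file columns to fields.
#' @param heading_set Admissible basic headings.
#' @param keep_highest_price If `TRUE`, schedules carrying several price
#'   tiers per code are reduced to the maximum price per code before
#'   validation (the per-region price ceiling, the comparable quantity when
#'   administrations publish tiered fees).
#' @return A `price_schedule`; attribute `rejected` holds rows with
#'   unparseable prices, if any.
#' @export
read_schedule <- function(path, region_id, dialect = schedule_dialect(),
                          heading_set = medical_headings(),
                          keep_highest_price = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           dec = dialect$dec, quote = "\"",
                           fileEncoding = dialect$encoding,
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (field in c("code", "name", "heading", "price")) {
    col <- dialect[[field]]
    if (!col %in% names(raw)) {
      stop("schema error in ", path, ": required column '", col,
           "' (", field, ") not found", call. = FALSE)
    }
  }
  items <- data.frame(code = raw[[dialect$code]],
                      name = raw[[dialect$name]],
                      heading = raw[[dialect$heading]],
                      price = suppressWarnings(as.numeric(
                        if (dialect$dec == ",") {
                          gsub(",", ".", raw[[dialect$price]], fixed = TRUE)
                        } else raw[[dialect$price]])),
                      stringsAsFactors = FALSE)
  bad <- !is.finite(items$price)
  rejected <- items[bad, , drop = FALSE]
  rejected$raw_price <- raw[[dialect$price]][bad]
  items <- items[!bad, , drop = FALSE]
  if (keep_highest_price && anyDuplicated(items$code)) {
    ord <- order(items$code, -items$price)
    items <- items[ord, , drop = FALSE]
    items <- items[!duplicated(items$code), , drop = FALSE]
  }
  out <- price_schedule(region_id, items, heading_set)
  attr(out, "rejected") <- rejected
  out
}

#' Write a price schedule to a delimited file
#'
#' Inverse of [read_schedule()] under the same dialect, so generated systems
#' round-trip through the on-disk format.
#'
#' @inheritParams read_schedule
#' @param schedule A `price_schedule`.
#' @return The path, invisibly.
#' @export
write_schedule <- function(schedule, path, dialect = schedule_dialect()) {
  stopifnot(inherits(schedule, "price_schedule"))
  out <- schedule$items
  names(out) <- vapply(c("code", "name", "heading", "price"),
                       function(f) dialect[[f]], "")
  utils::write.table(out, path, sep = dialect$sep, dec = dialect$dec,
                     row.names = FALSE, quote = TRUE,
                     fileEncoding = dialect$encoding)
  invisible(path)
}

#' Match services across regions into a complete price tableau
#'
#' Keeps the services present in every region under the matching key
#' (exact code equality by default, optionally case/whitespace-folded names)
#' and drops any matched service priced at or below zero in any region --
#' geometric-mean parities need strictly positive prices. Exclusions are
#' counted and reported, never silent.
#'
#' @param schedules List of two or more `price_schedule` objects with a
#'   common heading set.
#' @param key `"code"` for exact code equality (default) or `"name"` for the
#'   normalized-name fallback.
#' @return An object of class `price_tableau`: list with `regions` (ordered
#'   region ids), `services` (data frame of `code`, `heading`, sorted by
#'   code), `prices` (M x N matrix, rows = regions, columns = service codes),
#'   and `exclusions` (data frame of dropped services with reasons).
#' @export
match_services <- function(schedules, key = c("code", "name")) {
  key <- match.arg(key)
  stopifnot(is.list(schedules), length(schedules) >= 2L)
  if (!all(vapply(schedules, inherits, TRUE, "price_schedule"))) {
    stop("all elements must be price_schedule objects", call. = FALSE)
  }
  regions <- vapply(schedules, `[[`, "", "region_id")
  if (anyDuplicated(regions)) stop("duplicated region ids", call. = FALSE)
  hs <- schedules[[1L]]$heading_set
  for (s in schedules[-1L]) {
    if (!identical(s$heading_set, hs)) {
      stop("heading sets differ across schedules", call. = FALSE)
    }
  }
  keyed <- lapply(schedules, function(s) {
    k <- if (key == "code") s$items$code else
      tolower(gsub("\\s+", " ", trimws(s$items$name)))
    it <- s$items
    it$.key <- k
    it[!duplicated(it$.key), , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(keyed, `[[`, ".key"))
  if (!length(shared)) stop("no comparable items across regions", call. = FALSE)
  shared <- sort(shared)

  rows <- lapply(keyed, function(it) it[match(shared, it$.key), , drop = FALSE])
  head_mat <- vapply(rows, `[[`, character(length(shared)), "heading")
  if (is.null(dim(head_mat))) head_mat <- matrix(head_mat, nrow = 1L)
  incons <- shared[apply(head_mat, 1L, function(h) length(unique(h)) > 1L)]
  if (length(incons)) {
    stop("matched code(s) mapped to different headings across regions: ",
         paste(utils::head(incons, 10L), collapse = ", "), call. = FALSE)
  }
  prices <- t(vapply(rows, `[[`, numeric(length(shared)), "price"))
  dimnames(prices) <- list(regions, shared)

  nonpos <- colSums(prices <= 0) > 0
  exclusions <- data.frame(code = shared[nonpos],
                           reason = rep("non-positive price in >=1 region",
                                        sum(nonpos)),
                           stringsAsFactors = FALSE)
  keep <- !nonpos
  if (!any(keep)) stop("no comparable items with positive prices", call. = FALSE)

  services <- data.frame(code = shared[keep],
                         heading = head_mat[keep, 1L],
                         stringsAsFactors = FALSE)
  tab <- structure(list(regions = unname(regions),
                        services = services,
                        prices = prices[, keep, drop = FALSE],
                        heading_set = hs,
                        exclusions = exclusions,
                        match_counts = data.frame(
                          region = unname(regions),
                          n_items = vapply(schedules,
                                           function(s) nrow(s$items), 0L),
                          n_matched = sum(keep),
                          n_excluded = sum(nonpos))),
                   class = "price_tableau")
  validate_tableau(tab)
}

#' Construct a price tableau directly from a price matrix
#'
#' Builds the complete regions x services price tableau without going
#' through per-region schedule files; useful for programmatic systems and
#' for feeding externally computed matrices into the index stages.
#'
#' @param prices M x N numeric matrix, all entries finite and positive;
#'   rownames = region ids, colnames = service codes.
#' @param headings Character vector assigning each column (service) to a
#'   basic heading.
#' @param heading_set Ordered heading universe; defaults to the distinct
#'   values of `headings` in order of appearance.
#' @return A `price_tableau`.
#' @export
price_tableau <- function(prices, headings,
                          heading_set = unique(headings)) {
  stopifnot(is.matrix(prices), length(headings) == ncol(prices))
  if (is.null(rownames(prices))) {
    rownames(prices) <- paste0("R", seq_len(nrow(prices)))
  }
  if (is.null(colnames(prices))) {
    colnames(prices) <- sprintf("SVC%05d", seq_len(ncol(prices)))
  }
  ord <- order(colnames(prices))
  prices <- prices[, ord, drop = FALSE]
  headings <- headings[ord]
  tab <- structure(list(regions = rownames(prices),
                        services = data.frame(code = colnames(prices),
                                              heading = headings,
                                              stringsAsFactors = FALSE),
                        prices = prices,
                        heading_set = heading_set,
                        exclusions = data.frame(code = character(),
                                                reason = character()),
                        match_counts = data.frame(
                          region = rownames(prices),
                          n_items = ncol(prices),
                          n_matched = ncol(prices),
                          n_excluded = 0L)),
                   class = "price_tableau")
  validate_tableau(tab)
}

#' Validate a price tableau
#'
#' Checks completeness (every cell finite and positive), the heading
#' partition, and that at least two regions and one service per used heading
#' are present.
#'
#' @param tableau A `price_tableau`.
#' @return The tableau, invisibly usable, after validation.
#' @export
validate_tableau <- function(tableau) {
  stopifnot(inherits(tableau, "price_tableau"))
  p <- tableau$prices
  if (nrow(p) < 2L) stop("tableau needs at least 2 regions", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("tableau is not complete: every price must be finite and > 0",
         call. = FALSE)
  }
  if (!identical(colnames(p), tableau$services$code)) {
    stop("price columns out of step with the service list", call. = FALSE)
  }
  if (any(!tableau$services$heading %in% tableau$heading_set)) {
    stop("service assigned to a heading outside the heading set",
         call. = FALSE)
  }
  tableau
}

#' @export
print.price_tableau <- function(x, ...) {
  cat("<price_tableau>", nrow(x$prices), "regions x",
      ncol(x$prices), "services;",
      length(unique(x$services$heading)), "headings;",
      nrow(x$exclusions), "excluded\n")
  invisible(x)
}

#' Descriptive price statistics for one schedule
#'
#' Mean, extrema, median and quartiles of all item prices, the summary
#' reported per region before matching. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7), recorded in the
#' `quartile_type` column.
#'
#' @param schedule A non-empty `price_schedule`.
#' @return One-row data frame: `region`, `n`, `mean`, `max`, `min`,
#'   `median`, `q1`, `q3`, `quartile_type`.
#' @export
describe_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "price_schedule"))
  p <- schedule$items$price
  if (!length(p)) stop("empty schedule", call. = FALSE)
  q <- stats::quantile(p, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(region = schedule$region_id, n = length(p),
             mean = mean(p), max = max(p), min = min(p),
             median = q[2L], q1 = q[1L], q3 = q[3L],
             quartile_type = 7L, stringsAsFactors = FALSE)
}

#' Construct per-region expenditure weights over basic headings
#'
#' Weights are the shares of medical-service spending falling in each basic
#' heading within a region. Inputs are renormalized to sum to one; the
#' `renormalized` attribute records whether that changed the input by more
#' than 1e-6.
#'
#' @param region_id Region identifier.
#' @param weights Named non-negative numeric vector, one entry per heading.
#' @param heading_set Headings the weights must cover, in order.
#' @return Object of class `expenditure_weights` (named numeric vector
#'   summing to 1, with a `region_id` attribute).
#' @export
expenditure_weights <- function(region_id, weights,
                                heading_set = medical_headings()) {
  stopifnot(is.numeric(weights))
  if (is.null(names(weights))) {
    if (length(weights) != length(heading_set)) {
      stop("unnamed weights must have one entry per heading", call. = FALSE)
    }
    names(weights) <- heading_set
  }
  if (!setequal(names(weights), heading_set)) {
    stop("weights for ", region_id, " do not cover the heading set; got: ",
         paste(names(weights), collapse = ", "), call. = FALSE)
  }
  weights <- weights[heading_set]
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights for ", region_id, " must be finite and >= 0", call. = FALSE)
  }
  s <- sum(weights)
  if (s <= 0) stop("weights for ", region_id, " sum to zero", call. = FALSE)
  renorm <- abs(s - 1) > 1e-6
  if (renorm) {
    warning("weights for ", region_id, " summed to ", format(s),
            "; renormalized to 1", call. = FALSE)
  }
  structure(weights / s, region_id = as.character(region_id),
            renormalized = renorm, class = "expenditure_weights")
}

#' Read expenditure weights from a delimited table
#'
#' One row per region, one column per basic heading, plus a `region` column.
#'
#' @param path Delimited file (rows = regions, columns = headings).
#' @param heading_set Headings the columns must match.
#' @param sep Field separator.
#' @return Named list of [expenditure_weights()], one element per region.
#' @export
read_weights <- function(path, heading_set = medical_headings(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"region" %in% names(raw)) {
    stop("weights file needs a 'region' column", call. = FALSE)
  }
  cols <- setdiff(names(raw), "region")
  if (!setequal(cols, heading_set)) {
    stop("weights file columns do not match the heading set; got: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    expenditure_weights(raw$region[i],
                        unlist(raw[i, heading_set, drop = TRUE]),
                        heading_set)
  })
  names(out) <- raw$region
  out
}

#' Write expenditure weights to a delimited table
#'
#' @param weights Named list of [expenditure_weights()].
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path, sep = ",") {
  hs <- names(weights[[1L]])
  tab <- data.frame(region = vapply(weights, attr, "", "region_id"),
                    stringsAsFactors = FALSE)
  for (h in hs) tab[[h]] <- vapply(weights, `[[`, 0, h)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
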