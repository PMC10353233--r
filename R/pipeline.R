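#' Run the full spatial price index pipeline
#'
#' Orchestrates the pipeline end to end: read per-region schedules and
#' expenditure weights (or generate a synthetic system), match services into
#' a complete tableau, compute basic-heading parities and bilateral indexes,
#' derive GEKS and/or MST multilateral levels, and optionally back-cast them
#' with CPI series. Deterministic given its inputs (and the seed for a
#' synthetic run). When `out_dir` is set, the published-table-shaped
#' matrices, the MST edge list, matched-item counts and a JSON run report
#' with provenance metadata (input hashes, settings in effect, package
#' version) are written there.
#'
#' @param config List with entries:
#'   \describe{
#'     \item{schedules}{named character vector of schedule file paths
#'       (names = region ids), OR a `synthetic_config` under `synthetic`.}
#'     \item{weights}{path to the weights table (rows = regions).}
#'     \item{synthetic}{a [synthetic_config()] used instead of file input.}
#'     \item{method}{basic-heading method, `"jevons"` (default) or `"cpd"`.}
#'     \item{multilateral}{`"geks"`, `"mst"` or `"both"` (default).}
#'     \item{base_region}{presentation base region (default: first region).}
#'     \item{digits}{presentation rounding (default 2).}
#'     \item{dialect}{a [schedule_dialect()] for reading schedules.}
#'     \item{keep_highest_price}{passed to [read_schedule()].}
#'     \item{cpi, ref_year, span}{optional back-cast inputs: CPI table path
#'       or named list of [cpi_series()], reference year, year span.}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @return List: `tableau`, `weights`, `bilateral` (a `bilateral_set`),
#'   `geks` / `mst` (`multilateral_result`s), `tables` (presentation
#'   matrices), `backcast` (long data frame or `NULL`), `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  method <- if (is.null(config$method)) "jevons" else config$method
  multi <- if (is.null(config$multilateral)) "both" else config$multilateral
  digits <- if (is.null(config$digits)) 2 else config$digits
  stopifnot(multi %in% c("geks", "mst", "both"))
  input_hashes <- character()

  if (!is.null(config$synthetic)) {
    sys <- generate_system(config$synthetic)
    schedules <- sys$schedules
    weights <- sys$weights
    truth <- sys$truth
  } else {
    stopifnot(!is.null(config$schedules), !is.null(config$weights))
    paths <- config$schedules
    dialect <- if (is.null(config$dialect)) schedule_dialect() else
      config$dialect
    khp <- isTRUE(config$keep_highest_price)
    schedules <- lapply(names(paths), function(r) {
      read_schedule(paths[[r]], r, dialect = dialect,
                    heading_set = if (is.null(config$heading_set))
                      medical_headings() else config$heading_set,
                    keep_highest_price = khp)
    })
    names(schedules) <- names(paths)
    weights <- read_weights(config$weights,
                            heading_set = schedules[[1L]]$heading_set)
    truth <- NULL
    input_hashes <- tools::md5sum(c(unlist(paths), config$weights))
  }

  tableau <- match_services(schedules)
  bil <- compute_bilateral_set(tableau, weights, method = method)

  base_region <- if (is.null(config$base_region)) tableau$regions[1L] else
    config$base_region

  g <- if (multi %in% c("geks", "both")) geks(bil$fisher) else NULL
  m <- if (multi %in% c("mst", "both")) {
    tree <- build_mst(bil$pls, tableau$regions)
    mst_levels(tree, bil$fisher)
  } else NULL

  tables <- list(fisher = presentation_table(bil$fisher, digits = digits))
  if (!is.null(g)) tables$geks <- presentation_table(g, digits = digits)
  if (!is.null(m)) tables$mst <- presentation_table(m, digits = digits)

  backcast <- NULL
  if (!is.null(config$cpi)) {
    stopifnot(!is.null(config$ref_year), !is.null(config$span))
    cpi <- config$cpi
    if (is.character(cpi)) cpi <- read_cpi(cpi)
    ref <- if (!is.null(g)) g else m
    backcast <- backcast_levels(ref, cpi, base_region,
                                config$ref_year, config$span)
  }

  metadata <- list(package_version = as.character(
                     utils::packageVersion("spatialppp")),
                   method = method, multilateral = multi,
                   base_region = base_region, digits = digits,
                   matched = tableau$match_counts,
                   excluded = nrow(tableau$exclusions),
                   input_hashes = as.list(input_hashes),
                   synthetic_seed = if (!is.null(truth)) truth$seed else NULL,
                   settings = list(
                     matching_key = "code",
                     zero_price_rule = "exclude service if <= 0 anywhere",
                     quartile_type = 7,
                     weight_renormalization = "always, warn if off by >1e-6",
                     mst_tie_break = "lexicographic region-pair order"))

  result <- list(tableau = tableau, weights = weights, bilateral = bil,
                 geks = g, mst = m, tables = tables, backcast = backcast,
                 truth = truth, metadata = metadata)

  if (!is.null(config$out_dir)) {
    write_run_report(result, config$out_dir)
  }
  result
}

#' Read per-region CPI series from a delimited table
#'
#' Rows = regions (a `region` column), remaining columns = years.
#'
#' @param path Delimited file.
#' @param convention Passed to [cpi_series()].
#' @param sep Field separator.
#' @return Named list of [cpi_series()].
#' @export
read_cpi <- function(path, convention = "prev_year", sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"region" %in% names(raw)) {
    stop("CPI file needs a 'region' column", call. = FALSE)
  }
  years <- setdiff(names(raw), "region")
  out <- lapply(seq_len(nrow(raw)), function(i) {
    cpi_series(raw$region[i],
               stats::setNames(as.numeric(raw[i, years]), years),
               convention = convention)
  })
  stats::setNames(out, raw$region)
}

#' Write pipeline outputs to a directory
#'
#' Emits the presentation matrices as CSV, the MST edge list, the matched /
#' excluded item counts, the back-cast panel when present, and a JSON run
#' report with provenance metadata.
#'
#' @param result The list returned by [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$tables)) {
    tab <- result$tables[[nm]]
    utils::write.csv(data.frame(region = rownames(tab), tab,
                                check.names = FALSE),
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$mst)) {
    utils::write.csv(result$mst$tree, file.path(out_dir, "mst_edges.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$tableau$match_counts,
                   file.path(out_dir, "match_counts.csv"), row.names = FALSE)
  if (!is.null(result$backcast)) {
    utils::write.csv(result$backcast, file.path(out_dir, "backcast.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$metadata, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out_dir)
}
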