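#' Published bilateral Fisher matrix for the Yangtze River Delta (2020)
#'
#' The 4 x 4 Fisher index matrix between Shanghai, Jiangsu, Zhejiang and
#' Anhui (schedules as of December 2020), as published (base-100, the
#' region heading each column is the reference region). Returned on the
#' ratio scale (divided by 100) ready for [geks()] and [mst_levels()].
#'
#' @return 4 x 4 numeric matrix on the ratio scale, diagonal 1.
#' @export
yrd_fisher_matrix <- function() {
  path <- system.file("extdata", "yrd_fisher_2020.csv",
                      package = "spatialppp", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L]) / 100
  rownames(m) <- tab$region
  check_fisher_matrix(m)
}

#' Spanning tree underlying the published Yangtze River Delta comparison
#'
#' The edge set {Shanghai-Jiangsu, Shanghai-Zhejiang, Zhejiang-Anhui}. The
#' Paasche-Laspeyres spreads that would derive this tree were not published,
#' so the tree is INFERRED from the consistency of the published MST-method
#' table with the published Fisher matrix; the `status` column flags this.
#'
#' @return Data frame of edges: `from`, `to`, `status` (`"inferred"`).
#' @export
yrd_mst_tree <- function() {
  path <- system.file("extdata", "yrd_mst_edges.csv",
                      package = "spatialppp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute the published multilateral tables from the Fisher fixture
#'
#' Applies GEKS and tree-chaining to the packaged 2020 Fisher matrix and
#' returns both multilateral tables in published form (base 100, 2
#' decimals), together with the inferred tree.
#'
#' @param digits Presentation rounding (default 2, as published).
#' @return List: `fisher` (the fixture, base 100), `geks`, `mst`
#'   (presentation matrices), `tree` (edge data frame), and the unrounded
#'   `multilateral_result` objects `geks_result`, `mst_result`.
#' @export
reproduce_yrd_tables <- function(digits = 2) {
  fisher <- yrd_fisher_matrix()
  tree <- yrd_mst_tree()
  g <- geks(fisher)
  m <- mst_levels(tree, fisher)
  list(fisher = presentation_table(fisher, digits = digits),
       geks = presentation_table(g, digits = digits),
       mst = presentation_table(m, digits = digits),
       tree = tree,
       geks_result = g, mst_result = m)
}
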