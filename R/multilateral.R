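#' Construct a multilateral result
#'
#' Internal constructor; checks transitivity and reciprocity of the level
#' matrix before stamping the class.
#'
#' @param method `"GEKS"` or `"MST"`.
#' @param levels M x M matrix, entry (j, k) = price level of region j with
#'   region k as base (ratio scale).
#' @param tree For MST, data frame of tree edges (`from`, `to`, `weight`).
#' @return Object of class `multilateral_result`.
#' @keywords internal
multilateral_result <- function(method, levels, tree = NULL) {
  stopifnot(method %in% c("GEKS", "MST"), is.matrix(levels),
            nrow(levels) == ncol(levels))
  regions <- rownames(levels)
  recip <- levels * t(levels)
  if (max(abs(recip - 1)) > 1e-8) {
    stop("level matrix violates reciprocity", call. = FALSE)
  }
  structure(list(method = method, regions = regions,
                 levels = levels, tree = tree),
            class = "multilateral_result")
}

#' @export
print.multilateral_result <- function(x, ...) {
  cat("<multilateral_result>", x$method, "over",
      length(x$regions), "regions\n")
  print(round(100 * x$levels, 2))
  if (!is.null(x$tree)) {
    cat("tree edges:\n")
    print(x$tree, row.names = FALSE)
  }
  invisible(x)
}

check_fisher_matrix <- function(fisher) {
  if (!is.matrix(fisher) || nrow(fisher) != ncol(fisher)) {
    stop("Fisher matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(fisher)) || any(fisher <= 0)) {
    stop("Fisher matrix must be positive and finite", call. = FALSE)
  }
  if (max(abs(diag(fisher) - 1)) > 1e-8) {
    stop("Fisher matrix diagonal must be 1", call. = FALSE)
  }
  if (is.null(rownames(fisher))) {
    rn <- paste0("R", seq_len(nrow(fisher)))
    dimnames(fisher) <- list(rn, rn)
  }
  fisher
}

#' GEKS multilateral price levels
#'
#' Transitivizes a bilateral Fisher matrix by geometric averaging over all
#' bridge regions: level(j, k) is the geometric mean over regions i of
#' F(j, i) x F(i, k). Every region is treated symmetrically, and the result
#' is the transitive matrix closest to the Fisher matrix in the
#' log least-squares sense. Computed in log space.
#'
#' An exactly computed Fisher matrix is reciprocal (F_jk x F_kj = 1); a
#' matrix re-entered from a published table rounded to 2 decimals is not
#' quite. The log input is therefore antisymmetrized (each pair replaced by
#' `sqrt(F_jk / F_kj)`) before averaging -- a no-op on reciprocal input --
#' so transitivity and reciprocity of the output hold to machine precision
#' regardless of input roundoff.
#'
#' @param fisher M x M positive matrix of bilateral Fisher indexes, entry
#'   (j, k) = index of region j with base k; diagonal 1, reciprocal up to
#'   roundoff.
#' @return A `multilateral_result` with `method = "GEKS"`.
#' @export
geks <- function(fisher) {
  fisher <- check_fisher_matrix(fisher)
  lf <- log(fisher)
  lf <- (lf - t(lf)) / 2                  # enforce reciprocity in log space
  r <- rowMeans(lf)
  # log level(j,k) = mean_i [ log F(j,i) + log F(i,k) ] = r_j - r_k
  levels <- exp(outer(r, r, `-`))
  diag(levels) <- 1
  dimnames(levels) <- dimnames(fisher)
  multilateral_result("GEKS", levels)
}

#' Minimum spanning tree over Paasche-Laspeyres spreads
#'
#' Builds the minimum-total-weight spanning tree of the complete region graph
#' with PLS edge weights (Kruskal's greedy edge addition with union-find).
#' Regions whose expenditure structures are most alike -- smallest spread --
#' are linked directly. Ties are broken deterministically by lexicographic
#' region-pair order.
#'
#' @param pls M x M symmetric non-negative matrix with zero diagonal
#'   (spreads), rownames = regions.
#' @param regions Optional region ordering; defaults to `rownames(pls)`.
#' @return Data frame of M - 1 edges: `from`, `to`, `weight`, ordered as
#'   added.
#' @export
build_mst <- function(pls, regions = rownames(pls)) {
  stopifnot(is.matrix(pls), nrow(pls) == ncol(pls))
  M <- nrow(pls)
  if (M < 2L) stop("need at least 2 regions", call. = FALSE)
  if (is.null(regions)) regions <- paste0("R", seq_len(M))
  if (max(abs(pls - t(pls))) > 1e-9 || any(pls < 0) ||
      max(abs(diag(pls))) > 1e-12) {
    stop("PLS matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  }
  pairs <- which(upper.tri(pls), arr.ind = TRUE)
  ord <- order(pls[pairs], pairs[, "row"], pairs[, "col"])
  pairs <- pairs[ord, , drop = FALSE]

  parent <- seq_len(M)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  for (e in seq_len(nrow(pairs))) {
    a <- pairs[e, "row"]; b <- pairs[e, "col"]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      edges <- rbind(edges, data.frame(from = regions[a], to = regions[b],
                                       weight = pls[a, b],
                                       stringsAsFactors = FALSE))
      if (nrow(edges) == M - 1L) break
    }
  }
  edges
}

#' Multilateral levels by chaining Fisher links along a spanning tree
#'
#' The level of region j with base k is the product of bilateral Fisher
#' indexes along the unique tree path from k to j, each step oriented as
#' F(step_to, step_from). Transitive because tree paths are unique;
#' tree-adjacent pairs keep their bilateral Fisher index exactly.
#'
#' As in [geks()], links are antisymmetrized in log space first (a no-op on
#' an exactly reciprocal Fisher matrix) so that levels from a published,
#' 2-decimal matrix still satisfy reciprocity to machine precision.
#'
#' @param tree Data frame of edges (`from`, `to`), e.g. from [build_mst()].
#' @param fisher M x M bilateral Fisher matrix covering the tree's regions.
#' @return A `multilateral_result` with `method = "MST"` carrying the tree.
#' @export
mst_levels <- function(tree, fisher) {
  fisher <- check_fisher_matrix(fisher)
  lf <- log(fisher)
  fisher <- exp((lf - t(lf)) / 2)
  regions <- rownames(fisher)
  M <- length(regions)
  stopifnot(is.data.frame(tree), all(c("from", "to") %in% names(tree)))
  if (nrow(tree) != M - 1L ||
      !all(c(tree$from, tree$to) %in% regions)) {
    stop("tree must have M-1 edges over the Fisher matrix's regions",
         call. = FALSE)
  }
  adj <- lapply(stats::setNames(regions, regions), function(r) {
    c(tree$to[tree$from == r], tree$from[tree$to == r])
  })
  levels <- matrix(NA_real_, M, M, dimnames = list(regions, regions))
  for (k in regions) {
    lev <- stats::setNames(rep(NA_real_, M), regions)
    lev[k] <- 1
    queue <- k
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.na(lev[v])) {
          lev[v] <- lev[u] * fisher[v, u]   # one Fisher link outward
          queue <- c(queue, v)
        }
      }
    }
    if (anyNA(lev)) stop("tree does not span all regions", call. = FALSE)
    levels[, k] <- lev
  }
  tw <- if ("weight" %in% names(tree)) tree$weight else rep(NA_real_, M - 1L)
  multilateral_result("MST", levels,
                      tree = data.frame(from = tree$from, to = tree$to,
                                        weight = tw,
                                        stringsAsFactors = FALSE))
}

#' Re-express price levels relative to a base region
#'
#' Returns the vector of levels with the base region scaled to `scale`
#' (100 by convention in published tables). Rounding is presentation-only;
#' pass `digits = NULL` to keep full precision.
#'
#' @param x A `multilateral_result`, or a named numeric vector of levels.
#' @param base_region Region to set at `scale`.
#' @param scale Value assigned to the base region (default 100).
#' @param digits Decimal places for presentation rounding, or `NULL` for
#'   none.
#' @return Named numeric vector of levels, base region = `scale`.
#' @export
rebase <- function(x, base_region, scale = 100, digits = NULL) {
  if (inherits(x, "multilateral_result")) {
    if (!base_region %in% x$regions) {
      stop("unknown region: ", base_region, call. = FALSE)
    }
    v <- x$levels[, base_region]
  } else {
    v <- x
    if (is.null(names(v)) || !base_region %in% names(v)) {
      stop("unknown region: ", base_region, call. = FALSE)
    }
  }
  out <- v / v[[base_region]] * scale
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Published-table presentation of a multilateral result
#'
#' The full M x M matrix on the base-100 scale: the region heading each
#' column is the reference region. Rounding is presentation-only.
#'
#' @param x A `multilateral_result` or a level matrix.
#' @param scale Base value (default 100).
#' @param digits Decimal places (default 2, as in published tables).
#' @return M x M numeric matrix.
#' @export
presentation_table <- function(x, scale = 100, digits = 2) {
  levels <- if (inherits(x, "multilateral_result")) x$levels else x
  round(levels * scale, digits)
}
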