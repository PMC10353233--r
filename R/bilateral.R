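#' Jevons basic-heading parities
#'
#' For one basic heading, the Jevons purchasing power parity of region j
#' relative to base region k is the unweighted geometric mean over the
#' heading's services of the price ratios P_ij / P_ik. Computed in log space:
#' at thousands of services a raw product of ratios under- or overflows.
#'
#' @param tableau A complete `price_tableau`.
#' @param heading Basic-heading label present in the tableau.
#' @return M x M matrix (class `heading_ppp`); entry (j, k) is the parity of
#'   region j with region k as base. Diagonal 1; reciprocal by construction.
#' @export
jevons_heading_ppp <- function(tableau, heading) {
  validate_tableau(tableau)
  idx <- which(tableau$services$heading == heading)
  if (!length(idx)) stop("heading has no services: ", heading, call. = FALSE)
  lp <- log(tableau$prices[, idx, drop = FALSE])
  m <- rowMeans(lp)                       # mean log price per region
  ppp <- exp(outer(m, m, `-`))            # (j,k): exp(mean_j - mean_k)
  diag(ppp) <- 1
  structure(ppp, heading = heading, class = c("heading_ppp", "matrix"))
}

#' Country-product-dummy basic-heading parities
#'
#' Fits log price = region effect + service effect + residual by least
#' squares with the base region's effect constrained to zero, and returns
#' exp of region-effect differences as the parity matrix. On a complete
#' tableau this reproduces the Jevons parities; unlike Jevons it also
#' handles missing cells, which [cpd_fit()] exposes directly.
#'
#' @inheritParams jevons_heading_ppp
#' @param base_region Region whose effect is fixed at zero (dummy coding);
#'   defaults to the first tableau region. The parity matrix is invariant to
#'   this choice.
#' @return M x M `heading_ppp` matrix as in [jevons_heading_ppp()].
#' @export
cpd_heading_ppp <- function(tableau, heading, base_region = NULL) {
  validate_tableau(tableau)
  idx <- which(tableau$services$heading == heading)
  if (!length(idx)) stop("heading has no services: ", heading, call. = FALSE)
  p <- tableau$prices[, idx, drop = FALSE]
  ppp <- cpd_fit(p, base_region = base_region)
  structure(ppp, heading = heading, class = c("heading_ppp", "matrix"))
}

#' Country-product-dummy fit on a price matrix
#'
#' Low-level CPD solver on an M x N matrix of prices (rows = regions,
#' columns = services), tolerating `NA` cells. The normal equations of the
#' two-way dummy regression are solved sparsely.
#'
#' @param prices M x N numeric matrix, positive where observed, `NA` where
#'   missing; rownames are region ids.
#' @param base_region Region whose effect is fixed at 0 (default: first row).
#' @return M x M parity matrix, entry (j, k) = exp(effect_j - effect_k).
#' @export
cpd_fit <- function(prices, base_region = NULL) {
  stopifnot(is.matrix(prices), nrow(prices) >= 2L)
  regions <- rownames(prices)
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(prices)))
  if (is.null(base_region)) base_region <- regions[1L]
  b <- match(base_region, regions)
  if (is.na(b)) stop("unknown base region: ", base_region, call. = FALSE)

  obs <- which(is.finite(prices) & prices > 0, arr.ind = TRUE)
  if (any(is.finite(prices) & prices <= 0)) {
    stop("prices must be positive where observed", call. = FALSE)
  }
  M <- nrow(prices); N <- ncol(prices)
  if (length(unique(obs[, "row"])) < M || length(unique(obs[, "col"])) < N) {
    stop("rank-deficient design: a region or service has no observed price",
         call. = FALSE)
  }
  y <- log(prices[obs])
  reg <- obs[, "row"]; svc <- obs[, "col"]
  # design: M-1 region dummies (base dropped) then N service dummies
  ridx <- ifelse(reg < b, reg, reg - 1L)   # region column, 0 for base
  n_obs <- length(y)
  i <- c(which(reg != b), seq_len(n_obs))
  j <- c(ridx[reg != b], (M - 1L) + svc)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_obs, M - 1L + N))
  XtX <- Matrix::crossprod(X)
  coefs <- tryCatch(
    as.numeric(Matrix::solve(XtX, Matrix::crossprod(X, y))),
    error = function(e) stop("rank-deficient design: ", conditionMessage(e),
                             call. = FALSE))
  eff <- numeric(M)
  eff[-b] <- coefs[seq_len(M - 1L)]
  ppp <- exp(outer(eff, eff, `-`))
  diag(ppp) <- 1
  dimnames(ppp) <- list(regions, regions)
  ppp
}

#' Laspeyres aggregation of basic-heading parities
#'
#' Arithmetic mean of the heading parities for one ordered region pair,
#' weighted by the base region's expenditure shares.
#'
#' @param ppp Named numeric vector: parity of the comparison region relative
#'   to the base region, one entry per basic heading.
#' @param weights [expenditure_weights()] (or named vector) of the BASE
#'   region, aligned to the same headings.
#' @return The Laspeyres bilateral index (ratio scale).
#' @export
laspeyres_index <- function(ppp, weights) {
  w <- align_weights(ppp, weights)
  sum(ppp * w)
}

#' Paasche aggregation of basic-heading parities
#'
#' Harmonic mean of the heading parities for one ordered region pair,
#' weighted by the COMPARISON region's expenditure shares.
#'
#' @inheritParams laspeyres_index
#' @param weights Weights of the comparison region.
#' @return The Paasche bilateral index (ratio scale).
#' @export
paasche_index <- function(ppp, weights) {
  w <- align_weights(ppp, weights)
  1 / sum(w / ppp)
}

align_weights <- function(ppp, weights) {
  stopifnot(is.numeric(ppp), all(is.finite(ppp)), all(ppp > 0))
  w <- as.numeric(weights)
  names(w) <- names(weights)
  if (is.null(names(ppp)) || is.null(names(w))) {
    if (length(ppp) != length(w)) {
      stop("heading parities and weights are misaligned", call. = FALSE)
    }
    return(w)
  }
  if (!setequal(names(ppp), names(w))) {
    stop("heading parities and weights cover different headings",
         call. = FALSE)
  }
  w[names(ppp)]
}

#' Fisher ideal index
#'
#' Geometric mean of the Laspeyres and Paasche indexes; satisfies the
#' region-reversal property the two components lack.
#'
#' @param L,P Laspeyres and Paasche indexes, both positive.
#' @return `sqrt(L * P)`.
#' @export
fisher_index <- function(L, P) {
  if (any(!is.finite(L)) || any(!is.finite(P)) || any(L <= 0) || any(P <= 0)) {
    stop("Laspeyres and Paasche indexes must be positive", call. = FALSE)
  }
  sqrt(L * P)
}

#' Paasche-Laspeyres spread
#'
#' `|log(L / P)|` for one region pair: a dissimilarity measure of the two
#' regions' expenditure structures, used as the edge weight when linking
#' regions through a minimum spanning tree. Symmetric in pair orientation.
#'
#' @inheritParams fisher_index
#' @return Non-negative scalar; 0 when L = P.
#' @export
pls_spread <- function(L, P) {
  if (any(!is.finite(L)) || any(!is.finite(P)) || any(L <= 0) || any(P <= 0)) {
    stop("Laspeyres and Paasche indexes must be positive", call. = FALSE)
  }
  abs(log(L / P))
}

#' All bilateral indexes for a matched price system
#'
#' Computes basic-heading parities (Jevons or CPD) and aggregates them with
#' per-region expenditure weights into Laspeyres, Paasche and Fisher matrices
#' plus the Paasche-Laspeyres spread, for every ordered region pair.
#'
#' @param tableau A complete `price_tableau`.
#' @param all_weights Named list of [expenditure_weights()], one per tableau
#'   region.
#' @param method `"jevons"` (default) or `"cpd"` for the basic-heading stage;
#'   equivalent on a complete tableau.
#' @return Object of class `bilateral_set`: list with M x M matrices
#'   `laspeyres`, `paasche`, `fisher`, `pls` (entry (j, k) = index of region
#'   j with base k), and `heading_ppp`, a named list of per-heading parity
#'   matrices.
#' @export
compute_bilateral_set <- function(tableau, all_weights,
                                  method = c("jevons", "cpd")) {
  method <- match.arg(method)
  validate_tableau(tableau)
  regions <- tableau$regions
  missing_w <- setdiff(regions, names(all_weights))
  if (length(missing_w)) {
    stop("missing expenditure weights for region(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  headings <- intersect(tableau$heading_set,
                        unique(tableau$services$heading))
  hp <- lapply(headings, function(h) {
    switch(method,
           jevons = jevons_heading_ppp(tableau, h),
           cpd = cpd_heading_ppp(tableau, h))
  })
  names(hp) <- headings

  M <- length(regions)
  L <- P <- FI <- matrix(1, M, M, dimnames = list(regions, regions))
  S <- matrix(0, M, M, dimnames = list(regions, regions))
  for (k in seq_len(M)) {           # base region
    for (j in seq_len(M)) {         # comparison region
      if (j == k) next
      ppp <- vapply(hp, function(m) m[j, k], 0)
      names(ppp) <- headings
      l <- laspeyres_index(ppp, all_weights[[regions[k]]][headings])
      p <- paasche_index(ppp, all_weights[[regions[j]]][headings])
      L[j, k] <- l
      P[j, k] <- p
      FI[j, k] <- fisher_index(l, p)
      S[j, k] <- pls_spread(l, p)
    }
  }
  structure(list(regions = regions, method = method, heading_ppp = hp,
                 laspeyres = L, paasche = P, fisher = FI, pls = S),
            class = "bilateral_set")
}

#' @export
print.bilateral_set <- function(x, ...) {
  cat("<bilateral_set>", length(x$regions), "regions;",
      length(x$heading_ppp), "headings; method:", x$method, "\n")
  cat("Fisher (x100):\n")
  print(round(100 * x$fisher, 2))
  invisible(x)
}
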