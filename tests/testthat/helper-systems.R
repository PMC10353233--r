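# Small builders used across the suite.

toy_headings <- c("general medical services", "medical diagnosis services",
                  "clinical treatment services",
                  "traditional medicine services")

# One schedule with one service per heading, prices given in heading order.
toy_schedule <- function(region, prices = c(10, 20, 30, 40),
                         headings = toy_headings,
                         codes = sprintf("C%02d", seq_along(prices))) {
  price_schedule(region,
                 data.frame(code = codes,
                            name = paste("svc", codes),
                            heading = rep_len(headings, length(prices)),
                            price = prices,
                            stringsAsFactors = FALSE),
                 heading_set = toy_headings)
}

# Random complete tableau: M regions x (n_per_heading per heading).
random_tableau <- function(M = 4, n_per_heading = 5,
                           headings = toy_headings, sdlog = 1) {
  N <- n_per_heading * length(headings)
  p <- matrix(rlnorm(M * N, log(100), sdlog), M, N,
              dimnames = list(paste0("R", seq_len(M)),
                              sprintf("C%03d", seq_len(N))))
  price_tableau(p, rep(headings, each = n_per_heading),
                heading_set = headings)
}

# Random valid (reciprocal, unit-diagonal) Fisher matrix in log space.
random_fisher <- function(M = 4) {
  lf <- matrix(0, M, M)
  lf[upper.tri(lf)] <- rnorm(M * (M - 1) / 2, 0, 0.2)
  lf <- lf - t(lf)
  f <- exp(lf)
  dimnames(f) <- list(paste0("R", seq_len(M)), paste0("R", seq_len(M)))
  f
}

equal_weights <- function(regions, headings = toy_headings) {
  w <- lapply(regions, function(r) {
    expenditure_weights(r, setNames(rep(1 / length(headings),
                                        length(headings)), headings),
                        heading_set = headings)
  })
  setNames(w, regions)
}

random_weights <- function(regions, headings = toy_headings) {
  w <- lapply(regions, function(r) {
    x <- rgamma(length(headings), 5)
    expenditure_weights(r, setNames(x / sum(x), headings),
                        heading_set = headings)
  })
  setNames(w, regions)
}

# All spanning trees of the complete graph on M vertices, as edge-index
# matrices; used as the brute-force MST oracle (Cayley: M^(M-2) trees).
all_spanning_trees <- function(M) {
  pairs <- t(combn(M, 2))
  combos <- combn(nrow(pairs), M - 1)
  keep <- list()
  for (i in seq_len(ncol(combos))) {
    sel <- combos[, i]
    # connectivity check by union-find
    parent <- seq_len(M)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    n_merge <- 0L
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) { parent[ra] <- rb; n_merge <- n_merge + 1L }
    }
    if (n_merge == M - 1L) keep[[length(keep) + 1L]] <- sel
  }
  list(pairs = pairs, trees = keep)
}
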