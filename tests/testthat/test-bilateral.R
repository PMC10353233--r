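test_that("Jevons parities are geometric means of price ratios", {
  h <- toy_headings[1]
  # proportional prices: region 2 exactly twice region 1
  p <- matrix(c(10, 40, 20, 80), 2, 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), c("C1", "C2")))
  tab <- price_tableau(p, rep(h, 2), heading_set = h)
  ppp <- jevons_heading_ppp(tab, h)
  expect_equal(ppp["R2", "R1"], 2)
  expect_equal(ppp["R1", "R2"], 0.5)
  expect_equal(diag(unclass(ppp)), c(R1 = 1, R2 = 1))

  # ratios 2 and 8 -> geometric mean 4
  p2 <- matrix(c(1, 1, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("R1", "R2"), c("C1", "C2")))
  tab2 <- price_tableau(p2, rep(h, 2), heading_set = h)
  expect_equal(jevons_heading_ppp(tab2, h)["R2", "R1"], 4)

  # random 10-service heading vs naive product-then-root evaluation
  set.seed(5)
  p3 <- matrix(rlnorm(30, log(100), 1), 3, 10,
               dimnames = list(paste0("R", 1:3), sprintf("C%02d", 1:10)))
  tab3 <- price_tableau(p3, rep(h, 10), heading_set = h)
  ppp3 <- jevons_heading_ppp(tab3, h)
  naive <- prod(p3["R2", ] / p3["R1", ])^(1 / 10)
  expect_equal(ppp3["R2", "R1"], naive, tolerance = 1e-12)
  # reciprocity by construction
  expect_equal(max(abs(unclass(ppp3) * t(unclass(ppp3)) - 1)), 0,
               tolerance = 1e-12)

  expect_error(jevons_heading_ppp(tab3, toy_headings[2]), "no services")
})

test_that("CPD equals Jevons on complete tableaus and handles gaps", {
  set.seed(6)
  tab <- random_tableau(M = 4, n_per_heading = 7)
  for (h in toy_headings) {
    expect_equal(unclass(cpd_heading_ppp(tab, h)),
                 unclass(jevons_heading_ppp(tab, h)), tolerance = 1e-10)
  }

  # identical prices everywhere -> all parities 1
  p <- matrix(rep(c(3, 8, 11), each = 3), 3, 3,
              dimnames = list(paste0("R", 1:3), paste0("C", 1:3)))
  tabi <- price_tableau(p, rep(toy_headings[1], 3),
                        heading_set = toy_headings[1])
  expect_equal(max(abs(unclass(cpd_heading_ppp(tabi, toy_headings[1])) - 1)),
               0, tolerance = 1e-12)

  # incomplete matrix: matches a direct normal-equations solve on dummies
  set.seed(7)
  pm <- matrix(rlnorm(12, log(50), 0.5), 3, 4,
               dimnames = list(paste0("R", 1:3), paste0("C", 1:4)))
  pm[2, 3] <- NA
  got <- cpd_fit(pm, base_region = "R1")
  # oracle: dense lm on region + item dummies, base region dropped
  obs <- which(is.finite(pm), arr.ind = TRUE)
  df <- data.frame(y = log(pm[obs]),
                   r = factor(rownames(pm)[obs[, 1]]),
                   s = factor(colnames(pm)[obs[, 2]]))
  fit <- lm(y ~ r + s, data = df)
  eff <- c(R1 = 0, coef(fit)[c("rR2", "rR3")])
  names(eff) <- c("R1", "R2", "R3")
  expect_equal(got["R2", "R1"], exp(eff[["R2"]]), tolerance = 1e-10)
  expect_equal(got["R3", "R2"], exp(eff[["R3"]] - eff[["R2"]]),
               tolerance = 1e-10)

  # a region with no observed price is rank-deficient
  pm[2, ] <- NA
  expect_error(cpd_fit(pm), "rank-deficient")
})

test_that("Laspeyres, Paasche, Fisher and PLS follow their closed forms", {
  hs <- toy_headings
  # constant parities pass through any weights
  w <- setNames(c(0.1, 0.2, 0.3, 0.4), hs)
  lam <- setNames(rep(1.7, 4), hs)
  expect_equal(laspeyres_index(lam, w), 1.7)
  expect_equal(paasche_index(lam, w), 1.7)

  # hand-computed two-heading cases
  ppp <- setNames(c(2, 4), hs[1:2])
  w2 <- setNames(c(0.5, 0.5), hs[1:2])
  expect_equal(laspeyres_index(ppp, w2), 3)
  expect_equal(paasche_index(ppp, w2), 1 / (0.25 + 0.125))

  # random parities/weights equal explicit dot product / harmonic form
  set.seed(8)
  p4 <- setNames(rlnorm(4, 0, 0.4), hs)
  w4 <- setNames(rdir <- {x <- rgamma(4, 3); x / sum(x)}, hs)
  expect_equal(laspeyres_index(p4, w4), sum(p4 * w4), tolerance = 1e-14)
  expect_equal(paasche_index(p4, w4), 1 / sum(w4 / p4), tolerance = 1e-14)
  # mean-value bounds
  for (v in c(laspeyres_index(p4, w4), paasche_index(p4, w4))) {
    expect_gte(v, min(p4)); expect_lte(v, max(p4))
  }
  # misaligned headings error
  expect_error(laspeyres_index(p4, setNames(w4, rev(hs))[1:3]),
               "different headings")

  expect_equal(fisher_index(1.1, 1.1), 1.1)
  expect_equal(fisher_index(2, 0.5), 1)
  # algebraic consistency: L = c^2 / P  =>  F = c
  expect_equal(fisher_index(1.3658^2 / 0.9, 0.9), 1.3658)
  expect_error(fisher_index(-1, 2), "positive")

  expect_equal(pls_spread(1.2, 1.2), 0)
  expect_equal(pls_spread(exp(1) * 0.8, 0.8), 1)
  expect_error(pls_spread(0, 1), "positive")
})

test_that("bilateral sets satisfy identity, reversal and bound invariants", {
  set.seed(9)
  tab <- random_tableau(M = 4, n_per_heading = 8)
  w <- random_weights(tab$regions)
  bil <- compute_bilateral_set(tab, w)

  expect_equal(diag(bil$laspeyres), setNames(rep(1, 4), tab$regions))
  expect_equal(diag(bil$fisher), setNames(rep(1, 4), tab$regions))
  expect_equal(diag(bil$pls), setNames(rep(0, 4), tab$regions))

  # Fisher reversal and the L/P reversal identity
  expect_equal(max(abs(bil$fisher * t(bil$fisher) - 1)), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(bil$laspeyres * t(bil$paasche) - 1)), 0,
               tolerance = 1e-12)
  # F between L and P; F = sqrt(L P)
  expect_equal(bil$fisher, sqrt(bil$laspeyres * bil$paasche),
               tolerance = 1e-12)
  expect_true(all(bil$fisher >= pmin(bil$laspeyres, bil$paasche) - 1e-12))
  expect_true(all(bil$fisher <= pmax(bil$laspeyres, bil$paasche) + 1e-12))
  # PLS symmetric non-negative
  expect_equal(bil$pls, t(bil$pls), tolerance = 1e-12)
  expect_true(all(bil$pls >= 0))
  # mean-value bounds against heading parities
  hp <- sapply(bil$heading_ppp, function(m) m["R2", "R1"])
  expect_gte(bil$laspeyres["R2", "R1"], min(hp))
  expect_lte(bil$laspeyres["R2", "R1"], max(hp))

  expect_error(compute_bilateral_set(tab, w[-2]), "R2")
})

test_that("single-heading systems collapse Fisher to the Jevons parity", {
  h <- toy_headings[1]
  set.seed(10)
  p <- matrix(rlnorm(10, log(80), 0.7), 2, 5,
              dimnames = list(c("R1", "R2"), paste0("C", 1:5)))
  tab <- price_tableau(p, rep(h, 5), heading_set = h)
  w <- equal_weights(c("R1", "R2"), headings = h)
  bil <- compute_bilateral_set(tab, w)
  expect_equal(bil$fisher["R2", "R1"],
               jevons_heading_ppp(tab, h)["R2", "R1"], tolerance = 1e-12)
  expect_equal(bil$pls["R2", "R1"], 0, tolerance = 1e-12)
})

test_that("scaling one region's prices scales its indexes proportionally", {
  set.seed(12)
  tab <- random_tableau(M = 3, n_per_heading = 6)
  w <- random_weights(tab$regions)
  bil <- compute_bilateral_set(tab, w)

  lambda <- 1.37
  p2 <- tab$prices
  p2["R2", ] <- p2["R2", ] * lambda
  tab2 <- price_tableau(p2, tab$services$heading,
                        heading_set = tab$heading_set)
  bil2 <- compute_bilateral_set(tab2, w)
  # R2 relative to others scales by lambda; others relative to R2 by 1/lambda
  expect_equal(bil2$fisher["R2", "R1"], lambda * bil$fisher["R2", "R1"],
               tolerance = 1e-12)
  expect_equal(bil2$laspeyres["R1", "R2"],
               bil$laspeyres["R1", "R2"] / lambda, tolerance = 1e-12)
  expect_equal(bil2$paasche["R3", "R2"],
               bil$paasche["R3", "R2"] / lambda, tolerance = 1e-12)
})
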