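#' Configuration for a synthetic multi-region price system
#'
#' Defines a price system with known ground truth. Each region r has a true
#' price-level multiplier lambda_r (reference region = 1); the price of
#' service i in region r is base_i x lambda_r x tilt_{r,h(i)} x exp(noise),
#' with lognormal base prices, an optional per-heading tilt that creates
#' Laspeyres-Paasche spread, and item-level multiplicative noise.
#'
#' Defaults emulate the four-region system the package targets: level
#' multipliers 1.28 / 0.93 / 1.00 / 1.03 (Shanghai, Jiangsu, Zhejiang,
#' Anhui; Zhejiang the reference), 750 services in each of the four national
#' service categories (3000 matched items), base prices with median 150 CNY
#' and a heavy right tail reaching tens of thousands of CNY.
#'
#' @param regions Character vector of region ids.
#' @param lambda Positive true level multipliers, one per region (named or
#'   positional); the reference region's entry should be 1.
#' @param n_services Services per basic heading.
#' @param headings Basic-heading labels.
#' @param price_meanlog,price_sdlog Location/scale of the lognormal base
#'   prices (CNY).
#' @param noise_sigma SD of item-level lognormal noise (log scale, >= 0).
#' @param heading_sigma SD of the per-region per-heading lognormal tilt
#'   (0 gives a strictly proportional system with zero spread).
#' @param weight_alpha Dirichlet concentration for per-region expenditure
#'   weights: scalar or one value per heading.
#' @param ref_region Reference region (lambda rescaled so its entry is 1;
#'   its noise and tilt can be zeroed with `ref_noise_free`).
#' @param ref_noise_free If `TRUE`, the reference region gets no item noise.
#' @param seed Integer seed; recorded in the output metadata.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(regions = c("Shanghai", "Jiangsu", "Zhejiang",
                                         "Anhui"),
                             lambda = c(1.28, 0.93, 1.00, 1.03),
                             n_services = 750L,
                             headings = medical_headings(),
                             price_meanlog = log(150),
                             price_sdlog = 1.5,
                             noise_sigma = 0.3,
                             heading_sigma = 0.1,
                             weight_alpha = 8,
                             ref_region = "Zhejiang",
                             ref_noise_free = FALSE,
                             seed = 1L) {
  stopifnot(length(regions) >= 2L, length(lambda) == length(regions),
            all(lambda > 0), n_services >= 1L, length(headings) >= 1L,
            price_sdlog >= 0, noise_sigma >= 0, heading_sigma >= 0,
            all(weight_alpha > 0), ref_region %in% regions)
  if (is.null(names(lambda))) names(lambda) <- regions
  lambda <- lambda[regions] / lambda[[ref_region]]
  if (length(weight_alpha) == 1L) {
    weight_alpha <- rep(weight_alpha, length(headings))
  }
  stopifnot(length(weight_alpha) == length(headings))
  structure(list(regions = regions, lambda = lambda,
                 n_services = as.integer(n_services), headings = headings,
                 price_meanlog = price_meanlog, price_sdlog = price_sdlog,
                 noise_sigma = noise_sigma, heading_sigma = heading_sigma,
                 weight_alpha = weight_alpha, ref_region = ref_region,
                 ref_noise_free = ref_noise_free, seed = as.integer(seed)),
            class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a complete synthetic price system with known truth
#'
#' Draws base prices once, applies each region's level multiplier, heading
#' tilt and item noise, and packages the result as per-region schedules plus
#' expenditure weights, with a truth record holding the exact multipliers
#' and the implied true per-heading parities. Deterministic given the
#' config's seed. Generated systems always pass schedule validation and
#' match into a complete tableau.
#'
#' @param config A [synthetic_config()].
#' @return List with `schedules` (named list of `price_schedule`), `weights`
#'   (named list of [expenditure_weights()]), and `truth` (list: `lambda`,
#'   `heading_ppp` -- true parity of each region pair by heading --,
#'   `config`).
#' @export
generate_system <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rg <- config$regions
  hs <- config$headings
  M <- length(rg); H <- length(hs); n <- config$n_services
  N <- n * H

  codes <- sprintf("SVC%05d", seq_len(N))
  heading <- rep(hs, each = n)
  base <- stats::rlnorm(N, config$price_meanlog, config$price_sdlog)

  # per-region, per-heading tilt: geometric mean 1 across headings so the
  # region's overall multiplier stays lambda_r
  tilt <- matrix(1, M, H, dimnames = list(rg, hs))
  if (config$heading_sigma > 0) {
    z <- matrix(stats::rnorm(M * H, 0, config$heading_sigma), M, H)
    z <- z - rowMeans(z)
    tilt <- exp(z)
    dimnames(tilt) <- list(rg, hs)
    tilt[config$ref_region, ] <- 1
  }

  schedules <- stats::setNames(vector("list", M), rg)
  for (r in rg) {
    noise <- if (config$noise_sigma > 0 &&
                 !(config$ref_noise_free && r == config$ref_region)) {
      stats::rnorm(N, 0, config$noise_sigma)
    } else {
      numeric(N)
    }
    price <- base * config$lambda[[r]] * tilt[r, heading] * exp(noise)
    items <- data.frame(code = codes,
                        name = paste("service", codes),
                        heading = heading,
                        price = price,
                        stringsAsFactors = FALSE)
    schedules[[r]] <- price_schedule(r, items, heading_set = hs)
  }

  weights <- stats::setNames(lapply(rg, function(r) {
    expenditure_weights(r, stats::setNames(rdirichlet1(config$weight_alpha),
                                           hs), heading_set = hs)
  }), rg)

  # true parity of region j base k within heading h (noise-free component)
  heading_ppp <- stats::setNames(lapply(hs, function(h) {
    lev <- config$lambda * tilt[, h]
    outer(lev, lev, `/`)
  }), hs)

  list(schedules = schedules, weights = weights,
       truth = list(lambda = config$lambda, tilt = tilt,
                    heading_ppp = heading_ppp, seed = config$seed,
                    config = config))
}

#' Generate synthetic regional CPI series
#'
#' Yearly CPI values (previous year = 100 convention) drawn as
#' drift x exp(Normal(0, sigma^2)) per region and year.
#'
#' @param regions Character vector of region ids.
#' @param years Integer year range the series must cover.
#' @param drift Mean annual CPI per region (scalar or named per region),
#'   e.g. 103 for 3% average medical-service inflation.
#' @param sigma SD of the lognormal year-to-year disturbance (log scale).
#' @param seed Integer seed.
#' @return Named list of [cpi_series()].
#' @export
generate_cpi <- function(regions, years, drift = 103, sigma = 0.01,
                         seed = 1L) {
  years <- as.integer(years)
  if (!length(years) || anyNA(years)) stop("invalid years", call. = FALSE)
  if (length(drift) == 1L) {
    drift <- stats::setNames(rep(drift, length(regions)), regions)
  }
  stopifnot(all(drift > 0), sigma >= 0)
  set.seed(as.integer(seed))
  stats::setNames(lapply(regions, function(r) {
    v <- drift[[r]] * exp(stats::rnorm(length(years), 0, sigma))
    cpi_series(r, stats::setNames(v, years))
  }), regions)
}
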