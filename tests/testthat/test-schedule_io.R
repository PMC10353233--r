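test_that("schedule files read back with validation and error reporting", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sched.csv")

  # identity read-back of a 4-row schedule, one service per heading
  s <- toy_schedule("Shanghai", prices = c(12.5, 30, 7, 400))
  write_schedule(s, f)
  back <- read_schedule(f, "Shanghai")
  expect_equal(back$items, s$items)
  expect_identical(back$heading_set, s$heading_set)

  # duplicated code names the offender
  items <- s$items
  items$code[2] <- items$code[1]
  utils::write.csv(items, f, row.names = FALSE)
  expect_error(read_schedule(f, "Shanghai"), "C01")

  # missing column is a schema error naming the column
  utils::write.csv(s$items[, c("code", "heading", "price")], f,
                   row.names = FALSE)
  expect_error(read_schedule(f, "Shanghai"), "'name'")

  # unknown heading label rejected
  items <- s$items
  items$heading[1] <- "cosmetic services"
  utils::write.csv(items, f, row.names = FALSE)
  expect_error(read_schedule(f, "Shanghai"), "cosmetic services")

  # unparseable prices rejected with a report, not dropped silently
  items <- s$items
  items$price <- as.character(items$price)
  items$price[3] <- "n/a"
  utils::write.csv(items, f, row.names = FALSE)
  got <- read_schedule(f, "Shanghai")
  expect_equal(nrow(got$items), 3)
  expect_equal(attr(got, "rejected")$code, "C03")
})

test_that("alternative dialects and the highest-price pre-pass are honoured", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sched.tsv")
  d <- schedule_dialect(code = "item_code", name = "item_name",
                        heading = "category", price = "fee", sep = "\t",
                        dec = ",")
  writeLines(c("item_code\titem_name\tcategory\tfee",
               "A1\tward fee\tgeneral medical services\t12,5",
               "A1\tward fee\tgeneral medical services\t15,0",
               "B2\tct scan\tmedical diagnosis services\t230,0"), f)
  s <- read_schedule(f, "Jiangsu", dialect = d, keep_highest_price = TRUE)
  expect_equal(nrow(s$items), 2)
  expect_equal(s$items$price[s$items$code == "A1"], 15) # max tier kept
  # without the pre-pass the duplicate tier is a validation error
  expect_error(read_schedule(f, "Jiangsu", dialect = d), "A1")
})

test_that("matching keeps the all-region intersection and reports exclusions", {
  s1 <- toy_schedule("A", prices = c(1, 2, 3, 4, 5),
                     codes = c("C1", "C2", "C3", "C4", "C5"),
                     headings = rep(toy_headings[1], 5))
  s2 <- toy_schedule("B", prices = c(9, 8, 7),
                     codes = c("C2", "C3", "C9"),
                     headings = rep(toy_headings[1], 3))
  # shared codes C2, C3 only
  tab <- match_services(list(s1, s2))
  expect_equal(tab$services$code, c("C2", "C3"))
  expect_equal(tab$prices["A", "C2"], 2)
  expect_equal(tab$prices["B", "C2"], 9)

  # zero price in one region excludes the service and counts it
  s2z <- toy_schedule("B", prices = c(0, 8, 7),
                      codes = c("C2", "C3", "C9"),
                      headings = rep(toy_headings[1], 3))
  tabz <- match_services(list(s1, s2z))
  expect_equal(tabz$services$code, "C3")
  expect_equal(nrow(tabz$exclusions), 1)
  expect_equal(tabz$exclusions$code, "C2")

  # empty intersection errors
  s3 <- toy_schedule("B", prices = 1, codes = "ZZ",
                     headings = toy_headings[1])
  expect_error(match_services(list(s1, s3)), "no comparable items")

  # heading conflict across regions is named
  s4 <- toy_schedule("B", prices = c(9, 8), codes = c("C2", "C3"),
                     headings = c(toy_headings[2], toy_headings[1]))
  expect_error(match_services(list(s1, s4)), "C2")
})

test_that("matching is order-insensitive and yields complete tableaus", {
  set.seed(41)
  cfg <- synthetic_config(n_services = 6, seed = 11)
  sys <- generate_system(cfg)
  t1 <- match_services(sys$schedules)
  t2 <- match_services(rev(sys$schedules))
  expect_identical(t1$services, t2$services)
  expect_equal(t1$prices[rownames(t2$prices), ], t2$prices)
  expect_true(all(is.finite(t1$prices)) && all(t1$prices > 0))
  # generator bookkeeping: all codes shared, none zero
  expect_equal(ncol(t1$prices), cfg$n_services * length(cfg$headings))
})

test_that("descriptive statistics follow the documented quartile convention", {
  s <- toy_schedule("A", prices = c(1, 2, 3),
                    codes = c("C1", "C2", "C3"),
                    headings = rep(toy_headings[1], 3))
  d <- describe_schedule(s)
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$min, 1)
  expect_equal(d$max, 3)

  s1 <- toy_schedule("A", prices = 5, codes = "C1",
                     headings = toy_headings[1])
  d1 <- describe_schedule(s1)
  expect_true(all(unlist(d1[c("mean", "max", "min", "median",
                              "q1", "q3")]) == 5))

  # 1000 lognormal prices: agree with direct recomputation from raw vector
  set.seed(99)
  p <- rlnorm(1000, log(150), 1.5)
  sb <- toy_schedule("A", prices = p, codes = sprintf("C%04d", 1:1000),
                     headings = rep(toy_headings, 250))
  db <- describe_schedule(sb)
  expect_equal(db$mean, mean(p))
  expect_equal(db$median, unname(quantile(p, 0.5, type = 7)))
  expect_equal(db$q1, unname(quantile(p, 0.25, type = 7)))
  expect_equal(db$q3, unname(quantile(p, 0.75, type = 7)))
  # ordering invariant
  expect_true(db$min <= db$q1 && db$q1 <= db$median &&
                db$median <= db$q3 && db$q3 <= db$max)
  expect_true(db$min <= db$mean && db$mean <= db$max)
})

test_that("expenditure weights normalize, align and round-trip", {
  w <- expenditure_weights("A", c(0.25, 0.25, 0.25, 0.25),
                           heading_set = toy_headings)
  expect_false(attr(w, "renormalized"))
  expect_equal(as.numeric(w), rep(0.25, 4))

  expect_warning(
    w2 <- expenditure_weights("A", c(1, 1, 1, 1), heading_set = toy_headings),
    "renormalized")
  expect_equal(as.numeric(w2), rep(0.25, 4))

  expect_warning(
    w3 <- expenditure_weights("B", c(0.5, 0.3, 0.1, 0.2),
                              heading_set = toy_headings))
  expect_equal(as.numeric(w3), c(5, 3, 1, 2) / 11)

  expect_error(expenditure_weights("A", c(-0.1, 0.5, 0.3, 0.3),
                                   heading_set = toy_headings), ">= 0")

  dir <- withr::local_tempdir()
  f <- file.path(dir, "w.csv")
  write_weights(list(A = w, B = w3), f)
  back <- read_weights(f, heading_set = toy_headings)
  expect_equal(as.numeric(back$B), as.numeric(w3), tolerance = 1e-12)

  # heading mismatch vs heading_set errors
  expect_error(read_weights(f, heading_set = toy_headings[c(2, 1, 3, 4)][1:3]),
               "heading set")
})
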