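test_that("read_rwl parses the decadal layout and converts units", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c("TRE01 1960 100 200 300 999"), f)
  x <- read_rwl(f)
  expect_length(x, 1L)
  expect_equal(x[["TRE01"]]$first_year, 1960L)
  expect_equal(x[["TRE01"]]$widths, c(0.100, 0.200, 0.300))

  # fixed-column dialect: 8-character ID abuts the year
  f2 <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c("ABCDEFGH1963   500   600   700   800   900 -9999"), f2)
  y <- read_rwl(f2)
  expect_equal(y[["ABCDEFGH"]]$first_year, 1963L)
  expect_equal(length(y[["ABCDEFGH"]]$widths), 5L)
})

test_that("read_rwl handles empty files, malformed lines and duplicates", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines(character(), f)
  expect_warning(x <- read_rwl(f), "empty")
  expect_length(x, 0L)

  writeLines(c("A 1960 100 x 999"), f)
  expect_error(read_rwl(f), "line 1")

  writeLines(c("A 1960 100 200", "A 1975 100 999"), f)
  expect_error(read_rwl(f), "starts at 1975")

  writeLines(c("A 1960 100 999", "B 1960 100 999", "A 1970 100 999"), f)
  expect_error(read_rwl(f), "duplicate series ID 'A'")
})

test_that("a trailing width of 999 units is not mistaken for a sentinel", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c("A       1961   100   200   300   400   500   600   700   800   999",
               "A       1970   150 -9999"), f)
  x <- read_rwl(f)
  expect_equal(length(x[["A"]]$widths), 10L)
  expect_equal(x[["A"]]$widths[9L], 0.999)
})

test_that("write_rwl follows the decade-line rules", {
  s <- make_rw(rep(1.0, 5), first_year = 1960)
  f <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(list(s), f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_equal(length(gregexpr("1000", lines[1L])[[1L]]), 5L)

  # mid-decade start: first line covers 1963-1969 only
  s2 <- make_rw(seq(0.5, 1.4, by = 0.1), first_year = 1963)
  write_rwl(list(s2), f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[1L], "1963")
  expect_match(lines[2L], "1970")
  expect_equal(length(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]) - 2L,
               7L)

  expect_error(write_rwl(list(make_rw(c(1, 10.5))), f), "overflow")
})

test_that("write_rwl / read_rwl round-trips random collections exactly", {
  set.seed(42)
  series <- lapply(1:50, function(i) {
    n <- sample(15:80, 1)
    w <- round(runif(n, 0.02, 6), 3)
    w[runif(n) < 0.03] <- 0            # missing rings
    if (all(w == 0)) w[1] <- 0.5
    make_rw(w, first_year = sample(1880:1960, 1), id = sprintf("SER%02d", i))
  })
  f <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(series, f)
  back <- read_rwl(f)
  expect_equal(length(back), 50L)
  for (s in series) {
    expect_equal(back[[s$tree_id]]$first_year, s$first_year)
    expect_equal(back[[s$tree_id]]$widths, s$widths, tolerance = 1e-12)
  }
})

test_that("climate CSV reader validates and round-trips", {
  d <- expand.grid(year = 1961:2000, month = 1:12)
  set.seed(1)
  rows <- rbind(
    data.frame(location_id = "L1", variable = "scPDSI", d,
               value = rnorm(nrow(d))),
    data.frame(location_id = "L2", variable = "scPDSI", d,
               value = rnorm(nrow(d))))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  cl <- read_climate_csv(f)
  expect_length(cl, 2L)
  expect_equal(dim(cl[["L1.scPDSI"]]$monthly_values), c(40L, 12L))

  # missing-value code flags the cell rather than zeroing it
  rows2 <- rows
  rows2$value[rows2$location_id == "L1" & rows2$year == 1969 &
                rows2$month == 5] <- -9999
  write.csv(rows2, f, row.names = FALSE)
  cl2 <- read_climate_csv(f)
  expect_true(is.na(cl2[["L1.scPDSI"]]$monthly_values[1969 - 1961 + 1, 5]))

  # writer round-trip
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(cl, f2)
  cl3 <- read_climate_csv(f2)
  expect_equal(cl3[["L2.scPDSI"]]$monthly_values,
               cl[["L2.scPDSI"]]$monthly_values)

  # validation errors
  bad <- rows; bad$month[1] <- 13
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_climate_csv(f), "month")
  dup <- rbind(rows, rows[1, ])
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_climate_csv(f), "duplicate")
})

test_that("nearest_gridpoint matches an exhaustive great-circle scan", {
  grid <- list()
  for (lat in seq(28, 38, by = 0.5)) for (lon in seq(90, 101, by = 0.5))
    grid[[length(grid) + 1L]] <-
      site_location(sprintf("G%.1f_%.1f", lat, lon), lat, lon)
  # coincident node
  expect_equal(nearest_gridpoint(site_location("s", 30, 95), grid),
               "G30.0_95.0")
  # equidistant tie broken lexicographically
  two <- list(site_location("B", 30, 95), site_location("A", 30, 96))
  expect_equal(nearest_gridpoint(site_location("s", 30, 95.5), two), "A")
  expect_error(nearest_gridpoint(site_location("s", 30, 95), list()), "empty")

  set.seed(7)
  glat <- vapply(grid, `[[`, 0, "latitude")
  glon <- vapply(grid, `[[`, 0, "longitude")
  gid <- vapply(grid, `[[`, "", "site_id")
  for (i in 1:100) {
    s <- site_location("s", runif(1, 28.1, 37.9), runif(1, 90.1, 100.9))
    d <- oracle_haversine(s$latitude, s$longitude, glat, glon)
    expect_equal(nearest_gridpoint(s, grid), gid[which.min(d)])
  }
})

test_that("site table reader/writer round-trips", {
  sites <- list(site_location("S1", 30.2, 95.1, 4000),
                site_location("S2", 33.7, 98.4, 3600))
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_table(sites, f)
  back <- read_site_table(f)
  expect_equal(back[["S2"]]$longitude, 98.4)
  expect_equal(back[["S1"]]$elevation, 4000)
})
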