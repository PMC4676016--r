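test_that("generic CSV reading validates and parses headers and comments", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,10", "1,10", "2,5", "3,0"), p)
  cv <- read_dvh_table(p)
  expect_s3_class(cv, "cdvh")
  expect_equal(cv$total_volume, 10)
  expect_equal(cv$dose, 0:3)

  writeLines(c("0,5", "1,7"), p)
  expect_error(read_dvh_table(p), "monotone")

  writeLines(c("# a comment", "Dose[Gy],Volume[cc]", "0,4.2", "60,0"), p)
  expect_equal(read_dvh_table(p)$total_volume, 4.2)

  writeLines(c("# only comments"), p)
  expect_error(read_dvh_table(p), "empty")
  writeLines(c("2,10", "3,abc"), p)
  expect_error(read_dvh_table(p), "non-numeric")
  expect_error(read_dvh_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("a scale comment round-trips through write_dvh_csv", {
  p <- withr::local_tempfile(fileext = ".csv")
  cv <- cdvh(c(0, 0.5, 1.0), c(10, 6, 0), structure = "GTV",
             scale = "relative")
  write_dvh_csv(cv, p)
  back <- read_dvh_table(p)
  expect_equal(back$scale, "relative")
  expect_equal(back$dose, cv$dose)
  expect_equal(back$volume, cv$volume)
})

test_that("export-text dialect parses blocks and relative volumes", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Structure: GTV",
    "Total Volume: 4.0 cc",
    "0.0   100.0 %",
    "30.0  50.0 %",
    "60.0  0.0 %",
    "Structure: Lung",
    "Total Volume: 3000 cc",
    "0.0   3000",
    "20.0  300",
    "40.0  0"
  ), p)
  gtv <- read_dvh_table(p, dialect = "export_text", structure = "GTV")
  expect_equal(gtv$total_volume, 4)
  expect_equal(gtv$volume, c(4, 2, 0))
  lung <- read_dvh_table(p, dialect = "export_text", structure = "Lung")
  expect_equal(lung$volume, c(3000, 300, 0))
  expect_error(read_dvh_table(p, dialect = "export_text", structure = "CW"),
               "not found")
})

test_that("the shipped example files parse", {
  csv <- system.file("extdata", "example_gtv_dvh.csv", package = "sbrtfx")
  cv <- read_dvh_table(csv)
  expect_equal(cv$total_volume, 4.9)
  expect_equal(cv$scale, "physical")
  expect_equal(max(cv$dose), 60)
  txt <- system.file("extdata", "example_export.txt", package = "sbrtfx")
  lung <- read_dvh_table(txt, dialect = "export_text", structure = "Lung")
  expect_equal(lung$total_volume, 3200)
  gtv <- read_dvh_table(txt, dialect = "export_text")
  expect_equal(gtv$volume[1L], 4.9)  # percent column converted
})

test_that("cumulative validation rejects malformed tables", {
  expect_error(cdvh(c(0, 1), c(5, 7)), "monotone")
  expect_error(cdvh(c(0, 0), c(5, 5)), "increasing")
  expect_error(cdvh(c(0, 1), c(5, -1)), "negative")
  expect_error(cdvh(numeric(0), numeric(0)), "empty")
})

test_that("resampling interpolates linearly and preserves the total", {
  cv <- cdvh(c(0, 2), c(10, 0))
  rs <- resample_cumulative(cv, 1)
  expect_equal(rs$dose, c(0, 1, 2))
  expect_equal(rs$volume, c(10, 5, 0))

  cv2 <- cdvh(c(0, 1, 2), c(8, 8, 0))
  rs2 <- resample_cumulative(cv2, 0.5)
  expect_equal(rs2$volume[rs2$dose == 1.5], 4)
  expect_equal(rs2$total_volume, 8)

  # identity at the original width
  rs3 <- resample_cumulative(cv2, 1)
  expect_equal(rs3$dose, cv2$dose)
  expect_equal(rs3$volume, cv2$volume)
  expect_error(resample_cumulative(cv, 0), "> 0")
})

test_that("cumulative/differential conversion follows midpoint differencing", {
  cv <- cdvh(c(0, 1, 2), c(10, 6, 0))
  dd <- cumulative_to_differential(cv)
  expect_equal(dd$dose, c(0.5, 1.5, 2))
  expect_equal(dd$volume, c(4, 6, 0))
  expect_equal(sum(dd$volume), cv$total_volume)

  # degenerate single-edge table
  one <- cumulative_to_differential(cdvh(0, 7))
  expect_equal(one$dose, 0)
  expect_equal(one$volume, 7)

  back <- differential_to_cumulative(dd, edges = cv$dose)
  expect_equal(back$volume, cv$volume)
})

test_that("differential-to-cumulative sums volume at or above each edge", {
  dd <- ddvh(c(0.5, 1.5), c(4, 6))
  cv <- differential_to_cumulative(dd, edges = c(0, 1))
  expect_equal(cv$volume[cv$dose == 1], 6)
  expect_equal(cv$volume[cv$dose == 0], dd$total_volume)

  cold <- ddvh(0, 12)
  expect_equal(
    differential_to_cumulative(cold, edges = c(0, 1e-6))$volume, c(12, 0)
  )
})

test_that("mean dose is the volume-weighted bin average", {
  expect_equal(mean_dose(ddvh(20, 33)), 20)
  expect_equal(mean_dose(ddvh(c(0, 10), c(5, 5))), 5)
  expect_equal(mean_dose(ddvh(c(2, 4), c(1, 3))), 3.5)
  expect_error(mean_dose(ddvh(c(1, 2), c(0, 0))), "zero total volume")
})

test_that("hottest subvolume selects high-dose bins with boundary split", {
  expect_equal(hottest_subvolume(ddvh(30, 150), 100)$volume, 100)
  hot <- hottest_subvolume(ddvh(c(10, 30), c(80, 60)), 100)
  expect_equal(hot$dose, c(30, 10))
  expect_equal(hot$volume, c(60, 40))
  small <- ddvh(c(5, 10), c(20, 30))
  expect_identical(hottest_subvolume(small, 100), small)
  expect_error(hottest_subvolume(small, -1), "> 0")
})

test_that("conversions conserve volume and mean dose under resampling", {
  set.seed(41)
  for (i in 1:25) {
    cv <- random_cdvh(n_edges = sample(5:60, 1),
                      max_dose = stats::runif(1, 10, 90))
    dd <- cumulative_to_differential(cv)
    expect_equal(sum(dd$volume), cv$total_volume,
                 tolerance = 1e-12)
    bw <- stats::runif(1, 0.2, 2)
    rs <- resample_cumulative(cv, bw)
    m0 <- mean_dose(dd)
    m1 <- mean_dose(cumulative_to_differential(rs))
    expect_lt(abs(m0 - m1), bw)
    cap <- stats::runif(1, 1, 2 * cv$total_volume)
    hot <- hottest_subvolume(dd, cap)
    expect_equal(hot$total_volume, min(cap, dd$total_volume))
  }
})
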