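test_that("logarithmic grids have geometric edges with exact endpoints", {
  g <- log_diameter_grid()
  expect_length(g$edges, 81L)
  ratios <- g$edges[-1] / g$edges[-81]
  expect_lt(diff(range(ratios)) / ratios[1], 1e-9)
  expect_equal(ratios[1], (240 / 20)^(1 / 80))
  expect_identical(c(g$edges[1], g$edges[81]), c(20, 240))

  expect_equal(log_diameter_grid(1, 20, 240)$edges, c(20, 240))
  expect_equal(log_diameter_grid(4, 10, 160)$edges, c(10, 20, 40, 80, 160))
  expect_error(log_diameter_grid(4, 100, 50), "d_min < d_max")
  expect_error(log_diameter_grid(0), "positive integer")
})

test_that("count normalisation is proportional and rejects degenerate input", {
  expect_equal(normalize_to_percent(c(1, 1, 2)), c(25, 25, 50))
  expect_equal(normalize_to_percent(c(6000, 0, 0)), c(100, 0, 0))
  expect_error(normalize_to_percent(c(0, 0)), "all-zero")
})

test_that("mean distribution averages replicates within days, then days equally", {
  v <- rbind(c(60, 40), c(60, 40), c(60, 40))
  d1 <- manual_dataset(c(0L, 5L, 9L), v, grid = log_diameter_grid(2))
  expect_equal(mean_distribution(d1), c(60, 40))

  d2 <- manual_dataset(c(0L, 7L), rbind(c(100, 0), c(0, 100)),
                       grid = log_diameter_grid(2))
  expect_equal(mean_distribution(d2), c(50, 50))

  # unbalanced replicates: day 0 has 2 replicates, day 3 has 1; oracle is
  # the brute-force two-stage average
  v3 <- rbind(c(80, 20), c(60, 40), c(10, 90))
  d3 <- manual_dataset(c(0L, 0L, 3L), v3, replicates = c(1L, 2L, 1L),
                       grid = log_diameter_grid(2))
  oracle <- (colMeans(v3[1:2, ]) + v3[3, ]) / 2
  expect_equal(mean_distribution(d3), oracle)
})

test_that("fractional differences are elementwise (day - mean) / mean", {
  m <- c(20, 80)
  expect_equal(fractional_difference(m, m), c(0, 0))
  expect_equal(fractional_difference(c(30, 70), m), c(0.5, -0.125))
  expect_error(fractional_difference(1:3, 1:2), "equal length")

  set.seed(4)
  day <- as.numeric(normalize_to_percent(runif(10)))
  mn <- as.numeric(normalize_to_percent(runif(10)))
  expect_equal(fractional_difference(day, mn),
               vapply(1:10, function(i) (day[i] - mn[i]) / mn[i], numeric(1)))
})

test_that("dataset CSV round-trips and reports format errors", {
  sim <- quick_sim(11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cellsize_csv(sim$dataset, path)
  back <- read_cellsize_csv(path)
  expect_equal(back$values, sim$dataset$values, tolerance = 1e-9)
  expect_identical(back$day, sim$dataset$day)
  expect_identical(back$days, sim$dataset$days)

  # wrong number of bin columns
  lines <- readLines(path)
  lines[1] <- "# grid: n=7 dmin=20 dmax=240"
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path2)
  expect_error(read_cellsize_csv(path2), "bin_\\* columns")

  # rows out of day order are sorted on load, values preserved
  df <- utils::read.csv(path, skip = 1)
  df <- df[rev(seq_len(nrow(df))), ]
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines0 <- readLines(path, n = 1), path3)
  suppressWarnings(utils::write.table(df, path3, sep = ",", row.names = FALSE,
                                      col.names = TRUE, append = TRUE, quote = FALSE))
  back3 <- read_cellsize_csv(path3)
  expect_false(is.unsorted(back3$day))
  expect_equal(sort(rowSums(back3$values)), sort(rowSums(sim$dataset$values)),
               tolerance = 1e-9)
})

test_that("heat-map matrix has one replicate-averaged row per day", {
  sim <- quick_sim(12)
  m <- heatmap_matrix(sim$dataset)
  expect_identical(dim(m), c(16L, 6L))
  expect_identical(rownames(m), as.character(sim$dataset$days))

  d <- sim$dataset
  day1 <- d$days[5]
  expect_equal(unname(m[5, ]),
               unname(colMeans(d$values[d$day == day1, , drop = FALSE])))

  one <- manual_dataset(0L, matrix(c(50, 50), 1), grid = log_diameter_grid(2))
  expect_identical(dim(heatmap_matrix(one)), c(1L, 2L))
})

test_that("stored measurements always satisfy the percentage constraint", {
  sim <- quick_sim(13)
  expect_true(all(abs(rowSums(sim$dataset$values) - 100) < 1e-6))
  expect_true(all(sim$dataset$values >= 0))
  bad <- matrix(c(50, 49), 1)
  expect_error(manual_dataset(0L, bad, grid = log_diameter_grid(2)), "sum to 100")
})
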