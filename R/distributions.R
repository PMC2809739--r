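#' Longitudinal cell-size dataset
#'
#' Bundles replicate cell-size distribution measurements from repeated
#' biopsies of one animal. Each measurement is a percentage histogram over
#' the bins of a [log_diameter_grid()]; rows are replicate measurements, so
#' a biopsy day typically contributes several rows.
#'
#' @param day Integer vector, biopsy day of each measurement (days since the
#'   first biopsy; the first biopsy day must be 0).
#' @param replicate Vector identifying the replicate within each day.
#' @param values Numeric matrix, one row per measurement, `grid$n_bins`
#'   columns of percentages summing to 100 per row.
#' @param grid A [log_diameter_grid()].
#' @param animal_id Identifier for the animal.
#' @return An object of class `"cellsize_dataset"`: list with elements
#'   `animal_id`, `grid`, `day`, `replicate`, `values`, and `days` (sorted
#'   unique biopsy days).
#' @export
cellsize_dataset <- function(day, replicate, values, grid, animal_id = "animal") {
  stopifnot(inherits(grid, "diameter_grid"))
  values <- as.matrix(values)
  day <- as.integer(day)
  if (length(day) != nrow(values) || length(replicate) != nrow(values))
    stop("`day`, `replicate` and rows of `values` must have equal length", call. = FALSE)
  if (nrow(values) == 0L) stop("dataset must contain at least one measurement", call. = FALSE)
  if (ncol(values) != grid$n_bins)
    stop(sprintf("`values` has %d columns but the grid has %d bins",
                 ncol(values), grid$n_bins), call. = FALSE)
  if (any(values < 0)) stop("percentages must be non-negative", call. = FALSE)
  bad <- which(abs(rowSums(values) - 100) > 1e-6)
  if (length(bad))
    stop(sprintf("row %d does not sum to 100 (got %.9g)", bad[1], rowSums(values)[bad[1]]),
         call. = FALSE)
  if (min(day) != 0L)
    stop("the first biopsy day must be day 0", call. = FALSE)
  ord <- order(day, as.character(replicate))
  structure(
    list(animal_id = animal_id, grid = grid,
         day = day[ord], replicate = replicate[ord],
         values = values[ord, , drop = FALSE],
         days = sort(unique(day))),
    class = "cellsize_dataset"
  )
}

#' @export
print.cellsize_dataset <- function(x, ...) {
  cat(sprintf("<cellsize_dataset> '%s': %d measurements on %d days (day %d-%d), %d diameter bins\n",
              x$animal_id, nrow(x$values), length(x$days),
              min(x$days), max(x$days), x$grid$n_bins))
  invisible(x)
}

#' Convert raw particle counts to percentages
#'
#' @param counts Non-negative numeric vector with at least one positive entry.
#' @return Vector proportional to `counts` summing to 100.
#' @export
normalize_to_percent <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  s <- sum(counts)
  if (s <= 0) stop("cannot normalize an all-zero count vector", call. = FALSE)
  100 * counts / s
}

#' Mean cell-size distribution of a dataset
#'
#' Replicates are averaged within each biopsy day first, then the per-day
#' means are averaged with equal weight per day, so days with fewer
#' replicate measurements are not down-weighted.
#'
#' @param dataset A [cellsize_dataset()].
#' @return Numeric vector of per-bin mean percentages (sums to 100).
#' @export
mean_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "cellsize_dataset"))
  colMeans(day_means(dataset))
}

# per-day replicate-averaged matrix, rows ordered by ascending day
day_means <- function(dataset) {
  m <- vapply(dataset$days, function(d) {
    colMeans(dataset$values[dataset$day == d, , drop = FALSE])
  }, numeric(dataset$grid$n_bins))
  t(m)
}

#' Fractional difference of a distribution from the mean
#'
#' Computes `(day - mean) / mean` elementwise: the relative excess or
#' deficit of cells in each diameter bin on a given day compared with the
#' time-averaged distribution. Bins where the mean is zero yield `NaN`.
#'
#' @param day_values Percentage vector for one day.
#' @param mean_values Mean percentage vector (same length).
#' @return Dimensionless vector of fractional differences.
#' @export
fractional_difference <- function(day_values, mean_values) {
  if (length(day_values) != length(mean_values))
    stop("`day_values` and `mean_values` must have equal length", call. = FALSE)
  out <- (day_values - mean_values) / mean_values
  out[mean_values == 0 & day_values == mean_values] <- NaN
  out
}

#' Per-day mean matrix for heat-map display
#'
#' One row per biopsy day (ascending), one column per diameter bin; entries
#' are replicate-averaged percentages. Missing days are simply absent --
#' the gaps are the irregular biopsy schedule itself.
#'
#' @param dataset A [cellsize_dataset()].
#' @return Numeric matrix with day row names and bin-centre column names.
#' @export
heatmap_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "cellsize_dataset"))
  m <- day_means(dataset)
  rownames(m) <- dataset$days
  colnames(m) <- sprintf("%.2f", bin_centers(dataset$grid))
  m
}

#' Read / write a longitudinal dataset as CSV
#'
#' The CSV dialect is: an optional first comment line
#' `# grid: n=<bins> dmin=<um> dmax=<um>` fixing the diameter grid, then a
#' header `animal_id,day,replicate,bin_001,...`, then one row per replicate
#' measurement with percentage values. `write_cellsize_csv()` followed by
#' `read_cellsize_csv()` reproduces the dataset to within 1e-9.
#'
#' @param path File path.
#' @param grid Grid to assume when the file has no grid comment line.
#' @return `read_cellsize_csv()` returns a [cellsize_dataset()];
#'   `write_cellsize_csv()` returns `path` invisibly.
#' @export
read_cellsize_csv <- function(path, grid = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("n=([0-9]+) +dmin=([0-9.eE+-]+) +dmax=([0-9.eE+-]+)", first))[[1]]
    if (length(m) != 4L)
      stop("malformed grid comment line: ", first, call. = FALSE)
    grid <- log_diameter_grid(as.integer(m[2]), as.numeric(m[3]), as.numeric(m[4]))
    skip <- 1L
  }
  if (is.null(grid)) grid <- log_diameter_grid()
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  need <- c("animal_id", "day", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  vcols <- grep("^bin_[0-9]+$", names(df))
  if (length(vcols) != grid$n_bins)
    stop(sprintf("file has %d bin_* columns but the grid has %d bins",
                 length(vcols), grid$n_bins), call. = FALSE)
  vals <- as.matrix(df[, vcols])
  dimnames(vals) <- NULL
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[, vcols], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column '%s'", names(df)[vcols[bad]]), call. = FALSE)
  }
  cellsize_dataset(df$day, df$replicate, vals, grid, animal_id = df$animal_id[1])
}

#' @rdname read_cellsize_csv
#' @param dataset A [cellsize_dataset()] to write.
#' @export
write_cellsize_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cellsize_dataset"))
  g <- dataset$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid: n=%d dmin=%.10g dmax=%.10g", g$n_bins, g$d_min, g$d_max), con)
  df <- data.frame(animal_id = dataset$animal_id, day = dataset$day,
                   replicate = dataset$replicate, check.names = FALSE)
  vals <- dataset$values
  colnames(vals) <- sprintf("bin_%03d", seq_len(g$n_bins))
  utils::write.csv(cbind(df, as.data.frame(vals)), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
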