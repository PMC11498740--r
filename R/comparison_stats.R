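#' Replicate measurement series
#'
#' One cell of a technique-comparison experiment: the replicate values of
#' one inter-landmark distance, measured on one specimen with one
#' technique by one operator.
#'
#' @param specimen,distance_label,technique,operator identifier strings.
#' @param values replicate distances in mm (non-empty, all > 0).
#' @return an object of class `orbi_series`.
#' @export
measurement_series <- function(specimen, distance_label, technique, operator,
                               values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)) || any(values <= 0))
    orbi_stop("schema", "series values must be non-empty, finite and > 0")
  structure(list(specimen = specimen, distance_label = distance_label,
                 technique = technique, operator = operator, values = values),
            class = "orbi_series")
}

series_keys_match <- function(a, b, fields) {
  all(vapply(fields, function(f) identical(a[[f]], b[[f]]), logical(1)))
}

#' Percent difference of a technique to the reference technique
#'
#' `100 * (mean(series) - mean(reference)) / mean(reference)` — the
#' signed percent deviation of a technique's average from the reference
#' standard's (e.g. micro-CT) average, for the same specimen and
#' distance.
#'
#' @param series,reference [measurement_series()] objects sharing
#'   specimen and distance label.
#' @return signed percent difference.
#' @section Errors: `mismatched_keys` if specimen or distance label
#'   differ.
#' @export
pct_diff_to_reference <- function(series, reference) {
  stopifnot(inherits(series, "orbi_series"), inherits(reference, "orbi_series"))
  if (!series_keys_match(series, reference, c("specimen", "distance_label")))
    orbi_stop("mismatched_keys",
              "series and reference must share specimen and distance_label")
  100 * (mean(series$values) - mean(reference$values)) / mean(reference$values)
}

#' Percent difference between the two operators
#'
#' `100 * (mean(a) - mean(b)) / mean(b)` for the same specimen, distance
#' and technique measured by two different operators — the
#' inter-operator variability of a technique.
#'
#' @param a,b [measurement_series()] objects differing only in operator.
#' @return signed percent difference of operator `a` relative to `b`.
#' @section Errors: `mismatched_keys`.
#' @export
interoperator_diff <- function(a, b) {
  stopifnot(inherits(a, "orbi_series"), inherits(b, "orbi_series"))
  if (!series_keys_match(a, b, c("specimen", "distance_label", "technique")) ||
      identical(a$operator, b$operator))
    orbi_stop("mismatched_keys",
              "series must share specimen, distance and technique and differ in operator")
  100 * (mean(a$values) - mean(b$values)) / mean(b$values)
}

#' Range dispersion of pooled measurements
#'
#' `100 * (max - min) / mean` over the pooled replicate values of one
#' technique (both operators together): a simple spread statistic on the
#' percent scale, invariant under permutation and under uniform scaling
#' of the values.
#'
#' @param values pooled replicate values in mm (>= 2).
#' @return dispersion in percent (>= 0).
#' @section Errors: `too_few_values`.
#' @export
dispersion <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    orbi_stop("too_few_values", "dispersion needs at least 2 values")
  100 * (max(values) - min(values)) / mean(values)
}

# ---- tidy measurement tables -------------------------------------------

measurement_columns <- c("specimen", "distance_label", "technique",
                         "operator", "replicate", "value_mm")

#' Read a replicate-measurement CSV
#'
#' Expected columns: `specimen, distance_label, technique, operator,
#' replicate, value_mm`. The package ships fixture tables of this form
#' under `inst/extdata` (see [orbimetry_example()]).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_measurements_csv <- function(path) {
  m <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) orbi_stop("parse", conditionMessage(e)))
  miss <- setdiff(measurement_columns, names(m))
  if (length(miss))
    orbi_stop("parse", paste("measurement CSV missing column(s):",
                             paste(miss, collapse = ", ")))
  if (any(!is.finite(m$value_mm)) || any(m$value_mm <= 0))
    orbi_stop("schema", "value_mm must be finite and > 0")
  m[measurement_columns]
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return full path (or a character vector of file names).
#' @export
orbimetry_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "orbimetry")))
  path <- system.file("extdata", file, package = "orbimetry")
  if (!nzchar(path)) orbi_stop("parse", sprintf("no packaged file '%s'", file))
  path
}

get_series <- function(m, specimen, distance_label, technique, operator) {
  sub <- m[m$specimen == specimen & m$distance_label == distance_label &
             m$technique == technique & m$operator == operator, ]
  if (!nrow(sub))
    orbi_stop("mismatched_keys",
              sprintf("no measurements for (%s, %s, %s, operator %s)",
                      specimen, distance_label, technique, operator))
  measurement_series(specimen, distance_label, technique, operator,
                     sub$value_mm[order(sub$replicate)])
}

#' Per-distance comparison table
#'
#' Reproduces the layout of the per-specimen measurement tables: for
#' every (specimen, distance, technique) it reports each operator's
#' average and signed percent difference to the reference technique, the
#' inter-operator difference, and the pooled range dispersion. All
#' statistics are computed from full-precision inputs; round for display
#' with [round_half_up()].
#'
#' @param measurements data.frame as from [read_measurements_csv()].
#' @param reference technique label used as the metric standard
#'   (default `"uCT"`).
#' @param operators the two operator labels (default the sorted unique
#'   operators present).
#' @return data.frame with columns `specimen, distance_label, technique,
#'   avg_A, avg_B, diff_pct_A, diff_pct_B, interop_diff_pct,
#'   dispersion_pct` (reference rows have diff 0 by construction).
#' @export
comparison_table <- function(measurements, reference = "uCT",
                             operators = NULL) {
  m <- measurements
  if (is.null(operators)) operators <- sort(unique(m$operator))
  if (length(operators) != 2L)
    orbi_stop("schema", "comparison_table expects exactly two operators")
  keys <- unique(m[c("specimen", "distance_label", "technique")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sA <- get_series(m, k$specimen, k$distance_label, k$technique, operators[1])
    sB <- get_series(m, k$specimen, k$distance_label, k$technique, operators[2])
    rA <- get_series(m, k$specimen, k$distance_label, reference, operators[1])
    rB <- get_series(m, k$specimen, k$distance_label, reference, operators[2])
    data.frame(k,
               avg_A = mean(sA$values), avg_B = mean(sB$values),
               diff_pct_A = pct_diff_to_reference(sA, rA),
               diff_pct_B = pct_diff_to_reference(sB, rB),
               interop_diff_pct = interoperator_diff(sA, sB),
               dispersion_pct = dispersion(c(sA$values, sB$values)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average signed differences for one specimen and technique
#'
#' Per-operator arithmetic mean of the signed percent differences to the
#' reference over all of one specimen's distances, plus their grand mean
#' — the per-specimen summary of how far a technique sits from the
#' reference standard.
#'
#' @inheritParams comparison_table
#' @param specimen specimen identifier.
#' @param technique technique whose differences are averaged.
#' @return named numeric `c(avg_A, avg_B, avg_AB)` in percent.
#' @section Errors: `empty_input` if the specimen/technique has no rows.
#' @export
aggregate_differences <- function(measurements, specimen, technique,
                                  reference = "uCT", operators = NULL) {
  m <- measurements[measurements$specimen == specimen, ]
  if (!nrow(m[m$technique == technique, ]))
    orbi_stop("empty_input",
              sprintf("no measurements for specimen '%s', technique '%s'",
                      specimen, technique))
  tab <- comparison_table(m, reference = reference, operators = operators)
  tab <- tab[tab$technique == technique, ]
  a <- mean(tab$diff_pct_A); b <- mean(tab$diff_pct_B)
  c(avg_A = a, avg_B = b, avg_AB = (a + b) / 2)
}

#' Absolute average and cumulated differences of a technique
#'
#' Pools every (specimen, distance, operator) cell of one technique over
#' all specimens: `cumulated` is the sum of absolute percent differences
#' to the reference, and `absolute_average = cumulated / count`. The
#' technique with the smallest cumulated difference tracks the reference
#' standard most closely.
#'
#' @inheritParams comparison_table
#' @param technique technique to summarize.
#' @return list with `absolute_average`, `cumulated` (percent) and `n`
#'   (number of pooled cells).
#' @section Errors: `empty_input`.
#' @export
global_absolute_summary <- function(measurements, technique,
                                    reference = "uCT", operators = NULL) {
  if (!nrow(measurements[measurements$technique == technique, ]))
    orbi_stop("empty_input", sprintf("no measurements for technique '%s'", technique))
  tab <- comparison_table(measurements, reference = reference,
                          operators = operators)
  tab <- tab[tab$technique == technique, ]
  diffs <- abs(c(tab$diff_pct_A, tab$diff_pct_B))
  list(absolute_average = mean(diffs), cumulated = sum(diffs),
       n = length(diffs))
}

#' Repeatability summary of a long replicate run
#'
#' Distribution parameters for a distance measured many times with one
#' technique (typically 20 replicates, the usual scale of a geometric
#' morphometrics repeatability check): mean, sample standard deviation
#' (n-1), signed percent difference of means to a reference run, pooled
#' range dispersion, and a 95% interval `mean +/- t(0.975, n-1) * sd`
#' describing where individual repeat measurements fall.
#'
#' @param values replicate distances in mm (>= 2).
#' @param reference_values replicate distances of the reference technique
#'   for the same distance (>= 1); used only through its mean.
#' @return an object of class `orbi_repeatability`: list with `n`, `mean`,
#'   `stdev` (mm), `diff_to_reference_pct`, `dispersion_pct`, `ci95`
#'   (length-2 mm interval containing `mean`).
#' @section Errors: `too_few_values`.
#' @export
repeatability_summary <- function(values, reference_values) {
  values <- as.numeric(values)
  reference_values <- as.numeric(reference_values)
  if (length(values) < 2L)
    orbi_stop("too_few_values", "repeatability needs at least 2 values")
  if (!length(reference_values))
    orbi_stop("too_few_values", "reference_values must be non-empty")
  n <- length(values)
  m <- mean(values)
  sd <- stats::sd(values)
  half <- stats::qt(0.975, df = n - 1) * sd
  structure(list(n = n, mean = m, stdev = sd,
                 diff_to_reference_pct =
                   100 * (m - mean(reference_values)) / mean(reference_values),
                 dispersion_pct = dispersion(values),
                 ci95 = c(m - half, m + half)),
            class = "orbi_repeatability")
}

#' @export
print.orbi_repeatability <- function(x, ...) {
  cat(sprintf(
    "<repeatability> n=%d mean=%.2f mm sd=%.2f diff=%+.2f%% dispersion=%.2f%% 95%% [%.2f, %.2f]\n",
    x$n, x$mean, x$stdev, x$diff_to_reference_pct, x$dispersion_pct,
    x$ci95[1], x$ci95[2]))
  invisible(x)
}
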