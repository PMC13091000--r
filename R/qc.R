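## Group-wise IQR outlier filtering and the bilateral-validity rule.

#' Group-wise IQR outlier filter
#'
#' A value is kept iff it lies within [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with
#' quartiles computed within its own group by linear interpolation between
#' order statistics (`quantile` type 7).  Filtering is single-pass: fences
#' are computed once on the input and not re-estimated after removals.
#' Groups with fewer than 4 finite values are passed through unfiltered
#' with a warning; non-finite values are always removed and counted
#' separately.
#'
#' @param values numeric vector.
#' @param group grouping vector (same length); a single group when NULL.
#' @param k fence multiplier (1.5).
#' @return list with `keep` (logical vector) and `report` (a
#'   [FilterReport]).
#' @export
iqrFilter <- function(values, group = NULL, k = 1.5) {
  n <- length(values)
  if (is.null(group)) group <- rep("all", n)
  stopifnot(length(group) == n)
  keep <- rep(FALSE, n)
  finite <- is.finite(values)
  bounds <- list()
  for (g in unique(group)) {
    i <- which(group == g & finite)
    if (length(i) < 4L) {
      if (length(i) > 0L)
        warning("group '", g, "' has ", length(i),
                " finite values (< 4); passed through unfiltered")
      keep[i] <- TRUE
      bounds[[g]] <- data.frame(group = g, q1 = NA_real_, q3 = NA_real_,
                                iqr = NA_real_, low = -Inf, high = Inf,
                                n = length(i), n_removed = 0L)
      next
    }
    q <- stats::quantile(values[i], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
    ok <- values[i] >= lo & values[i] <= hi
    keep[i[ok]] <- TRUE
    bounds[[g]] <- data.frame(group = g, q1 = q[1], q3 = q[2], iqr = iqr,
                              low = lo, high = hi, n = length(i),
                              n_removed = sum(!ok))
  }
  bdf <- do.call(rbind, c(bounds, list(make.row.names = FALSE)))
  report <- new("FilterReport", n_input = n,
                n_removed = as.integer(sum(finite) - sum(keep)),
                n_nonfinite = as.integer(sum(!finite)), bounds = bdf)
  list(keep = keep, report = report)
}

#' Bilateral-validity rule
#'
#' A scan contributes a bilateral value only when both hemispheres
#' survived filtering; the bilateral value is the mean of the two sides.
#'
#' @param left_keep,right_keep logical masks from [iqrFilter()].
#' @param left,right the hemisphere values.
#' @return list with `keep` (both sides valid) and `bilateral` (mean where
#'   valid, NA otherwise).
#' @export
bilateralValidity <- function(left_keep, right_keep, left, right) {
  stopifnot(length(left_keep) == length(right_keep),
            length(left) == length(left_keep),
            length(right) == length(left_keep))
  keep <- left_keep & right_keep
  bil <- ifelse(keep, (left + right) / 2, NA_real_)
  list(keep = keep, bilateral = bil)
}

#' Apply the scan-level QC rules to a cohort table
#'
#' Filters `alps_left` and `alps_right` independently by the group-wise IQR
#' rule, then derives the bilateral column under the bilateral-validity
#' rule.  Returns the table with `keep_left`, `keep_right`, `keep_bilateral`
#' masks and the recomputed `alps_bilateral` (NA where invalid), plus the
#' two filter reports.
#'
#' @param table cohort data.frame with alps_left/alps_right columns.
#' @param group_var column name used for group-wise fences.
#' @param k fence multiplier.
#' @return list with `table`, `report_left`, `report_right`.
#' @export
filterAlpsTable <- function(table, group_var = "group", k = 1.5) {
  g <- table[[group_var]]
  fl <- iqrFilter(table$alps_left, g, k)
  fr <- iqrFilter(table$alps_right, g, k)
  bv <- bilateralValidity(fl$keep, fr$keep, table$alps_left,
                          table$alps_right)
  table$keep_left <- fl$keep
  table$keep_right <- fr$keep
  table$keep_bilateral <- bv$keep
  table$alps_bilateral <- bv$bilateral
  list(table = table, report_left = fl$report, report_right = fr$report)
}

#' Serialize a filter report to JSON
#'
#' @param report a [FilterReport].
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report@n_input, n_removed = report@n_removed,
         n_nonfinite = report@n_nonfinite, bounds = report@bounds),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
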