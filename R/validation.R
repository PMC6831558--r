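# Model validation: FEM gauge-site strains vs in-vivo strain-sample
# distributions. Magnitude verdicts use the boxplot envelope (median within
# Q1 - 1.5*IQR .. Q3 + 1.5*IQR) and the broader sample range; orientation
# verdicts use containment of the FEM orientation arc in the smallest
# circular arc covering the in-vivo orientations.

#' Boxplot whisker bounds of a sample
#'
#' Quartiles by linear interpolation between order statistics (the common
#' boxplot default, R quantile type 7), whiskers at `Q1 - 1.5*IQR` and
#' `Q3 + 1.5*IQR`.
#'
#' @param sample numeric vector, length >= 4 (quartiles defined).
#' @return list with `q1`, `q3`, `iqr`, `low`, `high`.
#' @export
whisker_bounds <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 4L) stop("need at least 4 samples for quartiles")
  q <- stats::quantile(sample, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  list(q1 = q[1L], q3 = q[2L], iqr = iqr,
       low = q[1L] - 1.5 * iqr, high = q[2L] + 1.5 * iqr)
}

# smallest circular arc (degrees) covering a set of angles; returns
# c(start, width), start in [0, 360), width in [0, 360]
.smallest_arc <- function(angles) {
  a <- sort(unique(angles %% 360))
  if (length(a) == 1L) return(c(start = a, width = 0))
  gaps <- diff(c(a, a[1L] + 360))
  k <- which.max(gaps)
  width <- 360 - gaps[k]
  start <- a[if (k == length(a)) 1L else k + 1L]
  c(start = start, width = width)
}

.in_arc <- function(angles, arc) {
  d <- (angles - arc[["start"]]) %% 360
  d <= arc[["width"]] + 1e-9
}

#' Validate one gauge site against in-vivo strain samples
#'
#' Compares the FEM median maximum/minimum principal strains at a gauge
#' patch against the in-vivo per-cycle sample for the same gauge:
#' \itemize{
#'   \item `within_whiskers`: FEM median inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#'     of the in-vivo sample;
#'   \item `within_range`: FEM median inside the full in-vivo min..max range;
#'   \item `orientation_within`: the smallest arc covering the FEM
#'     element-wise `e1` orientations is contained in the smallest arc
#'     covering the in-vivo orientations (circular containment).
#' }
#'
#' @param fem a [gauge_readout()] data.frame (attribute `"gauge"` names the
#'   gauge), strains in the same units as the in-vivo sample (microstrain).
#' @param invivo data.frame with columns `gauge`, `e1`, `emin`, `theta`
#'   (one row per chew cycle; `theta` in degrees).
#' @return object of class `gauge_validation`: `$magnitudes` (two rows,
#'   quantities `e1` and `emin`, with FEM median, in-vivo quartiles,
#'   whiskers, range and verdicts) and `$orientation` (FEM arc, in-vivo arc,
#'   verdict).
#' @export
validate_gauge <- function(fem, invivo) {
  gname <- attr(fem, "gauge")
  if (!is.null(gname) && "gauge" %in% names(invivo)) {
    invivo <- invivo[invivo$gauge == gname, , drop = FALSE]
    if (nrow(invivo) == 0)
      stop("in-vivo sample has no rows for gauge '", gname, "'")
  }
  if (nrow(fem) == 0 || nrow(invivo) == 0) stop("empty input")
  if (nrow(invivo) < 4L) stop("need >= 4 in-vivo cycles for quartiles")
  one <- function(quantity, fem_vals, iv_vals) {
    wb <- whisker_bounds(iv_vals)
    med <- stats::median(fem_vals)
    data.frame(gauge = if (is.null(gname)) NA_character_ else gname,
               quantity = quantity, fem_median = med,
               invivo_q1 = wb$q1, invivo_q3 = wb$q3,
               whisker_low = wb$low, whisker_high = wb$high,
               invivo_min = min(iv_vals), invivo_max = max(iv_vals),
               within_whiskers = med >= wb$low && med <= wb$high,
               within_range = med >= min(iv_vals) && med <= max(iv_vals))
  }
  mags <- rbind(one("e1", fem$e1, invivo$e1),
                one("emin", fem$e2, invivo$emin))
  fem_arc <- .smallest_arc(fem$theta_deg)
  iv_arc <- .smallest_arc(invivo$theta)
  ok <- all(.in_arc(c(fem_arc[["start"]],
                      fem_arc[["start"]] + fem_arc[["width"]]), iv_arc)) &&
    fem_arc[["width"]] <= iv_arc[["width"]] + 1e-9
  structure(list(magnitudes = mags,
                 orientation = list(fem_arc = fem_arc, invivo_arc = iv_arc,
                                    within = ok)),
            class = "gauge_validation")
}

#' @export
print.gauge_validation <- function(x, ...) {
  print(x$magnitudes, row.names = FALSE)
  o <- x$orientation
  cat(sprintf("orientation: FEM arc [%.1f, +%.1f] vs in-vivo [%.1f, +%.1f] -> %s\n",
              o$fem_arc[["start"]], o$fem_arc[["width"]],
              o$invivo_arc[["start"]], o$invivo_arc[["width"]],
              if (o$within) "within" else "outside"))
  invisible(x)
}

#' Combine gauge validations into a report table
#' @param validations list of `gauge_validation` objects.
#' @return data.frame with one row per gauge and quantity (including an
#'   `orientation` row whose verdict is in `within_range`/`within_whiskers`).
#' @export
validation_report <- function(validations) {
  rows <- lapply(validations, function(v) {
    m <- v$magnitudes
    o <- data.frame(gauge = m$gauge[1L], quantity = "orientation",
                    fem_median = NA_real_, invivo_q1 = NA_real_,
                    invivo_q3 = NA_real_, whisker_low = NA_real_,
                    whisker_high = NA_real_, invivo_min = NA_real_,
                    invivo_max = NA_real_,
                    within_whiskers = v$orientation$within,
                    within_range = v$orientation$within)
    rbind(m, o)
  })
  do.call(rbind, rows)
}

#' Read in-vivo strain samples from CSV
#'
#' Columns: `gauge`, `cycle`, `e1`, `emin`, `theta` (microstrain, degrees).
#' @param path CSV file.
#' @return data.frame.
#' @export
read_invivo <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gauge", "cycle", "e1", "emin", "theta")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("in-vivo table missing column(s): ",
                         paste(miss, collapse = ", "))
  d
}
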