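#' Published HDO vibrational observables for common water force fields
#'
#' Loads the bundled table of central frequencies (omega0, cm^-1),
#' fluctuation amplitudes (sigma, cm^-1) and spectral-diffusion times
#' (tau_c, ps) of the HDO bend, OD stretch and OH stretch for TIP3P,
#' SPC/E, TIP4P/Ew, OPC, TIP5P and the many-body reference potential
#' MB-pol, each with its 95% half-width. Useful as benchmark input and as
#' the reference scale for the mode-assignment windows.
#'
#' @return data.frame with columns `force_field`, `mode`, `metric`,
#'   `value`, `err`.
#' @export
hdo_reference_metrics <- function() {
  utils::read.csv(system.file("extdata", "hdo_ff_metrics.csv",
                              package = "hdospec", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Percent difference against a reference value
#'
#' `100 (value - reference) / reference`. Positive values mean the
#' reference potential yielded the lower number, negative that it yielded
#' the higher one.
#'
#' @param value metric from the force field under test.
#' @param reference same metric from the reference potential; non-zero.
#' @return percent difference.
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  100 * (value - reference) / reference
}

#' Propagate uncertainties into a percent difference
#'
#' First-order propagation of `p = 100 (v - r) / r` for independent `v`
#' and `r`: `100 sqrt((e_v / r)^2 + (v e_r / r^2)^2)`. The significance
#' flag is `TRUE` when the propagated interval excludes zero, the
#' numerical counterpart of an error bar that does not cross the axis.
#'
#' @param value,value_err metric and its half-width.
#' @param reference,reference_err reference metric and its half-width.
#' @return list with `percent`, `half_width`, `significant`.
#' @export
propagate_difference_uncertainty <- function(value, value_err,
                                             reference, reference_err) {
  if (any(value_err < 0) || any(reference_err < 0))
    stop("uncertainties must be non-negative")
  p <- percent_difference(value, reference)
  hw <- 100 * sqrt((value_err / reference)^2 +
                     (value * reference_err / reference^2)^2)
  list(percent = p, half_width = hw, significant = abs(p) > hw)
}

#' Benchmark force fields against a reference potential
#'
#' Takes a long metric table (one row per force field, mode and metric,
#' with 95% half-widths) and computes, for every non-reference force
#' field, the percent difference from the reference with propagated
#' uncertainty and significance flag, plus the (reference, force field)
#' value pairs used for correlation plots against the y = x line.
#'
#' @param metrics data.frame with columns `force_field`, `mode`, `metric`,
#'   `value`, `err` (as from [hdo_reference_metrics()]).
#' @param reference force-field label of the reference potential.
#'   Default `"MB-pol"`.
#' @return list of class `hdo_benchmark`: `differences` (force_field,
#'   mode, metric, value, reference_value, percent, half_width,
#'   significant) and `pairs` (force_field, mode, metric, reference_value,
#'   value).
#' @export
build_benchmark <- function(metrics, reference = "MB-pol") {
  need <- c("force_field", "mode", "metric", "value", "err")
  if (!all(need %in% names(metrics)))
    stop("metric table must have columns ", paste(need, collapse = ", "))
  if (!reference %in% metrics$force_field)
    stop("reference force field '", reference, "' not present")
  ref <- metrics[metrics$force_field == reference, ]
  ffs <- setdiff(unique(metrics$force_field), reference)
  cells <- unique(ref[, c("mode", "metric")])
  gaps <- character(0)
  rows <- list()
  for (ff in ffs) {
    m <- metrics[metrics$force_field == ff, ]
    for (i in seq_len(nrow(cells))) {
      mo <- cells$mode[i]; me <- cells$metric[i]
      mrow <- m[m$mode == mo & m$metric == me, ]
      rrow <- ref[ref$mode == mo & ref$metric == me, ]
      if (nrow(mrow) != 1L || nrow(rrow) != 1L) {
        gaps <- c(gaps, paste(ff, mo, me, sep = "/"))
        next
      }
      pr <- propagate_difference_uncertainty(mrow$value, mrow$err,
                                             rrow$value, rrow$err)
      rows[[length(rows) + 1L]] <- data.frame(
        force_field = ff, mode = mo, metric = me,
        value = mrow$value, reference_value = rrow$value,
        percent = pr$percent, half_width = pr$half_width,
        significant = pr$significant)
    }
  }
  if (length(gaps))
    stop("missing metric cells: ", paste(gaps, collapse = "; "))
  differences <- if (length(rows)) do.call(rbind, rows) else
    data.frame(force_field = character(0), mode = character(0),
               metric = character(0), value = numeric(0),
               reference_value = numeric(0), percent = numeric(0),
               half_width = numeric(0), significant = logical(0))
  pairs <- differences[, c("force_field", "mode", "metric",
                           "reference_value", "value")]
  structure(list(differences = differences, pairs = pairs,
                 reference = reference),
            class = "hdo_benchmark")
}

#' @export
print.hdo_benchmark <- function(x, ...) {
  cat(sprintf("<hdo_benchmark> %d force fields vs %s\n",
              length(unique(x$differences$force_field)), x$reference))
  d <- x$differences
  d$percent <- round(d$percent, 1)
  d$half_width <- round(d$half_width, 1)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}
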