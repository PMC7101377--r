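# Hysteresis scoring: width, loop area, and the two branch distances,
# plus the fixed logarithmic class grids used to bin them.

#' Score a bistable hysteresis loop
#'
#' For a bistable branch pair: `width = stim_on - stim_off`; `area` is the
#' trapezoidal integral of (coming-down minus going-up) response over
#' `[stim_off, stim_on]` on the linear stimulus axis; `distance_1` is the gap
#' between the branches at `stim_on` (the coming-down branch there minus the
#' going-up branch at its last pre-jump grid point); `distance_2` is the
#' coming-down output just above `stim_off` (its last pre-jump point) minus
#' the same pre-jump going-up output. The pre-jump side is used wherever a
#' branch is discontinuous at the threshold. Loops so narrow that quadrature
#' noise makes the area negative are flagged `excluded_negative_area` and
#' dropped from downstream statistics.
#'
#' @param pair a `branch_pair`.
#' @param result the [classify()] result for `pair`; must be bistable.
#' @return a `hysteresis_metrics` list: `width`, `area`, `distance_1`,
#'   `distance_2`, `stim_on`, `stim_off`, `excluded_negative_area`.
#' @export
score_hysteresis <- function(pair, result) {
  stopifnot(inherits(pair, "branch_pair"))
  if (!identical(result$label, "bistable")) {
    stop("hysteresis metrics are defined only for bistable results")
  }
  i_on <- result$idx_on
  i_off <- result$idx_off
  s <- pair$stimulus
  up_pre <- pair$up[i_on - 1L]           # lower branch just below Stim_on
  down_at_on <- pair$down[i_on]          # upper branch at Stim_on
  down_pre_off <- pair$down[i_off + 1L]  # upper branch just above Stim_off
  width <- result$stim_on - result$stim_off
  idx <- i_off:i_on
  gap <- pair$down[idx] - pair$up[idx]
  # the branches are discontinuous exactly at the thresholds: use one-sided
  # limits there (upper-branch value at stim_off, lower-branch at stim_on),
  # which makes the ideal rectangular loop exact on any grid
  gap[1] <- down_pre_off - pair$up[i_off]
  gap[length(gap)] <- pair$down[i_on] - up_pre
  area <- sum(diff(s[idx]) * (head(gap, -1) + tail(gap, -1)) / 2)
  structure(list(width = width, area = area,
                 distance_1 = down_at_on - up_pre,
                 distance_2 = down_pre_off - up_pre,
                 stim_on = result$stim_on, stim_off = result$stim_off,
                 excluded_negative_area = area < 0),
            class = "hysteresis_metrics")
}

#' @export
print.hysteresis_metrics <- function(x, ...) {
  cat("<hysteresis_metrics> width = ", format(x$width),
      ", area = ", format(x$area),
      ", distance_1 = ", format(x$distance_1),
      ", distance_2 = ", format(x$distance_2),
      if (x$excluded_negative_area) "  [excluded: negative area]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Class edges for the hysteresis metrics
#'
#' The fixed logarithmic grids used to bin each metric: decade bins
#' `1e-6`-`1e1` for the width (7 classes) and `1e-8`-`1e1` for the area
#' (9 classes); half-decade splits `1e-3`-`1` for `distance_1` (6 classes)
#' and `1e-4`-`1` for `distance_2` (7 classes, the top decade unsplit since
#' the response cannot exceed 1).
#'
#' @param metric one of `"width"`, `"area"`, `"distance_1"`, `"distance_2"`.
#' @return numeric vector of class edges.
#' @export
metric_class_edges <- function(metric = c("width", "area", "distance_1", "distance_2")) {
  metric <- match.arg(metric)
  half_split <- function(lo_exp, hi_exp) {
    e <- lo_exp:(hi_exp - 1)
    sort(unique(c(10^e, 0.5 * 10^(e + 1), 10^hi_exp)))
  }
  switch(metric,
         width = 10^(-6:1),
         area = 10^(-8:1),
         distance_1 = half_split(-3, 0),
         distance_2 = c(head(half_split(-4, 0), -2), 1))
}

#' Histogram of metric values over logarithmic classes
#'
#' @param values positive metric values.
#' @param metric metric name (sets the class edges) or `NULL` when `edges`
#'   are supplied directly.
#' @param edges explicit class edges (overrides `metric`).
#' @return data.frame with `lower`, `upper`, `count`, plus attributes
#'   `underflow` and `overflow` (counts outside the class range).
#' @export
bin_metric <- function(values, metric = NULL, edges = NULL) {
  if (is.null(edges)) edges <- metric_class_edges(metric)
  stopifnot(length(values) == 0 || all(values > 0 | is.na(values)))
  values <- values[!is.na(values)]
  counts <- if (length(values)) {
    tabulate(findInterval(values, edges, rightmost.closed = TRUE),
             nbins = length(edges))
  } else integer(length(edges))
  under <- sum(values < edges[1])
  over <- sum(values > edges[length(edges)])
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    count = counts[seq_len(length(edges) - 1)] )
  attr(out, "underflow") <- under
  attr(out, "overflow") <- over
  out
}
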