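# Enrichment (hypergeometric) and parameter-influence (Mann-Whitney U)
# statistics over sweep results.

#' Hypergeometric enrichment test per parameter class
#'
#' Bins the sampled values of one parameter into logarithmic classes and asks,
#' for each class, whether bistable outcomes are over-represented: with `N`
#' sampled values, `M` of them bistable, `y_i` values in class `i` of which
#' `x_i` bistable, the p-value is the upper-tail hypergeometric probability
#' of observing at least `x_i` bistable values in the class under random
#' assignment. A class is enriched when `p_i < alpha` (default `1e-4`). No
#' further multiple-testing correction is applied beyond this fixed
#' threshold.
#'
#' @param sample_values sampled values of the parameter (length `N`).
#' @param bistable_mask logical, same length: bistable outcome per sample.
#' @param class_edges increasing positive bin edges covering the values.
#' @param alpha enrichment threshold on the p-value.
#' @return an `enrichment_result` data.frame with one row per class:
#'   `lower`, `upper`, `y` (class total), `x` (bistable in class),
#'   `fraction` (`x/y`, 0 with `empty_class = TRUE` when `y = 0`),
#'   `p_value`, `enriched`.
#' @export
enrichment_test <- function(sample_values, bistable_mask, class_edges,
                            alpha = 1e-4) {
  stopifnot(length(sample_values) == length(bistable_mask))
  N <- length(sample_values)
  M <- sum(bistable_mask)
  cls <- findInterval(sample_values, class_edges, rightmost.closed = TRUE)
  nb <- length(class_edges) - 1L
  if (any(cls < 1 | cls > nb)) {
    stop("class_edges must cover the sampled range")
  }
  y <- tabulate(cls, nbins = nb)
  x <- tabulate(cls[bistable_mask], nbins = nb)
  p <- vapply(seq_len(nb), function(i) {
    if (y[i] == 0) return(1)
    # P(n >= x_i) drawing M from N with y_i in the class
    stats::phyper(x[i] - 1L, y[i], N - y[i], M, lower.tail = FALSE)
  }, numeric(1))
  out <- data.frame(lower = class_edges[-length(class_edges)],
                    upper = class_edges[-1],
                    y = y, x = x,
                    fraction = ifelse(y > 0, x / y, 0),
                    empty_class = y == 0,
                    p_value = p,
                    enriched = p < alpha)
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "N") <- N
  attr(out, "M") <- M
  out
}

#' Mann-Whitney U statistic with a signed z-value
#'
#' Two-sided Mann-Whitney U test with normal approximation, continuity
#' correction, and tie correction. The sign of `z` is positive when the
#' positive group tends to larger values.
#'
#' @param positive,negative numeric samples for the two groups.
#' @return list with `U` (for the positive group), `z`, `p_value`, `n1`, `n2`.
#' @export
mann_whitney_z <- function(positive, negative) {
  n1 <- length(positive); n2 <- length(negative)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(positive, negative))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p_value = 1, n1 = n1, n2 = n2))
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(sigma2)
  list(U = U, z = z, p_value = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
}

#' Rank parameters by their influence on a binary outcome
#'
#' For each parameter, splits its sampled values into the positive group
#' (outcome true, e.g. bistable) and the negative group and computes the
#' Mann-Whitney z-value; parameters are returned sorted by `|z|` descending,
#' the ordering used to read off which parameters control the outcome.
#'
#' @param parameter_values data.frame or matrix, one column per parameter,
#'   one row per sampled point.
#' @param group_mask logical vector defining the positive group.
#' @return data.frame with `parameter`, `z`, `p_value`, `rank`.
#' @export
influence_rank <- function(parameter_values, group_mask) {
  parameter_values <- as.data.frame(parameter_values)
  stopifnot(nrow(parameter_values) == length(group_mask))
  if (!any(group_mask) || all(group_mask)) {
    stop("group_mask must define two nonempty groups")
  }
  rows <- lapply(names(parameter_values), function(nm) {
    v <- parameter_values[[nm]]
    mw <- mann_whitney_z(v[group_mask], v[!group_mask])
    data.frame(parameter = nm, z = mw$z, p_value = mw$p_value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$z)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
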