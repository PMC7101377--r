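# End-to-end runs: sweep a sampled parameter space, persist one record per
# point, and analyze the results table (fractions per class, enrichment,
# influence rankings). Results are plain delimited text plus a JSON summary,
# so runs are comparable across machines and versions.

sweep_record_schema <- function() {
  c("sample_index", "label", "passed_response_floor", "converged_fraction",
    "stim_on", "stim_off", "width", "area", "distance_1", "distance_2",
    "excluded_negative_area", "one_way")
}

#' Sweep a sampled parameter space
#'
#' Draws a Latin hypercube sample and runs the going-up/coming-down analysis
#' on every point. Individual failures never abort the sweep: a point whose
#' relaxations fail is recorded as flagged with its convergence fraction.
#'
#' @param model a `reaction_network` or model name.
#' @param n_samples,seed,ranges sampling design (see
#'   [default_sampling_plan()]); `ranges` may restrict individual parameters.
#' @param points_per_decade,stimulus_range sweep grid controls.
#' @param rescan_flagged re-scan flagged cases once on a widened range.
#' @param progress_every print a progress line every so many points (0 = off).
#' @return a `sweep_results` data.frame: one row per sampled point with the
#'   parameter values and the record fields (label, thresholds, hysteresis
#'   metrics), plus a `summary` attribute.
#' @export
run_sweep <- function(model, n_samples = 5000, seed = 1, ranges = NULL,
                      points_per_decade = 10, stimulus_range = NULL,
                      rescan_flagged = FALSE, progress_every = 0) {
  if (is.character(model)) model <- build_model(model)
  plan <- if (is.null(ranges)) {
    default_sampling_plan(model, n_samples = n_samples, seed = seed)
  } else {
    full <- default_sampling_plan(model, n_samples = n_samples, seed = seed)$ranges
    full[names(ranges)] <- ranges
    sampling_plan(full, n_samples, seed)
  }
  X <- lhs_sample(plan)
  sv <- if (is.null(stimulus_range)) {
    rg <- default_stimulus_range(model)
    stimulus_grid(rg[1], rg[2], points_per_decade)
  } else {
    stimulus_grid(stimulus_range[1], stimulus_range[2], points_per_decade)
  }
  rec <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    p <- unlist(X[i, ])
    out <- tryCatch(
      scan_parameter_set(model, p, rescan_flagged = rescan_flagged,
                         stimulus_vector = sv),
      error = function(e) NULL)
    rec[[i]] <- if (is.null(out)) {
      data.frame(sample_index = i, label = "flagged",
                 passed_response_floor = NA, converged_fraction = 0,
                 stim_on = NA_real_, stim_off = NA_real_, width = NA_real_,
                 area = NA_real_, distance_1 = NA_real_,
                 distance_2 = NA_real_, excluded_negative_area = NA,
                 one_way = NA)
    } else {
      r <- out$result; mt <- out$metrics
      data.frame(sample_index = i, label = r$label,
                 passed_response_floor = r$passed_response_floor,
                 converged_fraction = r$converged_fraction,
                 stim_on = r$stim_on, stim_off = r$stim_off,
                 width = if (is.null(mt)) NA_real_ else mt$width,
                 area = if (is.null(mt)) NA_real_ else mt$area,
                 distance_1 = if (is.null(mt)) NA_real_ else mt$distance_1,
                 distance_2 = if (is.null(mt)) NA_real_ else mt$distance_2,
                 excluded_negative_area =
                   if (is.null(mt)) NA else mt$excluded_negative_area,
                 one_way = out$one_way)
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message(sprintf("[run_sweep] %d/%d points", i, nrow(X)))
    }
  }
  res <- cbind(X, do.call(rbind, rec))
  attr(res, "summary") <- list(
    model = model$name, n_samples = nrow(X), seed = seed,
    stimulus_range = range(sv), points_per_decade = points_per_decade,
    ranges = plan$ranges,
    counts = as.list(table(res$label)),
    n_floor_pass = sum(res$passed_response_floor, na.rm = TRUE),
    package_version = as.character(utils::packageVersion("compswitch")))
  class(res) <- c("sweep_results", "data.frame")
  res
}

#' Write sweep results to disk
#'
#' @param results a [run_sweep()] result.
#' @param dir output directory (created if needed); writes `results.csv`
#'   (one record per sampled point) and `summary.json`.
#' @return the directory, invisibly.
#' @export
write_sweep <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(results), file.path(dir, "results.csv"),
            row.names = FALSE)
  jsonlite::write_json(attr(results, "summary"),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read sweep results back
#'
#' @param dir directory written by [write_sweep()].
#' @return a `sweep_results` data.frame.
#' @export
read_sweep <- function(dir) {
  res <- read.csv(file.path(dir, "results.csv"))
  need <- sweep_record_schema()
  missing <- setdiff(need, names(res))
  if (length(missing)) {
    stop("results file lacks required columns: ", paste(missing, collapse = ", "))
  }
  attr(res, "summary") <- jsonlite::read_json(file.path(dir, "summary.json"))
  class(res) <- c("sweep_results", "data.frame")
  res
}

#' Analyze sweep results
#'
#' Computes, for every sampled parameter: the bistable fraction per
#' logarithmic class, the hypergeometric enrichment flags, and the
#' Mann-Whitney influence ranking for bistability; plus, over the bistable
#' subset, the influence ranking for each hysteresis metric using the
#' high/low group split at `metric_split`. Rows failing the response floor
#' are excluded from the analyzed population, mirroring the sweep protocol's
#' restriction to responsive parameter sets; bistable loops flagged for
#' negative area are excluded from metric-based rankings.
#'
#' @param results a [run_sweep()] / [read_sweep()] data.frame.
#' @param classes_per_decade bins per decade of the sampled range (default 1).
#' @param metric_split group split value for metric rankings (default `0.1`).
#' @param alpha enrichment threshold.
#' @return an `sweep_analysis` list: `fractions` (long data.frame:
#'   parameter, class bounds, y, x, fraction, p_value, enriched),
#'   `bistability_ranking`, `metric_rankings` (list by metric, NULL when
#'   there are no bistable rows), `counts`.
#' @export
analyze_sweep <- function(results, classes_per_decade = 1, metric_split = 0.1,
                          alpha = 1e-4) {
  need <- sweep_record_schema()
  missing <- setdiff(need, names(results))
  if (length(missing)) {
    stop("results lack required columns: ", paste(missing, collapse = ", "))
  }
  pars <- setdiff(names(results), need)
  keep <- !is.na(results$passed_response_floor) & results$passed_response_floor
  dat <- results[keep, , drop = FALSE]
  bist <- dat$label == "bistable"
  frac <- do.call(rbind, lapply(pars, function(p) {
    rg <- log10(range(results[[p]]))
    edges <- 10^seq(floor(rg[1] + 1e-9), ceiling(rg[2] - 1e-9),
                    by = 1 / classes_per_decade)
    if (min(edges) > min(results[[p]])) edges <- c(min(results[[p]]), edges)
    if (max(edges) < max(results[[p]])) edges <- c(edges, max(results[[p]]))
    en <- enrichment_test(dat[[p]], bist, edges, alpha = alpha)
    cbind(parameter = p, as.data.frame(en))
  }))
  ranking <- if (any(bist) && !all(bist)) {
    influence_rank(dat[pars], bist)
  } else NULL
  metric_rankings <- NULL
  bi <- dat[bist & !is.na(dat$excluded_negative_area) &
              !dat$excluded_negative_area, , drop = FALSE]
  if (nrow(bi) >= 4) {
    metric_rankings <- lapply(
      c(width = "width", area = "area",
        distance_1 = "distance_1", distance_2 = "distance_2"),
      function(mcol) {
        grp <- bi[[mcol]] >= metric_split
        if (!any(grp) || all(grp)) return(NULL)
        influence_rank(bi[pars], grp)
      })
  }
  structure(list(fractions = frac,
                 bistability_ranking = ranking,
                 metric_rankings = metric_rankings,
                 counts = list(analyzed = nrow(dat), bistable = sum(bist),
                               below_floor = sum(!keep))),
            class = "sweep_analysis")
}

#' @export
print.sweep_analysis <- function(x, ...) {
  cat("<sweep_analysis> ", x$counts$analyzed, " analyzed (",
      x$counts$below_floor, " below response floor), ",
      x$counts$bistable, " bistable\n", sep = "")
  if (!is.null(x$bistability_ranking)) {
    cat("  influence ranking (|z|): ",
        paste(x$bistability_ranking$parameter, collapse = " > "), "\n", sep = "")
  } else {
    cat("  influence ranking skipped (no bistable/monostable contrast)\n")
  }
  top <- x$fractions[order(-x$fractions$fraction), ][1, ]
  cat("  max bistable fraction: ", sprintf("%.2f%%", 100 * top$fraction),
      " (", top$parameter, " in [", format(top$lower), ", ",
      format(top$upper), "])\n", sep = "")
  invisible(x)
}

#' Write an analysis to disk
#'
#' @param analysis an [analyze_sweep()] result.
#' @param dir output directory; writes `fractions.csv`,
#'   `ranking_bistability.csv`, `ranking_<metric>.csv`, `analysis.json`.
#' @return the directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(analysis$fractions, file.path(dir, "fractions.csv"),
            row.names = FALSE)
  if (!is.null(analysis$bistability_ranking)) {
    write.csv(analysis$bistability_ranking,
              file.path(dir, "ranking_bistability.csv"), row.names = FALSE)
  }
  for (nm in names(analysis$metric_rankings)) {
    rk <- analysis$metric_rankings[[nm]]
    if (!is.null(rk)) {
      write.csv(rk, file.path(dir, paste0("ranking_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(analysis$counts, file.path(dir, "analysis.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
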