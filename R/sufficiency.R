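# Actionable outputs: the point of diminishing returns on a learning curve
# and the minimal data ratio achieving a target Dice.

# centered moving average; edges use the available part of the window
smooth_curve <- function(v, window) {
  if (window <= 1) return(v)
  half <- (window - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Detect the performance plateau of a learning curve
#'
#' The curve is smoothed by a centered moving average, then the plateau
#' ratio is the smallest ladder ratio r such that every smoothed value at
#' or beyond r lies within `epsilon` of the smoothed value at the final
#' ratio (full data). Returns `NA` when no ratio below the final one
#' qualifies: the curve is still climbing. The criterion is relative to
#' the full-data value, not the global maximum, and estimates are reported
#' on the ladder grid, never interpolated.
#'
#' @param curve Single-curve `learning_curves` data.frame (or anything with
#'   `data_ratio` and `dsc` columns), needing at least
#'   `smoothing_window + 2` points.
#' @param epsilon Dice tolerance defining "within reach of the final value".
#' @param smoothing_window Width of the centered moving average.
#' @return The plateau data ratio, or `NA_real_` if none exists below the
#'   final ratio.
#' @export
estimate_plateau <- function(curve, epsilon = 0.01, smoothing_window = 3) {
  n <- nrow(curve)
  if (n < smoothing_window + 2)
    stop_config("estimate_plateau: need >= %d points, got %d", smoothing_window + 2, n)
  cv <- curve[order(curve$data_ratio), , drop = FALSE]
  sm <- smooth_curve(cv$dsc, smoothing_window)
  final <- sm[n]
  ok <- vapply(seq_len(n), function(i) all(abs(sm[i:n] - final) <= epsilon), logical(1))
  first <- which(ok)[1]
  if (is.na(first) || first == n) NA_real_ else cv$data_ratio[first]
}

#' Minimal data ratio reaching a target Dice
#'
#' Smallest ladder ratio whose smoothed Dice meets or exceeds the target;
#' `NA` ("unreachable") when even the full-data point falls short.
#'
#' @inheritParams estimate_plateau
#' @param target_dsc Target Dice in \[0, 1\].
#' @return A ladder ratio or `NA_real_`.
#' @export
minimal_data_for_target <- function(curve, target_dsc, smoothing_window = 3) {
  if (nrow(curve) == 0L) stop_config("minimal_data_for_target: empty curve")
  cv <- curve[order(curve$data_ratio), , drop = FALSE]
  sm <- smooth_curve(cv$dsc, min(smoothing_window, nrow(cv)))
  hit <- which(sm >= target_dsc)[1]
  if (is.na(hit)) NA_real_ else cv$data_ratio[hit]
}

#' Data-sufficiency report across depths and sources
#'
#' Combines observed curves and forecaster predictions into per-depth
#' sufficiency estimates (plateau ratio and minimal ratio for the target),
#' each flagged by its source, plus a summary naming the cheapest
#' (depth, ratio) pair that meets the target.
#'
#' @param observed A `learning_curves` data.frame of observed curves.
#' @param forecast Optional `learning_curves` data.frame of predicted
#'   curves on the same ratio ladder (e.g. prefix + rollout).
#' @param target_dsc Target Dice.
#' @param epsilon Plateau tolerance.
#' @param smoothing_window Moving-average width.
#' @return List with `estimates` (data.frame: depth, source, plateau_ratio,
#'   minimal_ratio_for_target, target_dsc, epsilon) and `summary`.
#' @export
sufficiency_report <- function(observed, forecast = NULL, target_dsc = 0.8,
                               epsilon = 0.01, smoothing_window = 3) {
  sources <- list(observed = observed)
  if (!is.null(forecast)) {
    obs_l <- sort(unique(round(observed$data_ratio, 9)))
    for_l <- sort(unique(round(forecast$data_ratio, 9)))
    if (!all(for_l %in% obs_l))
      stop_config("sufficiency_report: forecast ladder does not align with observed ladder")
    sources$forecast <- forecast
  }
  rows <- list()
  for (src in names(sources)) {
    for (cv in split_curves(sources[[src]])) {
      rows[[length(rows) + 1]] <- data.frame(
        depth = cv$depth[1], source = src,
        plateau_ratio = estimate_plateau(cv, epsilon, smoothing_window),
        minimal_ratio_for_target = minimal_data_for_target(cv, target_dsc,
                                                           smoothing_window),
        target_dsc = target_dsc, epsilon = epsilon)
    }
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  reach <- est[!is.na(est$minimal_ratio_for_target), , drop = FALSE]
  summary <- if (nrow(reach) == 0) {
    list(target_reachable = FALSE)
  } else {
    best <- reach[order(reach$minimal_ratio_for_target, reach$depth), ][1, ]
    list(target_reachable = TRUE, best_depth = best$depth,
         best_ratio = best$minimal_ratio_for_target, source = best$source)
  }
  list(estimates = est, summary = summary)
}

#' Write a sufficiency report to JSON
#'
#' @param report Output of [sufficiency_report()].
#' @param path Output file.
#' @export
write_sufficiency_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
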