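#' Build a normalized aggregation curve from frame measurements
#'
#' Total aggregate area per frame, normalized to the first acquired frame.
#'
#' @param measurements list of `frame_measurement` objects (in frame order)
#'   or a numeric vector of per-frame total areas.
#' @param frame_interval_h hours between frames.
#' @param well_id optional label.
#' @return An `aggregation_curve`: data frame with `time_h` and
#'   `normalized_area`; attributes `well_id` and `frame_interval_h`.
#' @export
build_curve <- function(measurements, frame_interval_h = 0.25,
                        well_id = "well") {
  areas <- if (is.numeric(measurements)) measurements
           else vapply(measurements, function(m) as.numeric(m$total_area_px),
                       numeric(1))
  if (length(areas) < 1) stop("no measurements")
  if (areas[1] <= 0) stop("total area at t = 0 is zero; cannot normalize")
  curve <- data.frame(time_h = (seq_along(areas) - 1) * frame_interval_h,
                      normalized_area = areas / areas[1])
  structure(curve, class = c("aggregation_curve", "data.frame"),
            well_id = well_id, frame_interval_h = frame_interval_h)
}

#' Normalized area at a given time
#'
#' Nearest-sample lookup (2 h lies exactly on the 15-min grid; off-grid
#' queries warn rather than interpolate).
#'
#' @param curve an [build_curve()] result.
#' @param t_h query time in hours, within the curve's range.
#' @return Normalized area at the sample nearest `t_h`.
#' @export
area_at <- function(curve, t_h) {
  tt <- curve$time_h
  if (t_h < 0 || t_h > tt[length(tt)]) stop("'t_h' outside the curve range")
  i <- which.min(abs(tt - t_h))
  if (abs(tt[i] - t_h) > 1e-9)
    warning(sprintf("t = %g h is off the sampling grid; using nearest sample %g h",
                    t_h, tt[i]))
  curve$normalized_area[i]
}

#' Area under the aggregation curve
#'
#' Trapezoidal integral of the normalized area over `[0, window_h]`, in
#' hours. For curves with values in `(0, 1]` the AUC is in `(0, window_h]`,
#' equal to `window_h` only for the constant-1 curve.
#'
#' @param curve an [build_curve()] result.
#' @param window_h integration window (hours); must not exceed the curve.
#' @return AUC in hours.
#' @export
compute_auc <- function(curve, window_h) {
  tt <- curve$time_h; y <- curve$normalized_area
  if (window_h > tt[length(tt)] + 1e-9)
    stop("'window_h' exceeds the curve duration")
  sel <- tt <= window_h + 1e-9
  tt <- tt[sel]; y <- y[sel]
  sum(diff(tt) * (head(y, -1) + y[-1]) / 2)
}

#' Mean aggregate circularity at the final frame
#'
#' Unweighted mean over retained aggregates. With no retained aggregate the
#' value is undefined: `NA` is returned with a warning.
#'
#' @param measurement the final frame's `frame_measurement`.
#' @return Mean circularity, or `NA`.
#' @export
end_circularity <- function(measurement) {
  circ <- measurement$objects$circularity
  circ <- circ[!is.na(circ)]
  if (length(circ) == 0) {
    warning("no retained aggregate at the final frame; circularity undefined")
    return(NA_real_)
  }
  mean(circ)
}

#' Extract the per-well aggregation parameters
#'
#' @param curve an [build_curve()] result.
#' @param end_measurement final-frame `frame_measurement` (or `NULL` to skip
#'   circularity).
#' @param window_h AUC integration window in hours (explicit by design; the
#'   assay duration varies between experiments).
#' @return A `well_parameters` list: `area_2h`, `auc`, `circularity_end`,
#'   `window_h`, `well_id`. A curve shorter than 2 h cannot provide area-2h;
#'   `NA` is reported with a warning.
#' @export
well_parameters <- function(curve, end_measurement = NULL, window_h) {
  if (missing(window_h)) stop("'window_h' must be given explicitly")
  a2 <- if (max(curve$time_h) >= 2) area_at(curve, 2) else {
    warning("curve shorter than 2 h; area-2h undefined")
    NA_real_
  }
  structure(list(
    area_2h = a2,
    auc = compute_auc(curve, window_h),
    circularity_end = if (is.null(end_measurement)) NA_real_
                      else end_circularity(end_measurement),
    window_h = window_h,
    well_id = attr(curve, "well_id")), class = "well_parameters")
}

#' Summarize replicate wells of one condition
#'
#' @param curves list of [build_curve()] curves (replicate wells).
#' @param end_measurements optional list of final-frame measurements,
#'   parallel to `curves`.
#' @param window_h AUC window (hours).
#' @param label condition label.
#' @return A `condition_summary`: per-replicate parameter table plus mean
#'   and sample SD (n-1); for a single replicate the SD is reported as 0 by
#'   convention.
#' @export
summarize_condition <- function(curves, end_measurements = NULL, window_h,
                                label = "condition") {
  if (length(curves) < 1) stop("need at least one curve")
  iv <- vapply(curves, function(cu) attr(cu, "frame_interval_h"), numeric(1))
  if (length(unique(iv)) != 1) stop("mixed frame intervals between replicates")
  reps <- lapply(seq_along(curves), function(i)
    well_parameters(curves[[i]],
                    if (!is.null(end_measurements)) end_measurements[[i]],
                    window_h = window_h))
  tab <- data.frame(
    well_id = vapply(reps, `[[`, character(1), "well_id"),
    area_2h = vapply(reps, `[[`, numeric(1), "area_2h"),
    auc = vapply(reps, `[[`, numeric(1), "auc"),
    circularity_end = vapply(reps, `[[`, numeric(1), "circularity_end"))
  stats_of <- function(v) c(mean = mean(v, na.rm = TRUE),
                            sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                                 else 0)
  structure(list(label = label, replicates = tab,
                 n_replicates = nrow(tab), window_h = window_h,
                 area_2h = stats_of(tab$area_2h),
                 auc = stats_of(tab$auc),
                 circularity_end = stats_of(tab$circularity_end)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition '%s' (n = %d, AUC window %g h)\n", x$label,
              x$n_replicates, x$window_h))
  for (p in c("area_2h", "auc", "circularity_end"))
    cat(sprintf("  %-16s %.4g +- %.4g\n", p, x[[p]]["mean"], x[[p]]["sd"]))
  invisible(x)
}

#' Compare one aggregation parameter between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The p-value is exact
#' when both groups have fewer than 50 observations and the data have no
#' ties, otherwise a normal approximation with continuity correction is used
#' (the policy of [stats::wilcox.test()]).
#'
#' @param a,b `condition_summary` objects.
#' @param parameter `"area_2h"`, `"auc"` or `"circularity_end"`.
#' @return List with `parameter`, `u` (the Mann-Whitney U statistic for
#'   group `a`), `p_value`, group sizes and the test object.
#' @export
compare_conditions <- function(a, b, parameter = c("auc", "area_2h",
                                                   "circularity_end")) {
  parameter <- match.arg(parameter)
  va <- a$replicates[[parameter]]; vb <- b$replicates[[parameter]]
  if (length(va) < 3 || length(vb) < 3)
    stop("need >= 3 replicates per condition")
  ht <- wilcox.test(va, vb, alternative = "two.sided", exact = NULL,
                    correct = TRUE)
  list(parameter = parameter, u = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(va), n_b = length(vb), test = ht)
}
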