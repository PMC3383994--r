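#' Uniform background subtraction
#'
#' Subtracts a single constant from a lane and clips at zero. In `"auto"` mode
#' the constant is the 5th percentile of the lane intensities -- a robust
#' stand-in for supervised background reading, accurate when part of the lane
#' is signal-free.
#'
#' @param trace a [densitometry_trace()].
#' @param level non-negative constant, or `"auto"`.
#' @return a background-subtracted [densitometry_trace()]; the level used is
#'   stored in the `background_level` attribute.
#' @export
subtract_background <- function(trace, level = "auto") {
  stopifnot(inherits(trace, "densitometry_trace"))
  if (identical(level, "auto")) {
    level <- as.numeric(stats::quantile(trace$intensities, 0.05))
  } else {
    stopifnot(is.numeric(level), level >= 0)
    if (level > max(trace$intensities))
      stop("background level exceeds the lane maximum; subtraction would zero the lane")
  }
  out <- densitometry_trace(trace$distances,
                            pmax(trace$intensities - level, 0),
                            trace$lane_label)
  attr(out, "background_level") <- level
  out
}

#' Calibration curve between migration distance and log size
#'
#' @param alpha intercept (distance units).
#' @param beta slope (distance units per log nt), negative.
#' @param residual_sd residual standard deviation of the fit.
#' @param size_range_fitted range of ladder sizes used in the fit.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(alpha, beta, residual_sd = 0,
                              size_range_fitted = c(NA_real_, NA_real_)) {
  stopifnot(beta < 0, residual_sd >= 0)
  structure(list(alpha = alpha, beta = beta, residual_sd = residual_sd,
                 size_range_fitted = size_range_fitted),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> distance = %.6g %+.6g * log(size)\n  residual sd %.3g; fitted over %.4g-%.4g nt\n",
              x$alpha, x$beta, x$residual_sd,
              x$size_range_fitted[1], x$size_range_fitted[2]))
  invisible(x)
}

#' Fit the ladder calibration
#'
#' Ordinary least squares of distance on `log(size)` over the annotated ladder
#' peaks, as `lm(distance ~ log(size))`. Prediction outside the fitted size
#' range is permitted (extrapolation along the same line) and flagged by
#' [cal_size()] / [cal_distance()].
#'
#' @param annotation a [ladder_annotation()] with at least 2 peaks, distances
#'   strictly decreasing in size.
#' @return a [calibration_curve()].
#' @export
fit_calibration <- function(annotation) {
  stopifnot(inherits(annotation, "ladder_annotation"))
  if (nrow(annotation) < 2) stop("need at least 2 annotated peaks")
  fit <- stats::lm(distance ~ log(size), data = annotation)
  s <- if (fit$df.residual > 0)
    sqrt(sum(stats::residuals(fit)^2) / fit$df.residual) else 0
  calibration_curve(alpha = unname(stats::coef(fit)[1]),
                    beta = unname(stats::coef(fit)[2]),
                    residual_sd = s,
                    size_range_fitted = range(annotation$size))
}

#' Convert between migration distance and fragment size
#'
#' `cal_distance()` maps size to distance along the calibration line;
#' `cal_size()` inverts it, `size = exp((distance - alpha) / beta)`. Both are
#' smooth and monotone everywhere; values outside the fitted size range are
#' extrapolations and set the `extrapolated` attribute.
#'
#' @param cal a [calibration_curve()].
#' @param size,distance values to convert.
#' @name calibration-convert
NULL

#' @rdname calibration-convert
#' @export
cal_distance <- function(cal, size) {
  stopifnot(inherits(cal, "calibration_curve"))
  out <- cal$alpha + cal$beta * log(size)
  rng <- cal$size_range_fitted
  if (!anyNA(rng))
    attr(out, "extrapolated") <- any(size < rng[1] | size > rng[2])
  out
}

#' @rdname calibration-convert
#' @export
cal_size <- function(cal, distance) {
  stopifnot(inherits(cal, "calibration_curve"))
  out <- exp((distance - cal$alpha) / cal$beta)
  rng <- cal$size_range_fitted
  if (!anyNA(rng))
    attr(out, "extrapolated") <- any(out < rng[1] | out > rng[2])
  out
}

#' Smooth a trace with a cubic smoothing spline
#'
#' Fits `stats::smooth.spline` with the requested equivalent degrees of
#' freedom in the distance domain and clips the fitted curve at zero.
#' `effective_df` equal to the number of grid points returns the input
#' unchanged (saturated smoother).
#'
#' @param trace a [densitometry_trace()].
#' @param effective_df target equivalent degrees of freedom, in
#'   `[2, n_points]`. Default 40.
#' @return a smoothed [densitometry_trace()]; the achieved degrees of freedom
#'   are stored in the `effective_df` attribute.
#' @export
smooth_trace <- function(trace, effective_df = 40) {
  stopifnot(inherits(trace, "densitometry_trace"))
  n <- length(trace$distances)
  if (effective_df < 2 || effective_df > n)
    stop("effective_df must be between 2 and the number of grid points")
  if (effective_df == n) {
    out <- trace
    attr(out, "effective_df") <- n
    return(out)
  }
  fit <- stats::smooth.spline(trace$distances, trace$intensities,
                              df = effective_df)
  if (abs(fit$df - effective_df) > 0.5)
    warning(sprintf("achieved df %.2f differs from requested %.2f by more than 0.5",
                    fit$df, effective_df))
  y <- stats::predict(fit, trace$distances)$y
  out <- densitometry_trace(trace$distances, pmax(y, 0), trace$lane_label)
  attr(out, "effective_df") <- fit$df
  out
}

#' Size histograms of fragment mass and counts
#'
#' Binned fragment mass (nt equivalents, intensity-derived) over a size
#' window, with fragment counts obtained by dividing each bin's mass by its
#' geometric mid size. After [normalize_and_count()], total mass equals
#' `total_mass_target`.
#'
#' @param bin_edges strictly increasing size values (nt), length `n + 1`.
#' @param mass non-negative mass per bin, length `n`.
#' @param counts fragments per bin; computed as `mass / geometric mid` if
#'   omitted.
#' @param total_mass_target the mass the histogram is (to be) normalized to;
#'   `NA` until normalized.
#' @return an object of class `size_histogram`.
#' @export
size_histogram <- function(bin_edges, mass, counts = NULL,
                           total_mass_target = NA_real_) {
  stopifnot(all(diff(bin_edges) > 0), length(mass) == length(bin_edges) - 1,
            all(mass >= 0))
  mid <- sqrt(bin_edges[-1] * bin_edges[-length(bin_edges)])
  if (is.null(counts)) counts <- mass / mid
  structure(list(bin_edges = as.numeric(bin_edges), mass = as.numeric(mass),
                 counts = as.numeric(counts),
                 total_mass_target = total_mass_target),
            class = "size_histogram")
}

#' Geometric mid sizes of a histogram's bins
#' @param hist a [size_histogram()].
#' @return numeric vector of representative bin sizes (nt).
#' @export
bin_mids <- function(hist) {
  e <- hist$bin_edges
  sqrt(e[-1] * e[-length(e)])
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %d log bins over %.4g-%.4g nt\n  total mass %.6g nt, total count %.6g fragments\n",
              length(x$mass), min(x$bin_edges), max(x$bin_edges),
              sum(x$mass), sum(x$counts)))
  invisible(x)
}

#' @export
plot.size_histogram <- function(x, what = c("mass", "counts"), ...) {
  what <- match.arg(what)
  graphics::plot(bin_mids(x), x[[what]], type = "s", log = "x",
                 xlab = "fragment size (nt)", ylab = what, ...)
  invisible(x)
}

#' Transform a trace to the nucleotide-size domain
#'
#' Changes variables from migration distance to fragment size via the
#' calibration curve, `size = exp((distance - alpha) / beta)`, conserving
#' integrated intensity (mass): the binned mass in a size interval equals the
#' trapezoid integral of the trace over the corresponding distance interval,
#' which applies the Jacobian `|beta| / size` implicitly and exactly. Bins are
#' log-spaced over `window`; mass migrating to sizes outside the window
#' accumulates into the edge bins, with the off-window fraction stored in the
#' `edge_mass_fraction` attribute.
#'
#' @param trace a background-subtracted [densitometry_trace()].
#' @param cal a [calibration_curve()].
#' @param window size window `(min_nt, max_nt)`. Default 200 nt to 100 kb.
#' @param n_bins number of log-spaced bins. Default 200.
#' @return a [size_histogram()] (mass in trace-intensity x distance units;
#'   scale is fixed later by [normalize_and_count()]).
#' @export
to_size_domain <- function(trace, cal, window = c(200, 1e5), n_bins = 200) {
  stopifnot(inherits(trace, "densitometry_trace"),
            inherits(cal, "calibration_curve"),
            length(window) == 2, window[1] > 0, window[2] > window[1])
  d <- trace$distances
  y <- trace$intensities
  n <- length(d)
  # cumulative trapezoid integral of intensity over distance
  C <- c(0, cumsum((y[-1] + y[-n]) / 2 * diff(d)))
  total <- C[n]
  cum_at <- stats::approxfun(d, C, rule = 2)
  edges <- exp(seq(log(window[1]), log(window[2]), length.out = n_bins + 1))
  d_edges <- cal$alpha + cal$beta * log(edges)  # decreasing in size
  if (d_edges[1] < min(d) || d_edges[n_bins + 1] > max(d))
    stop("size window does not overlap the trace's distance span")
  # size bin [e_b, e_{b+1}] corresponds to distances [d(e_{b+1}), d(e_b)]
  cum_e <- cum_at(d_edges)
  mass <- cum_e[-(n_bins + 1)] - cum_e[-1]
  low_extra <- total - cum_e[1]     # distances beyond d(min size): sizes < window
  high_extra <- cum_e[n_bins + 1]   # distances short of d(max size): sizes > window
  mass[1] <- mass[1] + low_extra
  mass[n_bins] <- mass[n_bins] + high_extra
  h <- size_histogram(edges, pmax(mass, 0))
  attr(h, "edge_mass_fraction") <- if (total > 0) (low_extra + high_extra) / total else 0
  h
}

#' Normalize a histogram to a fixed nucleotide total and count fragments
#'
#' Rescales bin mass so that total mass equals `total_mass_target` (default
#' 1e9 nt), then computes fragments per bin as mass divided by the bin's
#' geometric mid size. The total fragment count `sum(counts)` is the quantity
#' whose lane-to-lane difference equals the number of extra cleavage sites per
#' `total_mass_target` nucleotides.
#'
#' @param hist a [size_histogram()] with positive total mass.
#' @param total_mass_target nucleotide total to scale to. Default 1e9.
#' @return the normalized [size_histogram()].
#' @export
normalize_and_count <- function(hist, total_mass_target = 1e9) {
  stopifnot(inherits(hist, "size_histogram"))
  tot <- sum(hist$mass)
  if (tot <= 0) stop("cannot normalize an all-zero histogram")
  mass <- hist$mass * (total_mass_target / tot)
  size_histogram(hist$bin_edges, mass, total_mass_target = total_mass_target)
}

#' Total fragment count of a histogram
#' @param hist a [size_histogram()].
#' @return `sum(counts)`.
#' @export
fragment_count <- function(hist) sum(hist$counts)

#' Bin a fragment multiset directly into a size histogram
#'
#' The generator-truth counterpart of the densitometry chain: actual fragment
#' counts and actual mass (sum of lengths) per log-spaced bin. Fragments
#' outside the window fall into the edge bins.
#'
#' @param fragments a [fragment_set()] or numeric vector of lengths.
#' @param window size window `(min_nt, max_nt)`.
#' @param n_bins number of log-spaced bins.
#' @return a [size_histogram()] with exact counts.
#' @export
fragment_histogram <- function(fragments, window = c(200, 1e5), n_bins = 200) {
  lens <- if (inherits(fragments, "fragment_set")) fragments$lengths else fragments
  stopifnot(length(lens) > 0)
  edges <- exp(seq(log(window[1]), log(window[2]), length.out = n_bins + 1))
  idx <- findInterval(lens, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)  # clamp off-window fragments to edge bins
  counts <- numeric(n_bins)
  mass <- numeric(n_bins)
  agg_c <- rowsum(rep(1, length(lens)), idx)
  agg_m <- rowsum(lens, idx)
  counts[as.integer(rownames(agg_c))] <- agg_c[, 1]
  mass[as.integer(rownames(agg_m))] <- agg_m[, 1]
  size_histogram(edges, mass, counts = counts)
}

#' Histogram TSV I-O
#'
#' Round-trips as four columns: `bin_lo`, `bin_hi`, `mass_nt`, `count`.
#'
#' @param x a [size_histogram()].
#' @param path file path.
#' @name histogram-io
NULL

#' @rdname histogram-io
#' @export
write_histogram <- function(x, path) {
  stopifnot(inherits(x, "size_histogram"))
  e <- x$bin_edges
  df <- data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                   mass_nt = x$mass, count = x$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_mass_target=%s", format(x$total_mass_target)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname histogram-io
#' @export
read_histogram <- function(path) {
  hdr <- readLines(path, n = 1)
  tgt <- suppressWarnings(as.numeric(sub("^# total_mass_target=", "", hdr)))
  df <- utils::read.delim(path, comment.char = "#")
  size_histogram(c(df$bin_lo, df$bin_hi[nrow(df)]), df$mass_nt,
                 counts = df$count, total_mass_target = tgt)
}
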