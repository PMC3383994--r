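#' Gel model: log-size migration, band spread, background and noise
#'
#' Migration distance is affine in log fragment size,
#' `distance = alpha + beta * log(size)` with `beta < 0` (larger fragments
#' migrate less far). Each fragment contributes a Gaussian band of standard
#' deviation `band_sigma` (in distance units, size-independent) whose total
#' area is `mass_scale * length`, i.e. staining intensity is proportional to
#' nucleotide mass, as for intercalating dyes. A uniform background and
#' additive truncated-Gaussian scanner noise complete the lane.
#'
#' Defaults place ~45 nt to ~1.4 Mb on the 512-point grid over `[5, 130]`
#' distance units, comfortably containing both shear-only control lanes (mean
#' ~30 kb) and digested mutant lanes (mean ~6-8 kb).
#'
#' @param alpha intercept: distance of a 1-nt fragment.
#' @param beta distance units per log(nt); must be negative.
#' @param band_sigma Gaussian band standard deviation, distance units.
#' @param background uniform background intensity.
#' @param noise_sd scanner noise standard deviation (intensity units).
#' @param distance_grid strictly increasing sample points.
#' @param mass_scale intensity units per nt of fragment mass.
#' @return an object of class `gel_model`.
#' @export
gel_model <- function(alpha = 175, beta = -12, band_sigma = 1.5,
                      background = 1, noise_sd = 0.05,
                      distance_grid = seq(5, 130, length.out = 512),
                      mass_scale = 1e-6) {
  stopifnot(beta < 0, band_sigma > 0, background >= 0, noise_sd >= 0,
            all(diff(distance_grid) > 0), mass_scale > 0)
  structure(list(alpha = alpha, beta = beta, band_sigma = band_sigma,
                 background = background, noise_sd = noise_sd,
                 distance_grid = distance_grid, mass_scale = mass_scale),
            class = "gel_model")
}

#' @export
print.gel_model <- function(x, ...) {
  rng <- range(x$distance_grid)
  cat(sprintf(paste0("<gel_model> distance = %.4g %+.4g * log(size)\n",
                     "  band sigma %.3g, background %.3g, noise sd %.3g\n",
                     "  grid: %d points on [%.4g, %.4g] (sizes %.3g-%.3g nt)\n"),
              x$alpha, x$beta, x$band_sigma, x$background, x$noise_sd,
              length(x$distance_grid), rng[1], rng[2],
              exp((rng[2] - x$alpha) / x$beta), exp((rng[1] - x$alpha) / x$beta)))
  invisible(x)
}

#' Migration distance of a fragment
#'
#' @param size fragment size(s) in nt (>= 1).
#' @param gel a [gel_model()].
#' @return `alpha + beta * log(size)`, strictly decreasing in size.
#' @examples
#' migrate(1000, gel_model(alpha = 120, beta = -12))  # ~37.11
#' @export
migrate <- function(size, gel) {
  stopifnot(inherits(gel, "gel_model"))
  if (any(size < 1)) stop("size must be >= 1 nt")
  gel$alpha + gel$beta * log(size)
}

#' Densitometry trace
#'
#' A 1-D intensity profile along a gel lane, sampled at ordered distances.
#'
#' @param distances ordered sample points (distance units).
#' @param intensities non-negative intensities, same length.
#' @param lane_label text label.
#' @return an object of class `densitometry_trace`.
#' @export
densitometry_trace <- function(distances, intensities, lane_label = "") {
  stopifnot(length(distances) == length(intensities),
            all(diff(distances) > 0), all(intensities >= 0))
  structure(list(distances = as.numeric(distances),
                 intensities = as.numeric(intensities),
                 lane_label = lane_label),
            class = "densitometry_trace")
}

#' @export
print.densitometry_trace <- function(x, ...) {
  cat(sprintf("<densitometry_trace> '%s': %d points, distance [%.4g, %.4g], max intensity %.4g\n",
              x$lane_label, length(x$distances), min(x$distances),
              max(x$distances), max(x$intensities)))
  invisible(x)
}

#' @export
plot.densitometry_trace <- function(x, ...) {
  graphics::plot(x$distances, x$intensities, type = "l",
                 xlab = "migration distance", ylab = "intensity",
                 main = x$lane_label, ...)
  invisible(x)
}

# Sum Gaussian bands at centres mu with areas mass onto the gel grid.
# Mass is first accumulated into fine bins spanning the grid extended by
# 4 sigma, then convolved with the Gaussian kernel; mass whose centre falls
# beyond the extended span is dropped and reported.
render_bands <- function(mu, mass, gel, sigma, n_fine = 4096) {
  grid <- gel$distance_grid
  lo <- min(grid) - 4 * sigma
  hi <- max(grid) + 4 * sigma
  total <- sum(mass)
  inside <- mu >= lo & mu <= hi
  lost <- if (total > 0) sum(mass[!inside]) / total else 0
  signal <- numeric(length(grid))
  if (any(inside)) {
    edges <- seq(lo, hi, length.out = n_fine + 1)
    idx <- findInterval(mu[inside], edges, rightmost.closed = TRUE)
    wm <- numeric(n_fine)
    agg <- rowsum(mass[inside], idx)
    wm[as.integer(rownames(agg))] <- agg[, 1]
    centers <- (edges[-1] + edges[-(n_fine + 1)]) / 2
    keep <- wm > 0
    if (any(keep))
      signal <- as.numeric(
        stats::dnorm(outer(grid, centers[keep], "-"), sd = sigma) %*% wm[keep])
  }
  list(signal = signal, lost_fraction = lost)
}

#' Render a densitometry trace from a fragment set
#'
#' Each fragment of length L contributes a Gaussian band centred at
#' `migrate(L)` with total area `mass_scale * L`; bands are summed on the
#' distance grid, background is added, then i.i.d. Gaussian noise of sd
#' `noise_sd`, and the result is clipped at zero. Mass migrating beyond the
#' grid span (plus a 4-sigma margin) is dropped with a warning reporting the
#' lost fraction, which is also stored in the `mass_lost_fraction` attribute.
#'
#' @param fragments a [fragment_set()] (may be empty).
#' @param gel a [gel_model()].
#' @param seed integer seed for the noise draw.
#' @param lane_label label for the trace.
#' @return a [densitometry_trace()].
#' @export
render_trace <- function(fragments, gel, seed = NULL, lane_label = "") {
  stopifnot(inherits(fragments, "fragment_set"), inherits(gel, "gel_model"))
  lens <- fragments$lengths
  if (length(lens) > 0) {
    rb <- render_bands(migrate(lens, gel), gel$mass_scale * lens, gel,
                       gel$band_sigma)
    if (rb$lost_fraction > 0)
      warning(sprintf("%.3g%% of fragment mass migrates outside the distance grid",
                      100 * rb$lost_fraction),
              call. = FALSE)
    signal <- rb$signal
    lost <- rb$lost_fraction
  } else {
    signal <- numeric(length(gel$distance_grid))
    lost <- 0
  }
  y <- signal + gel$background
  if (gel$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, gel$noise_sd)
  }
  tr <- densitometry_trace(gel$distance_grid, pmax(y, 0), lane_label)
  attr(tr, "mass_lost_fraction") <- lost
  tr
}

#' Supervised-style ladder annotation
#'
#' @param distance peak migration distances.
#' @param size corresponding fragment sizes (nt).
#' @return an object of class `ladder_annotation` (a data frame with columns
#'   `distance`, `size`), sorted by size.
#' @export
ladder_annotation <- function(distance, size) {
  stopifnot(length(distance) == length(size), length(size) >= 2)
  o <- order(size)
  df <- data.frame(distance = distance[o], size = size[o])
  if (any(diff(df$distance) >= 0))
    stop("annotation distances must be strictly decreasing in size")
  class(df) <- c("ladder_annotation", "data.frame")
  df
}

#' Render a size-standard ladder lane
#'
#' Sharp bands (standard deviation `band_sigma / 4`) of equal mass at each
#' ladder size, with the gel's background and noise. The returned annotation
#' records the true (distance, size) pairs, emulating supervised peak
#' identification in the size-reference lane.
#'
#' @param sizes ladder fragment sizes in nt (>= 2 distinct values). Default: a
#'   1-kb ladder from 0.5 to 12 kb.
#' @param gel a [gel_model()].
#' @param seed integer seed for the noise draw.
#' @param band_mass intensity-area of each band.
#' @return a list with elements `trace` ([densitometry_trace()]) and
#'   `annotation` ([ladder_annotation()]).
#' @export
render_ladder <- function(sizes = c(0.5, 1, 1.6, 2, 3, 4, 5, 6, 8, 10, 12) * 1e3,
                          gel = gel_model(), seed = NULL, band_mass = 100) {
  if (anyDuplicated(sizes)) {
    warning("duplicate ladder sizes collapsed")
    sizes <- unique(sizes)
  }
  stopifnot(length(sizes) >= 2)
  sizes <- sort(sizes)
  mu <- migrate(sizes, gel)
  rb <- render_bands(mu, rep(band_mass, length(sizes)), gel, gel$band_sigma / 4)
  y <- rb$signal + gel$background
  if (gel$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, gel$noise_sd)
  }
  list(trace = densitometry_trace(gel$distance_grid, pmax(y, 0), "ladder"),
       annotation = ladder_annotation(mu, sizes))
}

#' Trace / annotation TSV I-O
#'
#' Traces round-trip as two-column TSV (`distance`, `intensity`); ladder
#' annotations as (`distance`, `size`).
#'
#' @param x object to write.
#' @param path file path.
#' @name trace-io
NULL

#' @rdname trace-io
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "densitometry_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lane=%s", x$lane_label), con)
  utils::write.table(data.frame(distance = x$distances, intensity = x$intensities),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace-io
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 1)
  lab <- sub("^# lane=", "", hdr)
  df <- utils::read.delim(path, comment.char = "#")
  densitometry_trace(df$distance, df$intensity, lane_label = lab)
}

#' @rdname trace-io
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "ladder_annotation"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace-io
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path)
  ladder_annotation(df$distance, df$size)
}
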