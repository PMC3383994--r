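#' Genome constants for per-cell arithmetic
#'
#' @param haploid_bp haploid genome size in bp (default 2.5e9, mouse).
#' @param ploidy genome copies per nucleus (default 2).
#' @return an object of class `genome_constants`. At the defaults a diploid
#'   nucleus contains `haploid_bp * ploidy * 2 = 1e10` nucleotides of DNA.
#' @export
genome_constants <- function(haploid_bp = 2.5e9, ploidy = 2) {
  stopifnot(haploid_bp > 0, ploidy >= 1)
  structure(list(haploid_bp = haploid_bp, ploidy = ploidy, strands_per_bp = 2),
            class = "genome_constants")
}

new_frequency_estimate <- function(rate, delta_fragments, method,
                                   replicate_spacings = numeric(0),
                                   total_mass_target = 1e9,
                                   n_cuts = NA_real_,
                                   objective_trace = numeric(0),
                                   note = NULL) {
  spacing <- if (rate > 0) 1 / rate else Inf
  spacing_sd <- if (length(replicate_spacings) > 1)
    stats::sd(replicate_spacings) else NA_real_
  structure(list(rate = rate,
                 spacing = spacing,
                 delta_fragments = delta_fragments,
                 replicate_spacings = replicate_spacings,
                 spacing_sd = spacing_sd,
                 method = method,
                 total_mass_target = total_mass_target,
                 n_cuts = n_cuts,
                 objective_trace = objective_trace,
                 note = note),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("<frequency_estimate> method: %s\n", x$method))
  if (x$rate > 0) {
    cat(sprintf("  1 ribonucleotide every %s nt (rate %.4g per nt)\n",
                format(round(x$spacing), big.mark = ","), x$rate))
    cat(sprintf("  excess fragments: %s per %s nt\n",
                format(round(x$delta_fragments), big.mark = ","),
                format(x$total_mass_target, big.mark = ",", scientific = FALSE)))
  } else {
    cat("  no detectable additional sites (rate 0)\n")
  }
  if (length(x$replicate_spacings) > 1)
    cat(sprintf("  replicates: 1 in %.2f +/- %.2f kb (SD, n = %d)\n",
                mean(x$replicate_spacings) / 1e3, x$spacing_sd / 1e3,
                length(x$replicate_spacings)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
summary.frequency_estimate <- function(object, constants = genome_constants(), ...) {
  out <- list(estimate = object,
              sites_per_cell = sites_per_cell(object, constants),
              constants = constants)
  class(out) <- "summary.frequency_estimate"
  out
}

#' @export
print.summary.frequency_estimate <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  genome: %.3g bp haploid x %d-ploid x 2 strands = %.3g nt\n",
              x$constants$haploid_bp, x$constants$ploidy,
              x$constants$haploid_bp * x$constants$ploidy * 2))
  cat(sprintf("  implied sites per cell: %s\n",
              format(round(x$sites_per_cell), big.mark = ",")))
  invisible(x)
}

#' @export
coef.frequency_estimate <- function(object, ...) {
  c(rate = object$rate, spacing = object$spacing,
    delta_fragments = object$delta_fragments)
}

#' Analytic frequency estimate by fragment-count subtraction
#'
#' The number of extra cleavage sites per `total_mass_target` nucleotides is
#' the difference in total fragment count between a mutant and a control lane
#' normalized to the same nucleotide total: each extra cut adds exactly one
#' fragment. The per-nucleotide rate is `delta / total_mass_target` and the
#' spacing its reciprocal. With replicate pairs, per-pair spacings are pooled
#' by a mass-weighted mean rate and reported with their SD.
#'
#' A non-positive difference (control at least as fragmented as the mutant) is
#' reported as "no detectable additional sites" with rate 0, not an error.
#'
#' @param mutant,control normalized [size_histogram()]s, or lists of them
#'   (replicate pairs, matched by position).
#' @return a [frequency_estimate()] with `method = "analytic"`.
#' @export
analytic_estimate <- function(mutant, control) {
  if (inherits(mutant, "size_histogram")) mutant <- list(mutant)
  if (inherits(control, "size_histogram")) control <- list(control)
  stopifnot(length(mutant) == length(control), length(mutant) >= 1)
  tgt <- vapply(c(mutant, control), function(h) h$total_mass_target, 0)
  if (anyNA(tgt) || length(unique(tgt)) != 1)
    stop("all histograms must be normalized to the same total_mass_target")
  tgt <- tgt[1]
  deltas <- mapply(function(m, ctl) fragment_count(m) - fragment_count(ctl),
                   mutant, control)
  rates <- pmax(deltas, 0) / tgt
  spacings <- ifelse(rates > 0, 1 / rates, Inf)
  mean_rate <- mean(rates)
  note <- if (any(deltas <= 0))
    "one or more pairs had no detectable additional sites (delta <= 0)" else NULL
  new_frequency_estimate(rate = mean_rate,
                         delta_fragments = mean(deltas),
                         method = "analytic",
                         replicate_spacings = if (length(deltas) > 1)
                           spacings[is.finite(spacings)] else numeric(0),
                         total_mass_target = tgt,
                         note = note)
}

# Draw explicit fragment lengths whose size distribution matches a histogram's
# counts, rescaled so total length is exactly genome_nt. Lengths are sampled
# log-uniformly within each bin.
draw_start_fragments <- function(start, genome_nt) {
  if (is.null(start)) return(genome_nt)
  stopifnot(inherits(start, "size_histogram"))
  if (sum(start$mass) <= 0) stop("start histogram has zero mass")
  n <- max(1L, round(sum(start$counts)))
  bins <- sample.int(length(start$counts), n, replace = TRUE,
                     prob = start$counts)
  e <- start$bin_edges
  lo <- log(e[bins]); hi <- log(e[bins + 1])
  lens <- exp(lo + stats::runif(n) * (hi - lo))
  lens * (genome_nt / sum(lens))
}

# Fragment lengths after adding cuts at the given global coordinates (in
# [0, sum(start_lengths))) to a concatenation of the start fragments.
apply_cuts <- function(start_lengths, cut_points) {
  bounds <- cumsum(start_lengths)
  all_cuts <- sort(c(bounds[-length(bounds)], cut_points))
  diff(c(0, all_cuts, bounds[length(bounds)]))
}

#' Random-cut fragmentation simulation
#'
#' Draws a starting set of fragments (one intact genome, or fragments matching
#' a starting histogram estimated from densitometry), adds `n_cuts` cuts at
#' positions uniform over the total length, and bins the resulting fragment
#' lengths.
#'
#' @param n_cuts number of random cuts to add (>= 0).
#' @param start optional [size_histogram()] describing the starting
#'   fragmentation; `NULL` starts from one intact genome.
#' @param genome_nt total nucleotides simulated. Default 1e9.
#' @param seed integer seed.
#' @param window,n_bins histogram binning, as in [fragment_histogram()].
#' @return a [size_histogram()] with exact simulated counts.
#' @export
simulate_fragment_histogram <- function(n_cuts, start = NULL, genome_nt = 1e9,
                                        seed = NULL, window = c(200, 1e5),
                                        n_bins = 200) {
  stopifnot(n_cuts >= 0, genome_nt >= 1)
  if (!is.null(seed)) set.seed(seed)
  start_lengths <- draw_start_fragments(start, genome_nt)
  cuts <- sort(stats::runif(n_cuts) * genome_nt)
  lens <- apply_cuts(start_lengths, cuts)
  fragment_histogram(lens[lens >= 1], window = window, n_bins = n_bins)
}

# Smooth histogram counts over log size with the same effective-df spline used
# on traces; clipped at zero.
smooth_histogram_counts <- function(hist, effective_df = 40) {
  x <- log(bin_mids(hist))
  y <- hist$counts
  df <- min(effective_df, length(y))
  if (df >= length(y)) return(y)
  fit <- stats::smooth.spline(x, y, df = df)
  pmax(stats::predict(fit, x)$y, 0)
}

#' Fit the number of random cuts by hill climbing
#'
#' Finds the number of uniform random cuts that, added to the starting
#' fragment distribution, best reproduces a target histogram: the objective is
#' the Manhattan (L1) distance between the smoothed simulated histogram and
#' the smoothed target. The search is a 1-D hill climb with multiplicative
#' proposals `n * (1 +/- step)` (minimum absolute step 1), the step halved
#' when neither proposal improves, initialized from the analytic
#' fragment-count difference. Common random numbers -- a single pre-drawn cut
#' pool shared by every objective evaluation -- make the stochastic objective
#' a deterministic function of `n`, so the accepted objective is
#' non-increasing by construction.
#'
#' @param target normalized [size_histogram()] to fit (e.g. the mutant lane).
#' @param start normalized [size_histogram()] for the starting distribution
#'   (e.g. the control lane), or `NULL` to start from one intact genome.
#' @param iterations hill-climbing iterations. Default 50.
#' @param seed integer seed for the start draw and the common cut pool.
#' @param genome_nt nucleotides simulated per evaluation; defaults to the
#'   target's `total_mass_target` (1e9 if unset).
#' @param effective_df spline degrees of freedom for smoothing both
#'   histograms. Default 40.
#' @return a [frequency_estimate()] with `method = "simulation"`; the fitted
#'   cut count is in `$n_cuts` and the accepted objective per iteration in
#'   `$objective_trace`.
#' @export
hill_climb_fit <- function(target, start = NULL, iterations = 50, seed = NULL,
                           genome_nt = NULL, effective_df = 40) {
  stopifnot(inherits(target, "size_histogram"), iterations >= 1)
  if (sum(target$mass) <= 0) stop("target histogram has zero mass")
  if (!is.null(start)) {
    stopifnot(inherits(start, "size_histogram"))
    if (!isTRUE(all.equal(target$bin_edges, start$bin_edges)))
      stop("target and start must share bin edges")
    if (sum(start$mass) <= 0)
      stop("target and start histograms have non-overlapping support")
    # random cuts only shrink fragments: a target with mass at larger sizes
    # than any start mass cannot be reached
    if (max(which(target$mass > 0)) > max(which(start$mass > 0)))
      stop("target has mass at larger fragment sizes than the start; random cuts cannot reach it")
  }
  if (is.null(genome_nt))
    genome_nt <- if (is.finite(target$total_mass_target))
      target$total_mass_target else 1e9
  if (!is.null(seed)) set.seed(seed)

  window <- range(target$bin_edges)
  n_bins <- length(target$mass)
  target_sm <- smooth_histogram_counts(target, effective_df)
  start_lengths <- draw_start_fragments(start, genome_nt)

  pool <- new.env(parent = emptyenv())
  pool$u <- stats::runif(1e5)
  get_cuts <- function(n) {
    while (length(pool$u) < n) pool$u <- c(pool$u, stats::runif(length(pool$u)))
    if (n == 0) numeric(0) else pool$u[seq_len(n)] * genome_nt
  }
  objective <- function(n) {
    lens <- apply_cuts(start_lengths, sort(get_cuts(n)))
    h <- fragment_histogram(lens[lens >= 1], window = window, n_bins = n_bins)
    h <- normalize_and_count(h, target$total_mass_target %||% 1e9)
    sum(abs(smooth_histogram_counts(h, effective_df) - target_sm))
  }

  init <- fragment_count(target) - if (is.null(start)) 1 else fragment_count(start)
  best <- max(0, round(init))
  f_best <- objective(best)
  trace <- numeric(iterations + 1)
  trace[1] <- f_best
  step <- 0.5
  for (it in seq_len(iterations)) {
    up <- max(best + 1, round(best * (1 + step)))
    down <- max(0, min(best - 1, round(best * (1 - step))))
    cand <- unique(c(up, down))
    f_cand <- vapply(cand, objective, 0)
    if (min(f_cand) < f_best) {
      best <- cand[which.min(f_cand)]
      f_best <- min(f_cand)
    } else {
      step <- step / 2
    }
    trace[it + 1] <- f_best
  }
  new_frequency_estimate(rate = best / genome_nt,
                         delta_fragments = best * (1e9 / genome_nt),
                         method = "simulation",
                         total_mass_target = target$total_mass_target %||% 1e9,
                         n_cuts = best,
                         objective_trace = trace)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Estimate the embedded-ribonucleotide rate from a mutant/control lane pair
#'
#' Front end to the two estimators: `"analytic"` fragment-count subtraction
#' ([analytic_estimate()]) or `"simulation"` random-cut fitting by hill
#' climbing ([hill_climb_fit()]).
#'
#' @param mutant,control normalized [size_histogram()]s (lists of replicate
#'   pairs are accepted for the analytic method).
#' @param method `"analytic"` or `"simulation"`.
#' @param ... passed to the selected estimator.
#' @return a [frequency_estimate()].
#' @export
estimate_ribo_rate <- function(mutant, control,
                               method = c("analytic", "simulation"), ...) {
  method <- match.arg(method)
  switch(method,
         analytic = analytic_estimate(mutant, control),
         simulation = {
           if (!inherits(mutant, "size_histogram")) mutant <- mutant[[1]]
           if (!inherits(control, "size_histogram")) control <- control[[1]]
           hill_climb_fit(mutant, control, ...)
         })
}

#' Ribonucleotide sites per cell
#'
#' `haploid_bp * ploidy * 2 strands * rate`: at the defaults (2.5e9 bp
#' haploid, diploid) a nucleus contains 1e10 nt of DNA, so a frequency of 1 in
#' 7,600 nt implies ~1.3 million sites per cell.
#'
#' @param estimate a [frequency_estimate()], or a numeric per-nt rate.
#' @param constants a [genome_constants()].
#' @return expected site count per cell.
#' @examples
#' sites_per_cell(1 / 7600)  # 1,315,789
#' @export
sites_per_cell <- function(estimate, constants = genome_constants()) {
  rate <- if (inherits(estimate, "frequency_estimate")) estimate$rate
          else as.numeric(estimate)
  stopifnot(rate >= 0, inherits(constants, "genome_constants"))
  constants$haploid_bp * constants$ploidy * constants$strands_per_bp * rate
}

#' Count-weighted mean fragment size of a histogram
#'
#' @param hist a [size_histogram()] with positive total count.
#' @return `sum(counts * mid) / sum(counts)` in nt.
#' @export
mean_fragment_size <- function(hist) {
  stopifnot(inherits(hist, "size_histogram"))
  tot <- sum(hist$counts)
  if (tot <= 0) stop("histogram has no fragments")
  sum(hist$counts * bin_mids(hist)) / tot
}
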