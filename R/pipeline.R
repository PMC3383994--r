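#' Run configuration for synthetic datasets and the analysis pipeline
#'
#' Bundles every tunable of a reproducible run: the root seed (all lane-level
#' randomness is derived from it via named substreams), genome size, the
#' lesion models of the control (shear-only) and mutant (shear + ribo runs)
#' lanes, the cleavage agent, the gel model, and the analysis settings.
#'
#' @param seed root integer seed.
#' @param genome_nt duplex genome length per lane, nt.
#' @param n_replicates number of mutant/control lane pairs.
#' @param control_model,mutant_model [lesion_model()]s for the two conditions.
#' @param agent [cleavage_agent()] applied before electrophoresis.
#' @param gel [gel_model()]. The default emulates equal lane loading: the same
#'   total DNA mass is applied to the gel whatever `genome_nt` is, so
#'   `mass_scale` is scaled by `1e9 / genome_nt`.
#' @param effective_df spline degrees of freedom for trace smoothing.
#' @param n_bins,window size-histogram binning.
#' @param total_mass_target nucleotide total each lane is normalized to.
#' @param iterations hill-climbing iterations.
#' @param ladder_sizes ladder fragment sizes, nt.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       genome_nt = 1e9,
                       n_replicates = 4,
                       control_model = lesion_model(ribo_rate = 0),
                       mutant_model = lesion_model(),
                       agent = cleavage_agent("alkali"),
                       gel = gel_model(mass_scale = 1e-6 * (1e9 / genome_nt)),
                       effective_df = 40,
                       n_bins = 200,
                       window = c(200, 1e5),
                       total_mass_target = 1e9,
                       iterations = 50,
                       ladder_sizes = c(0.5, 1, 1.6, 2, 3, 4, 5, 6, 8, 10, 12) * 1e3) {
  stopifnot(genome_nt >= 1, n_replicates >= 1,
            inherits(control_model, "lesion_model"),
            inherits(mutant_model, "lesion_model"),
            inherits(agent, "cleavage_agent"), inherits(gel, "gel_model"))
  structure(list(seed = as.integer(seed), genome_nt = genome_nt,
                 n_replicates = as.integer(n_replicates),
                 control_model = control_model, mutant_model = mutant_model,
                 agent = agent, gel = gel, effective_df = effective_df,
                 n_bins = n_bins, window = window,
                 total_mass_target = total_mass_target,
                 iterations = iterations, ladder_sizes = ladder_sizes),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Only scalar/vector settings are configurable from YAML (seed, genome_nt,
#' n_replicates, rates, gel parameters, analysis settings); unspecified keys
#' keep the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  num <- function(key, default) if (is.null(y[[key]])) default else as.numeric(y[[key]])
  gel_args <- y$gel %||% list()
  gel <- do.call(gel_model, lapply(gel_args, as.numeric))
  run_config(seed = num("seed", 1),
             genome_nt = num("genome_nt", 1e9),
             n_replicates = num("n_replicates", 4),
             control_model = lesion_model(
               ribo_rate = num("control_ribo_rate", 0),
               shear_rate = num("shear_rate", 1 / 30000)),
             mutant_model = lesion_model(
               ribo_rate = num("mutant_ribo_rate", 1 / 7600),
               shear_rate = num("shear_rate", 1 / 30000),
               rate_multiplier = num("rate_multiplier", 1)),
             agent = cleavage_agent(y$agent %||% "alkali"),
             gel = gel,
             effective_df = num("effective_df", 40),
             n_bins = num("n_bins", 200),
             window = if (is.null(y$window)) c(200, 1e5) else as.numeric(y$window),
             total_mass_target = num("total_mass_target", 1e9),
             iterations = num("iterations", 50))
}

lane_seed_table <- function(config) {
  set.seed(config$seed)
  n <- config$n_replicates
  seeds <- sample.int(.Machine$integer.max - 1L, 4 * n + 1L)
  list(ladder = seeds[1],
       control_genome = seeds[1 + seq_len(n)],
       mutant_genome = seeds[1 + n + seq_len(n)],
       control_noise = seeds[1 + 2 * n + seq_len(n)],
       mutant_noise = seeds[1 + 3 * n + seq_len(n)])
}

#' Generate a synthetic gel dataset
#'
#' Writes, for each replicate, control (shear-only) and mutant (shear + ribo
#' runs) lanes: the undigested and digested fragment sets (TSV), and the
#' rendered densitometry trace of the digested lane (TSV); plus a ladder lane
#' with its supervised annotation, a YAML lane manifest, and a generator-truth
#' TSV with true rates and fragment counts for oracle checks. Every file is a
#' deterministic function of the configuration seed.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly, as a list.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- lane_seed_table(config)
  gel <- config$gel

  lad <- render_ladder(config$ladder_sizes, gel, seed = seeds$ladder)
  write_trace(lad$trace, file.path(dir, "ladder.tsv"))
  write_annotation(lad$annotation, file.path(dir, "ladder_annotation.tsv"))

  lanes <- list()
  truth <- list()
  for (r in seq_len(config$n_replicates)) {
    for (cond in c("control", "mutant")) {
      model <- if (cond == "control") config$control_model else config$mutant_model
      gseed <- seeds[[paste0(cond, "_genome")]][r]
      nseed <- seeds[[paste0(cond, "_noise")]][r]
      genome <- simulate_genome(config$genome_nt, model, seed = gseed)
      pre <- electrophorese(genome, "denaturing")
      dig <- digest(genome, config$agent)
      post <- electrophorese(dig, "denaturing")
      base <- sprintf("%s_rep%d", cond, r)
      write_fragments(pre, file.path(dir, paste0(base, "_predigest_fragments.tsv")))
      write_fragments(post, file.path(dir, paste0(base, "_fragments.tsv")))
      tr <- withCallingHandlers(
        render_trace(post, gel, seed = nseed, lane_label = base),
        warning = function(w) invokeRestart("muffleWarning"))
      write_trace(tr, file.path(dir, paste0(base, "_trace.tsv")))
      lanes[[base]] <- list(role = cond, replicate = r,
                            trace = paste0(base, "_trace.tsv"),
                            fragments = paste0(base, "_fragments.tsv"))
      truth[[base]] <- data.frame(
        lane = base, condition = cond, replicate = r,
        ribo_rate = model$ribo_rate * model$rate_multiplier,
        shear_rate = model$shear_rate,
        n_fragments = length(post$lengths),
        total_nt = sum(post$lengths),
        mean_fragment_nt = mean(post$lengths),
        genome_seed = gseed)
    }
  }
  manifest <- list(seed = config$seed, genome_nt = config$genome_nt,
                   agent = config$agent$name,
                   ladder = "ladder.tsv",
                   ladder_annotation = "ladder_annotation.tsv",
                   lanes = lanes)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  utils::write.table(do.call(rbind, truth), file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

quantify_lane <- function(trace, cal, config) {
  tr <- subtract_background(trace, "auto")
  tr <- smooth_trace(tr, config$effective_df)
  h <- to_size_domain(tr, cal, window = config$window, n_bins = config$n_bins)
  normalize_and_count(h, config$total_mass_target)
}

#' Run the full analysis pipeline on a generated dataset
#'
#' Executes, per lane: background subtraction (auto), calibration from the
#' ladder annotation, spline smoothing, transformation to the nucleotide-size
#' domain, normalization to the configured nucleotide total and fragment
#' counting; then the analytic subtraction estimate across replicate pairs
#' and, optionally, the random-cut hill-climbing fit on each pair. Writes
#' per-lane histograms and a JSON report to `dir`.
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @param config the [run_config()] used to generate it (analysis settings and
#'   seeds are taken from here).
#' @param methods `"analytic"`, or `c("analytic", "simulation")` to add the
#'   hill-climbing fit.
#' @return a list with the aggregate `estimate` ([frequency_estimate()]),
#'   per-pair details, the calibration, and the report (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(dir, config, methods = "analytic") {
  stopifnot(inherits(config, "run_config"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (is.null(manifest$ladder_annotation) ||
      !file.exists(file.path(dir, manifest$ladder_annotation)))
    stop("missing ladder lane / annotation")
  cal <- fit_calibration(read_annotation(file.path(dir, manifest$ladder_annotation)))

  lanes <- manifest$lanes
  hists <- lapply(lanes, function(l) {
    quantify_lane(read_trace(file.path(dir, l$trace)), cal, config)
  })
  for (nm in names(hists))
    write_histogram(hists[[nm]], file.path(dir, paste0(nm, "_histogram.tsv")))

  reps <- sort(unique(vapply(lanes, function(l) l$replicate, 0)))
  mut <- lapply(reps, function(r) hists[[sprintf("mutant_rep%d", r)]])
  ctl <- lapply(reps, function(r) hists[[sprintf("control_rep%d", r)]])
  est <- analytic_estimate(mut, ctl)

  sim <- NULL
  if ("simulation" %in% methods) {
    set.seed(config$seed + 1L)
    sim_seeds <- sample.int(.Machine$integer.max - 1L, length(reps))
    sim <- lapply(seq_along(reps), function(i) {
      hill_climb_fit(mut[[i]], ctl[[i]], iterations = config$iterations,
                     seed = sim_seeds[i], effective_df = config$effective_df)
    })
  }

  report <- list(
    schema_version = "1.0",
    settings = list(seed = config$seed, genome_nt = config$genome_nt,
                    effective_df = config$effective_df, n_bins = config$n_bins,
                    window = config$window,
                    total_mass_target = config$total_mass_target,
                    agent = config$agent$name),
    calibration = list(alpha = cal$alpha, beta = cal$beta,
                       residual_sd = cal$residual_sd),
    analytic = list(delta_fragments = est$delta_fragments,
                    rate = est$rate, spacing = est$spacing,
                    replicate_spacings = est$replicate_spacings,
                    spacing_sd = est$spacing_sd),
    simulation = if (!is.null(sim)) list(
      n_cuts = vapply(sim, function(s) s$n_cuts, 0),
      spacings = vapply(sim, function(s) s$spacing, 0)))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(estimate = est, simulation = sim, calibration = cal,
       histograms = hists, report = report)
}
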