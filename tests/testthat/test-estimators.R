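test_that("identical lanes give a zero rate, reported gracefully", {
  h <- normalize_and_count(fragment_histogram(exp_fragments(2e4, 1e4, 1)), 1e9)
  est <- analytic_estimate(h, h)
  expect_equal(est$rate, 0)
  expect_identical(est$spacing, Inf)
  # control more fragmented than mutant: rate 0 with a note, not an error
  hc <- normalize_and_count(fragment_histogram(exp_fragments(4e4, 5e3, 2)), 1e9)
  est2 <- analytic_estimate(h, hc)
  expect_equal(est2$rate, 0)
  expect_match(est2$note, "no detectable")
})

test_that("analytic subtraction recovers added Poisson cuts (noise-free forward model)", {
  # Poisson additivity oracle: extra cuts at 1/7,600 on top of 1/30,000 shear
  gel <- quiet_gel()
  cal <- default_cal(gel)
  gm <- simulate_genome(2e8, lesion_model(seed = 301))
  gc <- simulate_genome(2e8, lesion_model(ribo_rate = 0, seed = 301))
  quant <- function(g) {
    fr <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
    tr <- suppressWarnings(render_trace(fr, gel))
    normalize_and_count(to_size_domain(smooth_trace(tr, 40), cal), 1e9)
  }
  est <- analytic_estimate(quant(gm), quant(gc))
  expect_lt(abs(est$spacing - 7600) / 7600, 0.05)
})

test_that("the random-cut simulator fragments uniformly", {
  # no cuts: the intact genome
  h0 <- simulate_fragment_histogram(0, genome_nt = 1e9, seed = 1)
  expect_equal(sum(h0$counts), 1)
  expect_equal(sum(h0$mass), 1e9)

  # 131,579 cuts on 1e9 nt: mean ~7,600, sizes ~exponential
  h <- simulate_fragment_histogram(131579, genome_nt = 1e9, seed = 2)
  expect_lt(abs(mean_fragment_size(h) - 7600) / 7600, 0.03)
  p_obs <- h$mass / sum(h$mass)
  p_exp <- diff(stats::pgamma(h$bin_edges, shape = 2, scale = 7600))
  expect_lt(sum(abs(p_obs - p_exp / sum(p_exp))), 0.05)

  # adding cuts stochastically shrinks fragments
  h_more <- simulate_fragment_histogram(3e5, genome_nt = 1e9, seed = 2)
  expect_lt(mean_fragment_size(h_more), mean_fragment_size(h))
})

test_that("hill climbing recovers a known cut count with a monotone objective", {
  target <- normalize_and_count(
    simulate_fragment_histogram(131579, genome_nt = 1e9, seed = 99), 1e9)
  fit <- hill_climb_fit(target, start = NULL, iterations = 50, seed = 123)
  expect_lt(abs(fit$n_cuts - 131579) / 131579, 0.1)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_equal(fit$rate, fit$n_cuts / 1e9)

  # target = start: optimum stays at (essentially) zero added cuts
  ctl <- normalize_and_count(
    simulate_fragment_histogram(33333, genome_nt = 1e9, seed = 7), 1e9)
  fit0 <- hill_climb_fit(ctl, ctl, iterations = 20, seed = 11)
  expect_lt(fit0$n_cuts, 0.005 * 33333)

  # a target coarser than its start is unreachable by adding cuts
  expect_error(hill_climb_fit(ctl, target), "cannot reach")
})

test_that("simulation and analytic estimates agree on matched synthetic lanes", {
  gel <- quiet_gel()
  cal <- default_cal(gel)
  gm <- simulate_genome(2e8, lesion_model(seed = 401))
  gc <- simulate_genome(2e8, lesion_model(ribo_rate = 0, seed = 401))
  quant <- function(g) {
    fr <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
    tr <- suppressWarnings(render_trace(fr, gel))
    normalize_and_count(to_size_domain(smooth_trace(tr, 40), cal), 1e9)
  }
  hm <- quant(gm); hc <- quant(gc)
  ana <- analytic_estimate(hm, hc)
  sim <- hill_climb_fit(hm, hc, iterations = 50, seed = 402)
  expect_lt(abs(sim$spacing - ana$spacing) / ana$spacing, 0.3)
})

test_that("per-cell arithmetic multiplies out the diploid genome", {
  expect_equal(sites_per_cell(0), 0)
  est <- ribofrag:::new_frequency_estimate(1 / 7600, 1e9 / 7600, "analytic")
  expect_equal(sites_per_cell(est), 1e10 / 7600)
  expect_gt(sites_per_cell(est), 1.3e6)
  expect_gt(sites_per_cell(est), 1e6)
  # halve ploidy, halve the burden
  expect_equal(sites_per_cell(est, genome_constants(ploidy = 1)), 5e9 / 7600)
})

test_that("mean fragment size is the count-weighted mean", {
  h1 <- size_histogram(c(5000, 2e4), 1e6)  # single bin, mid 10,000
  expect_equal(mean_fragment_size(h1), 10000)
  h2 <- fragment_histogram(exp_fragments(2e5, 7600, seed = 88))
  expect_lt(abs(mean_fragment_size(h2) - 7600) / 7600, 0.03)
  expect_error(mean_fragment_size(size_histogram(c(1, 2), 0)), "no fragments")
})

test_that("estimate_ribo_rate dispatches to both methods with S3 accessors", {
  hm <- normalize_and_count(
    simulate_fragment_histogram(150000, genome_nt = 5e8, seed = 5), 1e9)
  hc <- normalize_and_count(
    simulate_fragment_histogram(20000, genome_nt = 5e8, seed = 5), 1e9)
  ana <- estimate_ribo_rate(hm, hc, method = "analytic")
  expect_s3_class(ana, "frequency_estimate")
  expect_named(coef(ana), c("rate", "spacing", "delta_fragments"))
  expect_equal(unname(coef(ana)["spacing"]), 1 / ana$rate)

  sim <- estimate_ribo_rate(hm, hc, method = "simulation", seed = 6,
                            iterations = 20)
  expect_identical(sim$method, "simulation")
  expect_output(print(ana), "ribonucleotide every")
  expect_output(print(summary(ana)), "sites per cell")
})

test_that("replicate estimates report a spacing SD that brackets the truth", {
  gel <- quiet_gel()
  cal <- default_cal(gel)
  quant <- function(g) {
    fr <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
    tr <- suppressWarnings(render_trace(fr, gel))
    normalize_and_count(to_size_domain(smooth_trace(tr, 40), cal), 1e9)
  }
  pairs <- lapply(1:4, function(r) {
    gm <- simulate_genome(1e8, lesion_model(seed = 500 + r))
    gc <- simulate_genome(1e8, lesion_model(ribo_rate = 0, seed = 500 + r))
    list(m = quant(gm), c = quant(gc))
  })
  est <- analytic_estimate(lapply(pairs, `[[`, "m"), lapply(pairs, `[[`, "c"))
  expect_length(est$replicate_spacings, 4)
  expect_false(is.na(est$spacing_sd))
  half_width <- max(2 * est$spacing_sd, 0.05 * 7600)
  expect_lt(abs(mean(est$replicate_spacings) - 7600), half_width)
})

test_that("estimators are consistent across the study's range of spacings", {
  # true spacings from 20 kb down to the 3.7-kb nickase scale, 3 replicates
  # each on reduced (1e8 nt) genomes with equal-loading gels
  gel <- gel_model(mass_scale = 1e-6 * (1e9 / 1e8))
  cal <- default_cal(gel)
  quant <- function(g) {
    fr <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
    tr <- suppressWarnings(render_trace(fr, gel, seed = 1))
    quantify_trace(tr, cal)
  }
  spacings <- c(20000, 11000, 7600, 3700)
  res <- expand.grid(spacing = spacings, rep = 1:3)
  res$analytic <- NA_real_
  res$simulation <- NA_real_
  for (i in seq_len(nrow(res))) {
    sp <- res$spacing[i]
    seed <- 9000 + 10 * res$rep[i] + match(sp, spacings)
    gm <- simulate_genome(1e8, lesion_model(ribo_rate = 1 / sp, seed = seed))
    gc <- simulate_genome(1e8, lesion_model(ribo_rate = 0, seed = seed))
    hm <- quant(gm); hc <- quant(gc)
    res$analytic[i] <- analytic_estimate(hm, hc)$spacing
    res$simulation[i] <- hill_climb_fit(hm, hc, iterations = 25,
                                        seed = seed + 1)$spacing
  }
  bias <- function(est) abs(est - res$spacing) / res$spacing
  expect_lt(stats::median(bias(res$analytic)), 0.10)
  expect_lt(stats::median(bias(res$simulation)), 0.15)
})

test_that("the mutant lane is bracketed by the nickase reference ladders", {
  # fragment sizes at the 7,600-nt ribo spacing lie between Poisson nickase
  # digests at 3,700 and 11,000 nt (stochastic ordering)
  frag_lengths <- function(model, seed) {
    g <- simulate_genome(5e7, model, seed = seed)
    electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")$lengths
  }
  mut <- frag_lengths(lesion_model(shear_rate = 0), 801)
  nk37 <- frag_lengths(lesion_model(ribo_rate = 0, nick_rate = 1 / 3700,
                                    shear_rate = 0), 802)
  nk110 <- frag_lengths(lesion_model(ribo_rate = 0, nick_rate = 1 / 11000,
                                     shear_rate = 0), 803)
  qs <- c(0.25, 0.5, 0.75)
  expect_true(all(stats::quantile(nk37, qs) < stats::quantile(mut, qs)))
  expect_true(all(stats::quantile(mut, qs) < stats::quantile(nk110, qs)))
  expect_gt(mean(mut), mean(nk37))
  expect_lt(mean(mut), mean(nk110))
})
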