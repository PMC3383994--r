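test_that("an all-zero lesion model yields a pristine genome", {
  m <- lesion_model(ribo_rate = 0, nick_rate = 0, shear_rate = 0)
  g <- simulate_genome(1e6, m, seed = 1)
  expect_s3_class(g, "lesion_genome")
  expect_identical(nrow(g$lesions), 0L)
})

test_that("lesion counts are Poisson with the stated means and scale with the multiplier", {
  # closed-form Poisson moments: mean 2e8/7600 across both strands, sd sqrt(mean)
  m <- lesion_model(ribo_rate = 1 / 7600, shear_rate = 0)
  g <- simulate_genome(1e8, m, seed = 101)
  n_runs <- sum(g$lesions$kind == "ribo_run")
  mu <- 2e8 / 7600
  expect_lt(abs(n_runs - mu), 4 * sqrt(mu))

  m2 <- lesion_model(ribo_rate = 1 / 7600, shear_rate = 0, rate_multiplier = 2)
  g2 <- simulate_genome(1e8, m2, seed = 202)
  n2 <- sum(g2$lesions$kind == "ribo_run")
  expect_lt(abs(n2 - 2 * mu), 4 * sqrt(2 * mu))

  # reproducible under a fixed seed
  g_again <- simulate_genome(1e8, m, seed = 101)
  expect_identical(g$lesions, g_again$lesions)
})

test_that("simulate_genome validates its inputs", {
  expect_error(simulate_genome(0, lesion_model()), "length")
  expect_error(lesion_model(run_length_dist = c("1" = 0.5, "2" = 0.4)), "sum to 1")
  expect_error(lesion_model(ribo_rate = -1))
})

test_that("cleavage conventions place the nick on the declared side of the run", {
  run <- data.frame(strand = "top", position = 10, run_length = 1L,
                    kind = "ribo_run")
  g <- lesion_genome(100, run)

  alk <- digest(g, cleavage_agent("alkali"))   # 3' cut: bond between 10 and 11
  expect_identical(alk$lesions$kind, "nick")
  expect_equal(alk$lesions$position, 10)
  fr_alk <- electrophorese(alk, "denaturing")
  expect_setequal(fr_alk$lengths, c(10, 90, 100))

  h2 <- digest(g, cleavage_agent("rnaseh2"))   # 5' cut: bond between 9 and 10
  expect_equal(h2$lesions$position, 9)
  fr_h2 <- electrophorese(h2, "denaturing")
  expect_setequal(fr_h2$lengths, c(9, 91, 100))

  # brute-force cut-list diff: downstream fragment boundaries differ by 1 nt
  expect_equal(sort(fr_alk$lengths)[1] - sort(fr_h2$lengths)[1], 1)
})

test_that("RNase HI leaves mono- and di-ribonucleotide genomes untouched", {
  set.seed(3)
  runs <- data.frame(strand = rep(c("top", "bottom"), each = 20),
                     position = seq(100, 4000, length.out = 40),
                     run_length = rep(c(1L, 2L), 20),
                     kind = "ribo_run")
  g <- lesion_genome(5000, runs)
  out <- digest(g, cleavage_agent("rnasehi"))
  expect_identical(out$lesions[, c("strand", "position", "run_length", "kind")],
                   g$lesions[, c("strand", "position", "run_length", "kind")])
  # but a >= 3 run is cleaved, at the 5' boundary
  g3 <- lesion_genome(5000, data.frame(strand = "top", position = 1000,
                                       run_length = 3L, kind = "ribo_run"))
  out3 <- digest(g3, cleavage_agent("rnasehi"))
  expect_identical(out3$lesions$kind, "nick")
  expect_equal(out3$lesions$position, 999)
})

test_that("denaturing electrophoresis conserves per-strand length exactly", {
  for (seed in 1:3) {
    g <- simulate_genome(2e6, lesion_model(ribo_rate = 1 / 5000,
                                           nick_rate = 1 / 8000,
                                           shear_rate = 1 / 20000), seed = seed)
    dig <- digest(g, cleavage_agent("alkali"))
    fr <- electrophorese(dig, "denaturing")
    expect_equal(sum(fr$lengths), 2 * g$length)
  }
  # no nicks at all: two full-length strands
  g0 <- lesion_genome(1234, data.frame(strand = "top", position = 50,
                                       run_length = 1L, kind = "ribo_run"))
  fr0 <- electrophorese(g0, "denaturing")
  expect_equal(fr0$lengths, c(1234, 1234))
})

test_that("Poisson nicking gives exponential fragments with mean 1/rate", {
  g <- simulate_genome(1e8, lesion_model(ribo_rate = 0, nick_rate = 1 / 11000,
                                         shear_rate = 0), seed = 9)
  fr <- electrophorese(g, "denaturing")
  expect_lt(abs(mean(fr$lengths) - 11000) / 11000, 0.05)

  # goodness of fit against the exponential at ~1e5 fragments
  g2 <- simulate_genome(5e8, lesion_model(ribo_rate = 0, nick_rate = 1 / 10000,
                                          shear_rate = 0), seed = 10)
  lens <- electrophorese(g2, "denaturing")$lengths
  ks <- suppressWarnings(stats::ks.test(lens, "pexp", 1 / mean(lens)))
  expect_gt(ks$p.value, 0.001)
})

test_that("alkali and RNase H2 digests are equivalent to within the cut-side offset", {
  g <- simulate_genome(5e6, lesion_model(ribo_rate = 1 / 5000, shear_rate = 0),
                       seed = 21)
  fr_alk <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
  fr_h2 <- electrophorese(digest(g, cleavage_agent("rnaseh2")), "denaturing")
  expect_equal(length(fr_alk$lengths), length(fr_h2$lengths))
  # per-strand, in genomic order, interior fragments differ by at most 1 nt;
  # the two chromosome-end fragments by at most the run length (2 nt)
  for (s in c("top", "bottom")) {
    ga <- digest(g, cleavage_agent("alkali"))
    gh <- digest(g, cleavage_agent("rnaseh2"))
    cuts_a <- ga$lesions$position[ga$lesions$strand == s]
    cuts_h <- gh$lesions$position[gh$lesions$strand == s]
    fa <- diff(c(0, sort(cuts_a), g$length))
    fh <- diff(c(0, sort(cuts_h), g$length))
    d <- abs(fa - fh)
    n <- length(d)
    expect_true(all(d[-c(1, n)] <= 1))
    expect_true(all(d <= 2))
  }
})

test_that("native electrophoresis hides ribonucleotides and isolated nicks", {
  mut <- simulate_genome(1e7, lesion_model(ribo_rate = 1 / 7600,
                                           shear_rate = 1 / 30000), seed = 55)
  ctl <- simulate_genome(1e7, lesion_model(ribo_rate = 0,
                                           shear_rate = 1 / 30000), seed = 55)
  # same shear substream: native fragments identical with or without ribo runs
  expect_equal(electrophorese(mut, "native")$lengths,
               electrophorese(ctl, "native")$lengths)
  # a lone single-strand nick does not break the duplex
  g1 <- lesion_genome(1e4, data.frame(strand = "top", position = 5000,
                                      run_length = 1L, kind = "nick"))
  expect_equal(electrophorese(g1, "native")$lengths, 1e4)
  # opposing nicks within the window do
  g2 <- lesion_genome(1e4, data.frame(strand = c("top", "bottom"),
                                      position = c(5000, 5004),
                                      run_length = 1L, kind = "nick"))
  expect_equal(sort(electrophorese(g2, "native", ds_break_window = 10)$lengths),
               c(5000, 5000))
  expect_equal(electrophorese(g2, "native", ds_break_window = 2)$lengths, 1e4)
})

test_that("raising the rate multiplier stochastically shortens fragments", {
  frag_mean <- function(mult, seed) {
    g <- simulate_genome(2e7, lesion_model(rate_multiplier = mult), seed = seed)
    mean(electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")$lengths)
  }
  m1 <- frag_mean(1, 77)
  m2 <- frag_mean(2, 77)
  expect_lt(m2, m1)
  # ECDF dominance at the quartiles
  g1 <- simulate_genome(2e7, lesion_model(rate_multiplier = 1), seed = 78)
  g2 <- simulate_genome(2e7, lesion_model(rate_multiplier = 3), seed = 78)
  l1 <- electrophorese(digest(g1, cleavage_agent("alkali")), "denaturing")$lengths
  l2 <- electrophorese(digest(g2, cleavage_agent("alkali")), "denaturing")$lengths
  expect_true(all(stats::quantile(l2, c(0.25, 0.5, 0.75)) <
                  stats::quantile(l1, c(0.25, 0.5, 0.75))))
})

test_that("opposed-pair expectation matches Monte-Carlo coincidence counting", {
  expect_equal(opposed_pair_expectation(1e6, 0), 0)
  expect_error(opposed_pair_expectation(1e6, 1.5), "<= 1")

  # brute-force oracle: Bernoulli sites on both strands of a small genome
  set.seed(42)
  bp <- 2e4; rate <- 0.02; reps <- 400
  hits <- replicate(reps, {
    top <- stats::rbinom(bp, 1, rate)
    bot <- stats::rbinom(bp, 1, rate)
    sum(top & bot)
  })
  mc <- mean(hits)
  se <- stats::sd(hits) / sqrt(reps)
  expect_lt(abs(opposed_pair_expectation(bp, rate) - mc), 4 * se)

  # the in-genome arithmetic: ~43 haploid, ~87 diploid at 1/7600
  expect_equal(opposed_pair_expectation(2.5e9, 1 / 7600), 43.28, tolerance = 1e-3)
  expect_equal(opposed_pair_expectation(5e9, 1 / 7600), 86.57, tolerance = 1e-3)
})

test_that("genomes and fragment sets round-trip through TSV", {
  g <- simulate_genome(1e5, lesion_model(ribo_rate = 1 / 2000), seed = 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_genome(g, p)
  g2 <- read_genome(p)
  expect_equal(g2$length, g$length)
  expect_equal(g2$lesions$position, g$lesions$position)

  fr <- electrophorese(digest(g, cleavage_agent("alkali")), "denaturing")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, p2)
  fr2 <- read_fragments(p2)
  expect_equal(sort(fr2$lengths), sort(fr$lengths))
  expect_identical(fr2$strandedness, "single")
})
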