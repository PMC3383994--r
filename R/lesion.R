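#' Lesion model for synthetic genomes
#'
#' Describes the stochastic placement of lesions on a duplex genome:
#' ribonucleotide runs (the alkali/RNase H2-sensitive sites), pre-existing
#' single-strand nicks, and background double-strand shear breaks from DNA
#' extraction. All rates are expected events per nucleotide; lesion counts are
#' Poisson with mean `rate * length` (times `rate_multiplier` for ribo runs and
#' nicks, modelling increased polymerase ribonucleotide incorporation under
#' hydroxyurea).
#'
#' @param ribo_rate expected ribonucleotide runs per nt per strand. The default
#'   is one run every 7,600 nt, the steady-state frequency measured in
#'   RNase H2-null mouse embryonic fibroblasts.
#' @param run_length_dist named numeric vector giving the distribution of run
#'   lengths; names are run lengths (>= 1), values are probabilities summing to
#'   one. Default: 90% single ribonucleotides, 10% diribonucleotides, matching
#'   the enzymatic evidence that embedded runs are mono- or di-ribonucleotides.
#' @param nick_rate expected pre-existing single-strand nicks per nt per strand.
#' @param shear_rate expected double-strand shear breaks per nt (background
#'   fragmentation from extraction; default one per 30 kb).
#' @param rate_multiplier dimensionless multiplier applied to `ribo_rate` and
#'   `nick_rate` (hydroxyurea emulation). Shear is unaffected.
#' @param seed optional integer seed; used by [simulate_genome()] when no seed
#'   is passed there.
#' @return an object of class `lesion_model`.
#' @seealso [simulate_genome()], [cleavage_agent()]
#' @export
lesion_model <- function(ribo_rate = 1 / 7600,
                         run_length_dist = c("1" = 0.9, "2" = 0.1),
                         nick_rate = 0,
                         shear_rate = 1 / 30000,
                         rate_multiplier = 1,
                         seed = NULL) {
  stopifnot(is.numeric(ribo_rate), ribo_rate >= 0,
            is.numeric(nick_rate), nick_rate >= 0,
            is.numeric(shear_rate), shear_rate >= 0,
            is.numeric(rate_multiplier), rate_multiplier >= 0)
  if (is.null(names(run_length_dist)) ||
      any(is.na(suppressWarnings(as.integer(names(run_length_dist))))))
    stop("run_length_dist must be a named vector with integer run lengths as names")
  rl <- as.integer(names(run_length_dist))
  if (any(rl < 1L)) stop("run lengths must be >= 1")
  if (any(run_length_dist < 0) || abs(sum(run_length_dist) - 1) > 1e-8)
    stop("run_length_dist must be non-negative and sum to 1")
  structure(list(ribo_rate = ribo_rate,
                 run_length_dist = run_length_dist,
                 nick_rate = nick_rate,
                 shear_rate = shear_rate,
                 rate_multiplier = rate_multiplier,
                 seed = seed),
            class = "lesion_model")
}

#' Construct a lesion-bearing duplex genome
#'
#' A genome is represented abstractly as a duplex length plus a table of
#' lesions; no base sequence is stored, so gigabase genomes are cheap.
#' Coordinates are 1-based. A nick at position `i` marks a broken
#' phosphodiester bond between nucleotides `i` and `i + 1` of that strand;
#' valid cut positions are therefore `1 .. length - 1`. Ribonucleotide runs
#' occupy `position .. position + run_length - 1`.
#'
#' @param length duplex length in nt.
#' @param lesions data frame with columns `strand` ("top"/"bottom"),
#'   `position`, `run_length`, `kind` ("ribo_run"/"nick").
#' @param label free-text provenance label.
#' @return an object of class `lesion_genome`.
#' @export
lesion_genome <- function(length, lesions = empty_lesions(), label = "") {
  stopifnot(is.numeric(length), length >= 1)
  lesions <- as.data.frame(lesions)
  g <- structure(list(length = as.numeric(length),
                      lesions = lesions,
                      label = label),
                 class = "lesion_genome")
  validate_lesion_genome(g)
  g
}

empty_lesions <- function() {
  data.frame(strand = character(0), position = numeric(0),
             run_length = integer(0), kind = character(0),
             stringsAsFactors = FALSE)
}

validate_lesion_genome <- function(g) {
  les <- g$lesions
  need <- c("strand", "position", "run_length", "kind")
  if (!all(need %in% names(les))) stop("lesions must have columns ", paste(need, collapse = ", "))
  if (nrow(les) == 0) return(invisible(g))
  if (!all(les$strand %in% c("top", "bottom"))) stop("strand must be 'top' or 'bottom'")
  if (!all(les$kind %in% c("ribo_run", "nick"))) stop("kind must be 'ribo_run' or 'nick'")
  if (any(les$position < 1) || any(les$position + les$run_length - 1 > g$length))
    stop("lesion coordinates out of range")
  if (any(les$run_length[les$kind == "nick"] != 1L))
    stop("nicks must have run_length 1")
  # ribo runs on a strand must not overlap; nicks are zero-width bond marks and
  # only need distinct positions per strand
  for (s in c("top", "bottom")) {
    runs <- les[les$strand == s & les$kind == "ribo_run", , drop = FALSE]
    if (nrow(runs) > 1) {
      o <- order(runs$position)
      p <- runs$position[o]; r <- runs$run_length[o]
      if (any(p[-1] <= (p + r - 1)[-length(p)]))
        stop("overlapping ribo runs on strand ", s)
    }
    nk <- les$position[les$strand == s & les$kind == "nick"]
    if (anyDuplicated(nk)) stop("duplicated nick positions on strand ", s)
  }
  invisible(g)
}

#' @export
print.lesion_genome <- function(x, ...) {
  n_runs <- sum(x$lesions$kind == "ribo_run")
  n_nicks <- sum(x$lesions$kind == "nick")
  cat(sprintf("<lesion_genome> %s nt duplex%s\n  %d ribo run(s), %d nick(s)\n",
              format(x$length, big.mark = ","),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              n_runs, n_nicks))
  invisible(x)
}

# Draw n non-overlapping runs of the given lengths on one strand of a genome
# of the given length by rejection re-draw (rates are << 1/run_length so
# collisions are rare).
draw_runs <- function(genome_length, run_lengths) {
  n <- length(run_lengths)
  if (n == 0) return(numeric(0))
  pos <- numeric(n)
  todo <- seq_len(n)
  for (iter in 1:100) {
    pos[todo] <- sapply_pos(genome_length, run_lengths[todo])
    o <- order(pos)
    p <- pos[o]; r <- run_lengths[o]
    bad_sorted <- which(p[-1] <= (p + r - 1)[-n])
    if (length(bad_sorted) == 0) return(pos)
    todo <- o[bad_sorted + 1L]  # re-draw the later member of each colliding pair
  }
  stop("could not place non-overlapping lesions; rates too high for genome length")
}

sapply_pos <- function(genome_length, run_lengths) {
  # uniform start such that the run fits on the strand
  floor(stats::runif(length(run_lengths)) * (genome_length - run_lengths + 1)) + 1
}

#' Simulate a lesion-bearing genome
#'
#' Lesion counts per strand are Poisson with mean `rate * length` (ribo runs
#' and nicks additionally scaled by `rate_multiplier`); positions are uniform,
#' with overlapping draws resolved by rejection re-draw. Shear breaks are
#' double-strand breaks and are stored as a pair of nicks at the same position
#' on both strands. Three independent RNG substreams (ribo, nick, shear) are
#' derived from the seed, so genomes differing only in `ribo_rate` share
#' identical shear breaks under the same seed.
#'
#' @param length duplex length in nt (>= 1).
#' @param model a [lesion_model()].
#' @param seed integer seed; defaults to `model$seed`. If both are `NULL` the
#'   current RNG state is used.
#' @return a [lesion_genome()].
#' @examples
#' g <- simulate_genome(1e6, lesion_model(seed = 1))
#' g
#' @export
simulate_genome <- function(length, model, seed = model$seed) {
  stopifnot(inherits(model, "lesion_model"), is.numeric(length), length >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  mult <- model$rate_multiplier

  set.seed(sub[1])  # ribo substream
  rl_support <- as.integer(names(model$run_length_dist))
  ribo <- lapply(c("top", "bottom"), function(s) {
    n <- stats::rpois(1, model$ribo_rate * length * mult)
    if (n == 0) return(NULL)
    rl <- sample(rl_support, n, replace = TRUE, prob = model$run_length_dist)
    data.frame(strand = s, position = draw_runs(length, rl),
               run_length = rl, kind = "ribo_run", stringsAsFactors = FALSE)
  })

  set.seed(sub[2])  # nick substream
  nicks <- lapply(c("top", "bottom"), function(s) {
    n <- stats::rpois(1, model$nick_rate * length * mult)
    if (n == 0) return(NULL)
    p <- unique(floor(stats::runif(n) * (length - 1)) + 1)
    data.frame(strand = s, position = p, run_length = 1L,
               kind = "nick", stringsAsFactors = FALSE)
  })

  set.seed(sub[3])  # shear substream (rate_multiplier does not apply)
  n_shear <- stats::rpois(1, model$shear_rate * length)
  shear <- NULL
  if (n_shear > 0) {
    p <- unique(floor(stats::runif(n_shear) * (length - 1)) + 1)
    shear <- data.frame(strand = rep(c("top", "bottom"), each = length(p)),
                        position = rep(p, 2), run_length = 1L,
                        kind = "nick", stringsAsFactors = FALSE)
  }

  les <- do.call(rbind, c(ribo, nicks, list(shear)))
  if (is.null(les)) les <- empty_lesions()
  # nicks from different substreams may coincide; keep one per (strand, pos)
  nk <- les$kind == "nick"
  if (any(nk)) {
    dup <- nk & duplicated(les[, c("strand", "position", "kind")])
    les <- les[!dup, , drop = FALSE]
  }
  lesion_genome(length, les)
}

#' Cleavage agents acting on ribonucleotide runs or at random
#'
#' An agent either cleaves every ribo run of at least `min_run` consecutive
#' ribonucleotides (replacing the run by one nick, on the side given by
#' `cut_side`), or -- in abstract nickase mode -- adds Poisson nicks at
#' `extra_nick_rate` per nt per strand regardless of lesions. Exactly one of
#' `min_run` / `extra_nick_rate` must be set. Presets:
#'
#' * `"alkali"` -- hot NaOH; the 2'-OH renders the bond 3' of a ribonucleotide
#'   alkali-labile, so every run (`min_run = 1`) is cut 3' of its last ribo.
#' * `"rnaseh2"` -- RNase H2 recognizes single embedded ribonucleotides and
#'   cleaves the 5'-phosphodiester bond (`min_run = 1`, 5' cut).
#' * `"rnasehi"` -- E. coli RNase HI requires at least three consecutive
#'   embedded ribonucleotides (`min_run = 3`, 5' cut).
#' * `"nickase"` -- sequence-nonspecific stand-in for a nicking endonuclease;
#'   supply `extra_nick_rate` (e.g. 1/11000 for a 7-cutter on mouse DNA).
#'
#' @param name preset name above, or any label for a custom agent.
#' @param min_run minimum run length cleaved, or `NULL` for nickase mode.
#' @param cut_side `"three_prime"` or `"five_prime"` relative to the run.
#' @param extra_nick_rate per-nt Poisson nicking rate, or `NULL`.
#' @return an object of class `cleavage_agent`.
#' @export
cleavage_agent <- function(name,
                           min_run = NULL,
                           cut_side = NULL,
                           extra_nick_rate = NULL) {
  presets <- list(
    alkali  = list(min_run = 1L, cut_side = "three_prime"),
    rnaseh2 = list(min_run = 1L, cut_side = "five_prime"),
    rnasehi = list(min_run = 3L, cut_side = "five_prime"))
  if (name %in% names(presets) && is.null(min_run) && is.null(extra_nick_rate)) {
    p <- presets[[name]]
    min_run <- p$min_run
    cut_side <- p$cut_side
  }
  if (is.null(min_run) == is.null(extra_nick_rate))
    stop("exactly one of min_run and extra_nick_rate must be set")
  if (!is.null(min_run)) {
    if (is.null(cut_side)) cut_side <- "three_prime"
    cut_side <- match.arg(cut_side, c("three_prime", "five_prime"))
    stopifnot(min_run >= 1)
  } else {
    stopifnot(extra_nick_rate >= 0)
  }
  structure(list(name = name, min_run = min_run, cut_side = cut_side,
                 extra_nick_rate = extra_nick_rate),
            class = "cleavage_agent")
}

#' @export
print.cleavage_agent <- function(x, ...) {
  if (!is.null(x$min_run))
    cat(sprintf("<cleavage_agent> %s: cleaves runs >= %d ribonucleotides (%s cut)\n",
                x$name, x$min_run, gsub("_", " ", x$cut_side)))
  else
    cat(sprintf("<cleavage_agent> %s: Poisson nicking at %.3g per nt per strand\n",
                x$name, x$extra_nick_rate))
  invisible(x)
}

#' Digest a genome with a cleavage agent
#'
#' Each ribo run with `run_length >= min_run` is replaced by a single nick:
#' 3' of the run's last ribonucleotide for `cut_side = "three_prime"` (the cut
#' bond is `position + run_length - 1`), or 5' of its first for `"five_prime"`
#' (bond `position - 1`). Runs below `min_run` are untouched. Cuts that fall on
#' a strand end (bond index outside `1 .. length - 1`) are dropped. In nickase
#' mode, Poisson nicks at `extra_nick_rate` are added on each strand instead.
#'
#' @param genome a [lesion_genome()].
#' @param agent a [cleavage_agent()].
#' @param seed integer seed (used only in nickase mode).
#' @return a [lesion_genome()] after digestion.
#' @export
digest <- function(genome, agent, seed = NULL) {
  stopifnot(inherits(genome, "lesion_genome"), inherits(agent, "cleavage_agent"))
  les <- genome$lesions
  if (!is.null(agent$min_run)) {
    cut_these <- les$kind == "ribo_run" & les$run_length >= agent$min_run
    if (any(cut_these)) {
      runs <- les[cut_these, , drop = FALSE]
      bond <- if (agent$cut_side == "three_prime")
        runs$position + runs$run_length - 1 else runs$position - 1
      ok <- bond >= 1 & bond <= genome$length - 1
      new_nicks <- data.frame(strand = runs$strand[ok], position = bond[ok],
                              run_length = 1L, kind = "nick",
                              stringsAsFactors = FALSE)
      les <- rbind(les[!cut_these, , drop = FALSE], new_nicks)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    extra <- lapply(c("top", "bottom"), function(s) {
      n <- stats::rpois(1, agent$extra_nick_rate * genome$length)
      if (n == 0) return(NULL)
      data.frame(strand = s,
                 position = unique(floor(stats::runif(n) * (genome$length - 1)) + 1),
                 run_length = 1L, kind = "nick", stringsAsFactors = FALSE)
    })
    les <- do.call(rbind, c(list(les), extra))
  }
  nk <- les$kind == "nick"
  if (any(nk)) {
    dup <- nk & duplicated(les[, c("strand", "position", "kind")])
    les <- les[!dup, , drop = FALSE]
  }
  lesion_genome(genome$length, les,
                label = paste0(genome$label,
                               if (nzchar(genome$label)) " + " else "",
                               agent$name))
}

#' Fragment multisets
#'
#' @param lengths numeric vector of fragment lengths in nt (every length >= 1).
#' @param strandedness `"single"` or `"double"`.
#' @param source provenance text.
#' @return an object of class `fragment_set`.
#' @export
fragment_set <- function(lengths, strandedness = c("single", "double"),
                         source = "") {
  strandedness <- match.arg(strandedness)
  stopifnot(all(lengths >= 1))
  structure(list(lengths = as.numeric(lengths), strandedness = strandedness,
                 source = source),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d %s-stranded fragment(s), total %s nt, mean %s nt\n",
              length(x$lengths), x$strandedness,
              format(sum(x$lengths), big.mark = ","),
              format(round(mean(x$lengths)), big.mark = ",")))
  invisible(x)
}

strand_cuts <- function(genome, strand) {
  les <- genome$lesions
  p <- les$position[les$strand == strand & les$kind == "nick"]
  sort(unique(p[p >= 1 & p <= genome$length - 1]))
}

#' Resolve a genome into fragments by gel electrophoresis mode
#'
#' Denaturing mode (alkaline gel, or formamide denaturation) separates the two
#' strands: each strand yields fragments between consecutive nicks on that
#' strand. Intact ribonucleotide runs are covalent and are NOT breaks -- only
#' nicks terminate fragments. Native mode preserves the duplex: fragments run
#' between double-strand breaks, defined as opposing-strand nicks within
#' `ds_break_window` nt of each other (this captures extraction shear, which is
#' stored as coincident nicks on both strands); isolated single-strand nicks
#' are invisible.
#'
#' @param genome a [lesion_genome()].
#' @param mode `"denaturing"` or `"native"`.
#' @param ds_break_window maximum offset (nt) between opposing nicks that
#'   counts as a double-strand break in native mode. Default 10.
#' @return a [fragment_set()]; single-stranded fragments from both strands are
#'   pooled in denaturing mode.
#' @export
electrophorese <- function(genome, mode = c("denaturing", "native"),
                           ds_break_window = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "lesion_genome"), ds_break_window >= 0)
  L <- genome$length
  if (mode == "denaturing") {
    lens <- unlist(lapply(c("top", "bottom"), function(s) {
      diff(c(0, strand_cuts(genome, s), L))
    }))
    return(fragment_set(lens[lens >= 1], "single",
                        source = paste0(genome$label, " [denaturing]")))
  }
  top <- strand_cuts(genome, "top")
  bot <- strand_cuts(genome, "bottom")
  # greedy two-pointer matching of opposing nicks within the window
  dsb <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= length(top) && j <= length(bot)) {
    if (abs(top[i] - bot[j]) <= ds_break_window) {
      dsb <- c(dsb, top[i]); i <- i + 1L; j <- j + 1L
    } else if (top[i] < bot[j]) i <- i + 1L else j <- j + 1L
  }
  lens <- diff(c(0, sort(unique(dsb)), L))
  fragment_set(lens[lens >= 1], "double",
               source = paste0(genome$label, " [native]"))
}

#' Expected number of directly opposed ribonucleotide pairs
#'
#' Under independent uniform placement at `per_strand_rate` ribonucleotide
#' sites per nt on each strand, the expected number of base-pair positions
#' carrying a ribonucleotide on both strands is `bp_count * rate^2`. Such
#' opposed pairs are candidate double-strand-break precursors upon hydrolysis.
#'
#' @param bp_count number of base pairs considered (e.g. 2.5e9 for the haploid
#'   mouse genome).
#' @param per_strand_rate ribonucleotide sites per nt per strand, in `[0, 1]`.
#' @return expected count of opposed pairs.
#' @examples
#' opposed_pair_expectation(2.5e9, 1 / 7600)  # ~43 per haploid genome
#' @export
opposed_pair_expectation <- function(bp_count, per_strand_rate) {
  stopifnot(bp_count >= 1, per_strand_rate >= 0)
  if (per_strand_rate > 1) stop("per_strand_rate must be <= 1")
  bp_count * per_strand_rate^2
}

#' Write / read fragment sets and genomes as TSV
#'
#' Fragment sets serialize as two columns (`length_nt`, `count`); genomes as
#' four (`strand`, `position`, `run_length`, `kind`) with the duplex length in
#' a `# length=` header comment.
#'
#' @param x object to write.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name lesion-io
NULL

#' @rdname lesion-io
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "fragment_set"))
  tab <- table(x$lengths)
  df <- data.frame(length_nt = as.numeric(names(tab)),
                   count = as.integer(tab))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strandedness=%s source=%s", x$strandedness, x$source), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lesion-io
#' @export
read_fragments <- function(path) {
  hdr <- readLines(path, n = 1)
  strd <- sub(".*strandedness=(\\S+).*", "\\1", hdr)
  df <- utils::read.delim(path, comment.char = "#")
  fragment_set(rep(df$length_nt, df$count),
               strandedness = if (strd %in% c("single", "double")) strd else "single",
               source = path)
}

#' @rdname lesion-io
#' @export
write_genome <- function(x, path) {
  stopifnot(inherits(x, "lesion_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# length=%.0f label=%s", x$length, x$label), con)
  utils::write.table(x$lesions, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lesion-io
#' @export
read_genome <- function(path) {
  hdr <- readLines(path, n = 1)
  len <- as.numeric(sub(".*length=(\\S+).*", "\\1", hdr))
  lab <- sub(".*label=(.*)$", "\\1", hdr)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(strand = "character", kind = "character"))
  lesion_genome(len, df, label = lab)
}
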