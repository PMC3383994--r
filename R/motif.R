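#' Nicking-endonuclease recognition motif
#'
#' @param name enzyme or motif label.
#' @param site IUPAC nucleotide string, length >= 4. Recognition strings are
#'   user-supplied configuration; standard REBASE sequences such as
#'   `"GCTCTTC"` (Nt.BspQI, 7-cutter) and `"GCAGTG"` (Nb.BtsI, 6-cutter) are
#'   typical inputs.
#' @param nicked_strand_only logical; nicking enzymes cut one strand, but
#'   recognition sites are counted on both strands of the duplex.
#' @return an object of class `motif_spec`.
#' @export
motif_spec <- function(name, site, nicked_strand_only = TRUE) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("site must be at least 4 bases")
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(strsplit(site, "")[[1]] %in% iupac))
    stop("site contains non-IUPAC characters")
  structure(list(name = name, site = site,
                 nicked_strand_only = nicked_strand_only),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s: %s (%d-cutter)\n", x$name, x$site, nchar(x$site)))
  invisible(x)
}

as_motif <- function(motif) {
  if (inherits(motif, "motif_spec")) motif else motif_spec(motif, motif)
}

#' Scan a sequence for motif sites on both strands
#'
#' Reports all 1-based match start positions of the recognition site on the
#' top strand and of its reverse complement (bottom-strand sites), in
#' top-strand coordinates. Overlapping occurrences are counted -- each site is
#' an independent nick opportunity. IUPAC ambiguity codes in the site are
#' honoured; `N` in the sequence never matches. Matching is case-insensitive.
#'
#' @param sequence character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @param motif a [motif_spec()] or a plain site string.
#' @return a list with integer vectors `top` and `bottom` (match starts) and
#'   `n_sites = length(top) + length(bottom)`.
#' @examples
#' scan_motif("GCTCTTCAAA", "GCTCTTC")$top  # 1
#' @export
scan_motif <- function(sequence, motif) {
  motif <- as_motif(motif)
  if (is.character(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
    sequence <- Biostrings::DNAString(sequence)
  }
  site <- Biostrings::DNAString(motif$site)
  # fixed = "subject": IUPAC codes in the pattern are interpreted, sequence
  # letters are literal, so N in the sequence matches nothing but pattern N
  top <- Biostrings::start(Biostrings::matchPattern(site, sequence,
                                                    fixed = "subject"))
  bottom <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::reverseComplement(site), sequence,
                             fixed = "subject"))
  list(top = as.integer(top), bottom = as.integer(bottom),
       n_sites = length(top) + length(bottom))
}

#' Mean site spacing from a site count
#'
#' Duplex spacing with both-strand sites pooled: `sequence_length / n_sites`.
#'
#' @param sequence_length sequence length in nt.
#' @param n_sites number of sites (both strands pooled).
#' @return nt per site, or `NA` (with a message) when `n_sites` is 0.
#' @export
mean_spacing <- function(sequence_length, n_sites) {
  stopifnot(sequence_length >= 1, n_sites >= 0)
  if (n_sites == 0) {
    message("no sites found; spacing undefined")
    return(NA_real_)
  }
  sequence_length / n_sites
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_revcomp <- function(site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(site, "")[[1]]]), collapse = "")
}

#' Expected site spacing under an independent-base model
#'
#' With i.i.d. bases at frequencies `base_freqs`, the per-position match
#' probability is the product over site letters of the summed frequencies of
#' the bases each IUPAC code admits. Non-palindromic sites occur on both
#' strands, so the expected duplex spacing is `1 / (2 * p)`; palindromic sites
#' coincide with their reverse complement and use factor 1.
#'
#' @param motif a [motif_spec()] or site string.
#' @param base_freqs named probabilities over `A, C, G, T`, summing to 1.
#' @return expected nt per site (duplex, both strands pooled).
#' @examples
#' expected_spacing_iid("GCTCTTC")  # 4^7 / 2 = 8192
#' @export
expected_spacing_iid <- function(motif,
                                 base_freqs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  motif <- as_motif(motif)
  stopifnot(all(c("A", "C", "G", "T") %in% names(base_freqs)))
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  letters <- strsplit(motif$site, "")[[1]]
  p <- prod(vapply(letters, function(l) sum(base_freqs[IUPAC_SETS[[l]]]), 0))
  palindromic <- identical(iupac_revcomp(motif$site), motif$site)
  1 / (p * if (palindromic) 1 else 2)
}

#' Motif spacing over a FASTA file
#'
#' Scans every record of a (multi-record) FASTA file; sites and lengths are
#' pooled across records.
#'
#' @param path FASTA file path.
#' @param motif a [motif_spec()] or site string.
#' @return a list with `n_sites`, `total_length`, and `spacing` (nt per site,
#'   both strands pooled).
#' @export
motif_spacing_fasta <- function(path, motif) {
  motif <- as_motif(motif)
  seqs <- Biostrings::readDNAStringSet(path)
  hits <- vapply(seq_along(seqs),
                 function(i) scan_motif(seqs[[i]], motif)$n_sites, 0L)
  total_length <- sum(Biostrings::width(seqs))
  n <- sum(hits)
  list(n_sites = n, total_length = total_length,
       spacing = if (n > 0) total_length / n else NA_real_)
}
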