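#' k-mer configuration
#'
#' Word length for all k-mer operations. The default, k = 31, is the
#' standard word size for metagenomic k-mer matching: long enough to be
#' effectively unique in microbial pan-genomes, short enough to tolerate
#' moderate read error. Odd k guarantees no k-mer equals its own reverse
#' complement; even k is accepted and palindromes canonicalize to
#' themselves deterministically.
#'
#' @param k positive integer word length, at least 2 (the anchor criterion
#'   needs at least two k-mer windows per read).
#' @return an object of class `kmer_config`.
#' @export
#' @examples
#' kmer_config(31)
kmer_config <- function(k = 31L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("k must be a single integer >= 2")
  if (k %% 2L == 0L)
    warning("even k admits palindromic k-mers; they canonicalize to themselves")
  structure(list(k = k), class = "kmer_config")
}

#' @export
print.kmer_config <- function(x, ...) {
  cat("<kmer_config> k =", x$k, "\n")
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised Watson-Crick reverse complement over the alphabet
#' \{A, C, G, T, N\}; N is self-complementary. Lowercase input is
#' uppercased. Any other character is an error naming its position.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements, uppercase.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(seq) {
  .cpp_revcomp(as.character(seq))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' word and its reverse complement; it identifies the two strands. Errors
#' on non-ACGT characters.
#'
#' @param kmers character vector of k-mers (ACGT only; any common length).
#' @return character vector of canonical k-mers.
#' @export
canonicalize <- function(kmers) {
  .cpp_canonicalize(as.character(kmers))
}

#' Enumerate canonical k-mers of a sequence
#'
#' Slides a window of width k over the sequence and emits the canonical
#' k-mer of every window consisting solely of A/C/G/T. Windows containing
#' any other character (N, ambiguity codes) are skipped, but start
#' positions are preserved so adjacency of surviving windows can still be
#' judged. For a clean sequence of length L there are exactly
#' max(0, L - k + 1) rows.
#'
#' @param seq a single DNA sequence.
#' @param cfg a [kmer_config()].
#' @return data.frame with columns `pos` (0-based window start, integer)
#'   and `kmer` (canonical k-mer, character).
#' @export
#' @examples
#' canonical_kmers("ACGTAC", kmer_config(3))
canonical_kmers <- function(seq, cfg = kmer_config()) {
  stopifnot(inherits(cfg, "kmer_config"), length(seq) == 1L)
  res <- .cpp_canonical_kmers(as.character(seq), cfg$k)
  data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
}
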