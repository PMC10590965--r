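#' Exact canonical k-mer set
#'
#' In-memory hash set of canonical k-mers. Used for the pass-2 anchor
#' k-mer set and, in tests, as an exact stand-in for the Bloom filter
#' (identical interface, zero false positives).
#'
#' @param kmers character vector of k-mers (canonicalized on entry).
#' @param k word length; inferred from `kmers` when missing.
#' @return object of class `kmer_set`.
#' @export
kmer_set <- function(kmers = character(), k = NULL) {
  kmers <- if (length(kmers)) canonicalize(as.character(kmers)) else character()
  if (is.null(k)) {
    if (!length(kmers)) stop("k must be given for an empty set")
    k <- nchar(kmers[1])
  }
  structure(list(ptr = .cpp_set_new(kmers, as.integer(k)),
                 k = as.integer(k)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("<kmer_set>", .cpp_set_size(x$ptr), "k-mers, k =", x$k, "\n")
  invisible(x)
}

#' @export
length.kmer_set <- function(x) as.integer(.cpp_set_size(x$ptr))

#' @export
as.character.kmer_set <- function(x, ...) .cpp_set_members(x$ptr)

#' Query membership in an exact k-mer set
#' @param set a [kmer_set()].
#' @param kmers character vector of k-mers.
#' @return logical vector.
#' @export
set_contains <- function(set, kmers) {
  stopifnot(inherits(set, "kmer_set"))
  if (!length(kmers)) return(logical())
  .cpp_set_contains(set$ptr, canonicalize(as.character(kmers)))
}

# Resolve a membership backend: a Bloom filter or an exact kmer_set.
memb_backend <- function(x) {
  if (inherits(x, "oral_bloom_filter"))
    list(ptr = x$ptr, is_bloom = TRUE, k = x$k)
  else if (inherits(x, "kmer_set"))
    list(ptr = x$ptr, is_bloom = FALSE, k = x$k)
  else stop("membership structure must be an oral_bloom_filter or a kmer_set")
}

#' Classifier settings
#'
#' @param tau anchor-proportion retention threshold in \[0, 1\]; a read is
#'   retained when the fraction of its k-mers found in the anchor k-mer
#'   set is at least tau (inclusive). Default 0.5.
#' @param mode `"two_pass"` (anchor detection, then anchor-set
#'   proportion) or `"one_pass"` (retain anchors directly, no second
#'   pass).
#' @return object of class `classifier_config`. The anchor criterion
#'   itself (two consecutive matches) is fixed.
#' @export
classifier_config <- function(tau = 0.5, mode = c("two_pass", "one_pass")) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must be a single value in [0, 1]")
  structure(list(tau = tau, consecutive_required = 2L,
                 mode = match.arg(mode)),
            class = "classifier_config")
}

read_sequences <- function(reads) {
  if (is.character(reads)) reads
  else if (is.data.frame(reads)) as.character(reads$sequence)
  else stop("reads must be a character vector or a read-record data.frame")
}

read_ids <- function(reads) {
  if (is.data.frame(reads) && !is.null(reads$seq_id))
    as.character(reads$seq_id)
  else paste0("read", seq_along(read_sequences(reads)))
}

#' Pass 1: anchor-read detection
#'
#' A read is an anchor when two k-mer windows at adjacent start positions
#' (overlap k-1) are both valid (A/C/G/T only) and both match the
#' membership structure. Requiring two consecutive matches keeps a single
#' Bloom-filter false positive from promoting a read to anchor. Reads
#' with fewer than two valid windows are never anchors.
#'
#' @param reads character vector of sequences or a read-record data.frame
#'   (column `sequence`).
#' @param bf membership structure: an `oral_bloom_filter` or an exact
#'   [kmer_set()].
#' @param cfg a [kmer_config()].
#' @return logical vector, one flag per read.
#' @export
find_anchor <- function(reads, bf, cfg = kmer_config()) {
  be <- memb_backend(bf)
  if (be$k != cfg$k)
    stop("membership structure indexes k = ", be$k, ", config has k = ", cfg$k)
  .cpp_find_anchors(read_sequences(reads), be$ptr, be$is_bloom, cfg$k)
}

#' Harvest the anchor k-mer set
#'
#' K-merizes every anchor read (valid windows only) and returns the union
#' as an exact [kmer_set()]. Anchor reads contribute all of their k-mers,
#' including ones absent from the trusted set: that enrichment with new
#' putative ancient k-mers is the point of the second pass.
#'
#' @inheritParams find_anchor
#' @param anchor_flags logical vector from [find_anchor()]; computed here
#'   when missing.
#' @return list with `anchors` (a `kmer_set`) and `anchor_flags`.
#' @export
collect_anchor_set <- function(reads, bf, cfg = kmer_config(),
                               anchor_flags = NULL) {
  if (is.null(anchor_flags)) anchor_flags <- find_anchor(reads, bf, cfg)
  ptr <- .cpp_collect_kmers(read_sequences(reads), anchor_flags, cfg$k)
  anchors <- structure(list(ptr = ptr, k = cfg$k), class = "kmer_set")
  list(anchors = anchors, anchor_flags = anchor_flags)
}

#' Pass 2: classify reads against the anchor k-mer set
#'
#' The anchor proportion of a read is (number of its k-mers found in the
#' anchor set) / (number of valid k-mer windows), defined as 0 for reads
#' with no valid window. A read is retained when the proportion is >= tau
#' (inclusive). Non-anchor reads can be retained.
#'
#' @param reads sequences or read-record data.frame.
#' @param anchors a [kmer_set()] of anchor k-mers.
#' @param cfg a [classifier_config()].
#' @param kcfg a [kmer_config()].
#' @param anchor_flags optional logical vector recorded in the annotation
#'   column `is_consecutive_match_found`.
#' @return data.frame of read annotations: `seq_id`, `read_len`,
#'   `is_consecutive_match_found`, `anchor_proportion`, `retained`.
#' @export
classify_read <- function(reads, anchors, cfg = classifier_config(),
                          kcfg = kmer_config(), anchor_flags = NULL) {
  stopifnot(inherits(anchors, "kmer_set"), inherits(cfg, "classifier_config"))
  seqs <- read_sequences(reads)
  st <- .cpp_anchor_stats(seqs, anchors$ptr, kcfg$k)
  prop <- ifelse(st$n_valid > 0, st$n_hit / st$n_valid, 0)
  if (is.null(anchor_flags)) anchor_flags <- rep(NA, length(seqs))
  data.frame(seq_id = read_ids(reads),
             read_len = nchar(seqs),
             is_consecutive_match_found = anchor_flags,
             anchor_proportion = prop,
             retained = prop >= cfg$tau,
             stringsAsFactors = FALSE)
}

#' Run the full two-pass decontamination
#'
#' Pass 1 flags anchor reads (two consecutive matches against `bf`),
#' their k-mers form the exact anchor set, and pass 2 retains reads whose
#' anchor proportion is at least tau. Output order follows input order;
#' every input read yields exactly one annotation row.
#'
#' @param reads a read-record data.frame (from [read_fastx()]) or a
#'   character vector of sequences, or a FASTA/FASTQ path (read in full).
#' @param bf an `oral_bloom_filter` or exact [kmer_set()] over the
#'   trusted k-mers.
#' @param cfg a [classifier_config()].
#' @param kcfg a [kmer_config()].
#' @return list with `annotations` (data.frame, all reads), `retained`
#'   (the retained subset of the input records), and `anchors` (the
#'   anchor `kmer_set`).
#' @export
run_two_pass <- function(reads, bf, cfg = classifier_config(),
                         kcfg = kmer_config()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastx(reads)
  p1 <- collect_anchor_set(reads, bf, kcfg)
  ann <- classify_read(reads, p1$anchors, cfg, kcfg,
                       anchor_flags = p1$anchor_flags)
  retained <- if (is.data.frame(reads)) reads[ann$retained, , drop = FALSE]
              else read_sequences(reads)[ann$retained]
  list(annotations = ann, retained = retained, anchors = p1$anchors)
}

#' Run the one-pass baseline
#'
#' Retains exactly the pass-1 anchor reads (two consecutive matches
#' against the trusted-k-mer filter); no anchor set is built and the
#' anchor proportion is reported as the sentinel 0, with
#' `is_consecutive_match_found` carrying the decision. This is the
#' ablation the two-pass design improves on.
#'
#' @inheritParams run_two_pass
#' @return list with `annotations` and `retained`, as [run_two_pass()].
#' @export
run_one_pass <- function(reads, bf, kcfg = kmer_config()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastx(reads)
  flags <- find_anchor(reads, bf, kcfg)
  seqs <- read_sequences(reads)
  ann <- data.frame(seq_id = read_ids(reads),
                    read_len = nchar(seqs),
                    is_consecutive_match_found = flags,
                    anchor_proportion = 0,
                    retained = flags,
                    stringsAsFactors = FALSE)
  retained <- if (is.data.frame(reads)) reads[flags, , drop = FALSE]
              else seqs[flags]
  list(annotations = ann, retained = retained)
}
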