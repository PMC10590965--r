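# Independent pure-R reference implementations used as oracles. These stay
# deliberately naive (character vectors, %in%, explicit loops) and never
# call the package's C++ kernels.

ref_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", s), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

ref_canon <- function(w) {
  rc <- ref_revcomp(w)
  if (rc < w) rc else w
}

# all valid k-mer windows of one sequence, with 0-based start positions
ref_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  pos <- integer(); kmer <- character()
  if (n >= k) {
    for (i in 0:(n - k)) {
      w <- substr(seq, i + 1L, i + k)
      if (!grepl("[^ACGT]", w)) {
        pos <- c(pos, i)
        kmer <- c(kmer, ref_canon(w))
      }
    }
  }
  data.frame(pos = pos, kmer = kmer, stringsAsFactors = FALSE)
}

# quadratic-scan reference of the full two-pass algorithm over an exact
# trusted k-mer set (character vector)
ref_two_pass <- function(seqs, trusted, k, tau = 0.5) {
  trusted <- vapply(trusted, ref_canon, character(1), USE.NAMES = FALSE)
  km <- lapply(seqs, ref_kmers, k = k)
  anchor <- vapply(km, function(df) {
    if (nrow(df) < 2) return(FALSE)
    hit <- df$kmer %in% trusted
    any(hit[-nrow(df)] & hit[-1] & diff(df$pos) == 1L)
  }, logical(1))
  aset <- unique(unlist(lapply(km[anchor], `[[`, "kmer")))
  prop <- vapply(km, function(df)
    if (nrow(df) == 0) 0 else mean(df$kmer %in% aset), numeric(1))
  list(anchor = anchor, anchor_set = sort(aset), proportion = prop,
       retained = prop >= tau)
}

# --- random fixture builders ----------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# n distinct random canonical k-mers (vectorised; used up to a few 1e5)
rand_canonical_kmers <- function(n, k) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out) + 100L
    mat <- matrix(sample(c("A", "C", "G", "T"), need * k, replace = TRUE),
                  need, k)
    batch <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    out <- unique(c(out, canonicalize(batch)))
  }
  out[seq_len(n)]
}

# a small read corpus: some reads from a toy genome, some random background
rand_fixture <- function(n_reads = 60, read_len = 40, k = 11,
                         genome_len = 600) {
  genome <- rand_dna(genome_len)
  starts <- sample.int(genome_len - read_len + 1L, ceiling(n_reads / 2),
                       replace = TRUE)
  from_genome <- substring(genome, starts, starts + read_len - 1L)
  background <- vapply(seq_len(floor(n_reads / 2)),
                       function(i) rand_dna(read_len), character(1))
  seqs <- sample(c(from_genome, background))
  list(genome = genome,
       trusted = unique(ref_kmers(genome, k)$kmer),
       seqs = seqs, k = k)
}

# read records data.frame from bare sequences
as_records <- function(seqs, quality = TRUE) {
  data.frame(seq_id = sprintf("r%04d", seq_along(seqs)),
             description = rep("", length(seqs)),
             sequence = seqs,
             quality = if (quality) strrep("I", nchar(seqs))
                       else rep(NA_character_, length(seqs)),
             stringsAsFactors = FALSE)
}

# exhaustive truth-table evaluation of the trusted-set boolean formula
ref_select_trusted <- function(presence, labels) {
  apply(presence, 1L, function(row) {
    in_oral <- any(row[labels %in% c("aOral", "mOral")])
    in_bad <- any(row[labels %in% c("Skin", "SedimentSoil")])
    in_oral && !in_bad
  })
}
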