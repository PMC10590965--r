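#' Mixture design for synthetic evaluation datasets
#'
#' Describes a labelled read mixture emulating ancient-dental-calculus
#' sequencing: equal numbers of reads from an ancient-oral source and two
#' contaminant sources (Skin, SedimentSoil), i.e. a 1/3 : 1/3 : 1/3
#' mixture, with uniform read start positions, random strand, and
#' substitution-only sequencing error. `overlap_mode` controls whether the
#' read-source genomes were available when the trusted k-mer matrix was
#' built: `"seen"` (best case — all sources in the matrix),
#' `"partially_seen"` (the oral read source is novel, contaminants are
#' known), `"unseen"` (all read sources novel; the novel oral genome is
#' related to, but not identical to, the matrix oral genomes).
#'
#' @param n_reads_per_source reads drawn from each of the three sources.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error rate in \[0, 0.1\];
#'   default 0.005, typical of Illumina data.
#' @param overlap_mode `"seen"`, `"partially_seen"` or `"unseen"`.
#' @param rng_seed integer seed; every draw in the generator flows from it.
#' @return object of class `mixture_design`.
#' @export
mixture_design <- function(n_reads_per_source = 2000L,
                           read_length = 100L,
                           error_rate = 0.005,
                           overlap_mode = c("seen", "partially_seen", "unseen"),
                           rng_seed = 1L) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  structure(list(n_reads_per_source = as.integer(n_reads_per_source),
                 sources = c("aOral", "Skin", "SedimentSoil"),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 overlap_mode = match.arg(overlap_mode),
                 rng_seed = as.integer(rng_seed)),
            class = "mixture_design")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate labelled toy source genomes
#'
#' One random genome per source label. `shared_fraction` dials the
#' hard-case overlap between the oral genome and each contaminant genome:
#' a fraction of each contaminant is copied from the oral genome so that
#' the pairwise k-mer Jaccard index is approximately `shared_fraction`
#' (copied length fraction 2J/(1+J), the value that yields Jaccard J
#' between equal-sized k-mer sets).
#'
#' @param seed integer RNG seed; identical seeds give identical genomes.
#' @param labels source labels, first one oral.
#' @param genome_length genome length in bases (all sources).
#' @param shared_fraction target oral-contaminant k-mer Jaccard in \[0, 1).
#' @param cfg a [kmer_config()] (validates `genome_length >= k`).
#' @return named character vector of genomes, names = labels.
#' @export
sim_genomes <- function(seed = 1L,
                        labels = c("aOral", "Skin", "SedimentSoil"),
                        genome_length = 20000L,
                        shared_fraction = 0,
                        cfg = kmer_config()) {
  if (genome_length < cfg$k)
    stop("genome_length must be at least k = ", cfg$k)
  if (!is.numeric(shared_fraction) || shared_fraction < 0 ||
      shared_fraction >= 1)
    stop("shared_fraction must be in [0, 1)")
  with_seed(seed, {
    genomes <- vapply(labels, function(l) random_dna(genome_length),
                      character(1))
    if (shared_fraction > 0 && length(labels) > 1) {
      f <- 2 * shared_fraction / (1 + shared_fraction)
      copy_len <- round(f * genome_length)
      for (i in seq_along(labels)[-1]) {
        src_start <- sample.int(genome_length - copy_len + 1L, 1L)
        dst_start <- sample.int(genome_length - copy_len + 1L, 1L)
        g <- genomes[[i]]
        substr(g, dst_start, dst_start + copy_len - 1L) <-
          substr(genomes[[1]], src_start, src_start + copy_len - 1L)
        genomes[[i]] <- g
      }
    }
    genomes
  })
}

mutate_bases <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(runif(n) < error_rate)
    if (!length(hits)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[hits] <- vapply(chars[hits], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a labelled read mixture
#'
#' Draws `n_reads_per_source` reads from each source genome with uniform
#' random start positions, random strand, and i.i.d. substitution errors,
#' then interleaves sources in a fixed round-robin order. Ground truth is
#' carried in a sidecar table keyed by read id, not encoded in the ids
#' themselves.
#'
#' @param genomes named character vector from [sim_genomes()] (names are
#'   the truth labels).
#' @param design a [mixture_design()].
#' @param random_strand draw each read's strand at random (default); if
#'   FALSE all reads are forward.
#' @return list with `reads` (read-record data.frame with constant "I"
#'   qualities) and `truth` (data.frame `read_id`, `label`).
#' @export
sim_reads <- function(genomes, design = mixture_design(),
                      random_strand = TRUE) {
  stopifnot(inherits(design, "mixture_design"))
  L <- design$read_length
  glen <- nchar(genomes)
  if (any(L > glen)) stop("read_length exceeds a genome length")
  with_seed(design$rng_seed, {
    # coordinates and strands for every source are drawn before any
    # error is applied, so read placement at a given seed does not
    # depend on the error rate
    per <- lapply(names(genomes), function(lab) {
      g <- genomes[[lab]]
      starts <- sample.int(nchar(g) - L + 1L, design$n_reads_per_source,
                           replace = TRUE)
      seqs <- substring(g, starts, starts + L - 1L)
      if (random_strand) {
        flip <- runif(length(seqs)) < 0.5
        seqs[flip] <- reverse_complement(seqs[flip])
      }
      seqs
    })
    per <- lapply(per, mutate_bases, error_rate = design$error_rate)
    n_tot <- design$n_reads_per_source * length(genomes)
    labels <- rep(names(genomes), each = design$n_reads_per_source)
    ord <- as.vector(matrix(seq_len(n_tot),
                            nrow = length(genomes), byrow = TRUE))
    seqs <- unlist(per, use.names = FALSE)[ord]
    labels <- labels[ord]
    ids <- sprintf("read_%05d", seq_len(n_tot))
    list(reads = data.frame(seq_id = ids, description = "",
                            sequence = seqs,
                            quality = strrep("I", L),
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Build a labelled k-mer matrix from source genomes
#'
#' Emulates the role of a real multi-sample k-mer collection: each
#' synthetic sample of an environment carries a random subset of its
#' genome's canonical k-mers (`subset_fraction`) plus a small number of
#' random noise k-mers (`noise_rate` times the genome k-mer count).
#' Counts are drawn so the within-sample singleton filter has something
#' to act on: subset k-mers get count >= 2, noise k-mers count 1.
#'
#' @param genomes named character vector; names are environment labels
#'   (repeat a label for several genomes of one environment).
#' @param n_samples_per_genome synthetic samples per genome (default 3).
#' @param subset_fraction fraction of genome k-mers present per sample.
#' @param noise_rate noise k-mers per genome k-mer (default 0).
#' @param seed integer RNG seed.
#' @param cfg a [kmer_config()].
#' @return a [kmer_sample_matrix()] with counts.
#' @export
sim_matrix <- function(genomes, n_samples_per_genome = 3L,
                       subset_fraction = 1, noise_rate = 0,
                       seed = 1L, cfg = kmer_config()) {
  labels <- names(genomes)
  if (is.null(labels)) stop("genomes must be named by environment label")
  gk <- lapply(genomes, function(g) unique(canonical_kmers(g, cfg)$kmer))
  with_seed(seed, {
    cols <- list(); col_labels <- character(); col_ids <- character()
    for (i in seq_along(genomes)) {
      for (s in seq_len(n_samples_per_genome)) {
        kk <- gk[[i]]
        take <- sample(kk, round(subset_fraction * length(kk)))
        n_noise <- round(noise_rate * length(kk))
        noise <- if (n_noise > 0)
          setdiff(unique(vapply(seq_len(n_noise), function(j)
            canonicalize(random_dna(cfg$k)), character(1))), take)
        else character()
        cols[[length(cols) + 1L]] <-
          list(kmers = c(take, noise),
               counts = c(sample(2:9, length(take), replace = TRUE),
                          rep(1L, length(noise))))
        col_labels <- c(col_labels, labels[i])
        col_ids <- c(col_ids, sprintf("%s_g%d_s%d", labels[i], i, s))
      }
    }
    all_kmers <- unique(unlist(lapply(cols, `[[`, "kmers")))
    counts <- matrix(0L, nrow = length(all_kmers), ncol = length(cols))
    for (j in seq_along(cols)) {
      idx <- match(cols[[j]]$kmers, all_kmers)
      counts[idx, j] <- as.integer(cols[[j]]$counts)
    }
    kmer_sample_matrix(all_kmers, col_ids, col_labels, counts = counts)
  })
}

#' Generate a complete labelled evaluation scenario
#'
#' Wires the pieces together the way the evaluation protocol uses them:
#' source genomes, a labelled k-mer matrix, a trusted k-mer set, and a
#' read mixture with ground truth.
#'
#' * `seen`: the matrix is built from the same three genomes the reads
#'   are drawn from (best case).
#' * `partially_seen`: reads' oral genome is novel; the matrix oral
#'   columns come from a different (related) oral genome.
#' * `unseen`: as `partially_seen`, and the contaminant read sources are
#'   novel too.
#'
#' In the non-seen modes the novel oral genome is a mosaic: a fraction
#' `relatedness` of its length is copied from the matrix oral genome
#' (conserved core), the rest is novel sequence.
#'
#' @param design a [mixture_design()].
#' @param genome_length source genome length (default 20000).
#' @param shared_fraction oral-contaminant k-mer overlap dial, see
#'   [sim_genomes()].
#' @param relatedness fraction of the novel oral genome conserved from
#'   the matrix oral genome (non-seen modes; default 0.7).
#' @param filters a [trusted_set_filters()]; the scenario default keeps
#'   every row (`subsample_fraction = 1`, singleton filter on) so toy
#'   matrices are not decimated.
#' @param cfg a [kmer_config()].
#' @return list with `genomes`, `matrix`, `trusted` (a
#'   `trusted_kmer_set`), `reads`, `truth`, and the `design`.
#' @export
sim_scenario <- function(design = mixture_design(),
                         genome_length = 20000L,
                         shared_fraction = 0,
                         relatedness = 0.7,
                         filters = trusted_set_filters(
                           min_sample_prevalence = 3L,
                           drop_within_sample_singletons = TRUE,
                           subsample_fraction = 1,
                           rng_seed = 1L),
                         cfg = kmer_config()) {
  stopifnot(inherits(design, "mixture_design"))
  seed <- design$rng_seed
  genomes <- sim_genomes(seed = seed, genome_length = genome_length,
                         shared_fraction = shared_fraction, cfg = cfg)
  matrix_genomes <- genomes
  read_genomes <- genomes
  if (design$overlap_mode %in% c("partially_seen", "unseen")) {
    read_genomes[["aOral"]] <- with_seed(seed + 1000L, {
      novel <- random_dna(genome_length)
      cons_len <- round(relatedness * genome_length)
      if (cons_len > 0) {
        start <- sample.int(genome_length - cons_len + 1L, 1L)
        substr(novel, start, start + cons_len - 1L) <-
          substr(genomes[["aOral"]], start, start + cons_len - 1L)
      }
      novel
    })
  }
  if (design$overlap_mode == "unseen") {
    read_genomes[["Skin"]] <- with_seed(seed + 2000L,
                                        random_dna(genome_length))
    read_genomes[["SedimentSoil"]] <- with_seed(seed + 3000L,
                                                random_dna(genome_length))
  }
  mat <- sim_matrix(matrix_genomes, seed = seed + 1L, cfg = cfg)
  trusted <- build_trusted_set(mat, filters)
  rd <- sim_reads(read_genomes, design)
  list(genomes = read_genomes, matrix = mat, trusted = trusted,
       reads = rd$reads, truth = rd$truth, design = design)
}

#' Write / read a mixture ground-truth table
#'
#' @param truth data.frame `read_id`, `label`.
#' @param path TSV path, optionally `.gz`.
#' @return `read_truth` returns the data.frame.
#' @export
write_truth <- function(truth, path) {
  con <- open_text(path, "wt")
  on.exit(close(con))
  write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, colClasses = "character")
}
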