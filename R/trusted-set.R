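#' @rdname kmer_sample_matrix
#' @format NULL
#' @export
ENV_LABELS <- c("aOral", "mOral", "Skin", "SedimentSoil")

normalize_env_label <- function(x) {
  x <- as.character(x)
  x[x %in% c("Sediment/Soil", "Soil", "Sediment")] <- "SedimentSoil"
  bad <- setdiff(unique(x), ENV_LABELS)
  if (length(bad) > 0)
    stop("unknown environment label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(ENV_LABELS, collapse = ", "))
  x
}

#' k-mer by sample presence matrix with environment labels
#'
#' The source object for trusted-set construction: rows are canonical
#' k-mers, columns are samples, each sample carries an environment label
#' from the closed vocabulary aOral (ancient oral), mOral (modern oral),
#' Skin, SedimentSoil. Presence is boolean; an optional count matrix of
#' the same shape carries per-sample k-mer abundance, which the
#' within-sample singleton filter needs.
#'
#' Row k-mers are canonicalized on construction; duplicate rows arising
#' from canonicalization are merged (presence OR-ed, counts summed) with a
#' warning.
#'
#' @param kmers character vector of k-mers (row keys, one length).
#' @param sample_ids character vector of unique sample identifiers.
#' @param labels environment label per sample; "Sediment/Soil" is accepted
#'   as an alias for "SedimentSoil".
#' @param presence logical (or 0/1) matrix, `length(kmers)` rows by
#'   `length(sample_ids)` columns. Derived from `counts` when omitted.
#' @param counts optional non-negative integer matrix of the same shape.
#' @return object of class `kmer_sample_matrix`.
#' @export
kmer_sample_matrix <- function(kmers, sample_ids, labels,
                               presence = NULL, counts = NULL) {
  kmers <- as.character(kmers)
  sample_ids <- as.character(sample_ids)
  labels <- normalize_env_label(labels)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(labels) != length(sample_ids))
    stop("one label per sample required")
  if (length(kmers) > 0 && length(unique(nchar(kmers))) > 1L)
    stop("all k-mers must have the same length")
  if (is.null(presence)) {
    if (is.null(counts)) stop("supply presence and/or counts")
    presence <- counts >= 1L
  }
  presence <- matrix(as.logical(presence), nrow = length(kmers),
                     ncol = length(sample_ids))
  if (!is.null(counts)) {
    counts <- matrix(as.integer(counts), nrow = length(kmers),
                     ncol = length(sample_ids))
    if (any(counts < 0L)) stop("counts must be non-negative")
    if (!identical(unname(counts >= 1L), unname(presence)))
      stop("presence[i,j] must be TRUE exactly when counts[i,j] >= 1")
  }

  canon <- if (length(kmers)) canonicalize(kmers) else character()
  if (anyDuplicated(canon)) {
    warning("duplicate k-mer rows after canonicalization; merging")
    u <- canon[!duplicated(canon)]
    g <- match(canon, u)  # rowsum orders groups by value = first occurrence
    presence <- rowsum(presence * 1L, g) > 0
    if (!is.null(counts)) {
      counts <- rowsum(counts, g)
      storage.mode(counts) <- "integer"
    }
    canon <- u
  }
  rownames(presence) <- canon
  colnames(presence) <- sample_ids
  if (!is.null(counts)) dimnames(counts) <- dimnames(presence)
  structure(list(kmers = canon,
                 samples = data.frame(sample_id = sample_ids, label = labels,
                                      stringsAsFactors = FALSE),
                 presence = presence, counts = counts,
                 k = if (length(canon)) nchar(canon[1]) else NA_integer_),
            class = "kmer_sample_matrix")
}

#' @export
print.kmer_sample_matrix <- function(x, ...) {
  cat("<kmer_sample_matrix>", nrow(x$presence), "k-mers x",
      ncol(x$presence), "samples (k =", x$k, ")\n")
  print(table(x$samples$label))
  invisible(x)
}

#' Trusted-set filter settings
#'
#' Filters applied to a [kmer_sample_matrix()] before the boolean
#' environment selection: within-sample singleton removal (k-mers counted
#' exactly once in a sample are likely sequencing errors and are treated as
#' absent there), a minimum sample prevalence (default: present in at
#' least 3 samples), and uniform row subsampling (default 10%) to bound
#' memory.
#'
#' @param min_sample_prevalence keep rows present in at least this many
#'   samples (all environments count). Default 3.
#' @param drop_within_sample_singletons clear entries with count exactly 1.
#'   Requires the matrix to carry counts. Default TRUE.
#' @param subsample_fraction fraction of rows to keep, in (0, 1]. Default 0.10.
#' @param rng_seed integer seed for the subsampling draw.
#' @return object of class `trusted_set_filters`.
#' @export
trusted_set_filters <- function(min_sample_prevalence = 3L,
                                drop_within_sample_singletons = TRUE,
                                subsample_fraction = 0.10,
                                rng_seed = 1L) {
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  structure(list(min_sample_prevalence = as.integer(min_sample_prevalence),
                 drop_within_sample_singletons =
                   isTRUE(drop_within_sample_singletons),
                 subsample_fraction = subsample_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "trusted_set_filters")
}

#' Apply abundance filters to a k-mer matrix
#'
#' Two steps, in fixed order: (1) if enabled, within-sample singletons
#' (count exactly 1) are cleared to absent; (2) rows present in fewer than
#' `min_sample_prevalence` samples are dropped.
#'
#' @param mat a [kmer_sample_matrix()].
#' @param filters a [trusted_set_filters()].
#' @return the filtered `kmer_sample_matrix`.
#' @export
apply_abundance_filters <- function(mat, filters = trusted_set_filters()) {
  stopifnot(inherits(mat, "kmer_sample_matrix"),
            inherits(filters, "trusted_set_filters"))
  presence <- mat$presence
  counts <- mat$counts
  if (filters$drop_within_sample_singletons) {
    if (is.null(counts))
      stop("the within-sample singleton filter needs k-mer counts, ",
           "but this matrix carries presence only; supply counts or set ",
           "drop_within_sample_singletons = FALSE")
    single <- counts == 1L
    presence[single] <- FALSE
    counts[single] <- 0L
  }
  keep <- rowSums(presence) >= filters$min_sample_prevalence
  kmer_sample_matrix(mat$kmers[keep], mat$samples$sample_id,
                     mat$samples$label,
                     presence = presence[keep, , drop = FALSE],
                     counts = if (!is.null(counts)) counts[keep, , drop = FALSE])
}

#' Uniformly subsample matrix rows
#'
#' Keeps `floor(fraction * nrow)` rows drawn uniformly without
#' replacement, reproducibly for a fixed seed; original row order is
#' preserved among survivors. `fraction = 1` is the identity.
#'
#' @inheritParams apply_abundance_filters
#' @param fraction fraction of rows to keep, in (0, 1].
#' @param seed integer RNG seed.
#' @return the subsampled `kmer_sample_matrix`.
#' @export
subsample_rows <- function(mat, fraction, seed = 1L) {
  stopifnot(inherits(mat, "kmer_sample_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- length(mat$kmers)
  n_keep <- floor(fraction * n)
  if (n_keep == n) return(mat)
  keep <- sort(with_seed(seed, sample.int(n, n_keep)))
  kmer_sample_matrix(mat$kmers[keep], mat$samples$sample_id,
                     mat$samples$label,
                     presence = mat$presence[keep, , drop = FALSE],
                     counts = if (!is.null(mat$counts))
                       mat$counts[keep, , drop = FALSE])
}

#' Select trusted oral k-mers from a labelled matrix
#'
#' A k-mer is trusted when it is present in at least one ancient-oral or
#' modern-oral sample AND absent from every Skin sample AND absent from
#' every SedimentSoil sample:
#' `(inAOral | inMOral) & !(inSkin | inSedimentSoil)`.
#'
#' @param mat a [kmer_sample_matrix()] with at least one oral-labelled
#'   column.
#' @param provenance optional list recording upstream filter settings.
#' @return object of class `trusted_kmer_set` with elements `kmers`
#'   (character), `k`, and `provenance`.
#' @export
select_trusted <- function(mat, provenance = list()) {
  stopifnot(inherits(mat, "kmer_sample_matrix"))
  lab <- mat$samples$label
  oral <- lab %in% c("aOral", "mOral")
  if (!any(oral))
    stop("matrix has no aOral or mOral columns; the selection formula is degenerate")
  p <- mat$presence
  in_oral <- rowSums(p[, oral, drop = FALSE]) > 0
  in_skin <- rowSums(p[, lab == "Skin", drop = FALSE]) > 0
  in_soil <- rowSums(p[, lab == "SedimentSoil", drop = FALSE]) > 0
  keep <- in_oral & !in_skin & !in_soil
  trusted_kmer_set(mat$kmers[keep], k = mat$k,
                   provenance = c(provenance,
                                  list(n_matrix_rows = length(mat$kmers),
                                       n_selected = sum(keep))))
}

#' Construct a trusted k-mer set object
#'
#' @param kmers character vector of k-mers (canonicalized, deduplicated).
#' @param k word length; inferred from `kmers` when missing.
#' @param provenance list describing how the set was derived.
#' @return object of class `trusted_kmer_set`.
#' @export
trusted_kmer_set <- function(kmers, k = NULL, provenance = list()) {
  kmers <- unique(if (length(kmers)) canonicalize(kmers) else character())
  if (is.null(k)) {
    if (!length(kmers)) stop("k must be given for an empty set")
    k <- nchar(kmers[1])
  }
  if (length(kmers) && any(nchar(kmers) != k))
    stop("all k-mers must have length k = ", k)
  structure(list(kmers = kmers, k = as.integer(k), provenance = provenance),
            class = "trusted_kmer_set")
}

#' @export
print.trusted_kmer_set <- function(x, ...) {
  cat("<trusted_kmer_set>", length(x$kmers), "k-mers, k =", x$k, "\n")
  invisible(x)
}

#' Full trusted-set pipeline
#'
#' Convenience wrapper running the pipeline in its fixed order:
#' subsample rows, apply abundance filters, select by environment formula.
#' Subsampling first keeps peak memory proportional to the retained
#' fraction.
#'
#' @inheritParams apply_abundance_filters
#' @return a `trusted_kmer_set`.
#' @export
build_trusted_set <- function(mat, filters = trusted_set_filters()) {
  mat <- subsample_rows(mat, filters$subsample_fraction, filters$rng_seed)
  mat <- apply_abundance_filters(mat, filters)
  select_trusted(mat, provenance = unclass(filters))
}

# --- plain-text interchange ------------------------------------------------

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write / read a k-mer list (one per line, optionally gzipped)
#'
#' `read_kmer_list` validates the word length on every line (errors name
#' the offending line number), canonicalizes, and deduplicates, warning if
#' any input line was not already canonical.
#'
#' @param set a `trusted_kmer_set` (or character vector of k-mers).
#' @param path output (input) file; a `.gz` suffix triggers compression.
#' @param cfg a [kmer_config()] giving the expected word length.
#' @return `read_kmer_list` returns a `trusted_kmer_set`;
#'   `write_kmer_list` returns `path` invisibly.
#' @export
write_kmer_list <- function(set, path) {
  kmers <- if (inherits(set, "trusted_kmer_set")) set$kmers else
    as.character(set)
  con <- open_text(path, "wt")
  on.exit(close(con))
  writeLines(kmers, con)
  invisible(path)
}

#' @rdname write_kmer_list
#' @export
read_kmer_list <- function(path, cfg = kmer_config()) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con))
  lines <- toupper(lines[nzchar(lines)])
  bad_len <- which(nchar(lines) != cfg$k)
  if (length(bad_len))
    stop("line ", bad_len[1], " has length ", nchar(lines[bad_len[1]]),
         ", expected k = ", cfg$k)
  bad_chr <- grep("[^ACGT]", lines)
  if (length(bad_chr))
    stop("line ", bad_chr[1], " contains a non-ACGT character")
  canon <- canonicalize(lines)
  if (any(canon != lines))
    warning(sum(canon != lines), " k-mer(s) were not canonical; canonicalized")
  trusted_kmer_set(unique(canon), k = cfg$k,
                   provenance = list(source = path))
}

#' Write / read a labelled k-mer matrix as TSV
#'
#' Dialect: a headered TSV whose first column (`kmer`) holds the k-mer and
#' remaining columns one sample each, carrying either 0/1 presence or
#' non-negative counts; plus a two-column sidecar TSV (`sample_id`,
#' `label`) mapping samples to environment labels. Both files may be
#' gzipped.
#'
#' @param mat a [kmer_sample_matrix()].
#' @param matrix_path,labels_path paths for the matrix and label sidecar.
#' @param what write `counts` when present, else presence 0/1.
#' @return `read_kmer_matrix` returns a `kmer_sample_matrix`;
#'   `write_kmer_matrix` returns `matrix_path` invisibly.
#' @export
write_kmer_matrix <- function(mat, matrix_path, labels_path,
                              what = c("auto", "presence", "counts")) {
  stopifnot(inherits(mat, "kmer_sample_matrix"))
  what <- match.arg(what)
  use_counts <- (what == "counts") ||
    (what == "auto" && !is.null(mat$counts))
  if (use_counts && is.null(mat$counts))
    stop("matrix carries no counts")
  body <- if (use_counts) mat$counts else mat$presence * 1L
  df <- data.frame(kmer = mat$kmers, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- open_text(matrix_path, "wt")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- open_text(labels_path, "wt")
  write.table(mat$samples, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(matrix_path)
}

#' @rdname write_kmer_matrix
#' @export
read_kmer_matrix <- function(matrix_path, labels_path) {
  df <- read.delim(matrix_path, check.names = FALSE,
                   colClasses = "character")
  lab <- read.delim(labels_path, colClasses = "character")
  if (!identical(names(lab), c("sample_id", "label")))
    stop("label sidecar must have columns sample_id, label")
  if (names(df)[1] != "kmer") stop("first matrix column must be 'kmer'")
  sample_ids <- names(df)[-1]
  missing <- setdiff(sample_ids, lab$sample_id)
  if (length(missing))
    stop("samples without labels: ", paste(missing, collapse = ", "))
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  labels <- lab$label[match(sample_ids, lab$sample_id)]
  has_counts <- any(counts > 1L)
  kmer_sample_matrix(df$kmer, sample_ids, labels,
                     presence = counts >= 1L,
                     counts = if (has_counts) counts)
}
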