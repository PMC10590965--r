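#' Bloom filter sizing
#'
#' For capacity n and target false-positive rate p the standard sizing is
#' m = ceil(-n ln p / (ln 2)^2) bits and h = max(1, round((m/n) ln 2)) hash
#' functions. Inserting at most n elements then keeps the false-positive
#' rate at or below p; the structure never produces false negatives.
#'
#' @param capacity maximum number of elements n the contract covers.
#'   The shipped default is 2e9, sized for a trusted set of ~1.5e9 k-mers;
#'   pass a small capacity for desk-scale work.
#' @param error_rate target false-positive rate p in (0, 1); default 0.001.
#' @return object of class `bloom_config` with fields `capacity`,
#'   `error_rate`, `m` (bits) and `num_hashes`.
#' @export
#' @examples
#' bloom_config(1000, 0.001)  # m = 14378 bits, h = 10
bloom_config <- function(capacity = 2e9, error_rate = 0.001) {
  if (!is.numeric(capacity) || length(capacity) != 1L || capacity < 1)
    stop("capacity must be a positive number")
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1)
    stop("error_rate must be in (0, 1)")
  capacity <- floor(capacity)
  m <- ceiling(-capacity * log(error_rate) / log(2)^2)
  h <- max(1L, as.integer(round((m / capacity) * log(2))))
  if (m / 8 > 8e9)
    stop("sizing requires ", format(m / 8, big.mark = ","),
         " bytes of bit array; reduce capacity or raise error_rate")
  structure(list(capacity = capacity, error_rate = error_rate,
                 m = m, num_hashes = h),
            class = "bloom_config")
}

#' @export
print.bloom_config <- function(x, ...) {
  cat(sprintf("<bloom_config> capacity %.0f, error rate %g -> m = %.0f bits, h = %d\n",
              x$capacity, x$error_rate, x$m, x$num_hashes))
  invisible(x)
}

#' Create a Bloom filter for canonical k-mers
#'
#' Approximate-membership store for the trusted k-mer set. Membership of
#' any inserted element always queries TRUE (no false negatives);
#' non-members query TRUE with probability at most `error_rate` while at
#' most `capacity` elements have been inserted. Bit positions come from
#' double hashing: two seeded 64-bit string hashes g1, g2 give position_i
#' = (g1 + i*g2) mod m.
#'
#' @param config a [bloom_config()].
#' @param k k-mer length the filter indexes (recorded; inserts and queries
#'   of other lengths are rejected).
#' @return object of class `oral_bloom_filter`.
#' @export
bloom_filter <- function(config = bloom_config(), k = 31L) {
  stopifnot(inherits(config, "bloom_config"))
  k <- as.integer(k)
  ptr <- .cpp_bf_new(config$m, config$num_hashes, k,
                     config$capacity, config$error_rate)
  structure(list(ptr = ptr, config = config, k = k),
            class = "oral_bloom_filter")
}

bf_params <- function(bf) .cpp_bf_params(bf$ptr)

#' @export
print.oral_bloom_filter <- function(x, ...) {
  p <- bf_params(x)
  cat(sprintf("<oral_bloom_filter> k = %d, %.0f/%.0f inserted, m = %.0f bits, h = %d, p = %g\n",
              p$k, p$inserted, p$capacity, p$m, p$num_hashes, p$error_rate))
  invisible(x)
}

#' Insert k-mers / query membership
#'
#' K-mers are canonicalized before hashing so both strands of a word map
#' to the same element. `inserted_count` counts insert calls per element
#' (duplicates are counted; the bit array itself is idempotent). Inserting
#' beyond the configured capacity degrades the false-positive bound and
#' raises a warning, not an error.
#'
#' @param bf an `oral_bloom_filter`.
#' @param kmers character vector of k-mers of the filter's k.
#' @return `bf_insert` returns `bf` invisibly; `bf_query` a logical vector.
#' @export
bf_insert <- function(bf, kmers) {
  stopifnot(inherits(bf, "oral_bloom_filter"))
  kmers <- canonicalize(as.character(kmers))
  .cpp_bf_insert(bf$ptr, kmers)
  p <- bf_params(bf)
  if (p$inserted > p$capacity)
    warning(sprintf("filter holds %.0f elements, beyond its capacity %.0f; the false-positive bound no longer applies",
                    p$inserted, p$capacity))
  invisible(bf)
}

#' @rdname bf_insert
#' @export
bf_query <- function(bf, kmers) {
  stopifnot(inherits(bf, "oral_bloom_filter"))
  if (!length(kmers)) return(logical())
  .cpp_bf_query(bf$ptr, canonicalize(as.character(kmers)))
}

#' Count of insert calls recorded by the filter
#' @param bf an `oral_bloom_filter`.
#' @return numeric count of elements passed to [bf_insert()].
#' @export
bf_inserted_count <- function(bf) bf_params(bf)$inserted

#' Build a Bloom filter from a trusted k-mer set
#'
#' @param set a `trusted_kmer_set` (or character vector).
#' @param config a [bloom_config()]; default capacity is the set size.
#' @return an `oral_bloom_filter` loaded with the set.
#' @export
bf_from_trusted <- function(set, config = NULL) {
  kmers <- if (inherits(set, "trusted_kmer_set")) set$kmers
           else unique(canonicalize(set))
  if (!length(kmers)) stop("cannot infer k from an empty k-mer set")
  k <- nchar(kmers[1])
  if (is.null(config)) config <- bloom_config(capacity = max(length(kmers), 1))
  bf <- bloom_filter(config, k = k)
  bf_insert(bf, kmers)
  bf
}

# --- persistence -----------------------------------------------------------

BF_MAGIC <- charToRaw("KSWBLOOM")
BF_FORMAT_VERSION <- 1L

#' Save / load a Bloom filter
#'
#' Byte-exact round trip of bits, sizing, k and insert count. The file
#' starts with magic bytes and a format version; mismatches and truncated
#' payloads are rejected.
#'
#' @param bf an `oral_bloom_filter`.
#' @param path file path.
#' @param k if given, `bf_load` rejects a file whose k-mer length differs.
#' @return `bf_save` returns `path` invisibly; `bf_load` the filter.
#' @export
bf_save <- function(bf, path) {
  stopifnot(inherits(bf, "oral_bloom_filter"))
  p <- bf_params(bf)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BF_MAGIC, con)
  writeBin(as.integer(c(BF_FORMAT_VERSION, p$k, p$num_hashes)), con, size = 4L)
  writeBin(as.double(c(p$capacity, p$error_rate, p$m, p$inserted)), con)
  bits <- .cpp_bf_bits(bf$ptr)
  writeBin(as.double(length(bits)), con)
  writeBin(bits, con)
  invisible(path)
}

#' @rdname bf_save
#' @export
bf_load <- function(path, k = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(BF_MAGIC))
  if (!identical(magic, BF_MAGIC))
    stop("not a kmersweep Bloom filter file (bad magic bytes): ", path)
  ints <- readBin(con, "integer", n = 3L, size = 4L)
  if (ints[1] != BF_FORMAT_VERSION)
    stop("filter file has format version ", ints[1],
         " but this build reads version ", BF_FORMAT_VERSION)
  dbl <- readBin(con, "double", n = 5L)
  if (length(ints) < 3L || length(dbl) < 5L) stop("truncated filter file: ", path)
  nbytes <- dbl[5]
  bits <- readBin(con, "raw", n = nbytes)
  if (length(bits) != nbytes)
    stop("truncated filter file: expected ", nbytes, " payload bytes, got ",
         length(bits))
  if (!is.null(k) && as.integer(k) != ints[2])
    stop("filter file was built for k = ", ints[2],
         " but k = ", k, " was requested")
  config <- structure(list(capacity = dbl[1], error_rate = dbl[2],
                           m = dbl[3],
                           num_hashes = ints[3]),
                      class = "bloom_config")
  bf <- bloom_filter(config, k = ints[2])
  .cpp_bf_set_state(bf$ptr, bits, dbl[4])
  bf
}
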