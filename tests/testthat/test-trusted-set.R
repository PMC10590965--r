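toy_matrix <- function(presence, labels, counts = NULL, k = 5) {
  n <- nrow(presence)
  kmers <- rand_canonical_kmers(n, k)
  kmer_sample_matrix(kmers, sprintf("s%d", seq_along(labels)), labels,
                     presence = presence, counts = counts)
}

test_that("matrix construction validates labels, shapes, and canonical rows", {
  set.seed(1)
  expect_error(toy_matrix(matrix(TRUE, 1, 1), "Office"), "unknown environment")
  # alias accepted
  m <- toy_matrix(matrix(TRUE, 1, 1), "Sediment/Soil")
  expect_equal(m$samples$label, "SedimentSoil")
  expect_error(kmer_sample_matrix("AAAAA", c("s1", "s1"),
                                  c("aOral", "Skin"),
                                  presence = matrix(TRUE, 1, 2)),
               "unique")
  # presence/counts coherence
  expect_error(kmer_sample_matrix("AAAAA", "s1", "aOral",
                                  presence = matrix(TRUE, 1, 1),
                                  counts = matrix(0L, 1, 1)),
               "exactly when")
  # a k-mer and its reverse complement collapse to one row
  expect_warning(
    m2 <- kmer_sample_matrix(c("AACGT", "ACGTT"), c("s1", "s2"),
                             c("aOral", "Skin"),
                             presence = matrix(c(TRUE, FALSE, FALSE, TRUE),
                                               2, 2)),
    "merging")
  expect_equal(length(m2$kmers), 1L)
  expect_true(all(m2$presence))
})

test_that("abundance filters: singletons cleared first, then prevalence", {
  set.seed(2)
  # row with counts {s1:1, s2:5, s3:2, s4:1}: singletons leave {s2,s3} -> dropped at min 3
  counts <- matrix(c(1L, 5L, 2L, 1L,
                     2L, 3L, 4L, 0L), nrow = 2, byrow = TRUE)
  m <- toy_matrix(counts >= 1L, c("aOral", "aOral", "mOral", "Skin"),
                  counts = counts)
  f <- trusted_set_filters(min_sample_prevalence = 3)
  out <- apply_abundance_filters(m, f)
  expect_equal(out$kmers, m$kmers[2])
  # below threshold even without singletons
  counts2 <- matrix(c(3L, 4L, 0L, 0L), nrow = 1)
  m2 <- toy_matrix(counts2 >= 1L, c("aOral", "mOral", "Skin", "Skin"),
                   counts = counts2)
  expect_equal(length(apply_abundance_filters(m2, f)$kmers), 0L)
  # identity configuration leaves the matrix unchanged, no counts needed
  m3 <- toy_matrix(matrix(TRUE, 2, 2), c("aOral", "Skin"))
  f0 <- trusted_set_filters(min_sample_prevalence = 1,
                            drop_within_sample_singletons = FALSE)
  expect_equal(apply_abundance_filters(m3, f0)$presence, m3$presence)
  # singleton filter without counts is an explanatory error
  expect_error(apply_abundance_filters(m3, trusted_set_filters()),
               "counts")
})

test_that("subsample_rows honours the cardinality, determinism, and identity contracts", {
  set.seed(3)
  m <- toy_matrix(matrix(TRUE, 1000, 1), "aOral", k = 7)
  s1 <- subsample_rows(m, 0.10, seed = 11)
  s2 <- subsample_rows(m, 0.10, seed = 11)
  s3 <- subsample_rows(m, 0.10, seed = 12)
  expect_equal(length(s1$kmers), 100L)
  expect_true(all(s1$kmers %in% m$kmers))
  expect_identical(s1$kmers, s2$kmers)
  expect_false(identical(s1$kmers, s3$kmers))
  expect_identical(subsample_rows(m, 1)$kmers, m$kmers)
  expect_error(subsample_rows(m, 0), "fraction")
  expect_error(subsample_rows(m, 1.2), "fraction")
})

test_that("select_trusted implements the environment formula", {
  set.seed(4)
  labels <- c("aOral", "mOral", "Skin", "SedimentSoil")
  # present only in aOral -> included; oral + skin -> excluded
  pres <- rbind(c(TRUE, FALSE, FALSE, FALSE),
                c(FALSE, TRUE, TRUE, FALSE))
  m <- toy_matrix(pres, labels)
  got <- select_trusted(m)
  expect_equal(got$kmers, m$kmers[1])
  # no oral column at all is degenerate
  m2 <- toy_matrix(matrix(TRUE, 2, 2), c("Skin", "SedimentSoil"))
  expect_error(select_trusted(m2), "degenerate|no aOral")
})

test_that("select_trusted equals truth-table evaluation on random matrices", {
  set.seed(5)
  for (i in 1:30) {
    ns <- sample(2:6, 1)
    nk <- sample(1:8, 1)
    labels <- sample(ENV_LABELS, ns, replace = TRUE)
    if (!any(labels %in% c("aOral", "mOral"))) labels[1] <- "aOral"
    pres <- matrix(runif(nk * ns) < 0.5, nk, ns)
    m <- toy_matrix(pres, labels, k = 6)
    expect_identical(select_trusted(m)$kmers,
                     m$kmers[ref_select_trusted(m$presence, labels)],
                     info = paste("case", i))
  }
})

test_that("select_trusted is monotone under added columns", {
  set.seed(6)
  labels <- c("aOral", "mOral")
  pres <- matrix(runif(40) < 0.6, 20, 2)
  m <- toy_matrix(pres, labels, k = 6)
  base <- select_trusted(m)$kmers
  # adding a contaminant column can only shrink the set
  skin <- runif(20) < 0.5
  m_skin <- kmer_sample_matrix(m$kmers, c("s1", "s2", "s3"),
                               c(labels, "Skin"),
                               presence = cbind(pres, skin))
  expect_true(all(select_trusted(m_skin)$kmers %in% base))
  # adding an oral column can only grow it
  oral <- runif(20) < 0.5
  m_oral <- kmer_sample_matrix(m$kmers, c("s1", "s2", "s3"),
                               c(labels, "aOral"),
                               presence = cbind(pres, oral))
  expect_true(all(base %in% select_trusted(m_oral)$kmers))
})

test_that("k-mer list round trip canonicalizes, deduplicates, and validates", {
  set.seed(7)
  path <- withr::local_tempfile(fileext = ".txt")
  set <- trusted_kmer_set(rand_canonical_kmers(50, 9))
  write_kmer_list(set, path)
  back <- read_kmer_list(path, kmer_config(9))
  expect_setequal(back$kmers, set$kmers)
  # k-mer plus its reverse complement -> one entry, with a warning
  writeLines(c("AACGT", "ACGTT"), path)
  expect_warning(one <- read_kmer_list(path, kmer_config(5)), "canonical")
  expect_equal(one$kmers, "AACGT")
  # wrong-length line is named
  writeLines(c("AACGT", "ACG"), path)
  expect_error(read_kmer_list(path, kmer_config(5)), "line 2")
  # gzipped round trip
  gz <- withr::local_tempfile(fileext = ".txt.gz")
  write_kmer_list(set, gz)
  expect_setequal(read_kmer_list(gz, kmer_config(9))$kmers, set$kmers)
})

test_that("matrix TSV round trip preserves presence, counts, and labels", {
  set.seed(8)
  counts <- matrix(sample(0:5, 24, replace = TRUE), 6, 4)
  labels <- c("aOral", "mOral", "Skin", "SedimentSoil")
  m <- toy_matrix(counts >= 1L, labels, counts = counts)
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_matrix(m, mp, lp)
  back <- read_kmer_matrix(mp, lp)
  expect_equal(back$kmers, m$kmers)
  expect_equal(unname(back$presence), unname(m$presence))
  expect_equal(unname(back$counts), unname(m$counts))
  expect_equal(back$samples, m$samples)
})

test_that("build_trusted_set runs the pipeline in fixed order", {
  set.seed(9)
  counts <- matrix(sample(c(0L, 1L, 3L), 300 * 4, replace = TRUE,
                          prob = c(.3, .2, .5)), 300, 4)
  m <- toy_matrix(counts >= 1L, c("aOral", "mOral", "Skin", "SedimentSoil"),
                  counts = counts, k = 7)
  f <- trusted_set_filters(min_sample_prevalence = 2,
                           subsample_fraction = 0.5, rng_seed = 99)
  got <- build_trusted_set(m, f)
  # oracle: subsample -> singleton -> prevalence -> formula
  sub <- subsample_rows(m, 0.5, 99)
  cnt <- sub$counts; cnt[cnt == 1L] <- 0L
  keep <- rowSums(cnt >= 1L) >= 2
  sel <- ref_select_trusted((cnt >= 1L)[keep, , drop = FALSE],
                            sub$samples$label)
  expect_setequal(got$kmers, sub$kmers[keep][sel])
})
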