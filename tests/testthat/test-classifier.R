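test_that("anchor detection needs two adjacent matching windows", {
  kcfg <- kmer_config(3)
  trusted <- kmer_set(c("ACG", "CGT"))  # canonicalizes to {ACG}
  # "ACGTA": windows ACG, CGT->ACG both hit at adjacent starts -> anchor
  expect_true(find_anchor("ACGTA", trusted, kcfg))
  # hits only at non-adjacent windows 0 and 4 -> not an anchor
  expect_false(find_anchor("ACGAACG", trusted, kcfg))
  # a single window can never anchor
  expect_false(find_anchor("ACG", trusted, kcfg))
  # N between the two matches breaks consecutiveness
  expect_false(find_anchor("ACGNACG", trusted, kcfg))
})

test_that("anchor k-mer harvesting is a plain set union over anchor reads", {
  kcfg <- kmer_config(3)
  trusted <- kmer_set(c("ACG"))
  reads <- c("ACGTACG", "TTTTTTT", "ACGTA")
  res <- collect_anchor_set(reads, trusted, kcfg)
  expect_equal(res$anchor_flags, c(TRUE, FALSE, TRUE))
  got <- sort(as.character(res$anchors))
  ref <- sort(unique(c(ref_kmers("ACGTACG", 3)$kmer,
                       ref_kmers("ACGTA", 3)$kmer)))
  expect_equal(got, ref)
  # no anchors -> empty set
  none <- collect_anchor_set("TTTTTTT", trusted, kcfg)
  expect_equal(length(none$anchors), 0L)
})

test_that("retention threshold is inclusive and degenerates sensibly", {
  kcfg <- kmer_config(3)
  # read with 4 valid windows, anchor set covering exactly 2 -> proportion 0.5
  read <- "ACGTAC"  # windows: ACG ACG GTA GTA
  anchors <- kmer_set(c("ACG"))
  ann <- classify_read(read, anchors, classifier_config(tau = 0.5), kcfg)
  expect_equal(ann$anchor_proportion, 0.5)
  expect_true(ann$retained)  # >= is inclusive
  # 1 of 4 windows (ACG, CGA, GAA, AAA) -> 0.25, dropped at tau 0.5
  ann2 <- classify_read("ACGAAA", kmer_set("ACG"),
                        classifier_config(0.5), kcfg)
  expect_equal(ann2$anchor_proportion, 0.25)
  expect_false(ann2$retained)
  # empty anchor set: proportion 0 everywhere, nothing retained at tau > 0
  empty <- kmer_set(character(), k = 3)
  ann3 <- classify_read(c("ACGTAC", "TTTT"), empty,
                        classifier_config(0.5), kcfg)
  expect_equal(ann3$anchor_proportion, c(0, 0))
  expect_false(any(ann3$retained))
  # reads with no valid windows have proportion 0
  ann4 <- classify_read("NNNN", anchors, classifier_config(0), kcfg)
  expect_equal(ann4$anchor_proportion, 0)
})

test_that("two-pass run on a hand-built corpus keeps exactly the oral reads", {
  set.seed(10)
  k <- 11
  oral <- rand_dna(300)
  contam <- rand_dna(300)
  trusted <- kmer_set(unique(ref_kmers(oral, k)$kmer))
  reads <- c(substr(oral, 1, 60), substr(oral, 100, 159),
             substr(oral, 200, 259),
             substr(contam, 1, 60), substr(contam, 100, 159),
             substr(contam, 200, 259))
  res <- run_two_pass(as_records(reads), trusted,
                      classifier_config(0.5), kmer_config(k))
  expect_equal(res$annotations$retained, rep(c(TRUE, FALSE), each = 3))
  expect_equal(nrow(res$retained), 3L)
  # annotations align 1:1 with input order
  expect_equal(res$annotations$seq_id, sprintf("r%04d", 1:6))
  # anchor reads retained with their own k-mers all present -> proportion 1
  expect_equal(res$annotations$anchor_proportion[1:3], rep(1, 3))
})

test_that("tau floor retains everything, tau ceiling only fully covered reads", {
  set.seed(11)
  fx <- rand_fixture(n_reads = 40, read_len = 30, k = 9)
  trusted <- kmer_set(fx$trusted, k = fx$k)
  r0 <- run_two_pass(fx$seqs, trusted, classifier_config(0), kmer_config(fx$k))
  expect_true(all(r0$annotations$retained))
  r1 <- run_two_pass(fx$seqs, trusted, classifier_config(1), kmer_config(fx$k))
  expect_true(all(r1$annotations$anchor_proportion[r1$annotations$retained] == 1))
})

test_that("two-pass output equals the brute-force reference on random fixtures", {
  set.seed(12)
  for (i in 1:12) {
    fx <- rand_fixture(n_reads = sample(20:60, 1),
                       read_len = sample(25:50, 1), k = 9)
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    ref <- ref_two_pass(fx$seqs, fx$trusted, fx$k, tau)
    got <- run_two_pass(fx$seqs, kmer_set(fx$trusted, k = fx$k),
                        classifier_config(tau), kmer_config(fx$k))
    expect_equal(got$annotations$is_consecutive_match_found, ref$anchor)
    expect_equal(got$annotations$anchor_proportion, ref$proportion)
    expect_equal(got$annotations$retained, ref$retained)
    expect_equal(sort(as.character(got$anchors)), ref$anchor_set)
  }
})

test_that("one-pass baseline retains exactly the pass-1 anchors", {
  set.seed(13)
  fx <- rand_fixture()
  trusted <- kmer_set(fx$trusted, k = fx$k)
  one <- run_one_pass(fx$seqs, trusted, kmer_config(fx$k))
  flags <- find_anchor(fx$seqs, trusted, kmer_config(fx$k))
  expect_equal(one$annotations$retained, flags)
  expect_equal(one$annotations$anchor_proportion, rep(0, length(fx$seqs)))
  expect_equal(one$retained, fx$seqs[flags])
})

test_that("retention decisions are invariant to input read order", {
  set.seed(14)
  fx <- rand_fixture(n_reads = 50)
  trusted <- kmer_set(fx$trusted, k = fx$k)
  perm <- sample(length(fx$seqs))
  a <- run_two_pass(fx$seqs, trusted, classifier_config(0.5),
                    kmer_config(fx$k))
  b <- run_two_pass(fx$seqs[perm], trusted, classifier_config(0.5),
                    kmer_config(fx$k))
  expect_equal(b$annotations$retained, a$annotations$retained[perm])
  expect_setequal(as.character(b$anchors), as.character(a$anchors))
})

test_that("retained sets are nested as tau grows", {
  set.seed(15)
  fx <- rand_fixture(n_reads = 60)
  trusted <- kmer_set(fx$trusted, k = fx$k)
  ret <- lapply(c(0.1, 0.5, 0.9), function(tau)
    which(run_two_pass(fx$seqs, trusted, classifier_config(tau),
                       kmer_config(fx$k))$annotations$retained))
  expect_true(all(ret[[3]] %in% ret[[2]]))
  expect_true(all(ret[[2]] %in% ret[[1]]))
})

test_that("Bloom-backed pass 1 only ever adds anchors relative to the exact set", {
  set.seed(16)
  for (p in c(0.05, 1e-6)) {
    fx <- rand_fixture(n_reads = 50)
    exact <- kmer_set(fx$trusted, k = fx$k)
    bf <- bf_from_trusted(fx$trusted,
                          bloom_config(length(fx$trusted), p))
    a_exact <- find_anchor(fx$seqs, exact, kmer_config(fx$k))
    a_bf <- find_anchor(fx$seqs, bf, kmer_config(fx$k))
    expect_true(all(a_bf[a_exact]))         # superset, never a lost anchor
    if (p == 1e-6) expect_equal(a_bf, a_exact)  # excess vanishes
  }
})
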