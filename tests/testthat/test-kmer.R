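# An all-N mate contributes no windows, so single_reads() gives single-read
# examples despite the paired container.

test_that("k-mer counting matches hand counts and the window oracle", {
  # read in which CGG occurs twice and AAC/ACG once each
  cat3 <- count_kmers(single_reads("AACGGCGG"), 3, canonical = FALSE)
  counts <- setNames(cat3$counts, cat3$kmers)
  expect_equal(unname(counts[c("CGG", "AAC", "ACG")]), c(2L, 1L, 1L))

  # overlapping identical windows
  catA <- count_kmers(single_reads("AAAA"), 3, canonical = FALSE)
  expect_equal(setNames(catA$counts, catA$kmers), c(AAA = 2L))

  # canonical counting collapses a window with its reverse complement
  catC <- count_kmers(single_reads("ACGTACGT"), 4, canonical = TRUE)
  expect_equal(setNames(catC$counts, catC$kmers),
               c(ACGT = 2L, CGTA = 2L, GTAC = 1L))

  # brute-force oracle on random paired reads, both modes
  set.seed(101)
  rs <- read_set(vapply(rep(50, 20), rand_seq, character(1)),
                 vapply(rep(50, 20), rand_seq, character(1)))
  for (canonical in c(FALSE, TRUE)) {
    k <- 7
    cat <- count_kmers(rs, k, canonical = canonical)
    w <- unlist(lapply(c(rs$fwd, rs$rev), windows_of, k = k))
    if (canonical) {
      rcw <- vapply(w, rc_chr, character(1))
      w <- ifelse(w <= rcw, w, rcw)
    }
    expect_equal(setNames(cat$counts, cat$kmers), c(table(w))[cat$kmers])
    expect_equal(cat$total_occurrences, length(w))
    expect_equal(sum(cat$counts), cat$total_occurrences) # conservation
  }
})

test_that("N-containing windows are skipped, k >= read length errors", {
  cat <- count_kmers(read_set("ACNGT", "AAAAA"), 3, canonical = FALSE)
  expect_false(any(grepl("N", cat$kmers)))
  # every window of the 5 bp mate-1 read spans the N; only mate 2 counts
  expect_equal(cat$total_occurrences, 3)
  expect_error(count_kmers(read_set("ACGT", "ACGT"), 4),
               class = "parameter_error")
})

test_that("canonical catalogs are invariant under reverse-complementing reads", {
  set.seed(7)
  fwd <- vapply(rep(60, 10), rand_seq, character(1))
  rev <- vapply(rep(60, 10), rand_seq, character(1))
  a <- count_kmers(read_set(fwd, rev), 9, canonical = TRUE)
  b <- count_kmers(read_set(vapply(fwd, rc_chr, character(1)),
                            vapply(rev, rc_chr, character(1))), 9,
                   canonical = TRUE)
  expect_equal(a$kmers, b$kmers)
  expect_equal(a$counts, b$counts)
})

test_that("average frequency is the mean over distinct k-mers", {
  cat <- count_kmers(single_reads("AAAA"), 3, canonical = FALSE)
  expect_equal(average_frequency(cat), 2)
  set.seed(3)
  rs <- read_set(vapply(rep(100, 100), rand_seq, character(1)),
                 vapply(rep(100, 100), rand_seq, character(1)))
  cat29 <- count_kmers(rs, 29)
  expect_equal(average_frequency(cat29),
               sum(cat29$counts) / length(cat29$counts))
  empty <- count_kmers(read_set("NNNN", "NNNN"), 3)
  expect_error(average_frequency(empty), class = "degenerate_input_error")
})

test_that("frequent selection uses a strict cutoff and is monotone in f_K", {
  # 99 distinct k-mers of count 1 plus one of count 101: average 2
  cat <- structure(list(k = 5,
                        kmers = c(sprintf("K%04d", 1:99), "X"),
                        counts = c(rep(1L, 99), 101L),
                        total_occurrences = 200, distinct_count = 100,
                        canonical = TRUE, n_bases = NA_real_),
                   class = "kmer_catalog")
  expect_equal(names(select_frequent(cat, 10)), "X") # 101 > 20
  expect_length(select_frequent(cat, 1000), 0)       # cutoff above max count
  expect_equal(length(select_frequent(cat, 0)), 100) # f_K = 0 keeps all
  # strictness at the boundary: count == cutoff is not frequent
  cat3 <- structure(list(k = 3, kmers = c("AAA", "CCC"), counts = c(2L, 4L),
                         total_occurrences = 6, distinct_count = 2,
                         canonical = TRUE, n_bases = NA_real_),
                    class = "kmer_catalog")
  expect_equal(average_frequency(cat3), 3)
  expect_length(select_frequent(cat3, 4 / 3), 0) # 4 > 4 is false (strict)
  # monotonicity over random catalogs
  set.seed(19)
  for (i in 1:10) {
    rs <- read_set(rand_seq(200), rand_seq(200))
    cc <- count_kmers(rs, 5)
    sizes <- vapply(c(0, 0.5, 1, 2, 5, 10),
                    function(f) length(select_frequent(cc, f)), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("frequency bins are geometric, overlapping, and cover all members", {
  cfg <- pipeline_config()
  one <- make_frequency_bins(c(A = 40L), cfg)
  expect_equal(one[[1]]$target, 40)
  expect_equal(c(one[[1]]$low, one[[1]]$high), c(8, 200))
  expect_equal(names(one[[1]]$members), "A")

  b <- make_frequency_bins(c(a = 40L, b = 25L, c = 12L), cfg)
  expect_equal(vapply(b, `[[`, numeric(1), "target")[1:3], c(40, 20, 10))
  # membership equals the exhaustive interval test; k-mer 25 in bins 1 and 2
  counts <- c(a = 40, b = 25, c = 12)
  for (bin in b)
    expect_equal(sort(names(bin$members)),
                 sort(names(counts)[counts >= bin$low & counts <= bin$high]))
  expect_true("b" %in% names(b[[1]]$members) && "b" %in% names(b[[2]]$members))

  # union of bins covers the frequent set for random count vectors
  set.seed(23)
  for (i in 1:20) {
    counts <- setNames(sample.int(5000, 30), sprintf("m%02d", 1:30))
    bins <- make_frequency_bins(counts, cfg)
    expect_setequal(unique(unlist(lapply(bins, function(x) names(x$members)))),
                    names(counts))
    targets <- vapply(bins, `[[`, numeric(1), "target")
    expect_true(all(abs(diff(log(targets)) + log(cfg$bin_ratio)) < 1e-9))
  }
  expect_error(make_frequency_bins(integer(0), cfg),
               class = "degenerate_input_error")
})

test_that("k-mer tables round-trip through the TSV interchange format", {
  d <- withr::local_tempdir()
  rs <- single_reads("AACGGCGGTT")
  cat <- count_kmers(rs, 3, canonical = FALSE)
  p <- file.path(d, "kmers.tsv")
  write_kmer_table(cat, p)
  back <- read_kmer_table(p, canonical = FALSE)
  expect_equal(back$kmers, cat$kmers)
  expect_equal(back$counts, cat$counts)
  expect_equal(back$k, 3L)
})
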