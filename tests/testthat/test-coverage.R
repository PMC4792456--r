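mk_pl <- function(contig, start, end, pair = seq_along(start)) {
  n <- length(start)
  data.frame(pair = pair, mate = rep(1L, n), contig = contig, start = start,
             end = end, strand = rep("+", n), edits = rep(0L, n),
             stringsAsFactors = FALSE)
}

cfgc <- pipeline_config()

test_that("per-base coverage counts placements and conserves aligned bases", {
  ctg <- data.frame(id = "c1", sequence = strrep("A", 100), length = 100,
                    stringsAsFactors = FALSE)
  # no placements: all zeros
  p0 <- profile_coverage(mk_pl(character(0), integer(0), integer(0)), ctg)
  expect_equal(p0$per_base, rep(0L, 100))
  expect_equal(p0$mean, 0)
  # one full-length read: all ones
  p1 <- profile_coverage(mk_pl("c1", 1L, 100L), ctg)
  expect_equal(p1$per_base, rep(1L, 100))
  # random placements on a 50 bp contig: sum(depth) == sum(span lengths)
  set.seed(131)
  ctg50 <- data.frame(id = "c1", sequence = strrep("A", 50), length = 50,
                      stringsAsFactors = FALSE)
  for (i in 1:10) {
    st <- sample(1:40, 20, replace = TRUE)
    en <- pmin(st + sample(5:20, 20, replace = TRUE), 50L)
    pr <- profile_coverage(mk_pl("c1", st, en), ctg50)
    expect_equal(sum(pr$per_base), sum(en - st + 1))
  }
  # out-of-bounds placements are an internal error
  expect_error(profile_coverage(mk_pl("c1", 40L, 60L), ctg50),
               class = "internal_error")
})

test_that("coverage filtering discards, keeps, and truncates per the rules", {
  ctg <- function(len) data.frame(id = "c1", sequence = rand_seq(len),
                                  length = len, stringsAsFactors = FALSE)
  set.seed(137)
  # zero mapped reads: discarded
  c200 <- ctg(200)
  prof0 <- profile_coverage(mk_pl(character(0), integer(0), integer(0)), c200)
  expect_equal(nrow(filter_contig(c200, prof0, cfgc)), 0L)
  # uniform coverage 10: kept unchanged
  prof10 <- list(id = "c1", per_base = rep(10L, 200), mean = 10)
  expect_equal(filter_contig(c200, prof10, cfgc)$sequence, c200$sequence)
  # coverage 10 on [1,120], 0 after, min run 49: truncated to bases 1..120
  prof <- list(id = "c1", per_base = c(rep(10L, 120), rep(0L, 80)), mean = 6)
  out <- filter_contig(c200, prof, cfgc, min_run = 49)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, substr(c200$sequence, 1, 120))
  # a qualifying run shorter than the minimum is not emitted
  profshort <- list(id = "c1", per_base = c(rep(10L, 30), rep(0L, 170)),
                    mean = 2.0)
  expect_equal(nrow(filter_contig(c200, profshort, cfgc, min_run = 49)), 0L)
  # two separated high-coverage runs split the contig
  prof2 <- list(id = "c1",
                per_base = c(rep(9L, 60), rep(0L, 40), rep(7L, 100)),
                mean = (9 * 60 + 7 * 100) / 200)
  out2 <- filter_contig(c200, prof2, cfgc, min_run = 49)
  expect_equal(out2$sequence,
               c(substr(c200$sequence, 1, 60), substr(c200$sequence, 101, 200)))
  expect_equal(out2$id, c("c1.1", "c1.2"))
})

test_that("filtering is idempotent and monotone in the coverage threshold", {
  set.seed(139)
  genome <- rand_seq(4000)
  ctg <- data.frame(id = c("real", "junk"),
                    sequence = c(substr(genome, 1001, 1400), rand_seq(400)),
                    length = 400L, stringsAsFactors = FALSE)
  sim <- simulate_reads(list(genome = genome), depth = 12, read_length = 100,
                        insert_mean = 300, insert_sd = 30, error_rate = 0,
                        seed = 23)
  out1 <- filter_contigs(ctg, sim$reads, cfgc)
  expect_equal(out1$id, "real")             # decoy discarded
  out2 <- filter_contigs(out1, sim$reads, cfgc)
  expect_equal(out2$sequence, out1$sequence) # idempotent
  # raising the threshold never lengthens any retained contig
  lens1 <- sum(out1$length)
  for (thr in c(4, 8, 20, 50)) {
    cfg_hi <- pipeline_config(min_avg_coverage = thr)
    lo <- filter_contigs(ctg, sim$reads, cfg_hi)
    expect_lte(sum(lo$length), lens1)
    lens1 <- sum(lo$length)
  }
})

test_that("merged repeats are re-validated and chimeric junctions are split", {
  set.seed(149)
  genome <- rand_seq(3000)
  # a genuine repeat region and a chimera gluing two distant regions
  real <- substr(genome, 501, 900)
  chimera <- paste0(substr(genome, 1201, 1500), substr(genome, 2201, 2500))
  reps <- data.frame(id = c("rep_1", "rep_2"),
                     sequence = c(real, chimera),
                     length = c(400L, 600L), n_contigs = c(1L, 2L),
                     mean_coverage = NA_real_, stringsAsFactors = FALSE)
  reps$path <- list("a", c("b", "c"))
  reps$junctions <- list(integer(0), 30L)
  class(reps) <- c("assembled_repeats", "data.frame")
  sim <- simulate_reads(list(genome = genome), depth = 15, read_length = 100,
                        insert_mean = 300, insert_sd = 30, error_rate = 0,
                        seed = 29)
  # withhold reads near the glued ends so the chimeric junction has no
  # coverage at all (clipped placements would otherwise still cover it)
  tr <- sim$placements
  zones <- rbind(c(1461, 1520), c(2181, 2240))
  m1 <- cbind(tr$frag_start, tr$frag_start + 99L)
  m2 <- cbind(tr$frag_start + tr$frag_len - 100L, tr$frag_start + tr$frag_len - 1L)
  hits_zone <- function(iv) Reduce(`|`, lapply(seq_len(nrow(zones)), function(z)
    iv[, 1] <= zones[z, 2] & iv[, 2] >= zones[z, 1]))
  keep_pair <- !(hits_zone(m1) | hits_zone(m2))
  reads <- read_set(sim$reads$fwd[keep_pair], sim$reads$rev[keep_pair])
  ann <- annotate_repeats(reps, reads, cfgc)
  # the real repeat survives whole with mean coverage near the depth
  real_row <- ann[ann$sequence == real, ]
  expect_equal(nrow(real_row), 1L)
  expect_gt(real_row$mean_coverage, 8)
  # no surviving piece still spans the chimeric junction
  junction_probe <- substr(chimera, 281, 320)
  expect_false(any(grepl(junction_probe, ann$sequence, fixed = TRUE)))
  # pieces of the chimera's two halves may survive individually
  expect_true(all(ann$mean_coverage >= cfgc$min_avg_coverage | ann$length == 0))
  # empty repeat list passes through
  empty <- reps[0, ]
  class(empty) <- c("assembled_repeats", "data.frame")
  expect_equal(nrow(annotate_repeats(empty, sim$reads, cfgc)), 0L)
})
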