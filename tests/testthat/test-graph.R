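cfg_default <- pipeline_config()

test_that("candidate pairing by shared k0-mers matches the all-pairs scan", {
  mk <- function(seqs) data.frame(id = sprintf("c%02d", seq_along(seqs)),
                                  sequence = seqs, length = nchar(seqs),
                                  stringsAsFactors = FALSE)
  # zero shared 5-mers
  expect_equal(nrow(candidate_pairs(mk(c("AAAAAAAA", "CCCCCCCC")), 5)), 0L)
  # shared AAAAA reported in both orders
  cp <- candidate_pairs(mk(c("AAAAACTG", "CTGAAAAA")), 5)
  expect_setequal(paste(cp$source, cp$target), c("c01 c02", "c02 c01"))
  # oracle equivalence on 30 random contigs
  set.seed(61)
  ctg <- mk(replicate(30, rand_seq(60)))
  cp <- candidate_pairs(ctg, 5)
  got <- sort(paste(cp$source, cp$target))
  kset <- lapply(ctg$sequence, function(s)
    unique(c(windows_of(s, 5), windows_of(rc_chr(s), 5))))
  want <- character(0)
  for (i in 1:30) for (j in 1:30) {
    if (i != j && length(intersect(kset[[i]], kset[[j]])))
      want <- c(want, paste(ctg$id[i], ctg$id[j]))
  }
  expect_equal(got, sort(want))
})

test_that("overlap thresholds are boundary-exact", {
  s14 <- "ACGTGACTGACTGA"
  a14 <- paste0(strrep("T", 30), s14)
  b14 <- paste0(s14, strrep("C", 30))
  # a 14 bp exact overlap is below the 15 bp default
  expect_null(compute_overlap(a14, b14, cfg_default, orientation = "forward"))
  expect_equal(oracle_overlap(a14, b14, 15, 0.05)[["len"]], 0)
  # identical sequences: full overlap, zero mismatches
  set.seed(67)
  s30 <- rand_seq(30)
  ov <- compute_overlap(s30, s30, cfg_default, orientation = "forward")
  expect_equal(ov$length, 30)
  expect_equal(ov$mismatches, 0)
  # exactly one substitution in a 20 bp overlap: 1/20 is not < 0.05
  p20 <- "ACGTGACTGACTGAGGTCAT"
  p20mut <- p20
  substr(p20mut, 10, 10) <- if (substr(p20, 10, 10) == "A") "C" else "A"
  a20 <- paste0(strrep("T", 30), p20mut)
  b20 <- paste0(p20, strrep("C", 30))
  expect_null(compute_overlap(a20, b20, cfg_default, orientation = "forward"))
  # ... but it qualifies at a laxer rate, and then reports 1 mismatch
  lax <- pipeline_config(max_mismatch_rate = 0.08)
  ov2 <- compute_overlap(a20, b20, lax, orientation = "forward")
  expect_equal(ov2$length, 20)
  expect_equal(ov2$mismatches, 1)
})

test_that("overlap DP agrees with the adist-based oracle on random pairs", {
  set.seed(71)
  n_ok <- 0
  for (i in 1:100) {
    la <- sample(30:60, 1); lb <- sample(30:60, 1)
    if (i %% 2 == 0) { # plant a noisy suffix-prefix overlap
      ovl <- sample(10:25, 1)
      core <- rand_seq(ovl)
      noisy <- core
      if (runif(1) < 0.5) { # one substitution
        p <- sample(ovl, 1)
        substr(noisy, p, p) <- sample(setdiff(DNA4, substr(core, p, p)), 1)
      }
      a <- paste0(rand_seq(la), noisy)
      b <- paste0(core, rand_seq(lb))
    } else {
      a <- rand_seq(la); b <- rand_seq(lb)
    }
    want <- oracle_overlap(a, b, 15, 0.05)
    got <- compute_overlap(a, b, cfg_default, orientation = "forward")
    if (want[["len"]] == 0) {
      expect_null(got)
    } else {
      n_ok <- n_ok + 1
      expect_equal(got$length, unname(want[["len"]]))
      expect_equal(got$mismatches, unname(want[["edits"]]))
    }
  }
  expect_gt(n_ok, 10) # the case mix exercised real overlaps
})

test_that("exact overlaps are antisymmetric under reverse complement", {
  set.seed(73)
  for (i in 1:10) {
    core <- rand_seq(sample(16:28, 1))
    a <- paste0(rand_seq(35), core)
    b <- paste0(core, rand_seq(35))
    f <- compute_overlap(a, b, cfg_default, orientation = "forward")
    r <- compute_overlap(rc_chr(b), rc_chr(a), cfg_default,
                         orientation = "forward")
    expect_equal(f$length, nchar(core))
    expect_equal(r$length, f$length)
    expect_equal(r$mismatches, 0)
  }
})

test_that("overlap qualification is monotone in both thresholds", {
  set.seed(79)
  for (i in 1:20) {
    core <- rand_seq(sample(12:30, 1))
    p <- sample(nchar(core), 1)
    noisy <- core
    substr(noisy, p, p) <- sample(setdiff(DNA4, substr(core, p, p)), 1)
    a <- paste0(rand_seq(40), noisy); b <- paste0(core, rand_seq(40))
    quals <- outer(c(10, 15, 20, 25), c(0.10, 0.05, 0.02),
                   Vectorize(function(mo, mr) {
                     cfg <- pipeline_config(min_overlap_bp = mo,
                                            max_mismatch_rate = mr)
                     !is.null(compute_overlap(a, b, cfg, orientation = "forward"))
                   }))
    # raising min_overlap (down rows) or shrinking the rate (across cols)
    # can only lose the edge
    expect_true(all(apply(quals, 2, function(x) all(diff(x) <= 0))))
    expect_true(all(apply(quals, 1, function(x) all(diff(x) <= 0))))
  }
})

test_that("the seed-and-extend mapper recovers exact and simulated placements", {
  set.seed(83)
  ctg <- data.frame(id = "ctgA", sequence = rand_seq(200), length = 200,
                    stringsAsFactors = FALSE)
  rd <- substr(ctg$sequence, 51, 150)
  pl <- map_reads_to_contigs(single_reads(rd), ctg, cfg_default)
  pl <- pl[pl$mate == 1L, ]
  expect_equal(nrow(pl), 1L)
  expect_equal(c(pl$start, pl$end), c(51L, 150L))
  expect_equal(pl$strand, "+")
  expect_equal(pl$edits, 0L)
  # no shared seed, no placement
  miss <- map_reads_to_contigs(single_reads(rand_seq(100)), ctg, cfg_default)
  expect_equal(nrow(miss[miss$mate == 1L, ]), 0L)

  # 200 error-free simulated pairs recover the simulator's truth table
  genome <- rand_seq(2000)
  sim <- simulate_reads(list(genome = genome), depth = 20, read_length = 100,
                        insert_mean = 300, insert_sd = 30, error_rate = 0,
                        seed = 5)
  expect_equal(length(sim$reads), 200L) # round(20 * 2000 / 200)
  gctg <- data.frame(id = "g", sequence = genome, length = 2000,
                     stringsAsFactors = FALSE)
  pl <- map_reads_to_contigs(sim$reads, gctg, cfg_default)
  tr <- sim$placements
  want1 <- data.frame(pair = tr$pair, mate = 1L, contig = "g",
                      start = tr$frag_start, end = tr$frag_start + 99L,
                      strand = "+", edits = 0L, stringsAsFactors = FALSE)
  want2 <- data.frame(pair = tr$pair, mate = 2L, contig = "g",
                      start = tr$frag_start + tr$frag_len - 100L,
                      end = tr$frag_start + tr$frag_len - 1L,
                      strand = "-", edits = 0L, stringsAsFactors = FALSE)
  want <- rbind(want1, want2)
  key <- function(d) sort(do.call(paste, d))
  expect_true(all(key(want) %in% key(pl[names(want)])))
})

test_that("read-pair support counts straddling pairs and knows when to expect them", {
  empty_pl <- data.frame(pair = integer(0), mate = integer(0),
                         contig = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         edits = integer(0), stringsAsFactors = FALSE)
  v1 <- data.frame(id = "A", length = 400); v2 <- data.frame(id = "B", length = 400)
  ps <- pair_support(v1, v2, list(length = 30), empty_pl, cfg_default)
  expect_true(ps$expected)
  expect_equal(ps$support, 0L)
  # merged contig shorter than a read: no straddling geometry
  s1 <- data.frame(id = "A", length = 60); s2 <- data.frame(id = "B", length = 60)
  ps2 <- pair_support(s1, s2, list(length = 30), empty_pl, cfg_default)
  expect_false(ps2$expected)

  # simulated junction: support equals the truth-derived straddling count
  set.seed(89)
  genome <- paste0(rand_seq(300), rand_seq(400), rand_seq(300))
  rangeA <- c(301, 470); rangeB <- c(441, 610) # 30 bp true overlap
  ctg <- data.frame(id = c("A", "B"),
                    sequence = c(substr(genome, rangeA[1], rangeA[2]),
                                 substr(genome, rangeB[1], rangeB[2])),
                    stringsAsFactors = FALSE)
  ctg$length <- nchar(ctg$sequence)
  sim <- simulate_reads(list(genome = genome), depth = 30, read_length = 100,
                        insert_mean = 300, insert_sd = 30, error_rate = 0,
                        seed = 13)
  pl <- map_reads_to_contigs(sim$reads, ctg, cfg_default)
  got <- pair_support(ctg[1, ], ctg[2, ], list(length = 30), pl, cfg_default)
  expect_true(got$expected)

  ## oracle: clip each mate's true interval to each contig (>= 20 bases kept,
  ## matching the mapper's minimum span), then apply the same span and
  ## orientation window in merged coordinates (= genome coords - 300)
  clip <- function(lo, hi, r) c(max(lo, r[1]), min(hi, r[2]))
  n_true <- 0L
  for (i in seq_len(nrow(sim$placements))) {
    s <- sim$placements$frag_start[i]; F <- sim$placements$frag_len[i]
    mates <- list(`+` = c(s, s + 99), `-` = c(s + F - 100, s + F - 1))
    hitA <- hitB <- list()
    for (st in c("+", "-")) {
      cA <- clip(mates[[st]][1], mates[[st]][2], rangeA)
      cB <- clip(mates[[st]][1], mates[[st]][2], rangeB)
      if (cA[2] - cA[1] + 1 >= 20) hitA[[st]] <- cA
      if (cB[2] - cB[1] + 1 >= 20) hitB[[st]] <- cB
    }
    found <- FALSE
    for (sa in names(hitA)) for (sb in names(hitB)) {
      if (sa == sb) next
      pa <- hitA[[sa]]; pb <- hitB[[sb]]
      span <- max(pa[2], pb[2]) - min(pa[1], pb[1]) + 1
      left_strand <- if (pa[1] <= pb[1]) sa else sb
      if (left_strand == "+" && span >= 210 && span <= 390) found <- TRUE
    }
    if (found) n_true <- n_true + 1L
  }
  expect_equal(got$support, n_true)
  expect_gt(got$support, 0L)
})

test_that("graph construction recovers a tiled repeat and drops unsupported edges", {
  set.seed(97)
  genome <- paste0(rand_seq(300), rand_seq(400), rand_seq(300))
  ctg <- data.frame(id = c("A", "B", "C"),
                    sequence = c(substr(genome, 301, 470),
                                 substr(genome, 441, 610),
                                 substr(genome, 581, 700)),
                    stringsAsFactors = FALSE)
  ctg$length <- nchar(ctg$sequence)
  sim <- simulate_reads(list(genome = genome), depth = 30, read_length = 100,
                        insert_mean = 300, insert_sd = 30, error_rate = 0,
                        seed = 17)
  g <- build_graph(ctg, sim$reads, cfg_default)
  ekey <- paste(g$edges$source, g$edges$target)
  expect_true(all(c("A B", "B C") %in% ekey))
  expect_false(any(c("B A", "C B") %in% ekey))
  expect_equal(g$edges$length[match("A B", ekey)], 30L)
  expect_equal(g$edges$mismatches[match("A B", ekey)], 0L)

  # same contigs, reads withheld: junction support is expected but absent
  no_reads <- read_set(character(0), character(0), read_length = 100)
  g0 <- build_graph(ctg, no_reads, cfg_default)
  expect_equal(nrow(g0$edges), 0L)

  # contigs with no qualifying overlaps give an edgeless graph
  set.seed(98)
  iso <- data.frame(id = c("X", "Y"),
                    sequence = c(strrep("ACGTG", 12), strrep("TTGCA", 12)),
                    stringsAsFactors = FALSE)
  iso$length <- nchar(iso$sequence)
  g2 <- build_graph(iso, no_reads, cfg_default)
  expect_equal(nrow(g2$edges), 0L)
})
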