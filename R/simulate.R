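## Synthetic data: background genomes with planted repeat families and
## paired-end reads with fully recorded ground truth. Uniform base
## composition and i.i.d. errors — the simplest model that exercises the
## assembly algorithmics.

DNA <- c("A", "C", "G", "T")

#' Specify a planted repeat family
#'
#' @param length Consensus length (bp).
#' @param copies Copy number to plant.
#' @param divergence Expected per-base substitution rate of each copy
#'   relative to the consensus (in `[0, 0.5)`).
#' @param indel_rate Expected per-base single-base indel rate (in `[0, 0.5)`).
#' @param divergence_profile Optional per-base substitution-rate vector of
#'   `length` entries, overriding `divergence` position by position — used to
#'   emulate repeats whose internal block diverged more than the flanks.
#' @param name Family name (defaults to `famN` when planted).
#' @return A `repeat_family` spec.
#' @export
repeat_family <- function(length, copies, divergence = 0, indel_rate = 0,
                          divergence_profile = NULL, name = NULL) {
  if (divergence < 0 || divergence >= 0.5 || indel_rate < 0 || indel_rate >= 0.5)
    rf_stop("divergence and indel_rate must lie in [0, 0.5)", "parameter_error")
  if (!is.null(divergence_profile) && base::length(divergence_profile) != length)
    rf_stop("divergence_profile must have one rate per consensus base",
            "parameter_error")
  structure(list(length = as.integer(length), copies = as.integer(copies),
                 divergence = divergence, indel_rate = indel_rate,
                 divergence_profile = divergence_profile, name = name),
            class = "repeat_family")
}

## internal: mutate one copy of a consensus
mutate_copy <- function(bases, profile, indel_rate) {
  L <- length(bases)
  sub_pos <- which(stats::runif(L) < profile)
  if (length(sub_pos))
    bases[sub_pos] <- vapply(sub_pos, function(i)
      sample(setdiff(DNA, bases[i]), 1L), character(1))
  n_indel <- 0L
  if (indel_rate > 0) {
    idx <- which(stats::runif(L) < indel_rate)
    n_indel <- length(idx)
    if (n_indel) {
      keep <- rep(TRUE, L)
      ins_after <- character(L)
      for (i in idx) {
        if (stats::runif(1) < 0.5) keep[i] <- FALSE
        else ins_after[i] <- sample(DNA, 1L)
      }
      seq <- paste0(paste0(ifelse(keep, bases, ""), c(ins_after)), collapse = "")
      return(list(seq = seq, n_sub = length(sub_pos), n_indel = n_indel))
    }
  }
  list(seq = paste0(bases, collapse = ""), n_sub = length(sub_pos),
       n_indel = n_indel)
}

#' Generate a synthetic genome with planted repeat families
#'
#' Draws an i.i.d. uniform background sequence, then for each family draws a
#' random consensus, mutates it per copy (substitutions and single-base
#' indels at the stated rates), and plants the copies at non-overlapping
#' uniform positions on random strands (copies replace background segments of
#' the same length, so the genome length equals `background_length`). All
#' ground truth is recorded.
#'
#' @param background_length Genome length (bp).
#' @param families List of [repeat_family()] specs (may be empty).
#' @param seed RNG seed.
#' @return Object of class `sim_truth`: list with `genome` (character),
#'   `consensi` (named character), `copies` (data frame: `family`, `copy`,
#'   `start`, `end`, `strand`, `n_sub`, `n_indel`), `seed`.
#' @export
generate_genome <- function(background_length, families = list(), seed = 42L) {
  set.seed(seed)
  background_length <- as.integer(background_length)
  if (inherits(families, "repeat_family")) families <- list(families)
  planted <- sum(vapply(families, function(f) f$length * f$copies, numeric(1)))
  if (length(families) && planted >= background_length)
    rf_stop("total planted length must be smaller than the background length",
            "capacity_error")
  genome <- sample(DNA, background_length, replace = TRUE)
  consensi <- character(0)
  copies <- data.frame(family = character(0), copy = integer(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), n_sub = integer(0),
                       n_indel = integer(0), stringsAsFactors = FALSE)
  occupied_s <- integer(0); occupied_e <- integer(0)
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    nm <- if (is.null(fam$name)) sprintf("fam%d", fi) else fam$name
    cons <- sample(DNA, fam$length, replace = TRUE)
    consensi[nm] <- paste0(cons, collapse = "")
    profile <- if (is.null(fam$divergence_profile))
      rep(fam$divergence, fam$length) else fam$divergence_profile
    for (ci in seq_len(fam$copies)) {
      mc <- mutate_copy(cons, profile, fam$indel_rate)
      li <- nchar(mc$seq)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample.int(background_length - li + 1L, 1L)
        e <- s + li - 1L
        if (!any(s <= occupied_e & e >= occupied_s)) { placed <- TRUE; break }
      }
      if (!placed)
        rf_stop("cannot place all repeat copies without overlap", "capacity_error")
      strand <- sample(c("+", "-"), 1L)
      placed_seq <- if (strand == "+") mc$seq else revcomp(mc$seq)
      genome[s:e] <- strsplit(placed_seq, "")[[1]]
      occupied_s <- c(occupied_s, s); occupied_e <- c(occupied_e, e)
      copies <- rbind(copies, data.frame(
        family = nm, copy = ci, start = s, end = e, strand = strand,
        n_sub = mc$n_sub, n_indel = mc$n_indel, stringsAsFactors = FALSE))
    }
  }
  structure(list(genome = paste0(genome, collapse = ""),
                 consensi = consensi, copies = copies, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nchar(x$genome), "bp genome,",
      length(x$consensi), "repeat families,", nrow(x$copies), "planted copies\n")
  invisible(x)
}

## internal: inject substitution errors into one read
inject_errors <- function(s, pos) {
  b <- strsplit(s, "")[[1]]
  b[pos] <- vapply(pos, function(i) sample(setdiff(DNA, b[i]), 1L), character(1))
  paste0(b, collapse = "")
}

#' Simulate paired-end reads from a synthetic genome
#'
#' The number of pairs is `round(depth * genome_length / (2 * read_length))`.
#' Fragment lengths are normal (`insert_mean`, `insert_sd`, floored at the
#' read length), fragment starts uniform; mate 1 is the fragment 5' end,
#' mate 2 the reverse complement of the fragment 3' end. Base errors are
#' i.i.d. substitutions at `error_rate`. Every placement and every error
#' position is recorded in the returned truth table.
#'
#' @param truth A `sim_truth` from [generate_genome()].
#' @param depth Mean per-base sequencing depth.
#' @param read_length Read length (bp).
#' @param insert_mean,insert_sd Fragment (outer insert) length distribution.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return List with `reads` (a [read_set()]) and `placements` (data frame:
#'   `pair`, `frag_start`, `frag_len`; mate 1 covers
#'   `[frag_start, frag_start + read_length - 1]` forward, mate 2 covers
#'   `[frag_start + frag_len - read_length, frag_start + frag_len - 1]`
#'   reverse; `err1`, `err2` are list columns of error positions in read
#'   coordinates).
#' @export
simulate_reads <- function(truth, depth, read_length = 100L,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0, seed = 42L) {
  set.seed(seed)
  if (insert_mean <= read_length)
    rf_stop("insert_mean must exceed read_length", "parameter_error")
  G <- nchar(truth$genome)
  n <- round(depth * G / (2 * read_length))
  frag <- pmin(pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                    read_length), G)
  start <- vapply(G - frag + 1L, function(m) sample.int(m, 1L), integer(1))
  m1 <- substring(truth$genome, start, start + read_length - 1L)
  m2 <- revcomp(substring(truth$genome, start + frag - read_length,
                          start + frag - 1L))
  ne1 <- stats::rbinom(n, read_length, error_rate)
  ne2 <- stats::rbinom(n, read_length, error_rate)
  err1 <- vector("list", n); err2 <- vector("list", n)
  for (i in which(ne1 > 0L)) {
    err1[[i]] <- sort(sample.int(read_length, ne1[i]))
    m1[i] <- inject_errors(m1[i], err1[[i]])
  }
  for (i in which(ne2 > 0L)) {
    err2[[i]] <- sort(sample.int(read_length, ne2[i]))
    m2[i] <- inject_errors(m2[i], err2[[i]])
  }
  placements <- data.frame(pair = seq_len(n), frag_start = start,
                           frag_len = frag)
  placements$err1 <- err1
  placements$err2 <- err2
  list(reads = read_set(m1, m2, read_length, source = "simulated"),
       placements = placements)
}

#' Write a simulated data set to disk
#'
#' Writes the genome (FASTA), the reads (two split FASTQ files, constant
#' quality), the family consensus sequences (FASTA), and the copy/read truth
#' tables (TSV) into a directory.
#'
#' @param truth A `sim_truth`.
#' @param sim Result of [simulate_reads()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(truth, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- Biostrings::DNAStringSet(stats::setNames(truth$genome, "genome"))
  Biostrings::writeXStringSet(gen, file.path(out_dir, "genome.fasta"), width = 60L)
  if (length(truth$consensi))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(truth$consensi),
                                file.path(out_dir, "consensi.fasta"), width = 60L)
  qual <- strrep("I", sim$reads$read_length)
  for (mate in 1:2) {
    seqs <- if (mate == 1L) sim$reads$fwd else sim$reads$rev
    lines <- as.vector(rbind(sprintf("@pair%d/%d", seq_along(seqs), mate),
                             seqs, "+", qual))
    writeLines(lines, file.path(out_dir, sprintf("reads_%d.fastq", mate)))
  }
  utils::write.table(truth$copies, file.path(out_dir, "copies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$placements[, c("pair", "frag_start", "frag_len")],
                     file.path(out_dir, "fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
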